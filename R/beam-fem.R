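#' Discretize a wire into a clamped space-frame beam model
#'
#' Splits the wire centerline into 2-node space-frame elements (axial EA,
#' torsion GJ, two-plane Euler-Bernoulli bending EI; 6 DOF per node).
#' Nodes are placed at uniform arc-length intervals no longer than
#' `max_element_length`, plus exactly at any requested `stations` so loads
#' can be applied at nodes. Both end nodes are fully clamped when solved.
#'
#' Internally the solver works in N and mm, so E and G are converted from
#' Pa to MPa (N/mm^2) and the reported stiffnesses come out in N/mm.
#'
#' @param path a [wire_path()].
#' @param max_element_length maximum element arc length, mm (default 1, the
#'   mesh size used for the wire model).
#' @param stations arc-length positions (mm) that must coincide with nodes.
#' @param section_diameter wire diameter, mm (default 0.3556 = 0.014 in).
#' @param mat a [material()] (default the nitinol preset).
#' @return A `beam_model`: list with `nodes` (tibble `s_mm, x, y, z`),
#'   `elements` (tibble `n1, n2, length_mm`), section constants
#'   `A, I, J` (mm^2, mm^4), `E, G` (MPa), and the source `path`.
#' @export
discretize <- function(path, max_element_length = 1, stations = NULL,
                       section_diameter = 0.3556,
                       mat = material_preset("nitinol")) {
  stopifnot(inherits(path, "wire_path"))
  if (max_element_length <= 0) {
    abort("`max_element_length` must be positive.", class = "archforce_invalid_parameter")
  }
  L <- path$total_length
  if (L < max_element_length) {
    abort("wire shorter than one element.", class = "archforce_discretization_error")
  }
  if (!is.null(stations) && any(stations < 0 | stations > L)) {
    abort("stations outside the wire span.", class = "archforce_invalid_parameter")
  }
  # Stations are accommodated by snapping the nearest interior grid node to
  # the station (a slightly finer base grid keeps every element within the
  # requested size). Inserting extra nodes instead would create sliver
  # elements whose 1/L^3 bending stiffness ruins the conditioning.
  n_el <- if (is.null(stations)) ceiling(L / max_element_length) else
    ceiling(1.5 * L / max_element_length)
  s <- seq(0, L, length.out = n_el + 1)
  if (!is.null(stations)) {
    taken <- c(1L, length(s))          # clamped ends stay put
    for (st in sort(stations)) {
      free_i <- setdiff(seq_along(s), taken)
      i <- free_i[which.min(abs(s[free_i] - st))]
      s[i] <- st
      taken <- c(taken, i)
    }
    s <- sort(unique(s))
  }
  P <- point_at_arclength(path, s)
  d <- section_diameter
  structure(
    list(
      nodes = tibble(s_mm = s, x = P[, 1], y = P[, 2], z = P[, 3]),
      elements = tibble(
        n1 = seq_len(length(s) - 1), n2 = seq_len(length(s) - 1) + 1L,
        length_mm = sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
      ),
      A = pi * d^2 / 4, I = pi * d^4 / 64, J = pi * d^4 / 32,
      E = mat$E / 1e6, G = mat$G / 1e6,
      section_diameter = d, material = mat, path = path
    ),
    class = "beam_model"
  )
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("<beam_model> %d elements, %d nodes, d = %.4f mm, E = %.4g MPa\n",
              nrow(x$elements), nrow(x$nodes), x$section_diameter, x$E))
  invisible(x)
}

# 12x12 local space-frame stiffness (axial, torsion, biaxial bending).
# DOF order per node: ux, uy, uz, rx, ry, rz (local axes).
frame_element_stiffness <- function(E, G, A, I, J, L) {
  K <- matrix(0, 12, 12)
  ea <- E * A / L
  gj <- G * J / L
  a <- 12 * E * I / L^3
  b <- 6 * E * I / L^2
  c4 <- 4 * E * I / L
  c2 <- 2 * E * I / L
  K[1, 1] <- K[7, 7] <- ea; K[1, 7] <- K[7, 1] <- -ea
  K[4, 4] <- K[10, 10] <- gj; K[4, 10] <- K[10, 4] <- -gj
  # bending in the local x-y plane (v, theta_z): dofs 2, 6, 8, 12
  i <- c(2, 6, 8, 12)
  K[i, i] <- K[i, i] + matrix(c(
    a,  b, -a,  b,
    b, c4, -b, c2,
    -a, -b,  a, -b,
    b, c2, -b, c4
  ), 4, 4, byrow = TRUE)
  # bending in the local x-z plane (w, theta_y): dofs 3, 5, 9, 11
  i <- c(3, 5, 9, 11)
  K[i, i] <- K[i, i] + matrix(c(
    a, -b, -a, -b,
    -b, c4,  b, c2,
    -a,  b,  a,  b,
    -b, c2,  b, c4
  ), 4, 4, byrow = TRUE)
  K
}

# rotation of an element chord into a full 12x12 transformation
frame_transformation <- function(p1, p2, ref = c(0, 0, 1)) {
  xl <- p2 - p1
  xl <- xl / sqrt(sum(xl^2))
  yl <- pracma_cross(ref, xl)
  if (sqrt(sum(yl^2)) < 1e-6) yl <- pracma_cross(c(0, 1, 0), xl)
  yl <- yl / sqrt(sum(yl^2))
  zl <- pracma_cross(xl, yl)
  Tm <- rbind(xl, yl, zl)
  Lam <- matrix(0, 12, 12)
  for (b in 0:3) Lam[b * 3 + 1:3, b * 3 + 1:3] <- Tm
  Lam
}

#' Assemble the global stiffness matrix of a beam model
#'
#' Exposed mainly for verification (symmetry, rigid-body modes). Each node
#' carries 6 DOF (3 translations, 3 rotations) in the global frame.
#'
#' @param model a [discretize()] result.
#' @return dense symmetric matrix, `6 * n_nodes` square.
#' @export
assemble_stiffness <- function(model) {
  nn <- nrow(model$nodes)
  K <- matrix(0, 6 * nn, 6 * nn)
  P <- as.matrix(model$nodes[, c("x", "y", "z")])
  for (e in seq_len(nrow(model$elements))) {
    n1 <- model$elements$n1[e]; n2 <- model$elements$n2[e]
    Le <- model$elements$length_mm[e]
    if (Le <= 0) abort("zero-length element.", class = "archforce_solver_error")
    Kl <- frame_element_stiffness(model$E, model$G, model$A, model$I, model$J, Le)
    Lam <- frame_transformation(P[n1, ], P[n2, ])
    Kg <- t(Lam) %*% Kl %*% Lam
    idx <- c((n1 - 1) * 6 + 1:6, (n2 - 1) * 6 + 1:6)
    K[idx, idx] <- K[idx, idx] + Kg
  }
  (K + t(K)) / 2
}

#' A point-load case for the virtual load-deflection experiment
#'
#' @param station load position along the wire, mm.
#' @param F force magnitude, N (> 0).
#' @param direction unit 3D load direction; default `NULL` = the normal of
#'   the arch's best-fit plane (a transverse pull out of the occlusal
#'   plane).
#' @param frame `"chord"` if `station` is the straight-line coordinate z
#'   (default, how stations are specified in the calibration protocol) or
#'   `"arc"` for the curvilinear coordinate y.
#' @return A `load_case` list.
#' @export
load_case <- function(station, F, direction = NULL, frame = c("chord", "arc")) {
  frame <- match.arg(frame)
  if (F <= 0) abort("F must be positive.", class = "archforce_invalid_parameter")
  if (!is.null(direction)) {
    direction <- as.numeric(direction)
    nrm <- sqrt(sum(direction^2))
    if (abs(nrm - 1) > 1e-12) direction <- direction / nrm
  }
  structure(list(station = station, F = F, direction = direction, frame = frame),
            class = "load_case")
}

arch_plane_normal <- function(path) {
  P <- path_matrix(path)
  Pc <- sweep(P, 2, colMeans(P))
  v <- svd(Pc, nu = 0, nv = 3)$v[, 3]
  v / sqrt(sum(v^2))
}

#' Solve a clamped-clamped beam under a point load
#'
#' Assembles and solves `K u = f` for the space-frame model with both end
#' nodes fully clamped and a point force at the load station (which must
#' coincide with a node; pass the station to [discretize()]). Small
#' displacements, linear theory: the deflection is exactly linear in F.
#'
#' @param model a [discretize()] result.
#' @param load a [load_case()] (or a list of them, whose forces accumulate;
#'   the reported deflection is at the first load's node), strictly inside
#'   the span.
#' @param K optional precomputed [assemble_stiffness()] matrix (reused
#'   across a load sweep).
#' @return A `beam_solution`: `nodal` tibble
#'   (`s_mm, ux, uy, uz, rx, ry, rz`; mm and rad), `load_s_mm`,
#'   `deflection_mm` (translation magnitude at the load node), and the
#'   applied `load`.
#' @export
assemble_and_solve <- function(model, load, K = NULL) {
  stopifnot(inherits(model, "beam_model"))
  loads <- if (inherits(load, "load_case")) list(load) else load
  stopifnot(all(vapply(loads, inherits, logical(1), "load_case")))
  L <- model$path$total_length
  if (is.null(K)) K <- assemble_stiffness(model)
  nn <- nrow(model$nodes)
  f <- numeric(6 * nn)
  s_load <- node <- dir <- NULL
  for (lc in loads) {
    s_i <- if (lc$frame == "chord") chord_to_arc(model$path, lc$station) else lc$station
    if (s_i <= .EPS_LEN || s_i >= L - .EPS_LEN) {
      abort("load station is at or beyond a clamped end.", class = "archforce_invalid_load")
    }
    nd <- which(abs(model$nodes$s_mm - s_i) <= 1e-9)
    if (length(nd) != 1L) {
      abort("no node at the load station; pass it to discretize(stations=).",
            class = "archforce_lookup_error")
    }
    d_i <- lc$direction
    if (is.null(d_i)) d_i <- arch_plane_normal(model$path)
    f[(nd - 1) * 6 + 1:3] <- f[(nd - 1) * 6 + 1:3] + lc$F * d_i
    if (is.null(node)) { node <- nd; s_load <- s_i; dir <- d_i }
  }
  load <- loads[[1]]
  clamped <- c(1:6, (nn - 1) * 6 + 1:6)
  free <- setdiff(seq_len(6 * nn), clamped)
  u <- numeric(6 * nn)
  u[free] <- solve(K[free, free], f[free])
  U <- matrix(u, ncol = 6, byrow = TRUE)
  nodal <- tibble(
    s_mm = model$nodes$s_mm,
    ux = U[, 1], uy = U[, 2], uz = U[, 3],
    rx = U[, 4], ry = U[, 5], rz = U[, 6]
  )
  structure(
    list(
      nodal = nodal,
      load_s_mm = s_load,
      deflection_mm = sqrt(sum(U[node, 1:3]^2)),
      load = load, direction = dir
    ),
    class = "beam_solution"
  )
}

#' Probe the deflection at a station
#'
#' Translation magnitude at the node nearest within tolerance of the
#' requested arc-length station (the "deformation probe" of the virtual
#' experiment).
#'
#' @param solution a [assemble_and_solve()] result.
#' @param station arc-length position, mm.
#' @return deflection x in mm.
#' @export
probe_deflection <- function(solution, station) {
  stopifnot(inherits(solution, "beam_solution"))
  i <- which(abs(solution$nodal$s_mm - station) <= 1e-9)
  if (length(i) != 1L) {
    abort("no node at that station.", class = "archforce_lookup_error")
  }
  with(solution$nodal[i, ], sqrt(ux^2 + uy^2 + uz^2))
}

#' @export
print.beam_solution <- function(x, ...) {
  cat(sprintf("<beam_solution> F = %g N at s = %.3f mm -> x = %.6g mm\n",
              x$load$F, x$load_s_mm, x$deflection_mm))
  invisible(x)
}

#' @method tidy beam_solution
#' @export
tidy.beam_solution <- function(x, ...) x$nodal

#' @method glance beam_solution
#' @export
glance.beam_solution <- function(x, ...) {
  tibble(
    load_N = x$load$F, load_s_mm = x$load_s_mm,
    deflection_mm = x$deflection_mm,
    max_translation_mm = max(sqrt(x$nodal$ux^2 + x$nodal$uy^2 + x$nodal$uz^2)),
    n_nodes = nrow(x$nodal)
  )
}

#' @method autoplot beam_solution
#' @export
autoplot.beam_solution <- function(object, ...) {
  d <- object$nodal
  d$mag <- sqrt(d$ux^2 + d$uy^2 + d$uz^2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$s_mm, y = .data$mag)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$load_s_mm, linetype = 2) +
    ggplot2::labs(x = "arc length s (mm)", y = "|u| (mm)",
                  title = sprintf("Deflection under F = %g N", object$load$F))
}
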