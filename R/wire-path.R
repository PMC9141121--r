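#' Wire centerline paths
#'
#' A `wire_path` stores the centerline of an orthodontic wire as a densely
#' and uniformly resampled 3D polyline with its arc-length parameterization.
#' All coordinates are millimeters; the occlusal plane is the XY plane of a
#' right-handed frame.
#'
#' @param points numeric matrix (or data frame) with 3 columns `x, y, z` in
#'   mm, ordered along the wire.
#' @param n_samples number of uniform arc-length samples to store
#'   (default 1000; at least 16). Ignored when `resample = FALSE`.
#' @param arch optional arch label, `"upper"` or `"lower"`.
#' @param resample set `FALSE` to store `points` verbatim as the samples
#'   (used when the vertices must be preserved exactly, e.g. after
#'   trimming; zero-length segments are still dropped).
#' @return A `wire_path` object: list with `samples` (a tibble
#'   `s_mm, x_mm, y_mm, z_mm`), `total_length` (mm), `control_points`, and
#'   `arch`.
#' @examples
#' p <- wire_path(cbind(seq(0, 10, length.out = 50), 0, 0))
#' p$total_length
#' @export
wire_path <- function(points, n_samples = 1000, arch = NA_character_,
                      resample = TRUE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || nrow(points) < 2L) {
    abort("`points` must be an n x 3 matrix with n >= 2.", class = "archforce_invalid_parameter")
  }
  if (any(!is.finite(points))) {
    abort("`points` must be finite.", class = "archforce_invalid_parameter")
  }
  if (resample && n_samples < 16L) {
    abort("`n_samples` must be at least 16.", class = "archforce_invalid_parameter")
  }
  samples <- if (resample) resample_polyline(points, n_samples) else drop_zero_segments(points)
  structure(
    list(
      samples = polyline_to_tibble(samples),
      total_length = total_polyline_length(samples),
      control_points = points,
      arch = arch
    ),
    class = "wire_path"
  )
}

#' @export
print.wire_path <- function(x, ...) {
  cat(sprintf(
    "<wire_path> %s samples, total length %.4f mm%s\n",
    nrow(x$samples), x$total_length,
    if (is.na(x$arch)) "" else paste0(", arch: ", x$arch)
  ))
  invisible(x)
}

# ---- polyline primitives (matrix in, matrix out) ---------------------------

path_matrix <- function(path) {
  as.matrix(path$samples[, c("x_mm", "y_mm", "z_mm")])
}

polyline_to_tibble <- function(P) {
  s <- cumulative_arclength(P)
  tibble(s_mm = s, x_mm = P[, 1], y_mm = P[, 2], z_mm = P[, 3])
}

cumulative_arclength <- function(P) {
  d <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  c(0, cumsum(d))
}

total_polyline_length <- function(P) {
  sum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
}

drop_zero_segments <- function(P) {
  s <- cumulative_arclength(P)
  keep <- c(TRUE, diff(s) > 0)
  P <- P[keep, , drop = FALSE]
  if (nrow(P) < 2L) abort("degenerate polyline: zero length.", class = "archforce_invalid_parameter")
  P
}

# Uniform arc-length resampling by linear interpolation along the polyline.
# A single pass leaves the new vertices uniform in the *input* polyline's
# metric but slightly non-uniform in their own chord metric; iterating to a
# fixed point makes the stored polyline uniform in its own metric, so
# resampling at the same density becomes exactly idempotent.
resample_polyline <- function(P, n, max_iter = 10) {
  P <- drop_zero_segments(P)
  for (iter in seq_len(max_iter)) {
    s <- cumulative_arclength(P)
    si <- seq(0, s[length(s)], length.out = n)
    P <- cbind(
      approx(s, P[, 1], xout = si)$y,
      approx(s, P[, 2], xout = si)$y,
      approx(s, P[, 3], xout = si)$y
    )
    d <- diff(cumulative_arclength(P))
    if (max(abs(d - mean(d))) <= 1e-12 * mean(d)) break
  }
  P
}

#' @importFrom stats approx
point_at_arclength <- function(path, s) {
  sm <- path$samples
  cbind(
    approx(sm$s_mm, sm$x_mm, xout = s)$y,
    approx(sm$s_mm, sm$y_mm, xout = s)$y,
    approx(sm$s_mm, sm$z_mm, xout = s)$y
  )
}

unit_tangent_at <- function(path, s, h = NULL) {
  if (is.null(h)) h <- path$total_length / (nrow(path$samples) - 1)
  s0 <- max(0, s - h / 2)
  s1 <- min(path$total_length, s + h / 2)
  d <- point_at_arclength(path, s1) - point_at_arclength(path, s0)
  d / sqrt(sum(d^2))
}

#' Generate a synthetic dental arch curve
#'
#' Builds a smooth, symmetric, U-shaped planar-ish curve emulating the
#' centerline of an archwire adapted to a dental arch. The `"flattened"`
#' form is a symmetric power-law arch `y = depth * (1 - |t|^flatness)`
#' spanning `width`; the `"semicircle"` form is a half circle of radius
#' `width / 2` (useful for analytic checks). A `tilt` (radians) rotates the
#' arch out of the occlusal plane about its width axis. When
#' `total_length` is given the curve is rescaled so its polyline arc length
#' matches it exactly.
#'
#' @param width arch width (mm), distance between the distal ends.
#' @param depth arch depth (mm), ignored for `form = "semicircle"`.
#' @param flatness exponent >= 2 controlling how flat the anterior
#'   segment is (2 = parabolic; larger = flatter, squarer arch).
#' @param tilt rotation of the arch plane about the width axis, radians.
#' @param total_length optional target arc length (mm); the curve is scaled
#'   uniformly so the stored polyline length equals it exactly.
#' @param n_samples number of uniform samples (>= 16).
#' @param form `"flattened"` (default) or `"semicircle"`.
#' @param waviness amplitude (mm) of a smooth random perturbation normal to
#'   the arch plane; 0 disables it.
#' @param seed integer seed for the waviness perturbation; generation is
#'   deterministic for a fixed seed.
#' @param arch optional arch label.
#' @return A [wire_path()].
#' @examples
#' w <- generate_arch_curve(width = 60, depth = 50, total_length = 152.12)
#' w$total_length
#' @export
generate_arch_curve <- function(width = 60, depth = 50, flatness = 2.5,
                                tilt = 0, total_length = NULL,
                                n_samples = 1001,
                                form = c("flattened", "semicircle"),
                                waviness = 0, seed = NULL,
                                arch = NA_character_) {
  form <- match.arg(form)
  if (width <= 0 || (form == "flattened" && depth <= 0) || flatness < 2) {
    abort("degenerate arch form: need width > 0, depth > 0, flatness >= 2.",
          class = "archforce_invalid_parameter")
  }
  if (!is.null(total_length) && total_length <= 0) {
    abort("`total_length` must be positive.", class = "archforce_invalid_parameter")
  }
  if (n_samples < 16L) {
    abort("`n_samples` must be at least 16.", class = "archforce_invalid_parameter")
  }
  n_dense <- max(4L * n_samples, 4000L)
  if (form == "semicircle") {
    r <- width / 2
    th <- seq(0, pi, length.out = n_dense)
    P <- cbind(r * cos(th), r * sin(th), 0)
  } else {
    t <- seq(-1, 1, length.out = n_dense)
    P <- cbind(width / 2 * t, depth * (1 - abs(t)^flatness), 0)
  }
  if (waviness > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    ph <- runif(3, 0, 2 * pi)
    t01 <- seq(0, 1, length.out = n_dense)
    # smooth low-frequency bumps, zero at both ends
    P[, 3] <- P[, 3] + waviness * sin(pi * t01) *
      (sin(2 * pi * t01 + ph[1]) + 0.5 * sin(4 * pi * t01 + ph[2]))
  }
  if (tilt != 0) {
    ct <- cos(tilt); st <- sin(tilt)
    P <- cbind(P[, 1], ct * P[, 2] - st * P[, 3], st * P[, 2] + ct * P[, 3])
  }
  if (!is.null(total_length)) {
    L0 <- total_polyline_length(resample_polyline(P, n_samples))
    P <- P * (total_length / L0)
  }
  wire_path(P, n_samples = n_samples, arch = arch)
}

#' Trim a wire to a target length
#'
#' Sections the wire so its arc length matches the patient's arch, either
#' removing equal amounts from both ends (`"symmetric"`) or all from the far
#' end (`"from_end"`).
#'
#' @param path a [wire_path()].
#' @param target_length desired arc length (mm), `0 < target <= total`.
#' @param mode `"symmetric"` or `"from_end"`.
#' @return A trimmed [wire_path()]; `attr(, "removed_mm")` records the
#'   trimmed-off length.
#' @examples
#' w <- generate_arch_curve(total_length = 152.12)
#' t <- trim_wire(w, 109.68)
#' attr(t, "removed_mm")
#' @export
trim_wire <- function(path, target_length, mode = c("symmetric", "from_end")) {
  mode <- match.arg(mode)
  stopifnot(inherits(path, "wire_path"))
  L <- path$total_length
  if (target_length <= 0 || target_length > L + .EPS_LEN) {
    abort("`target_length` must lie in (0, total_length].",
          class = "archforce_invalid_parameter")
  }
  target_length <- min(target_length, L)
  if (mode == "symmetric") {
    s0 <- (L - target_length) / 2
  } else {
    s0 <- 0
  }
  s1 <- s0 + target_length
  sm <- path$samples
  inner <- sm$s_mm > s0 & sm$s_mm < s1
  P <- rbind(
    point_at_arclength(path, s0),
    as.matrix(sm[inner, c("x_mm", "y_mm", "z_mm")]),
    point_at_arclength(path, s1)
  )
  # keep the surviving vertices verbatim: re-resampling would cut corners
  # and change the trimmed length
  out <- wire_path(P, arch = path$arch, resample = FALSE)
  attr(out, "removed_mm") <- L - out$total_length
  out
}

# Closest-point projection onto the sampled polyline.
# Returns list(s = arc-length at the foot, dist, point).
project_to_path <- function(path, point, tol = 0.5) {
  point <- as.numeric(point)
  P <- path_matrix(path)
  A <- P[-nrow(P), , drop = FALSE]
  B <- P[-1, , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  AP <- sweep(-A, 2, point, FUN = "+")         # point - A
  t <- pmin(1, pmax(0, rowSums(AP * AB) / len2))
  foot <- A + AB * t
  d2 <- rowSums(sweep(foot, 2, point)^2)
  i <- which.min(d2)
  s <- path$samples$s_mm[i] + t[i] * sqrt(len2[i])
  dist <- sqrt(d2[i])
  if (dist > tol) {
    abort(sprintf("point is %.3f mm from the wire (tolerance %.3f mm).", dist, tol),
          class = "archforce_projection_error")
  }
  list(s = s, dist = dist, point = foot[i, ])
}

#' Curvilinear (arc-length) coordinate of a point on the wire
#'
#' Projects `point` onto the wire centerline and returns the cumulative arc
#' length y from the start end to the foot of the projection.
#'
#' @param path a [wire_path()].
#' @param point numeric length-3 point (mm).
#' @param tol projection tolerance (mm); points farther than this from the
#'   centerline raise a projection error. Default 0.5.
#' @return y in mm, in `[0, total_length]`.
#' @export
arc_length_coordinate <- function(path, point, tol = 0.5) {
  project_to_path(path, point, tol)$s
}

#' Chordwise coordinate of a point on the wire
#'
#' The straight-line station coordinate z: the Euclidean distance from the
#' start end of the wire to the projection of `point` onto the centerline.
#' Always `z <= y`, with equality on a straight wire.
#'
#' @inheritParams arc_length_coordinate
#' @return z in mm.
#' @export
chord_coordinate <- function(path, point, tol = 0.5) {
  pr <- project_to_path(path, point, tol)
  p0 <- as.numeric(path$samples[1, c("x_mm", "y_mm", "z_mm")])
  sqrt(sum((pr$point - p0)^2))
}

#' Map a chord station z to its arc-length position
#'
#' Finds the arc-length position s at which the straight-line distance from
#' the start end of the wire first reaches z (the inverse of
#' [chord_coordinate()] over its monotone range). This is how the
#' calibration stations, specified as chord coordinates, are located on the
#' curved wire.
#'
#' @param path a [wire_path()].
#' @param z chord station(s), mm.
#' @return arc-length position(s) s in mm.
#' @export
chord_to_arc <- function(path, z) {
  sm <- path$samples
  p0 <- c(sm$x_mm[1], sm$y_mm[1], sm$z_mm[1])
  chord <- sqrt((sm$x_mm - p0[1])^2 + (sm$y_mm - p0[2])^2 + (sm$z_mm - p0[3])^2)
  vapply(z, function(zi) {
    if (zi < 0 || zi > max(chord) + .EPS_LEN) {
      abort(sprintf("chord station %.3f mm is outside the wire's chord range.", zi),
            class = "archforce_projection_error")
    }
    if (zi <= 0) return(0)
    i <- which(chord >= zi)[1]
    if (i == 1L) return(0)
    f <- (zi - chord[i - 1]) / (chord[i] - chord[i - 1])
    sm$s_mm[i - 1] + f * (sm$s_mm[i] - sm$s_mm[i - 1])
  }, numeric(1))
}

#' Read or write a wire path as CSV
#'
#' The CSV layout is `s_mm,x_mm,y_mm,z_mm`, one row per sample.
#'
#' @param path a [wire_path()] (for writing).
#' @param file file path.
#' @param arch optional arch label applied on read.
#' @return `read_wire_path()` returns a [wire_path()];
#'   `write_wire_path()` returns `file` invisibly.
#' @export
write_wire_path <- function(path, file) {
  stopifnot(inherits(path, "wire_path"))
  readr::write_csv(path$samples, file)
  invisible(file)
}

#' @rdname write_wire_path
#' @export
read_wire_path <- function(file, arch = NA_character_) {
  d <- readr::read_csv(file, show_col_types = FALSE)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(d))) {
    abort("wire path CSV needs columns x_mm, y_mm, z_mm.", class = "archforce_io_error")
  }
  wire_path(as.matrix(d[, need]), n_samples = max(16L, nrow(d)), arch = arch)
}

#' Export a wire as an ASCII STL tube
#'
#' Sweeps a circular cross-section (default diameter 0.3556 mm, a
#' 0.014-inch wire) along the centerline and writes a triangulated tube for
#' visualization.
#'
#' @param path a [wire_path()].
#' @param file output `.stl` path.
#' @param diameter tube diameter in mm.
#' @param n_circ vertices around the circumference.
#' @param n_axial rings along the wire (default: every 40th sample).
#' @return `file`, invisibly.
#' @export
write_wire_path_stl <- function(path, file, diameter = 0.3556, n_circ = 12,
                                n_axial = NULL) {
  stopifnot(inherits(path, "wire_path"))
  if (is.null(n_axial)) n_axial <- max(16L, nrow(path$samples) %/% 40L)
  s <- seq(0, path$total_length, length.out = n_axial)
  C <- point_at_arclength(path, s)
  r <- diameter / 2
  ref <- c(0, 0, 1)
  rings <- lapply(seq_len(n_axial), function(i) {
    tg <- unit_tangent_at(path, s[i])
    u <- pracma_cross(ref, tg)
    if (sqrt(sum(u^2)) < 1e-6) u <- pracma_cross(c(0, 1, 0), tg)
    u <- u / sqrt(sum(u^2))
    v <- pracma_cross(tg, u)
    th <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
    sweep(outer(cos(th), u) * r + outer(sin(th), v) * r, 2, C[i, ], FUN = "+")
  })
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("solid wire", con)
  tri <- function(a, b, c3) {
    n <- pracma_cross(b - a, c3 - a)
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(
      sprintf("  facet normal %e %e %e", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %e %e %e", a[1], a[2], a[3]),
      sprintf("      vertex %e %e %e", b[1], b[2], b[3]),
      sprintf("      vertex %e %e %e", c3[1], c3[2], c3[3]),
      "    endloop",
      "  endfacet"
    ), con)
  }
  for (i in seq_len(n_axial - 1)) {
    R1 <- rings[[i]]; R2 <- rings[[i + 1]]
    for (j in seq_len(n_circ)) {
      jn <- j %% n_circ + 1
      tri(R1[j, ], R2[j, ], R2[jn, ])
      tri(R1[j, ], R2[jn, ], R1[jn, ])
    }
  }
  writeLines("endsolid wire", con)
  invisible(file)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @method autoplot wire_path
#' @export
autoplot.wire_path <- function(object, ...) {
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$x_mm, y = .data$y_mm)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (mm)", y = "y (mm)",
      title = sprintf("Wire centerline (%.2f mm)", object$total_length)
    )
}
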