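#' Tetrahedral meshes
#'
#' A `tet_mesh` stores nodes (mm), 4-node connectivity (consistently
#' positive-volume orientation) and a region label per element
#' (`"tooth"`, `"bone"`, `"bracket"`).
#'
#' @param nodes numeric n x 3 matrix, mm.
#' @param tets integer m x 4 connectivity (1-based).
#' @param region character length-m region labels.
#' @return A `tet_mesh` object.
#' @export
tet_mesh <- function(nodes, tets, region) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L || ncol(tets) != 4L || length(region) != nrow(tets)) {
    abort("bad mesh arrays.", class = "archforce_meshing_error")
  }
  v <- tet_volumes(nodes, tets)
  neg <- v < 0
  if (any(neg)) {   # fix orientation by swapping two vertices
    tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
    v <- abs(v)
  }
  if (any(v <= 0)) {
    abort("degenerate (zero-volume) tetrahedra.", class = "archforce_meshing_error")
  }
  used <- sort(unique(as.vector(tets)))
  if (!identical(used, seq_len(nrow(nodes)))) {
    abort("mesh has unreferenced nodes.", class = "archforce_meshing_error")
  }
  structure(
    list(nodes = nodes, tets = tets, region = as.character(region), volumes = v),
    class = "tet_mesh"
  )
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tets; regions: %s\n",
              nrow(x$nodes), nrow(x$tets),
              paste(sprintf("%s (%d)", names(table(x$region)), table(x$region)),
                    collapse = ", ")))
  invisible(x)
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  c3 <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
     a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
     a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Mesh quality audit
#'
#' Radius ratio per tet: `3 r_in / r_circ`, 1 for the regular tetrahedron,
#' approaching 0 for slivers.
#'
#' @param mesh a [tet_mesh()].
#' @return tibble `element, radius_ratio` plus `min`/`mean` as attributes.
#' @export
mesh_quality <- function(mesh) {
  n <- mesh$nodes; t4 <- mesh$tets
  V <- mesh$volumes
  face_area <- function(i, j, k) {
    u <- n[t4[, j], , drop = FALSE] - n[t4[, i], , drop = FALSE]
    v <- n[t4[, k], , drop = FALSE] - n[t4[, i], , drop = FALSE]
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    sqrt(cx^2 + cy^2 + cz^2) / 2
  }
  Atot <- face_area(1, 2, 3) + face_area(1, 2, 4) + face_area(1, 3, 4) + face_area(2, 3, 4)
  r_in <- 3 * V / Atot
  # circumradius via the standard determinant-free formula
  p1 <- n[t4[, 1], , drop = FALSE]
  aa <- n[t4[, 2], , drop = FALSE] - p1
  bb <- n[t4[, 3], , drop = FALSE] - p1
  cc <- n[t4[, 4], , drop = FALSE] - p1
  la <- rowSums(aa^2); lb <- rowSums(bb^2); lc <- rowSums(cc^2)
  crossr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
  num <- la * crossr(bb, cc) + lb * crossr(cc, aa) + lc * crossr(aa, bb)
  r_circ <- sqrt(rowSums(num^2)) / (12 * V)
  q <- 3 * r_in / r_circ
  out <- tibble(element = seq_along(q), radius_ratio = q)
  attr(out, "min") <- min(q)
  attr(out, "mean") <- mean(q)
  out
}

#' Build a synthetic tooth-in-bone tetrahedral model
#'
#' A desk-scale stand-in for a patient jaw segment: a rectangular bone
#' block meshed with a structured Kuhn (6-tets-per-hex) subdivision, with
#' `n_teeth` vertical frustum-shaped teeth embedded from the top surface
#' down `root_length`, and a bonded bracket pad labeled on the facial
#' (y = 0) side of each tooth crown. Regions partition the elements; the
#' mesh is watertight by construction. Interior nodes are jittered
#' slightly (seeded, deterministic) so the mesh is not perfectly
#' structured.
#'
#' @param n_teeth number of teeth (>= 1).
#' @param root_length embedded tooth depth, mm.
#' @param bone_block c(length, width, height) of the block, mm.
#' @param cell_size target hex cell edge, mm (mesh density knob).
#' @param jitter interior-node jitter as a fraction of `cell_size`.
#' @param seed integer seed for the jitter.
#' @return A [tet_mesh()] with attribute `"pads"`: a list (one per tooth)
#'   of facial pad node indices, plus `"tooth_centers"`.
#' @export
build_synthetic_tooth_model <- function(n_teeth = 3, root_length = 8,
                                        bone_block = c(30, 10, 12),
                                        cell_size = 2, jitter = 0.08,
                                        seed = 1L) {
  if (n_teeth < 1 || root_length <= 0 || any(bone_block <= 0) || cell_size <= 0) {
    abort("degenerate model parameters.", class = "archforce_meshing_error")
  }
  Lx <- bone_block[1]; Ly <- bone_block[2]; Lz <- bone_block[3]
  if (root_length >= Lz) {
    abort("root_length must be smaller than the block height.",
          class = "archforce_meshing_error")
  }
  grid <- block_tet_grid(c(Lx, Ly, Lz), cell_size, jitter, seed)
  nodes <- grid$nodes
  tets <- grid$tets
  # region labels from element centroids
  cent <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] + nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  pitch <- Lx / n_teeth
  xc <- pitch * (seq_len(n_teeth) - 0.5)
  r_top <- 0.42 * pitch
  r_bot <- 0.65 * r_top
  in_tooth <- rep(FALSE, nrow(cent))
  tooth_of <- rep(NA_integer_, nrow(cent))
  z0 <- Lz - root_length
  frac <- pmin(1, pmax(0, (cent[, 3] - z0) / root_length))
  r_at <- r_bot + (r_top - r_bot) * frac
  for (ti in seq_len(n_teeth)) {
    inside <- cent[, 3] >= z0 &
      (cent[, 1] - xc[ti])^2 + (cent[, 2] - Ly / 2)^2 <= r_at^2
    tooth_of[inside] <- ti
    in_tooth <- in_tooth | inside
  }
  pad_halfwidth <- max(cell_size, 0.3 * pitch)
  in_pad <- rep(FALSE, nrow(cent))
  pad_of <- rep(NA_integer_, nrow(cent))
  for (ti in seq_len(n_teeth)) {
    inside <- cent[, 2] <= 1.05 * cell_size &
      abs(cent[, 1] - xc[ti]) <= pad_halfwidth &
      cent[, 3] >= Lz - 0.35 * root_length
    pad_of[inside] <- ti
    in_pad <- in_pad | inside
  }
  region <- ifelse(in_pad, "bracket", ifelse(in_tooth, "tooth", "bone"))
  mesh <- tet_mesh(nodes, tets, region)
  # facial pad node sets (for distributing bracket forces)
  pads <- lapply(seq_len(n_teeth), function(ti) {
    el <- which(region == "bracket" & pad_of == ti)
    nd <- unique(as.vector(mesh$tets[el, ]))
    nd[mesh$nodes[nd, 2] <= .EPS_LEN]   # nodes on the facial face y = 0
  })
  if (any(lengths(pads) == 0L) || !all(c("tooth", "bone", "bracket") %in% region)) {
    abort("degenerate parameters: some region is empty; refine cell_size.",
          class = "archforce_meshing_error")
  }
  attr(mesh, "pads") <- pads
  attr(mesh, "tooth_centers") <- xc
  mesh
}

#' Structured tetrahedral block mesh
#'
#' Meshes an axis-aligned box with a uniform grid, splitting each hex cell
#' into 6 tetrahedra (Kuhn/Freudenthal subdivision, conforming across
#' cells). Interior nodes may be jittered (seeded) while boundary nodes
#' stay on the box faces. Used as the substrate of
#' [build_synthetic_tooth_model()] and handy for solver verification
#' problems (bars, patch tests).
#'
#' @param dims c(Lx, Ly, Lz) of the box, mm.
#' @param cell_size target hex edge, mm.
#' @param jitter interior-node jitter as a fraction of `cell_size`.
#' @param seed integer seed for the jitter.
#' @param region single region label applied to every element.
#' @return A [tet_mesh()].
#' @export
block_tet_mesh <- function(dims, cell_size, jitter = 0, seed = 1L,
                           region = "bone") {
  if (any(dims <= 0) || cell_size <= 0) {
    abort("degenerate block parameters.", class = "archforce_meshing_error")
  }
  g <- block_tet_grid(dims, cell_size, jitter, seed)
  tet_mesh(g$nodes, g$tets, rep(region, nrow(g$tets)))
}

block_tet_grid <- function(dims, cell_size, jitter, seed) {
  Lx <- dims[1]; Ly <- dims[2]; Lz <- dims[3]
  nx <- max(2L, ceiling(Lx / cell_size))
  ny <- max(2L, ceiling(Ly / cell_size))
  nz <- max(2L, ceiling(Lz / cell_size))
  xs <- seq(0, Lx, length.out = nx + 1)
  ys <- seq(0, Ly, length.out = ny + 1)
  zs <- seq(0, Lz, length.out = nz + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  nid <- function(i, j, k) i + (nx + 1L) * (j - 1L) + (nx + 1L) * (ny + 1L) * (k - 1L)
  # jitter interior nodes only (boundary stays planar -> watertight box)
  if (jitter > 0) {
    set.seed(as.integer(seed))
    interior <- nodes[, 1] > 0 & nodes[, 1] < Lx &
      nodes[, 2] > 0 & nodes[, 2] < Ly &
      nodes[, 3] > 0 & nodes[, 3] < Lz
    nodes[interior, ] <- nodes[interior, ] +
      matrix(runif(3 * sum(interior), -1, 1), ncol = 3) * jitter * cell_size
  }
  # Kuhn subdivision of each hex into 6 tets sharing the main diagonal
  kuhn <- rbind(c(1, 2, 4, 8), c(1, 2, 8, 6), c(1, 6, 8, 5),
                c(1, 4, 3, 8), c(1, 3, 7, 8), c(1, 7, 5, 8))
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  tets <- matrix(0L, nrow(cells) * 6L, 4L)
  row <- 0L
  for (c_i in seq_len(nrow(cells))) {
    i <- cells$i[c_i]; j <- cells$j[c_i]; k <- cells$k[c_i]
    corners <- c(
      nid(i, j, k),     nid(i + 1L, j, k),     nid(i, j + 1L, k),     nid(i + 1L, j + 1L, k),
      nid(i, j, k + 1L), nid(i + 1L, j, k + 1L), nid(i, j + 1L, k + 1L), nid(i + 1L, j + 1L, k + 1L)
    )
    for (t in 1:6) {
      row <- row + 1L
      tets[row, ] <- corners[kuhn[t, ]]
    }
  }
  list(nodes = nodes, tets = tets)
}

#' Select mesh nodes on an axis-aligned face or in a region
#'
#' @param mesh a [tet_mesh()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param value face coordinate, mm.
#' @param tol selection tolerance, mm.
#' @return integer node indices.
#' @export
select_face_nodes <- function(mesh, axis = c("x", "y", "z"), value, tol = 1e-6) {
  axis <- match.arg(axis)
  a <- match(axis, c("x", "y", "z"))
  which(abs(mesh$nodes[, a] - value) <= tol)
}

#' @rdname select_face_nodes
#' @param region region label.
#' @export
select_region_nodes <- function(mesh, region) {
  el <- which(mesh$region == region)
  sort(unique(as.vector(mesh$tets[el, , drop = FALSE])))
}
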