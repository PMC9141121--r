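#' Linear elastic tet4 solve with field maps
#'
#' Small-strain linear elasticity on a [tet_mesh()] with per-region
#' isotropic materials. Assembles the standard constant-strain (tet4)
#' stiffness, applies Dirichlet constraints (zero or prescribed), applies
#' nodal loads, solves the sparse symmetric system, and derives per-element
#' strain, von Mises stress, and strain energy plus the field maxima.
#'
#' Internally mm-N-MPa units; strain energy is converted to joules
#' (1 N mm = 1e-3 J). The reported equivalent strain is the von Mises
#' equivalent strain computed from principal strains with the material's
#' Poisson ratio, and the stress measure is von Mises equivalent stress:
#' `sigma_v = sqrt(((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2) / 2)`.
#'
#' @param mesh a [tet_mesh()].
#' @param materials named list of [material()]s, one entry per region label
#'   (default: the shipped presets — enamel teeth, bone block, Ni-Cr pads).
#' @param forces either a per-tooth force tibble with columns
#'   `tooth, F_N, dx, dy, dz` (distributed over the mesh's bracket pads in
#'   row order), or a nodal load tibble `node, fx, fy, fz` (N).
#' @param fixed integer node indices whose DOFs are constrained (all three
#'   translations), or a 2-column matrix `(node, dof)` for per-DOF control.
#'   Default: the base of the bone block (z = 0 face).
#' @param prescribed optional displacement values (mm) for the constrained
#'   DOFs, recycled; default 0 (supports imposed-displacement patch tests).
#' @return A `field_map`: list with `displacement` (tibble
#'   `node, ux, uy, uz, magnitude_mm`), `elements` (tibble
#'   `element, region, volume_mm3, strain_eqv, von_mises_MPa,
#'   strain_energy_J`), `maxima` (tibble `field, value, unit, at, x, y, z`),
#'   `reactions`, `total_strain_energy_J`, and the solve vectors `u`, `f`.
#' @export
solve_elasticity <- function(mesh, materials = NULL, forces = NULL,
                             fixed = NULL, prescribed = 0) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (is.null(materials)) {
    p <- material_presets()
    materials <- list(tooth = p$enamel, bone = p$bone, bracket = p$nicr)
  }
  regions <- unique(mesh$region)
  if (!all(regions %in% names(materials))) {
    abort(sprintf("missing material for region(s): %s",
                  paste(setdiff(regions, names(materials)), collapse = ", ")),
          class = "archforce_invalid_parameter")
  }
  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn
  # constrained dofs
  if (is.null(fixed)) fixed <- select_face_nodes(mesh, "z", min(mesh$nodes[, 3]))
  if (is.matrix(fixed)) {
    fixed_dofs <- (fixed[, 1] - 1L) * 3L + fixed[, 2]
  } else {
    fixed_dofs <- as.vector(t(outer((as.integer(fixed) - 1L) * 3L, 1:3, `+`)))
  }
  fixed_dofs <- unique(fixed_dofs)
  if (length(fixed_dofs) == 0L) {
    abort("at least one fixed DOF is required.", class = "archforce_invalid_parameter")
  }
  u_fixed <- rep_len(prescribed, length(fixed_dofs))
  # loads
  f <- numeric(ndof)
  if (!is.null(forces)) {
    forces <- tibble::as_tibble(forces)
    if (all(c("node", "fx", "fy", "fz") %in% names(forces))) {
      idx <- (forces$node - 1L) * 3L
      f[idx + 1L] <- f[idx + 1L] + forces$fx
      f[idx + 2L] <- f[idx + 2L] + forces$fy
      f[idx + 3L] <- f[idx + 3L] + forces$fz
    } else if (all(c("F_N", "dx", "dy", "dz") %in% names(forces))) {
      pads <- attr(mesh, "pads")
      if (is.null(pads)) {
        abort("mesh has no bracket pads; pass nodal loads instead.",
              class = "archforce_invalid_parameter")
      }
      if (nrow(forces) > length(pads)) {
        abort("more force records than bracket pads.", class = "archforce_invalid_parameter")
      }
      for (i in seq_len(nrow(forces))) {
        nd <- pads[[i]]
        per <- forces$F_N[i] / length(nd)
        dvec <- c(forces$dx[i], forces$dy[i], forces$dz[i])
        for (a in 1:3) f[(nd - 1L) * 3L + a] <- f[(nd - 1L) * 3L + a] + per * dvec[a]
      }
    } else {
      abort("`forces` must have node,fx,fy,fz or F_N,dx,dy,dz columns.",
            class = "archforce_invalid_parameter")
    }
  }
  asm <- assemble_tet_stiffness(mesh, materials)
  K <- asm$K
  free <- setdiff(seq_len(ndof), fixed_dofs)
  u <- numeric(ndof)
  u[fixed_dofs] <- u_fixed
  rhs <- f[free] - as.numeric(K[free, fixed_dofs, drop = FALSE] %*% u_fixed)
  # sparse Cholesky: fails (not positive definite) when a substructure can
  # still move rigidly, which is the right diagnostic here
  ch <- tryCatch(
    Matrix::Cholesky(Matrix::forceSymmetric(K[free, free]), LDL = FALSE),
    error = function(e) {
      abort(paste0("singular stiffness system (floating substructure?): ",
                   conditionMessage(e)),
            class = "archforce_solver_error")
    },
    warning = function(w) {   # CHMOD signals 'not positive definite' as a warning
      abort(paste0("singular stiffness system (floating substructure?): ",
                   conditionMessage(w)),
            class = "archforce_solver_error")
    }
  )
  sol <- Matrix::solve(ch, rhs, system = "A")
  u[free] <- as.numeric(sol)
  if (!all(is.finite(u))) {
    abort("singular stiffness system (floating substructure?).",
          class = "archforce_solver_error")
  }
  reactions <- as.numeric(K %*% u) - f
  # per-element fields
  fields <- tet_element_fields(mesh, materials, u, asm$B, asm$D_of)
  U <- matrix(u, ncol = 3, byrow = TRUE)
  disp <- tibble(
    node = seq_len(nn),
    ux = U[, 1], uy = U[, 2], uz = U[, 3],
    magnitude_mm = sqrt(rowSums(U^2))
  )
  cent <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
             mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  i_d <- which.max(disp$magnitude_mm)
  i_s <- which.max(fields$strain_eqv)
  i_v <- which.max(fields$von_mises_MPa)
  i_e <- which.max(fields$strain_energy_J)
  maxima <- tibble(
    field = c("displacement", "strain", "von_mises", "strain_energy"),
    value = c(disp$magnitude_mm[i_d], fields$strain_eqv[i_s],
              fields$von_mises_MPa[i_v], fields$strain_energy_J[i_e]),
    unit = c("mm", "-", "MPa", "J"),
    at = c(paste0("node ", i_d), paste0("element ", i_s),
           paste0("element ", i_v), paste0("element ", i_e)),
    x = c(mesh$nodes[i_d, 1], cent[i_s, 1], cent[i_v, 1], cent[i_e, 1]),
    y = c(mesh$nodes[i_d, 2], cent[i_s, 2], cent[i_v, 2], cent[i_e, 2]),
    z = c(mesh$nodes[i_d, 3], cent[i_s, 3], cent[i_v, 3], cent[i_e, 3])
  )
  structure(
    list(
      displacement = disp, elements = fields, maxima = maxima,
      reactions = reactions, fixed_dofs = fixed_dofs,
      total_strain_energy_J = sum(fields$strain_energy_J),
      u = u, f = f, mesh = mesh
    ),
    class = "field_map"
  )
}

# isotropic 6x6 elasticity matrix, MPa, engineering-shear Voigt convention
elasticity_matrix <- function(mat) {
  E <- mat$E / 1e6
  nu <- mat$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- mat$G / 1e6   # shear stiffness from the stored G (may depart from E/2(1+nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# assemble sparse global stiffness; also return per-element B and D lookup
assemble_tet_stiffness <- function(mesh, materials) {
  m <- nrow(mesh$tets)
  D_by_region <- lapply(materials, elasticity_matrix)
  ii <- vector("list", m); jj <- vector("list", m); xx <- vector("list", m)
  B_list <- vector("list", m)
  for (e in seq_len(m)) {
    nd <- mesh$tets[e, ]
    X <- mesh$nodes[nd, ]
    V <- mesh$volumes[e]
    # shape-function gradients: grad N = inv(J)^T applied to reference grads
    Jm <- rbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])
    invJ <- solve(Jm)
    gref <- rbind(c(-1, -1, -1), diag(3))       # dN/dxi for N1..N4
    g <- gref %*% t(invJ)                       # 4 x 3: dN_i/dx, dy, dz
    B <- matrix(0, 6, 12)
    for (a2 in 1:4) {
      col <- (a2 - 1) * 3
      B[1, col + 1] <- g[a2, 1]
      B[2, col + 2] <- g[a2, 2]
      B[3, col + 3] <- g[a2, 3]
      B[4, col + 1] <- g[a2, 2]; B[4, col + 2] <- g[a2, 1]
      B[5, col + 2] <- g[a2, 3]; B[5, col + 3] <- g[a2, 2]
      B[6, col + 1] <- g[a2, 3]; B[6, col + 3] <- g[a2, 1]
    }
    D <- D_by_region[[mesh$region[e]]]
    Ke <- V * t(B) %*% D %*% B
    idx <- as.vector(t(outer((nd - 1L) * 3L, 1:3, `+`)))
    ii[[e]] <- rep(idx, times = 12)
    jj[[e]] <- rep(idx, each = 12)
    xx[[e]] <- as.vector(Ke)
    B_list[[e]] <- B
  }
  K <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(3L * nrow(mesh$nodes), 3L * nrow(mesh$nodes))
  )
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  list(K = K, B = B_list, D_of = D_by_region)
}

tet_element_fields <- function(mesh, materials, u, B_list, D_of) {
  m <- nrow(mesh$tets)
  strain_eqv <- von_mises <- energy <- numeric(m)
  for (e in seq_len(m)) {
    nd <- mesh$tets[e, ]
    idx <- as.vector(t(outer((nd - 1L) * 3L, 1:3, `+`)))
    eps <- as.numeric(B_list[[e]] %*% u[idx])     # engineering shear
    D <- D_of[[mesh$region[e]]]
    sig <- as.numeric(D %*% eps)
    # principal stresses from the full tensor
    S <- matrix(c(sig[1], sig[4], sig[6],
                  sig[4], sig[2], sig[5],
                  sig[6], sig[5], sig[3]), 3, 3)
    sp <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    von_mises[e] <- sqrt(((sp[1] - sp[2])^2 + (sp[2] - sp[3])^2 + (sp[3] - sp[1])^2) / 2)
    Et <- matrix(c(eps[1], eps[4] / 2, eps[6] / 2,
                   eps[4] / 2, eps[2], eps[5] / 2,
                   eps[6] / 2, eps[5] / 2, eps[3]), 3, 3)
    ep <- eigen(Et, symmetric = TRUE, only.values = TRUE)$values
    nu <- materials[[mesh$region[e]]]$nu
    strain_eqv[e] <- sqrt(((ep[1] - ep[2])^2 + (ep[2] - ep[3])^2 + (ep[3] - ep[1])^2) / 2) / (1 + nu)
    energy[e] <- 0.5 * sum(sig * eps) * mesh$volumes[e] * 1e-3  # N mm -> J
  }
  tibble(
    element = seq_len(m), region = mesh$region,
    volume_mm3 = mesh$volumes,
    strain_eqv = strain_eqv, von_mises_MPa = von_mises,
    strain_energy_J = energy
  )
}

#' @export
print.field_map <- function(x, ...) {
  cat("<field_map> maxima:\n")
  print(as.data.frame(x$maxima[, c("field", "value", "unit", "at")]), row.names = FALSE)
  invisible(x)
}

#' @method tidy field_map
#' @export
tidy.field_map <- function(x, ...) x$elements

#' @method glance field_map
#' @export
glance.field_map <- function(x, ...) {
  tibble(
    max_displacement_mm = x$maxima$value[x$maxima$field == "displacement"],
    max_strain = x$maxima$value[x$maxima$field == "strain"],
    max_von_mises_MPa = x$maxima$value[x$maxima$field == "von_mises"],
    max_strain_energy_J = x$maxima$value[x$maxima$field == "strain_energy"],
    total_strain_energy_J = x$total_strain_energy_J,
    n_elements = nrow(x$elements)
  )
}

#' @method autoplot field_map
#' @export
autoplot.field_map <- function(object, ...) {
  ggplot2::ggplot(object$elements,
                  ggplot2::aes(x = .data$von_mises_MPa, fill = .data$region)) +
    ggplot2::geom_histogram(bins = 40, position = "stack") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "von Mises stress (MPa)", y = "elements",
                  title = "Element stress distribution")
}

#' Export field maps for visualization
#'
#' Writes the mesh and solved fields as a legacy ASCII VTK unstructured
#' grid (`fields.vtk`: point-data displacement vector, cell-data region id,
#' equivalent strain, von Mises stress, strain energy), the element field
#' table (`fields.csv`), and the maxima table (`maxima.json`,
#' `maxima.csv`). Output formatting is deterministic: re-export of the same
#' solution is byte-identical.
#'
#' @param fields a [solve_elasticity()] result.
#' @param mesh the solved [tet_mesh()] (defaults to the one in `fields`).
#' @param dir output directory (created).
#' @return invisibly, the paths written.
#' @export
export_maps <- function(fields, mesh = fields$mesh, dir = ".") {
  stopifnot(inherits(fields, "field_map"), inherits(mesh, "tet_mesh"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vtk <- file.path(dir, "fields.vtk")
  write_vtk_tet(
    vtk, mesh,
    point_vectors = list(displacement_mm = as.matrix(
      fields$displacement[, c("ux", "uy", "uz")])),
    cell_scalars = list(
      region_id = as.integer(factor(mesh$region)),
      strain_eqv = fields$elements$strain_eqv,
      von_mises_MPa = fields$elements$von_mises_MPa,
      strain_energy_J = fields$elements$strain_energy_J
    )
  )
  csv <- file.path(dir, "fields.csv")
  readr::write_csv(fields$elements, csv)
  mx_csv <- file.path(dir, "maxima.csv")
  readr::write_csv(fields$maxima, mx_csv)
  mx_json <- file.path(dir, "maxima.json")
  jsonlite::write_json(fields$maxima, mx_json, digits = NA)
  invisible(c(vtk, csv, mx_csv, mx_json))
}

# minimal legacy ASCII VTK unstructured-grid writer (cell type 10 = tet)
write_vtk_tet <- function(file, mesh, point_vectors = list(), cell_scalars = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "archforce field map", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", nn)), con)
  writeLines(sprintf("%.10g %.10g %.10g",
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(sprintf("4 %d %d %d %d",
                     mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (length(point_vectors)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nmv in names(point_vectors)) {
      V <- point_vectors[[nmv]]
      writeLines(sprintf("VECTORS %s double", nmv), con)
      writeLines(sprintf("%.10g %.10g %.10g", V[, 1], V[, 2], V[, 3]), con)
    }
  }
  if (length(cell_scalars)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nms in names(cell_scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nms), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", cell_scalars[[nms]]), con)
    }
  }
  invisible(file)
}
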