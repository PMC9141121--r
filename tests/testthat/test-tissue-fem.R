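bar_mesh <- function(L = 10, w = 2, cell = 1) {
  block_tet_mesh(c(L, w, w), cell_size = cell)
}

# axial restraint at x = 0 plus the minimal extra pins that block rigid-body
# modes without disturbing the exact uniaxial-stress field
bar_restraints <- function(mesh) {
  left <- select_face_nodes(mesh, "x", 0)
  fixed <- cbind(left, 1L)
  n0 <- left[which.min(rowSums(mesh$nodes[left, 2:3]^2))]
  y0 <- left[abs(mesh$nodes[left, 2]) < 1e-9]
  nz <- y0[which.max(mesh$nodes[y0, 3])]
  rbind(fixed, c(n0, 2L), c(n0, 3L), c(nz, 2L))
}

test_that("synthetic tooth model is valid, labeled, deterministic and refinable", {
  m1 <- build_synthetic_tooth_model(n_teeth = 3, seed = 4)
  expect_true(all(m1$volumes > 0))
  expect_setequal(unique(m1$region), c("tooth", "bone", "bracket"))
  expect_gte(nrow(m1$tets), 200)
  expect_length(attr(m1, "pads"), 3L)
  expect_true(all(lengths(attr(m1, "pads")) > 0))

  m2 <- build_synthetic_tooth_model(n_teeth = 3, seed = 4)
  expect_identical(m1$nodes, m2$nodes)

  fine <- build_synthetic_tooth_model(n_teeth = 3, cell_size = 1.4, seed = 4)
  expect_gt(nrow(fine$tets), nrow(m1$tets))

  # volume partition: tet volumes sum to the block volume
  expect_equal(sum(m1$volumes), 30 * 10 * 12, tolerance = 1e-9)

  expect_error(build_synthetic_tooth_model(root_length = 50),
               class = "archforce_meshing_error")
})

test_that("mesh quality stays above the configured floor for several seeds", {
  for (seed in c(1, 7, 23)) {
    m <- build_synthetic_tooth_model(n_teeth = 2, bone_block = c(20, 8, 10),
                                     seed = seed)
    q <- mesh_quality(m)
    expect_gt(attr(q, "min"), 0.1)
  }
})

test_that("zero forces give identically zero fields", {
  m <- build_synthetic_tooth_model(n_teeth = 2, bone_block = c(16, 8, 10),
                                   cell_size = 2.5, seed = 2)
  fm <- solve_elasticity(m, forces = NULL)
  expect_equal(max(abs(fm$u)), 0)
  expect_equal(max(fm$elements$von_mises_MPa), 0)
  expect_equal(fm$total_strain_energy_J, 0)
})

test_that("uniaxial bar matches sigma = F/A and tip displacement F L / (E A)", {
  L <- 10; w <- 2
  mesh <- bar_mesh(L, w, cell = 0.5)
  mat <- material("bar", 1000, 1e9, 0.3)
  A <- w * w
  Ftot <- 5
  fixed <- bar_restraints(mesh)
  right <- select_face_nodes(mesh, "x", L)
  loads <- tibble::tibble(node = right, fx = Ftot / length(right), fy = 0, fz = 0)
  fm <- solve_elasticity(mesh, materials = list(bone = mat),
                         forces = loads, fixed = fixed)
  E_mpa <- mat$E / 1e6
  tip <- mean(fm$displacement$ux[right])
  expect_equal(tip, Ftot * L / (E_mpa * A), tolerance = 0.02)
  sigma <- median(fm$elements$von_mises_MPa)
  expect_equal(sigma, Ftot / A, tolerance = 0.02)
})

test_that("constant-strain patch test is exact", {
  mesh <- build_synthetic_tooth_model(n_teeth = 1, root_length = 3,
                                      bone_block = c(6, 4, 5), cell_size = 1.6,
                                      seed = 9)
  mesh <- tet_mesh(mesh$nodes, mesh$tets, rep("bone", nrow(mesh$tets)))
  mat <- material("patch", 1000, 2e9, 0.25)
  # impose u = A x on every boundary node
  Amat <- matrix(c(1e-3, 4e-4, -2e-4,
                   3e-4, -5e-4, 1e-4,
                   -1e-4, 2e-4, 6e-4), 3, 3, byrow = TRUE)
  nd <- mesh$nodes
  lims <- apply(nd, 2, range)
  on_bd <- rowSums(sapply(1:3, function(a)
    abs(nd[, a] - lims[1, a]) < 1e-9 | abs(nd[, a] - lims[2, a]) < 1e-9)) > 0
  bnodes <- which(on_bd)
  fixed <- cbind(rep(bnodes, each = 3), rep(1:3, length(bnodes)))
  uvals <- as.vector(t(nd[bnodes, ] %*% t(Amat)))
  fm <- solve_elasticity(mesh, materials = list(bone = mat),
                         fixed = fixed, prescribed = uvals)
  # every element sees the same symmetric-gradient strain state
  Esym <- (Amat + t(Amat)) / 2
  ev <- eigen(Esym, symmetric = TRUE, only.values = TRUE)$values
  expected_eqv <- sqrt(((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                          (ev[3] - ev[1])^2) / 2) / (1 + mat$nu)
  expect_equal(fm$elements$strain_eqv, rep(expected_eqv, nrow(mesh$tets)),
               tolerance = 1e-10)
  expect_lt(diff(range(fm$elements$von_mises_MPa)) /
              mean(fm$elements$von_mises_MPa), 1e-10)
})

test_that("global equilibrium and the energy identity hold", {
  m <- build_synthetic_tooth_model(n_teeth = 2, bone_block = c(16, 8, 10),
                                   cell_size = 2, seed = 6)
  rec <- tibble::tibble(tooth = c("1.1", "1.2"), F_N = c(0.8, 1.5),
                        dx = c(0, 0.6), dy = c(1, 0.8), dz = c(0, 0))
  rec$dy[1] <- 1
  nrm <- sqrt(rec$dx^2 + rec$dy^2 + rec$dz^2)
  rec$dx <- rec$dx / nrm; rec$dy <- rec$dy / nrm; rec$dz <- rec$dz / nrm
  fm <- solve_elasticity(m, forces = rec)
  # sum of reactions at the fixed DOFs balances the applied force resultant
  comp <- (fm$fixed_dofs - 1L) %% 3L + 1L
  react_sum <- vapply(1:3, function(a) sum(fm$reactions[fm$fixed_dofs][comp == a]),
                      numeric(1))
  Fsum <- colSums(matrix(fm$f, ncol = 3, byrow = TRUE))
  expect_lt(max(abs(react_sum + Fsum)) / sum(abs(fm$f)), 1e-8)
  # energy identity: total strain energy = 1/2 u^T f (prescribed u are zero)
  expect_equal(fm$total_strain_energy_J,
               0.5 * sum(fm$u * fm$f) * 1e-3, tolerance = 1e-8)

  # linearity: doubled forces double displacements, quadruple energy
  rec2 <- rec; rec2$F_N <- 2 * rec2$F_N
  fm2 <- solve_elasticity(m, forces = rec2)
  expect_equal(fm2$u, 2 * fm$u, tolerance = 1e-9)
  expect_equal(fm2$total_strain_energy_J, 4 * fm$total_strain_energy_J,
               tolerance = 1e-9)
})

test_that("refinement reduces the bar-oracle error monotonically", {
  # fully clamped end face: the Poisson-constrained state is not exactly
  # representable, so the tip-displacement error is a real discretization
  # error and must shrink as the mesh is refined
  L <- 8; w <- 2
  mat <- material("bar", 1000, 1e9, 0.3)
  errs <- vapply(c(2, 1, 0.5), function(cell) {
    mesh <- bar_mesh(L, w, cell = cell)
    fixed <- select_face_nodes(mesh, "x", 0)   # all three DOFs
    right <- select_face_nodes(mesh, "x", L)
    loads <- tibble::tibble(node = right, fx = 1 / length(right), fy = 0, fz = 0)
    fm <- solve_elasticity(mesh, materials = list(bone = mat),
                           forces = loads, fixed = fixed)
    tip <- mean(fm$displacement$ux[right])
    abs(tip - 1 * L / (mat$E / 1e6 * w * w))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("maxima table matches the field arrays and exports are deterministic", {
  m <- build_synthetic_tooth_model(n_teeth = 2, bone_block = c(16, 8, 10),
                                   cell_size = 2.5, seed = 2)
  rec <- tibble::tibble(tooth = "1.1", F_N = 1, dx = 0, dy = 1, dz = 0)
  fm <- solve_elasticity(m, forces = rec[1, ])
  expect_equal(fm$maxima$value[fm$maxima$field == "displacement"],
               max(fm$displacement$magnitude_mm))
  expect_equal(fm$maxima$value[fm$maxima$field == "von_mises"],
               max(fm$elements$von_mises_MPa))
  expect_equal(fm$maxima$value[fm$maxima$field == "strain_energy"],
               max(fm$elements$strain_energy_J))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_maps(fm, m, d1)
  export_maps(fm, m, d2)
  for (f in c("fields.vtk", "fields.csv", "maxima.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  vtk <- readLines(file.path(d1, "fields.vtk"))
  expect_identical(vtk[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^VECTORS displacement_mm", vtk)))
  expect_true(any(grepl("^SCALARS von_mises_MPa", vtk)))

  # floating substructure -> diagnostic error
  expect_error(
    solve_elasticity(m, forces = rec[1, ],
                     fixed = cbind(1L, 1L)),
    class = "archforce_solver_error")
})
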