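mk_straight_model <- function(L = 10, n_el = 10, stations = NULL,
                              d = 0.3556, mat = material_preset("nitinol")) {
  p <- straight_path(L, n = 201)
  discretize(p, max_element_length = L / n_el, stations = stations,
             section_diameter = d, mat = mat)
}

test_that("shear modulus formula reproduces the preset transverse moduli", {
  expect_equal(shear_modulus_from(8.3e7, 0.33), 3.12e7, tolerance = 5e-3)
  expect_equal(shear_modulus_from(2.1e11, 0.31), 8.015e10, tolerance = 5e-4)
  expect_equal(shear_modulus_from(100, 0), 50)
  expect_error(shear_modulus_from(100, 0.7), class = "archforce_invalid_parameter")
})

test_that("material presets record their isotropy departure", {
  p <- material_presets()
  expect_named(p, c("nitinol", "nicr", "bone", "enamel"))
  # bone's stored G departs ~0.6% from E/(2(1+nu)); nitinol is consistent to 3 s.f.
  expect_gt(p$bone$iso_inconsistency, 0.004)
  expect_lt(p$nitinol$iso_inconsistency, 5e-3)
})

test_that("discretization respects element size and places nodes at stations", {
  m <- mk_straight_model(10, 10, stations = 3.14159)
  expect_gte(nrow(m$elements), 10)
  expect_true(any(abs(m$nodes$s_mm - 3.14159) <= 1e-9))
  expect_true(all(m$elements$length_mm <= 1 + 1e-9))

  p <- generate_arch_curve(width = 62, depth = 52, total_length = 152.12)
  tw <- trim_wire(p, 109.68)
  m2 <- discretize(tw, 1)
  expect_gte(nrow(m2$elements), 110)

  expect_error(discretize(straight_path(0.5), 1),
               class = "archforce_discretization_error")
})

test_that("center point load matches F L^3 / (192 E I) at machine precision", {
  mat <- test_material()
  m <- mk_straight_model(10, 10, stations = 5, d = 1, mat = mat)
  F <- 0.1
  sol <- assemble_and_solve(m, load_case(5, F, direction = c(0, 0, 1), frame = "arc"))
  E_mpa <- mat$E / 1e6
  expect_equal(sol$deflection_mm, F * 10^3 / (192 * E_mpa * m$I),
               tolerance = 1e-9)
  expect_equal(probe_deflection(sol, 5), sol$deflection_mm)
  expect_equal(probe_deflection(sol, 0), 0)
  expect_equal(probe_deflection(sol, 10), 0)
})

test_that("off-center load matches F a^3 b^3 / (3 E I L^3), any element count >= 2", {
  mat <- test_material()
  F <- 0.7; L <- 12; a <- 3.5
  E_mpa <- mat$E / 1e6
  for (n_el in c(4, 9, 40)) {
    m <- mk_straight_model(L, n_el, stations = a, d = 0.8, mat = mat)
    sol <- assemble_and_solve(m, load_case(a, F, direction = c(0, 1, 0), frame = "arc"))
    expect_equal(sol$deflection_mm,
                 clamped_clamped_deflection(F, L, E_mpa, m$I, a),
                 tolerance = 1e-9)
  }
})

test_that("deflection is linear in F and solutions superpose", {
  m <- mk_straight_model(10, 10, stations = c(3, 5))
  K <- assemble_stiffness(m)
  s1 <- assemble_and_solve(m, load_case(3, 1, direction = c(0, 0, 1), frame = "arc"), K = K)
  s2 <- assemble_and_solve(m, load_case(3, 2, direction = c(0, 0, 1), frame = "arc"), K = K)
  expect_equal(s2$deflection_mm, 2 * s1$deflection_mm, tolerance = 1e-12)

  # superposition: the two-load solution equals the sum of single-load ones
  lc3 <- load_case(3, 1, direction = c(0, 0, 1), frame = "arc")
  lc5 <- load_case(5, 1.7, direction = c(0, 1, 0), frame = "arc")
  s3 <- assemble_and_solve(m, lc3, K = K)
  s5 <- assemble_and_solve(m, lc5, K = K)
  s35 <- assemble_and_solve(m, list(lc3, lc5), K = K)
  sum_u <- as.matrix(s3$nodal[, -1]) + as.matrix(s5$nodal[, -1])
  expect_equal(as.matrix(s35$nodal[, -1]), sum_u, tolerance = 1e-10)
})

test_that("symmetric beam deflects symmetrically under a center load", {
  m <- mk_straight_model(10, 10, stations = c(3, 5, 7))
  sol <- assemble_and_solve(m, load_case(5, 1, direction = c(0, 0, 1), frame = "arc"))
  expect_equal(probe_deflection(sol, 3), probe_deflection(sol, 7), tolerance = 1e-9)
})

test_that("global stiffness is symmetric and has exactly 6 rigid-body modes", {
  p <- straight_path(3, n = 31)
  m <- discretize(p, 1)
  K <- assemble_stiffness(m)
  expect_lt(max(abs(K - t(K))) / max(abs(K)), 1e-10)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(ev)
  expect_equal(sum(abs(ev) / scale < 1e-10), 6L)

  # positive definite after clamping
  nn <- nrow(m$nodes)
  free <- setdiff(seq_len(6 * nn), c(1:6, (nn - 1) * 6 + 1:6))
  evc <- eigen(K[free, free], symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(evc), 0)
})

test_that("loads at a clamped end are rejected", {
  m <- mk_straight_model(10, 10)
  expect_error(assemble_and_solve(m, load_case(0, 1, frame = "arc")),
               class = "archforce_invalid_load")
  expect_error(assemble_and_solve(m, load_case(10, 1, frame = "arc")),
               class = "archforce_invalid_load")
})

test_that("solver handles the curved arch geometry of a real-size wire", {
  w <- trim_wire(generate_arch_curve(width = 62, depth = 52,
                                     total_length = 152.12, arch = "upper"),
                 109.68)
  s10 <- chord_to_arc(w, 10)
  m <- discretize(w, 2, stations = s10)
  sol <- assemble_and_solve(m, load_case(s10, 0.1, frame = "arc"))
  expect_gt(sol$deflection_mm, 0)
  # deflection linear in F on the curved geometry too
  sol2 <- assemble_and_solve(m, load_case(s10, 0.2, frame = "arc"))
  expect_equal(sol2$deflection_mm / sol$deflection_mm, 2, tolerance = 1e-9)
})
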