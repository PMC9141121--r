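test_that("published per-tooth forces are reproduced from (y, x) inputs", {
  teeth <- reference_tooth_measurements()
  law <- reference_force_law("upper")   # the set that regenerates both tables
  got <- compute_tooth_forces(teeth[, c("tooth", "arch", "y_mm", "x_mm")], law)
  merged <- dplyr::left_join(got, teeth[, c("tooth", "F_N")], by = "tooth",
                             suffix = c("", "_published"))
  rel <- abs(merged$F_N - merged$F_N_published) / merged$F_N_published
  expect_lt(max(rel), 0.01)
  # the spot value for the lower-right first molar
  expect_equal(got$F_N[got$tooth == "4.6"], 0.017648, tolerance = 3e-3)
  # rows beyond the outermost calibration node would be flagged if the law
  # carried its node set; the published-coefficient law has no span limit
  expect_false(any(got$extrapolated))
})

test_that("the 'lower'-labeled published coefficient set does NOT reproduce the tables", {
  teeth <- reference_tooth_measurements()
  law_lower <- reference_force_law("lower")
  got <- compute_tooth_forces(teeth[, c("tooth", "arch", "y_mm", "x_mm")], law_lower)
  merged <- dplyr::left_join(got, teeth[, c("tooth", "F_N")], by = "tooth",
                             suffix = c("", "_published"))
  rel <- abs(merged$F_N - merged$F_N_published) / merged$F_N_published
  expect_gt(median(rel), 0.05)
})

test_that("fitted law flags extrapolated teeth beyond the node span", {
  law <- fit_sextic(reference_stiffness_nodes(), arch = "upper")
  rec <- tibble::tibble(tooth = c("1.6", "1.1"), y_mm = c(25.66, 73.11),
                        x_mm = c(2.08, 5.84))
  got <- compute_tooth_forces(rec, law)  # sorted by quadrant then position
  expect_identical(got$extrapolated[got$tooth == "1.6"], FALSE)
  expect_identical(got$extrapolated[got$tooth == "1.1"], TRUE)
})

test_that("forces scale linearly in x and vanish at x = 0", {
  law <- reference_force_law("upper")
  rec <- tibble::tibble(tooth = c("4.6", "4.5", "4.3"),
                        y_mm = c(28.65, 38.32, 54.41),
                        x_mm = c(1.31, 2.75, 3.07))
  f1 <- compute_tooth_forces(rec, law)
  rec2 <- rec; rec2$x_mm <- 2 * rec2$x_mm
  f2 <- compute_tooth_forces(rec2, law)
  expect_equal(f2$F_N, 2 * f1$F_N, tolerance = 1e-12)
  rec0 <- rec; rec0$x_mm <- 0
  expect_equal(compute_tooth_forces(rec0, law)$F_N, rep(0, 3))
  # monotone in x at fixed y
  xg <- seq(0.5, 5, by = 0.5)
  Fg <- vapply(xg, function(x) {
    compute_tooth_forces(tibble::tibble(tooth = "4.6", y_mm = 28.65, x_mm = x),
                         law)$F_N
  }, numeric(1))
  expect_true(all(diff(Fg) > 0))
})

test_that("input validation: FDI codes, quadrant consistency, uniqueness", {
  law <- reference_force_law("upper")
  expect_error(compute_tooth_forces(
    tibble::tibble(tooth = "56", y_mm = 10, x_mm = 1), law),
    class = "archforce_parse_error")
  expect_error(compute_tooth_forces(
    tibble::tibble(tooth = "4.6", arch = "upper", y_mm = 10, x_mm = 1), law),
    class = "archforce_parse_error")
  expect_error(compute_tooth_forces(
    tibble::tibble(tooth = c("4.6", "4.6"), y_mm = c(10, 12), x_mm = c(1, 1)), law),
    class = "archforce_parse_error")
})

test_that("directions come from guide-point planes and rotate with the sites", {
  w <- straight_path(100, n = 500)
  sites <- bracket_sites(w, c(30, 70), c("1.1", "1.2"), arch = "upper")
  law <- reference_force_law("upper")
  rec <- compute_tooth_forces(
    tibble::tibble(tooth = c("1.1", "1.2"), y_mm = c(30, 40), x_mm = c(1, 2)), law)
  rec <- assign_directions(rec, sites)
  # straight wire along x with guide points offset in the XY plane -> +-z normal
  expect_equal(abs(rec$dz), rep(1, 2), tolerance = 1e-9)
  expect_equal(sqrt(rec$dx^2 + rec$dy^2 + rec$dz^2), rep(1, 2), tolerance = 1e-12)

  # equivariance: rotating all guide points rotates the directions identically
  set.seed(5)
  R <- random_rotation()
  sites_rot <- sites
  G <- as.matrix(sites[, c("px", "py", "pz")]) %*% t(R)
  sites_rot$px <- G[, 1]; sites_rot$py <- G[, 2]; sites_rot$pz <- G[, 3]
  rec_rot <- assign_directions(rec[, setdiff(names(rec), c("dx", "dy", "dz"))],
                               sites_rot)
  D0 <- as.matrix(rec[, c("dx", "dy", "dz")]) %*% t(R)
  D1 <- as.matrix(rec_rot[, c("dx", "dy", "dz")])
  expect_equal(D1, D0, tolerance = 1e-9, ignore_attr = TRUE)

  # collinear guide points are rejected
  bad <- sites
  bad$py <- 0; bad$pz <- 0
  expect_error(assign_directions(rec, bad), class = "archforce_invalid_parameter")
  expect_error(assign_directions(
    tibble::tibble(tooth = "4.8", F_N = 1), sites),
    class = "archforce_lookup_error")
})

test_that("force summary counts threshold exceedances as published", {
  teeth <- reference_tooth_measurements()
  law <- reference_force_law("upper")
  rec <- compute_tooth_forces(teeth[, c("tooth", "arch", "y_mm", "x_mm")], law)
  s <- summarize_forces(rec, threshold = 1)
  up <- s[s$arch == "upper", ]
  # two upper-arch teeth exceed 1 N (the central incisors' published forces
  # are 11.88 and 4.45 N)
  expect_identical(up$n_above_threshold, 2L)
  expect_identical(up$n, 11L)
  # empty input
  s0 <- summarize_forces(rec[0, ])
  expect_identical(nrow(s0), 0L)
  # all-equal forces
  eq <- tibble::tibble(arch = "upper", F_N = rep(2, 3), extrapolated = FALSE)
  se <- summarize_forces(eq)
  expect_equal(se$F_min, se$F_max)
})
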