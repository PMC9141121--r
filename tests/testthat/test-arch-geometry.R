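test_that("generated arch curves honor the requested total length exactly", {
  for (L in c(152.12, 143.12, 10)) {
    w <- generate_arch_curve(width = 60, depth = 50, total_length = L)
    expect_equal(w$total_length, L, tolerance = 1e-12)
  }
  expect_error(generate_arch_curve(total_length = -1),
               class = "archforce_invalid_parameter")
  expect_error(generate_arch_curve(width = -5),
               class = "archforce_invalid_parameter")
})

test_that("semicircular form has the analytic arc length pi * r", {
  r <- 10
  w <- generate_arch_curve(width = 2 * r, form = "semicircle", n_samples = 10000)
  expect_equal(w$total_length, pi * r, tolerance = 1e-6)
})

test_that("wire_path invariants: arc length consistency and idempotent resampling", {
  w <- generate_arch_curve(width = 55, depth = 45, n_samples = 800)
  seg <- diff(w$samples$s_mm)
  expect_true(all(seg > 0))
  P <- as.matrix(w$samples[, c("x_mm", "y_mm", "z_mm")])
  expect_equal(sum(sqrt(rowSums(diff(P)^2))), w$total_length,
               tolerance = 1e-9)
  w2 <- wire_path(P, n_samples = nrow(P))
  expect_equal(w2$total_length, w$total_length, tolerance = 1e-9)
})

test_that("trimming removes exactly the requested material", {
  w <- generate_arch_curve(width = 62, depth = 52, total_length = 152.12)
  t1 <- trim_wire(w, 109.68)
  expect_equal(t1$total_length, 109.68, tolerance = 1e-9)
  expect_equal(attr(t1, "removed_mm"), 152.12 - 109.68, tolerance = 1e-6)

  w2 <- generate_arch_curve(width = 60, depth = 48, total_length = 143.12)
  t2 <- trim_wire(w2, 104.09)
  expect_equal(attr(t2, "removed_mm"), 143.12 - 104.09, tolerance = 1e-6)

  t3 <- trim_wire(w, w$total_length)
  expect_equal(t3$total_length, w$total_length, tolerance = 1e-9)
  expect_error(trim_wire(w, 200), class = "archforce_invalid_parameter")
})

test_that("arc-length coordinate: endpoints, midpoint, projection tolerance", {
  p <- straight_path(10)
  expect_equal(arc_length_coordinate(p, c(0, 0, 0)), 0)
  expect_equal(arc_length_coordinate(p, c(10, 0, 0)), 10)
  expect_equal(arc_length_coordinate(p, c(5, 0, 0)), 5, tolerance = 1e-9)
  expect_error(arc_length_coordinate(p, c(5, 3, 0)),
               class = "archforce_projection_error")
})

test_that("chord coordinate equals arc length on a straight wire and is below it on curves", {
  p <- straight_path(10)
  expect_equal(chord_coordinate(p, c(7, 0, 0)), 7, tolerance = 1e-9)

  r <- 8
  qc <- generate_arch_curve(width = 2 * r, form = "semicircle", n_samples = 4001)
  # end of the first quarter of the semicircle: arc pi*r/2, chord r*sqrt(2)
  pt <- c(0, r, 0)
  expect_equal(arc_length_coordinate(qc, pt), pi * r / 2, tolerance = 1e-4)
  expect_equal(chord_coordinate(qc, pt), r * sqrt(2), tolerance = 1e-4)

  # y >= z along the whole curve
  idx <- seq(1, nrow(qc$samples), by = 200)
  for (i in idx) {
    pti <- as.numeric(qc$samples[i, c("x_mm", "y_mm", "z_mm")])
    y <- arc_length_coordinate(qc, pti)
    z <- chord_coordinate(qc, pti)
    expect_gte(y + 1e-9, z)
  }
})

test_that("arc length is invariant under rigid motion", {
  set.seed(42)
  w <- generate_arch_curve(width = 50, depth = 40, n_samples = 500)
  for (rep in 1:5) {
    R <- random_rotation()
    w2 <- rotate_path(w, R, shift = rnorm(3, sd = 20))
    expect_equal(w2$total_length, w$total_length, tolerance = 1e-9)
  }
})

test_that("injected bracket offsets are recovered by measure_deformation", {
  w <- generate_arch_curve(width = 62, depth = 52, total_length = 109.68,
                           arch = "upper", n_samples = 2000)
  pos <- seq(10, 100, length.out = 6)
  teeth <- c("1.6", "1.5", "1.3", "2.3", "2.5", "2.6")
  sites <- bracket_sites(w, pos, teeth, arch = "upper")

  # zero offsets: identical paths
  pair0 <- build_deformed_path(w, sites, matrix(0, 6, 3))
  expect_equal(measure_deformation(pair0)$x_mm, rep(0, 6))
  expect_equal(pair0$deformed$total_length, w$total_length, tolerance = 1e-9)

  # single displaced site, magnitude of a typical premolar deformation
  off <- matrix(0, 6, 3); off[2, ] <- c(0, 2.75, 0)
  pair1 <- build_deformed_path(w, sites, off)
  expect_equal(measure_deformation(pair1, "1.5"), 2.75, tolerance = 0.02 * 2.75)

  # random offsets U(1, 9) mm all recovered within 2%
  set.seed(7)
  mags <- runif(6, 1, 9)
  dirs <- matrix(rnorm(18), 6, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pair2 <- build_deformed_path(w, sites, dirs * mags)
  got <- measure_deformation(pair2)$x_mm
  expect_equal(got, mags, tolerance = 0.02)

  expect_error(measure_deformation(pair2, "4.6"), class = "archforce_lookup_error")
})

test_that("deformation distance matches plain Euclidean geometry", {
  w <- straight_path(100, n = 500)
  sites <- bracket_sites(w, c(30, 70), c("1.1", "2.1"), arch = "upper")
  pair <- build_deformed_path(w, sites, rbind(c(3, 4, 0), c(0, 0, 9.2)))
  expect_equal(measure_deformation(pair, "1.1"), 5, tolerance = 1e-9)
  expect_equal(measure_deformation(pair, "2.1"), 9.2, tolerance = 1e-9)
})

test_that("bracket sites validate FDI codes, uniqueness and collinearity", {
  w <- straight_path(50, n = 200)
  expect_error(bracket_sites(w, c(10, 20), c("9.9", "1.2"), arch = "upper"),
               class = "archforce_parse_error")
  expect_error(bracket_sites(w, c(10, 20), c("1.1", "1.1"), arch = "upper"),
               class = "archforce_invalid_parameter")
  expect_error(bracket_sites(w, c(10, 20), c("4.6", "4.5"), arch = "upper"),
               class = "archforce_parse_error")
  s <- bracket_sites(w, c(10, 20), c("1.1", "1.2"), arch = "upper")
  expect_equal(nrow(s), 6L)
})

test_that("wire path CSV round trip preserves geometry", {
  w <- generate_arch_curve(width = 40, depth = 30, n_samples = 300)
  f <- withr::local_tempfile(fileext = ".csv")
  write_wire_path(w, f)
  w2 <- read_wire_path(f)
  expect_equal(w2$total_length, w$total_length, tolerance = 1e-6)
})
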