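# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Monomial coefficients (degree 6 .. 0) of the Lagrange interpolant through
# (y_i, k_i): expand each Lagrange basis polynomial by repeated convolution.
lagrange_monomial_coefficients <- function(y, k) {
  n <- length(y)
  coef <- numeric(n)                       # constant term last
  for (i in seq_len(n)) {
    p <- 1                                 # polynomial "1", ascending order
    for (j in seq_len(n)[-i]) {
      # multiply by (t - y_j) / (y_i - y_j)
      p <- (c(0, p) - c(p * y[j], 0)) / (y[i] - y[j])
    }
    coef <- coef + k[i] * p
  }
  rev(coef)                                # descending: t^(n-1) .. t^0
}

# Clamped-clamped prismatic beam, transverse point load F at distance a from
# one end (b = L - a): deflection under the load.
clamped_clamped_deflection <- function(F, L, E, I, a) {
  b <- L - a
  F * a^3 * b^3 / (3 * E * I * L^3)
}

# random 3D rotation matrix, seeded by the caller
random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_path <- function(path, R, shift = c(0, 0, 0)) {
  P <- as.matrix(path$samples[, c("x_mm", "y_mm", "z_mm")]) %*% t(R)
  P <- sweep(P, 2, shift, `+`)
  wire_path(P, arch = path$arch, resample = FALSE)
}

# straight wire along the global x axis as a wire_path
straight_path <- function(L = 10, n = 101) {
  wire_path(cbind(seq(0, L, length.out = n), 0, 0), n_samples = n)
}

# a stiff generic test material with exact isotropy
test_material <- function() material("test steel", 7800, 2.1e11, 0.3)
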