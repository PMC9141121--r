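#' Reference calibration dataset
#'
#' Plain-text fixtures shipped with the package: the printed results of a
#' clinical straight-wire calibration case (0.014-inch nitinol wire, upper
#' wire trimmed to 109.68 mm). They comprise the load-deflection sweeps at
#' three stations, the seven (y, k) stiffness nodes, the two published
#' coefficient sets of the sextic force law, and the per-tooth measured
#' coordinates/deformations with their published forces.
#'
#' `reference_stiffness_nodes()` returns the node table with both published
#' k columns: `K_measured` (k recomputed at the station from the sweep) and
#' `k_y` (the column actually interpolated by the published fit). The two
#' disagree by a factor of 10 at y = 20.04 — a conflict in the source data
#' that [audit_reference_tables()] surfaces rather than resolves. The `k`
#' column returned is `k_y`, the set consistent with the published
#' coefficients.
#'
#' @name reference_data
#' @return Tibbles; see each function.
NULL

ref_file <- function(name) {
  f <- system.file("extdata", "reference", name, package = "archforce")
  if (f == "") {
    abort(sprintf("reference fixture '%s' is missing.", name),
          class = "archforce_configuration_error")
  }
  f
}

#' @rdname reference_data
#' @param station one of `"z10"`, `"z20"`, `"mid"` (the mid-wire station,
#'   z = 51.38 mm).
#' @export
reference_load_sweep <- function(station = c("z10", "z20", "mid")) {
  station <- match.arg(station)
  z <- c(z10 = 10, z20 = 20, mid = 51.38)[[station]]
  d <- readr::read_csv(ref_file(paste0("load_sweep_", station, ".csv")),
                       show_col_types = FALSE)
  d <- dplyr::mutate(d, z_mm = z, .before = 1)
  class(d) <- c("calibration_table", class(d))
  d
}

#' @rdname reference_data
#' @export
reference_stiffness_nodes <- function() {
  d <- readr::read_csv(ref_file("stiffness_nodes_upper.csv"), show_col_types = FALSE)
  dplyr::mutate(d, k = .data$k_y)
}

#' @rdname reference_data
#' @export
reference_tooth_measurements <- function() {
  readr::read_csv(
    ref_file("tooth_measurements.csv"), show_col_types = FALSE,
    col_types = readr::cols(tooth = readr::col_character())
  )
}

#' @rdname reference_data
#' @param arch `"upper"` or `"lower"`: which published coefficient set to
#'   load. Note the audit finding: the set published for the upper wire is
#'   the one that reproduces the per-tooth force tables of *both* arches;
#'   see [audit_reference_tables()].
#' @export
reference_force_law <- function(arch = c("upper", "lower")) {
  arch <- match.arg(arch)
  d <- readr::read_csv(ref_file("force_law_coefficients.csv"), show_col_types = FALSE)
  d <- d[d$arch == arch, ]
  co <- setNames(d$coefficient, d$term)[letters[1:7]]
  structure(
    list(coefficients = co, nodes = NULL, arch = arch, exponent = 1L,
         condition = NA_real_, max_residual = NA_real_),
    class = "sextic_force_law"
  )
}
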