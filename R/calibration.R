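#' Elastic constant from a load-deflection pair
#'
#' `k = F / x`, the pointwise elastic constant of the wire at the loaded
#' station (N/mm). Vectorized.
#'
#' @param F force, N.
#' @param x deflection, mm (> 0).
#' @return k in N/mm.
#' @examples
#' compute_k(0.1, 0.4233)
#' @export
compute_k <- function(F, x) {
  if (any(x <= 0)) {
    abort("deflection x must be positive.", class = "archforce_division_domain_error")
  }
  F / x
}

#' Sweep point loads over stations of a clamped wire
#'
#' The virtual calibration protocol: for every (station, force) pair, solve
#' the clamped-clamped beam, probe the deflection at the load point and
#' record `k = F/x`. The stiffness matrix is factored from one assembly and
#' reused; every load case is still solved individually.
#'
#' @param path a [wire_path()] (the trimmed wire).
#' @param stations_z station coordinates, mm. Interpreted in `frame`.
#' @param forces force magnitudes, N (default the reference grid 0.1-10 N).
#' @param frame `"chord"` (default) or `"arc"`.
#' @param direction optional unit load direction (default: arch-plane
#'   normal).
#' @param max_element_length element size for [discretize()], mm.
#' @param section_diameter,mat forwarded to [discretize()].
#' @return A `calibration_table` tibble with columns
#'   `z_mm, y_mm, F_N, x_mm, k` (one row per station x force).
#' @export
run_load_sweep <- function(path, stations_z,
                           forces = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.8, 0.9, 1, 2, 5, 10),
                           frame = c("chord", "arc"), direction = NULL,
                           max_element_length = 1,
                           section_diameter = 0.3556,
                           mat = material_preset("nitinol")) {
  frame <- match.arg(frame)
  if (any(forces <= 0)) abort("forces must be positive.", class = "archforce_invalid_parameter")
  s_arc <- if (frame == "chord") chord_to_arc(path, stations_z) else stations_z
  model <- discretize(path, max_element_length, stations = s_arc,
                      section_diameter = section_diameter, mat = mat)
  K <- assemble_stiffness(model)
  if (is.null(direction)) direction <- arch_plane_normal(path)
  grid <- tidyr::expand_grid(station_i = seq_along(stations_z), F_N = forces)
  rows <- purrr::pmap_dfr(grid, function(station_i, F_N) {
    lc <- load_case(s_arc[station_i], F_N, direction = direction, frame = "arc")
    sol <- assemble_and_solve(model, lc, K = K)
    x <- sol$deflection_mm
    tibble(
      z_mm = stations_z[station_i], y_mm = s_arc[station_i],
      F_N = F_N, x_mm = x, k = compute_k(F_N, x)
    )
  })
  class(rows) <- c("calibration_table", class(rows))
  attr(rows, "path") <- path
  rows
}

#' Check that k is independent of the applied force
#'
#' Per station, the relative spread `(max k - min k) / mean k` across the
#' force levels; the table passes if every spread is within `tol`. For a
#' linear solver the spread is at rounding level; for imported printed
#' tables 6-significant-figure rounding dominates.
#'
#' @param table a `calibration_table` (or any tibble with `z_mm, F_N, k`).
#' @param tol relative tolerance (default 1e-9 for solver output; use
#'   1e-6 for printed 6 s.f. tables).
#' @return An `invariance_report`: list with `pass` and `per_station`
#'   tibble (`z_mm, n_forces, k_mean, rel_spread, pass`).
#' @export
check_force_invariance <- function(table, tol = 1e-9) {
  per <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(table), .data$z_mm),
    n_forces = dplyr::n(),
    k_mean = mean(.data$k),
    rel_spread = (max(.data$k) - min(.data$k)) / mean(.data$k),
    .groups = "drop"
  )
  if (any(per$n_forces < 2L)) {
    abort("need at least 2 forces per station.", class = "archforce_invalid_parameter")
  }
  per$pass <- per$rel_spread <= tol
  structure(list(pass = all(per$pass), tol = tol, per_station = per),
            class = "invariance_report")
}

#' @export
print.invariance_report <- function(x, ...) {
  cat(sprintf("<invariance_report> %s (tol %.1e); worst relative spread %.2e\n",
              if (x$pass) "PASS" else "FAIL", x$tol, max(x$per_station$rel_spread)))
  invisible(x)
}

#' Collapse a calibration sweep into (y, k) interpolation nodes
#'
#' One node per station: k taken at the smallest force (identical to the
#' others under linearity; the spread is kept for audit), y the arc-length
#' coordinate of the station. The implicit node (0, 0) — zero stiffness
#' contribution at the clamped origin, which pins the polynomial's constant
#' term to zero — is prepended.
#'
#' @param table a [run_load_sweep()] result, or any tibble with
#'   `z_mm, F_N, x_mm, k` columns.
#' @param path optional [wire_path()] used to map `z_mm` to arc length when
#'   the table has no `y_mm` column.
#' @return A tibble `y_mm, z_mm, k`, sorted by `y_mm`, first row (0, 0, 0).
#' @export
build_node_table <- function(table, path = NULL) {
  tb <- tibble::as_tibble(table)
  if (!"y_mm" %in% names(tb)) {
    if (is.null(path)) path <- attr(table, "path")
    if (is.null(path)) {
      abort("no y_mm column and no path to map z -> y.", class = "archforce_coordinate_error")
    }
    tb$y_mm <- chord_to_arc(path, tb$z_mm)
  }
  nodes <- dplyr::summarise(
    dplyr::group_by(tb, .data$z_mm, .data$y_mm),
    k_spread = (max(.data$k) - min(.data$k)) / mean(.data$k),
    k = .data$k[which.min(.data$F_N)],
    .groups = "drop"
  )
  nodes <- dplyr::arrange(nodes, .data$y_mm)
  if (any(diff(nodes$y_mm) <= 0)) {
    abort("station y coordinates are not strictly increasing.",
          class = "archforce_coordinate_error")
  }
  dplyr::bind_rows(
    tibble(z_mm = 0, y_mm = 0, k = 0, k_spread = 0),
    nodes
  )[, c("y_mm", "z_mm", "k", "k_spread")]
}

#' @method autoplot calibration_table
#' @export
autoplot.calibration_table <- function(object, ...) {
  d <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(object), .data$z_mm),
                        k = mean(.data$k), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z_mm, y = .data$k)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "station z (mm)", y = "k (N/mm)",
                  title = "Calibrated elastic constant along the wire")
}
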