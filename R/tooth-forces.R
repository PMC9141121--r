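#' Per-tooth elastic forces from measured coordinates and deformations
#'
#' Applies the fitted force law `F = k(y) * x^n` to each tooth's measured
#' arc coordinate y and deformation x. Forces are reported as magnitudes
#' (the wire's restoring force; directions are assigned separately with
#' [assign_directions()]). Rows whose y exceeds the law's outermost fit
#' node are flagged `extrapolated`.
#'
#' @param records tibble with columns `tooth` (FDI code string), `y_mm`,
#'   `x_mm` and optionally `arch` (derived from the FDI quadrant when
#'   absent).
#' @param law a [fit_sextic()] / [reference_force_law()] law.
#' @return A tibble `tooth, arch, y_mm, x_mm, k, F_N, extrapolated`,
#'   sorted by quadrant then position; `k` keeps the signed interpolant
#'   value, `F_N` is the force magnitude.
#' @examples
#' law <- reference_force_law("upper")
#' compute_tooth_forces(
#'   tibble::tibble(tooth = "4.6", y_mm = 28.65, x_mm = 1.31), law
#' )
#' @export
compute_tooth_forces <- function(records, law) {
  records <- tibble::as_tibble(records)
  stopifnot(inherits(law, "sextic_force_law"))
  need <- c("tooth", "y_mm", "x_mm")
  if (!all(need %in% names(records))) {
    abort("`records` needs columns tooth, y_mm, x_mm.", class = "archforce_parse_error")
  }
  check_fdi(records$tooth)
  q <- as.integer(substr(records$tooth, 1, 1))
  derived_arch <- ifelse(q %in% c(1L, 2L), "upper", "lower")
  if (!"arch" %in% names(records)) {
    records$arch <- derived_arch
  } else if (any(records$arch != derived_arch)) {
    abort("arch column inconsistent with FDI quadrant.", class = "archforce_parse_error")
  }
  for (a in unique(records$arch)) {
    if (anyDuplicated(records$tooth[records$arch == a])) {
      abort("tooth codes must be unique per arch.", class = "archforce_parse_error")
    }
  }
  if (any(records$y_mm <= 0) || any(records$x_mm < 0)) {
    abort("need y_mm > 0 and x_mm >= 0.", class = "archforce_domain_error")
  }
  span <- law_span(law)
  if (!is.finite(span)) span <- Inf
  k <- evaluate_k(law, records$y_mm, warn_extrapolation = FALSE)
  out <- dplyr::mutate(
    records,
    k = k,
    F_N = abs(k) * records$x_mm^law$exponent,
    extrapolated = records$y_mm > span
  )
  pos <- as.integer(substr(out$tooth, 3, 3))
  out[order(q, pos), c("tooth", "arch", "y_mm", "x_mm", "k", "F_N",
                       setdiff(names(out), c("tooth", "arch", "y_mm", "x_mm", "k", "F_N")))]
}

#' Assign force directions from bracket guide-point planes
#'
#' Each tooth's force acts along the outward unit normal of its bracket's
#' guide-point plane (outward = away from the centroid of all sites),
#' emulating how the directions are set graphically on the bracket pads.
#'
#' @param records a [compute_tooth_forces()] tibble.
#' @param sites a [bracket_sites()] tibble covering every record's tooth.
#' @return `records` with unit-direction columns `dx, dy, dz` added.
#' @export
assign_directions <- function(records, sites) {
  records <- tibble::as_tibble(records)
  sites <- tibble::as_tibble(sites)
  centroid <- c(mean(sites$px), mean(sites$py), mean(sites$pz))
  dirs <- purrr::map(records$tooth, function(code) {
    G <- as.matrix(sites[sites$tooth == code, c("px", "py", "pz")])
    if (nrow(G) != 3L) {
      abort(sprintf("no bracket site with 3 guide points for tooth %s.", code),
            class = "archforce_lookup_error")
    }
    if (collinear3(G)) {
      abort(sprintf("guide points of tooth %s are collinear.", code),
            class = "archforce_invalid_parameter")
    }
    n <- pracma_cross(G[2, ] - G[1, ], G[3, ] - G[1, ])
    n <- n / sqrt(sum(n^2))
    if (sum(n * (colMeans(G) - centroid)) < 0) n <- -n
    n
  })
  D <- do.call(rbind, dirs)
  dplyr::mutate(records, dx = D[, 1], dy = D[, 2], dz = D[, 3])
}

#' Summarize a per-tooth force set
#'
#' Per-arch minimum, maximum and total force magnitude, the number of
#' extrapolated rows, and the number exceeding a clinical threshold
#' (default 1 N, the commonly cited upper bound for optimal orthodontic
#' force — informational only, never a filter).
#'
#' @param records a [compute_tooth_forces()] tibble (may be empty).
#' @param threshold clinical force threshold, N.
#' @return A tibble `arch, n, F_min, F_max, F_total, n_extrapolated,
#'   n_above_threshold`.
#' @export
summarize_forces <- function(records, threshold = 1) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    return(tibble(arch = character(), n = integer(),
                  F_min = numeric(), F_max = numeric(), F_total = numeric(),
                  n_extrapolated = integer(), n_above_threshold = integer()))
  }
  if (!"extrapolated" %in% names(records)) records$extrapolated <- FALSE
  dplyr::summarise(
    dplyr::group_by(records, .data$arch),
    n = dplyr::n(),
    F_min = min(.data$F_N), F_max = max(.data$F_N), F_total = sum(.data$F_N),
    n_extrapolated = sum(.data$extrapolated),
    n_above_threshold = sum(.data$F_N > threshold),
    .groups = "drop"
  )
}

#' Plot per-tooth forces
#'
#' @param records a [compute_tooth_forces()] tibble.
#' @param threshold reference line, N.
#' @return a ggplot.
#' @export
plot_tooth_forces <- function(records, threshold = 1) {
  ggplot2::ggplot(tibble::as_tibble(records),
                  ggplot2::aes(x = .data$tooth, y = .data$F_N, fill = .data$arch)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "tooth (FDI)", y = "elastic force (N)",
                  title = "Per-bracket elastic forces")
}

#' Read/write per-tooth force tables
#'
#' Input CSV `tooth,arch,y_mm,x_mm`; output CSV adds
#' `F_N,k,dx,dy,dz,extrapolated` as available.
#' @param records tibble to write.
#' @param file file path.
#' @return tibble (read) or `file` invisibly (write).
#' @export
read_tooth_measurements <- function(file) {
  readr::read_csv(file, show_col_types = FALSE,
                  col_types = readr::cols(tooth = readr::col_character()))
}

#' @rdname read_tooth_measurements
#' @export
write_tooth_forces <- function(records, file) {
  readr::write_csv(tibble::as_tibble(records), file)
  invisible(file)
}
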