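#' Bracket and tube sites along an arch
#'
#' Places bracket/tube sites at given arc-length positions on a wire path.
#' Each site carries three non-collinear guide points defining the local
#' bracket frame (two points along the wire tangent, one offset along the
#' outward normal), emulating the three path-defining points placed on each
#' bracket or tube model.
#'
#' @param path a [wire_path()].
#' @param positions arc-length positions (mm) of the sites, inside the span.
#' @param teeth FDI tooth codes as strings (e.g. `"1.3"`), one per site,
#'   unique within the arch.
#' @param arch `"upper"` or `"lower"`.
#' @param tangent_offset half-spacing of the two tangent guide points (mm).
#' @param normal_offset offset of the third guide point (mm).
#' @return A `bracket_sites` tibble with one row per guide point:
#'   `tooth, arch, s_mm, point, px, py, pz`.
#' @export
bracket_sites <- function(path, positions, teeth, arch = c("upper", "lower"),
                          tangent_offset = 1, normal_offset = 0.5) {
  arch <- match.arg(arch)
  stopifnot(inherits(path, "wire_path"))
  if (length(positions) != length(teeth)) {
    abort("`positions` and `teeth` must have the same length.",
          class = "archforce_invalid_parameter")
  }
  if (anyDuplicated(teeth)) {
    abort("tooth codes must be unique per arch.", class = "archforce_invalid_parameter")
  }
  check_fdi(teeth, arch)
  L <- path$total_length
  if (any(positions < tangent_offset) || any(positions > L - tangent_offset)) {
    abort("site positions fall outside the wire span.", class = "archforce_placement_error")
  }
  rows <- purrr::map2_dfr(positions, teeth, function(s, code) {
    p0 <- point_at_arclength(path, s)[1, ]
    tg <- unit_tangent_at(path, s)[1, ]
    nrm <- pracma_cross(c(0, 0, 1), tg)
    if (sqrt(sum(nrm^2)) < 1e-6) nrm <- pracma_cross(c(0, 1, 0), tg)
    nrm <- nrm / sqrt(sum(nrm^2))
    g1 <- point_at_arclength(path, s - tangent_offset)[1, ]
    g2 <- p0 + normal_offset * nrm
    g3 <- point_at_arclength(path, s + tangent_offset)[1, ]
    G <- rbind(g1, g2, g3)
    if (collinear3(G)) {
      abort("guide points are collinear; increase normal_offset.",
            class = "archforce_invalid_parameter")
    }
    tibble(tooth = code, arch = arch, s_mm = s, point = 1:3,
           px = G[, 1], py = G[, 2], pz = G[, 3])
  })
  class(rows) <- c("bracket_sites", class(rows))
  rows
}

collinear3 <- function(G, tol = 1e-8) {
  v1 <- G[2, ] - G[1, ]
  v2 <- G[3, ] - G[1, ]
  n <- pracma_cross(v1, v2)
  sqrt(sum(n^2)) < tol * max(1, sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
}

check_fdi <- function(teeth, arch = NULL) {
  ok <- grepl("^[1-4]\\.[1-8]$", teeth)
  if (!all(ok)) {
    abort(sprintf("malformed FDI code(s): %s", paste(teeth[!ok], collapse = ", ")),
          class = "archforce_parse_error")
  }
  if (!is.null(arch)) {
    q <- as.integer(substr(teeth, 1, 1))
    expected <- ifelse(q %in% c(1L, 2L), "upper", "lower")
    bad <- expected != arch
    if (any(bad)) {
      abort(sprintf("FDI quadrant inconsistent with arch '%s': %s",
                    arch, paste(teeth[bad], collapse = ", ")),
            class = "archforce_parse_error")
    }
  }
  invisible(TRUE)
}

#' Read/write bracket site tables
#'
#' CSV layout `tooth,arch,px,py,pz`, three grouped rows per site.
#' @param sites a `bracket_sites` tibble.
#' @param file file path.
#' @return the tibble (read) or `file` invisibly (write).
#' @export
write_bracket_sites <- function(sites, file) {
  readr::write_csv(dplyr::select(sites, "tooth", "arch", "px", "py", "pz"), file)
  invisible(file)
}

#' @rdname write_bracket_sites
#' @export
read_bracket_sites <- function(file) {
  d <- readr::read_csv(file, show_col_types = FALSE,
                       col_types = readr::cols(tooth = readr::col_character()))
  d <- dplyr::group_by(d, .data$tooth)
  d <- dplyr::mutate(d, point = dplyr::row_number())
  d <- dplyr::ungroup(d)
  class(d) <- c("bracket_sites", class(d))
  d
}

#' Build a deformed wire path from per-site displacements
#'
#' Displaces the wire at each bracket site by the given 3D offset, blending
#' smoothly back to the undeformed curve between sites with compactly
#' supported cosine bumps (so each site's displacement is attained exactly
#' at its station). Records the characteristic-point correspondences used
#' later to measure per-tooth deformations.
#'
#' @param undeformed a [wire_path()].
#' @param sites a [bracket_sites()] tibble (at least 2 sites).
#' @param offsets matrix or data frame of per-site displacements, columns
#'   `dx, dy, dz` (mm), rows in site order; or a single number = magnitude
#'   drawn towards the outward normal.
#' @param bump_halfwidth half-width (mm) of the blending bump; default
#'   0.45 x the minimum site spacing, which keeps neighbouring bumps from
#'   overlapping each other's centers.
#' @return A `deformation_pair`: list with `undeformed`, `deformed`
#'   ([wire_path()]s sharing the arch label) and `correspondences` (tibble
#'   `tooth, s_mm, ux, uy, uz, vx, vy, vz, x_mm`).
#' @export
build_deformed_path <- function(undeformed, sites, offsets,
                                bump_halfwidth = NULL) {
  stopifnot(inherits(undeformed, "wire_path"), inherits(sites, "bracket_sites"))
  site_tbl <- dplyr::distinct(sites, .data$tooth, .data$arch, .data$s_mm)
  n_sites <- nrow(site_tbl)
  if (n_sites < 2L) {
    abort("need at least 2 sites.", class = "archforce_invalid_parameter")
  }
  offsets <- as.matrix(offsets)
  if (ncol(offsets) != 3L || nrow(offsets) != n_sites || any(!is.finite(offsets))) {
    abort("`offsets` must be a finite n_sites x 3 matrix.",
          class = "archforce_invalid_parameter")
  }
  L <- undeformed$total_length
  if (any(site_tbl$s_mm <= 0 | site_tbl$s_mm >= L)) {
    abort("sites outside the wire span.", class = "archforce_placement_error")
  }
  if (is.null(bump_halfwidth)) {
    gaps <- diff(sort(site_tbl$s_mm))
    bump_halfwidth <- 0.45 * min(gaps)
  }
  s_samp <- undeformed$samples$s_mm
  disp <- matrix(0, length(s_samp), 3)
  bump <- function(u) ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)
  for (i in seq_len(n_sites)) {
    w <- bump((s_samp - site_tbl$s_mm[i]) / bump_halfwidth)
    disp <- disp + outer(w, offsets[i, ])
  }
  P_def <- path_matrix(undeformed) + disp
  deformed <- wire_path(P_def, arch = undeformed$arch, resample = FALSE)
  u_pts <- point_at_arclength(undeformed, site_tbl$s_mm)
  v_pts <- u_pts + offsets   # bump = 1 exactly at the site station
  correspondences <- tibble(
    tooth = site_tbl$tooth,
    s_mm = site_tbl$s_mm,
    ux = u_pts[, 1], uy = u_pts[, 2], uz = u_pts[, 3],
    vx = v_pts[, 1], vy = v_pts[, 2], vz = v_pts[, 3],
    x_mm = sqrt(rowSums(offsets^2))
  )
  structure(
    list(undeformed = undeformed, deformed = deformed,
         correspondences = correspondences),
    class = "deformation_pair"
  )
}

#' @export
print.deformation_pair <- function(x, ...) {
  cat(sprintf("<deformation_pair> %d correspondences, max deformation %.3f mm\n",
              nrow(x$correspondences), max(x$correspondences$x_mm)))
  invisible(x)
}

#' Measure per-tooth wire deformations
#'
#' The deformation x of a site is the Euclidean distance between its
#' characteristic points on the undeformed and deformed wire models.
#'
#' @param pair a [build_deformed_path()] result.
#' @param tooth optional FDI code; if given, returns that site's scalar x.
#' @return A tibble `tooth, s_mm, x_mm` (or a scalar when `tooth` is given).
#' @export
measure_deformation <- function(pair, tooth = NULL) {
  stopifnot(inherits(pair, "deformation_pair"))
  co <- pair$correspondences
  x <- sqrt((co$vx - co$ux)^2 + (co$vy - co$uy)^2 + (co$vz - co$uz)^2)
  out <- tibble(tooth = co$tooth, s_mm = co$s_mm, x_mm = x)
  if (is.null(tooth)) return(out)
  hit <- out$x_mm[out$tooth == tooth]
  if (length(hit) != 1L) {
    abort(sprintf("no recorded correspondence for tooth %s.", tooth),
          class = "archforce_lookup_error")
  }
  hit
}
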