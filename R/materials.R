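#' Isotropic material definitions
#'
#' A `material` bundles the linear-isotropic properties used by the beam and
#' tissue solvers: density (kg/m^3), Young's modulus E (Pa), shear modulus
#' G (Pa) and Poisson ratio. When `G` is omitted it is derived as
#' `E / (2 (1 + nu))`. The stored `iso_inconsistency` field reports the
#' relative departure `|G - E/(2(1+nu))| / G`, so presets whose printed G
#' does not exactly satisfy isotropy carry that information with them.
#'
#' @param name label.
#' @param density kg/m^3 (> 0).
#' @param E Young's modulus, Pa (> 0).
#' @param nu Poisson ratio, in (0, 0.5).
#' @param G shear modulus, Pa; derived from E and nu when `NULL`.
#' @return A `material` object (list).
#' @examples
#' material("steel", 7800, 2.1e11, 0.3)
#' @export
material <- function(name, density, E, nu, G = NULL) {
  if (E <= 0 || density <= 0 || nu <= 0 || nu >= 0.5) {
    abort("need E > 0, density > 0 and 0 < nu < 0.5.",
          class = "archforce_invalid_parameter")
  }
  if (is.null(G)) G <- shear_modulus_from(E, nu)
  if (G <= 0) abort("G must be positive.", class = "archforce_invalid_parameter")
  structure(
    list(
      name = name, density = density, E = E, G = G, nu = nu,
      iso_inconsistency = abs(G - E / (2 * (1 + nu))) / G
    ),
    class = "material"
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: E = %.4g Pa, G = %.4g Pa, nu = %.3g, rho = %g kg/m^3",
              x$name, x$E, x$G, x$nu, x$density))
  if (x$iso_inconsistency > 1e-3) {
    cat(sprintf("  [G departs %.2f%% from E/(2(1+nu))]", 100 * x$iso_inconsistency))
  }
  cat("\n")
  invisible(x)
}

#' Shear modulus of an isotropic material
#'
#' `G = E / (2 (1 + nu))`.
#'
#' @param E Young's modulus (Pa), > 0.
#' @param nu Poisson ratio, in (-1, 0.5).
#' @return G in Pa.
#' @examples
#' shear_modulus_from(8.3e7, 0.33)   # nitinol archwire preset
#' @export
shear_modulus_from <- function(E, nu) {
  if (any(E <= 0) || any(nu <= -1) || any(nu >= 0.5)) {
    abort("need E > 0 and -1 < nu < 0.5.", class = "archforce_invalid_parameter")
  }
  E / (2 * (1 + nu))
}

#' Shipped material presets
#'
#' The reference material table of the modeled orthodontic system: the
#' nitinol archwire, Ni-Cr bracket/tube alloy, bone and tooth enamel, read
#' from the plain-text preset file shipped with the package. The shear
#' moduli are stored exactly as given in the reference tables, even where
#' they depart slightly from `E/(2(1+nu))` (the departure is recorded on
#' the object). Note the wire preset's E of 8.3e7 Pa is far below
#' literature nitinol moduli; it is kept as given because it is internally
#' consistent with the reference load-deflection data.
#'
#' @param which preset key: `"nitinol"`, `"nicr"`, `"bone"`, `"enamel"`;
#'   `material_presets()` returns all of them as a named list.
#' @return A [material()] or a named list of them.
#' @export
material_presets <- function() {
  f <- system.file("extdata", "reference", "materials.json", package = "archforce")
  raw <- jsonlite::read_json(f, simplifyVector = TRUE)
  purrr::map(raw, function(m) {
    material(m$name, m$density_kg_m3, m$youngs_modulus_Pa, m$poisson,
             G = m$shear_modulus_Pa)
  })
}

#' @rdname material_presets
#' @export
material_preset <- function(which = c("nitinol", "nicr", "bone", "enamel")) {
  which <- match.arg(which)
  material_presets()[[which]]
}
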