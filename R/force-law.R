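#' Fit the degree-6 elastic-constant polynomial k(y)
#'
#' Exact polynomial interpolation of the elastic constant through seven
#' calibration nodes: `k(y) = a y^6 + b y^5 + c y^4 + d y^3 + e y^2 + f y + g`.
#' With the physical node (0, 0) present the constant term is fixed at
#' `g = 0` and the remaining six coefficients solve a 6x6 Vandermonde-type
#' system. The monomial Vandermonde over nodes spanning tens of mm is
#' severely ill-conditioned, so the solve uses a pivoted LU factorization
#' followed by one step of iterative refinement, warns when the condition
#' number exceeds 1e12, and asserts the interpolation residual at every
#' node.
#'
#' If no zero node is supplied, `g` is fitted as a seventh unknown (a
#' documented deviation from the constrained model) with a warning.
#'
#' @param nodes tibble or data frame with columns `y_mm` (or `y`) and `k`
#'   (or `k_y`): exactly 7 distinct y values.
#' @param arch optional arch label carried on the law.
#' @param exponent deformation exponent n of `F = k(y) x^n`; 1 (metallic
#'   wire, default), 2 or 3.
#' @return A `sextic_force_law`: list with named `coefficients`
#'   (`a` ... `g`, highest degree first), `nodes`, `arch`, `exponent`,
#'   `condition` (exact 2-norm condition number of the solved system) and
#'   `max_residual`.
#' @examples
#' nodes <- reference_stiffness_nodes()
#' law <- fit_sextic(nodes, arch = "upper")
#' evaluate_k(law, 10)
#' @export
fit_sextic <- function(nodes, arch = NA_character_, exponent = 1L) {
  nodes <- tibble::as_tibble(nodes)
  ycol <- intersect(c("y_mm", "y"), names(nodes))[1]
  kcol <- intersect(c("k", "k_y"), names(nodes))[1]
  if (is.na(ycol) || is.na(kcol)) {
    abort("`nodes` needs columns y_mm (or y) and k (or k_y).",
          class = "archforce_invalid_parameter")
  }
  if (!exponent %in% 1:3) {
    abort("`exponent` must be 1, 2 or 3.", class = "archforce_invalid_parameter")
  }
  y <- as.numeric(nodes[[ycol]])
  k <- as.numeric(nodes[[kcol]])
  if (length(y) != 7L) {
    abort("exactly 7 (y, k) nodes are required.", class = "archforce_invalid_parameter")
  }
  if (anyDuplicated(y)) {
    abort("duplicate y nodes make the system singular.",
          class = "archforce_singular_system")
  }
  o <- order(y)
  y <- y[o]; k <- k[o]
  has_zero <- any(y == 0)
  if (has_zero) {
    if (k[y == 0] != 0) {
      abort("the node at y = 0 must have k = 0 (g is fixed at 0).",
            class = "archforce_invalid_parameter")
    }
    yy <- y[y != 0]; kk <- k[y != 0]
    A <- outer(yy, 6:1, `^`)
    coef <- c(refined_solve(A, kk), 0)
  } else {
    warn("no (0, 0) node: fitting the constant term g as a 7th unknown.")
    A <- outer(y, 6:0, `^`)
    coef <- refined_solve(A, k)
  }
  names(coef) <- letters[1:7]
  cond <- kappa(A, exact = TRUE)
  if (cond > 1e12) {
    warn(sprintf("interpolation system condition number %.2e exceeds 1e12; coefficients may lose precision.", cond))
  }
  law <- structure(
    list(
      coefficients = coef,
      nodes = tibble(y_mm = y, k = k),
      arch = arch, exponent = as.integer(exponent),
      condition = cond, max_residual = NA_real_
    ),
    class = "sextic_force_law"
  )
  res <- abs(evaluate_k(law, y) - k)
  law$max_residual <- max(res)
  if (law$max_residual > 1e-9) {
    abort(sprintf("interpolation residual %.3e exceeds 1e-9; nodes too ill-separated.",
                  law$max_residual),
          class = "archforce_singular_system")
  }
  law
}

# pivoted LU solve plus one step of iterative refinement
refined_solve <- function(A, b) {
  x <- solve(A, b)
  r <- b - as.numeric(A %*% x)
  x + solve(A, r)
}

#' @export
print.sextic_force_law <- function(x, ...) {
  cat(sprintf("<sextic_force_law>%s F = k(y) * x^%d, coefficients (y^6 .. y^0):\n",
              if (is.na(x$arch)) "" else paste0(" [", x$arch, "]"), x$exponent))
  print(x$coefficients)
  invisible(x)
}

#' Evaluate the elastic constant k(y)
#'
#' Horner-scheme evaluation of the fitted sextic. Values of y beyond the
#' outermost fit node are extrapolations of a high-degree polynomial and
#' trigger a warning (the polynomial blows up outside its node span).
#' The signed value is returned: between nodes the interpolant can
#' oscillate negative.
#'
#' @param law a [fit_sextic()] result.
#' @param y arc-length coordinate(s), mm, >= 0.
#' @param warn_extrapolation set `FALSE` to silence the span warning.
#' @return k in N/mm (signed).
#' @export
evaluate_k <- function(law, y, warn_extrapolation = TRUE) {
  stopifnot(inherits(law, "sextic_force_law"))
  if (any(y < 0)) abort("y must be non-negative.", class = "archforce_domain_error")
  span <- law_span(law)
  if (warn_extrapolation && any(y > span)) {
    warn(sprintf("evaluating k(y) beyond the outermost fit node (%.2f mm): extrapolation.", span))
  }
  co <- law$coefficients
  r <- rep(0, length(y))
  for (ci in co) r <- r * y + ci
  r
}

law_span <- function(law) {
  if (!is.null(law$nodes) && nrow(law$nodes)) max(law$nodes$y_mm) else Inf
}

#' Evaluate the elastic force F = k(y) * x^n
#'
#' The signed restoring-force magnitude developed by the wire at arc
#' coordinate y under deformation x. The sign follows k(y): a fitted sextic
#' can oscillate negative between nodes; downstream per-tooth reporting
#' takes magnitudes.
#'
#' @param law a [fit_sextic()] result.
#' @param x deformation, mm, >= 0.
#' @param y arc coordinate, mm, >= 0.
#' @param warn_extrapolation forwarded to [evaluate_k()].
#' @return F in N (signed).
#' @examples
#' law <- reference_force_law("upper")
#' evaluate_force(law, x = 1.31, y = 28.65)
#' @export
evaluate_force <- function(law, x, y, warn_extrapolation = TRUE) {
  if (any(x < 0)) abort("x must be non-negative.", class = "archforce_domain_error")
  evaluate_k(law, y, warn_extrapolation) * x^law$exponent
}

#' Serialize a force law to JSON (and back)
#'
#' Full-precision coefficients, the node provenance, arch label and
#' exponent survive a round trip.
#'
#' @param law a `sextic_force_law`.
#' @param file JSON file path.
#' @return `read_force_law()` returns the law; `write_force_law()` the file
#'   path, invisibly.
#' @export
write_force_law <- function(law, file) {
  stopifnot(inherits(law, "sextic_force_law"))
  jsonlite::write_json(
    list(
      coefficients = as.list(law$coefficients),
      nodes = law$nodes,
      arch = law$arch, exponent = law$exponent,
      condition = law$condition, max_residual = law$max_residual
    ),
    file, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(file)
}

#' @rdname write_force_law
#' @export
read_force_law <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(
    list(
      coefficients = setNames(as.numeric(unlist(j$coefficients)), names(j$coefficients)),
      nodes = if (!is.null(j$nodes)) tibble::as_tibble(j$nodes) else NULL,
      arch = if (is.null(j$arch)) NA_character_ else j$arch,
      exponent = as.integer(j$exponent),
      condition = j$condition, max_residual = j$max_residual
    ),
    class = "sextic_force_law"
  )
}

#' @method tidy sextic_force_law
#' @export
tidy.sextic_force_law <- function(x, ...) {
  tibble(term = names(x$coefficients), degree = 6:0,
         estimate = unname(x$coefficients))
}

#' @method glance sextic_force_law
#' @export
glance.sextic_force_law <- function(x, ...) {
  tibble(
    arch = x$arch, exponent = x$exponent,
    n_nodes = if (is.null(x$nodes)) NA_integer_ else nrow(x$nodes),
    max_residual = x$max_residual, condition = x$condition
  )
}

#' @method autoplot sextic_force_law
#' @export
autoplot.sextic_force_law <- function(object, ...) {
  span <- law_span(object)
  if (!is.finite(span)) span <- 60
  yy <- seq(0, span, length.out = 400)
  d <- tibble(y_mm = yy, k = evaluate_k(object, yy, warn_extrapolation = FALSE))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$y_mm, y = .data$k)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arc coordinate y (mm)", y = "k(y) (N/mm)",
                  title = "Interpolated elastic constant")
  if (!is.null(object$nodes) && nrow(object$nodes)) {
    p <- p + ggplot2::geom_point(data = object$nodes,
                                 ggplot2::aes(x = .data$y_mm, y = .data$k),
                                 color = "red")
  }
  p
}
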