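#' Canonical lifespan trajectory shapes
#'
#' Fixed closed-form curves of normalized age \eqn{a \in [0, 1]} used as the
#' ground-truth trajectory families of the synthetic-data generator. They are
#' smooth, reproducible proxies for the qualitative trajectory classes that
#' lifespan studies of encoding activity report: weak monotonic increase, a
#' U-shape (negative effects in adulthood), weak and steep inverted-U shapes,
#' a childhood "developmental" rise to a plateau, and a null (flat, zero-mean)
#' shape.
#'
#' The base curves are:
#' \describe{
#'   \item{monotonic_up}{\eqn{a}}
#'   \item{u_shape}{\eqn{(2a-1)^2}}
#'   \item{weak_inverted_u}{\eqn{0.4\,(1-(2a-1)^2)}}
#'   \item{steep_inverted_u}{\eqn{1-(2a-1)^2}}
#'   \item{developmental_plateau}{\eqn{\min(a/0.3,\ 1)}}
#'   \item{null}{0}
#' }
#'
#' @param name one of `canonical_shape_names()`.
#' @param a normalized age values in `[0, 1]`.
#' @return `canonical_curve()` returns the base curve values; a `shape_spec`
#'   applies `amplitude * curve + baseline` on evaluation.
#' @examples
#' canonical_curve("steep_inverted_u", c(0, 0.5, 1))
#' @export
canonical_curve <- function(name, a) {
  name <- match.arg(name, canonical_shape_names())
  if (any(a < -1e-9 | a > 1 + 1e-9, na.rm = TRUE))
    stop_invalid("normalized age must lie in [0, 1]")
  switch(name,
    monotonic_up = a,
    u_shape = (2 * a - 1)^2,
    weak_inverted_u = 0.4 * (1 - (2 * a - 1)^2),
    steep_inverted_u = 1 - (2 * a - 1)^2,
    developmental_plateau = pmin(a / 0.3, 1),
    null = rep(0, length(a))
  )
}

#' @rdname canonical_curve
#' @export
canonical_shape_names <- function() {
  c("monotonic_up", "u_shape", "weak_inverted_u", "steep_inverted_u",
    "developmental_plateau", "null")
}

#' @rdname canonical_curve
#' @param amplitude multiplicative scale, in activity units (percent signal
#'   change for activity shapes).
#' @param baseline additive intercept (mean-effect sign and size). Must be 0
#'   for the `null` shape, which has zero mean effect by definition.
#' @export
shape_spec <- function(name, amplitude = 1, baseline = 0) {
  name <- match.arg(name, canonical_shape_names())
  check_number(amplitude, "amplitude")
  check_number(baseline, "baseline")
  if (name == "null" && (amplitude != 0 || baseline != 0)) {
    amplitude <- 0
    baseline <- 0
  }
  structure(list(name = name, amplitude = amplitude, baseline = baseline),
            class = "shape_spec")
}

#' @rdname canonical_curve
#' @param spec a `shape_spec`.
#' @export
eval_shape <- function(spec, a) {
  stopifnot(inherits(spec, "shape_spec"))
  spec$amplitude * canonical_curve(spec$name, a) + spec$baseline
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("<shape_spec> %s (amplitude = %g, baseline = %g)\n",
              x$name, x$amplitude, x$baseline))
  invisible(x)
}

# map ages to normalized [0,1] over an explicit range
normalize_age <- function(age, age_min = min(age), age_max = max(age)) {
  if (age_max <= age_min) stop_invalid("age_max must exceed age_min")
  pmin(pmax((age - age_min) / (age_max - age_min), 0), 1)
}
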