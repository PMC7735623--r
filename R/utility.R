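#' Utility (value) function specification
#'
#' The model applies a utility function branch-wise before the stochastic
#' transform.  Two families are supported: linear \eqn{u(o) = o} and CARA
#' (constant absolute risk aversion) \eqn{u(o) = (1 - e^{-r o}) / r}, whose
#' coefficient of absolute risk aversion \eqn{-u''/u'} is the constant `r`.
#' Linear is the continuous CARA limit as `r` goes to 0.
#'
#' `outcome_scale` rescales outcomes before `u` is applied (e.g. `1/100`
#' so that a 100-unit stake enters as 1).  Only the products of scale with
#' `r` and with the diffusion coefficient are identifiable, so the scale is
#' a fixed modelling choice, never a free parameter.
#'
#' @param family `"linear"` or `"cara"`.
#' @param r Absolute risk-aversion coefficient, `>= 0` (per currency unit).
#' @param outcome_scale Positive rescaling applied to outcomes before `u`.
#' @return An object of class `utility_spec`.
#' @examples
#' utility(utility_spec("cara", r = 1), c(-1, 0, 1))
#' @export
utility_spec <- function(family = c("linear", "cara"), r = 0,
                         outcome_scale = 1) {
  family <- match.arg(family)
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0) {
    stop("`r` must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(outcome_scale) || length(outcome_scale) != 1 ||
      is.na(outcome_scale) || outcome_scale <= 0) {
    stop("`outcome_scale` must be a single positive number", call. = FALSE)
  }
  if (family == "linear") r <- 0
  structure(list(family = family, r = r, outcome_scale = outcome_scale),
            class = "utility_spec")
}

#' @export
print.utility_spec <- function(x, ...) {
  cat("<utility_spec> ", x$family,
      if (x$family == "cara") paste0(" (r = ", format(x$r), ")"),
      ", outcome_scale = ", format(x$outcome_scale), "\n", sep = "")
  invisible(x)
}

#' Evaluate a utility function
#'
#' Vectorized over `o`.  Satisfies \eqn{u(0) = 0}, is strictly increasing,
#' and is concave for `r > 0`.  For `r` below `1e-10` the linear value is
#' returned (the CARA family is continuous in `r` at 0); small positive `r`
#' uses `expm1` for accuracy.
#'
#' @param spec A [utility_spec()].
#' @param o Numeric vector of outcomes.
#' @return Numeric vector of utilities.
#' @export
utility <- function(spec, o) {
  stopifnot(inherits(spec, "utility_spec"))
  x <- o * spec$outcome_scale
  if (spec$r < 1e-10) {
    x
  } else {
    -expm1(-spec$r * x) / spec$r
  }
}
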