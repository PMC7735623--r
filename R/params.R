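#' Model parameters
#'
#' The full parameterization of the theory: a utility specification, the
#' diffusion coefficient `D`, and the deliberation-time budget `T`.
#'
#' `D` sets the trade-off between outcome values and probabilities in the
#' construction of preferences: large `D` makes the decision maker attend
#' only to probabilities, small `D` only to values.  `T` is the (explicit
#' or implicit) time available to decide; `Inf` is an exact sentinel for
#' the unconstrained model, not a large number.
#'
#' @param utility A [utility_spec()] (default linear).
#' @param D Diffusion coefficient, `> 0`.
#' @param T Time budget, `> 0` or `Inf`.
#' @return An object of class `srdt_params`.
#' @examples
#' srdt_params(D = 10)
#' srdt_params(utility_spec("cara", r = 4), D = 10, T = 2000)
#' @export
srdt_params <- function(utility = utility_spec("linear"), D, T = Inf) {
  stopifnot(inherits(utility, "utility_spec"))
  if (!is.numeric(D) || length(D) != 1 || is.na(D) || D <= 0) {
    stop("`D` must be a single number > 0", call. = FALSE)
  }
  if (!is.numeric(T) || length(T) != 1 || is.na(T) || T <= 0) {
    stop("`T` must be a single number > 0 (Inf allowed)", call. = FALSE)
  }
  structure(list(utility = utility, D = as.numeric(D), T = as.numeric(T)),
            class = "srdt_params")
}

#' @export
print.srdt_params <- function(x, ...) {
  cat("<srdt_params> D = ", format(x$D), ", T = ", format(x$T),
      ", utility: ", x$utility$family,
      if (x$utility$family == "cara") paste0(" (r = ", format(x$utility$r), ")"),
      if (x$utility$outcome_scale != 1)
        paste0(", outcome_scale = ", format(x$utility$outcome_scale)),
      "\n", sep = "")
  invisible(x)
}
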