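#' Log effective utility of a branch (infinite time)
#'
#' The effective utility of a branch carrying utility `u` with probability
#' `p` is the non-separable weight
#' \deqn{\tilde U_p(u) = \frac{u}{1 - e^{-2u/(pD)}},}
#' the (unnormalized) splitting weight of a drifting particle on a branch
#' of length \eqn{1/p}.  It is strictly positive for every real `u`:
#' gains attract (\eqn{\tilde U > u}), losses are exponentially suppressed
#' but never impossible.  At `u = 0` the removable singularity has value
#' \eqn{pD/2}, the pure gambler's-ruin weight proportional to `p`.
#'
#' Computed in log space, stably over the whole real line; vectorized and
#' recycled over `u`, `p`, `D`.
#'
#' @param u Branch utility value(s), any real.
#' @param p Branch probability in `(0, 1]`.  `p = 0` is an error: an
#'   impossible outcome has no branch (callers drop such branches).
#' @param D Diffusion coefficient, `> 0`.
#' @return `log(\tilde U_p(u))`, finite for all finite inputs.
#' @examples
#' exp(log_effective_utility(10, 0.5, 10))  # 10 / (1 - exp(-4))
#' exp(log_effective_utility(0, 0.5, 10))   # pD/2 = 2.5
#' @export
log_effective_utility <- function(u, p, D) {
  n <- max(length(u), length(p), length(D))
  u <- rep_len(as.numeric(u), n)
  p <- rep_len(as.numeric(p), n)
  D <- rep_len(as.numeric(D), n)
  if (any(p <= 0 | p > 1)) {
    stop("`p` must lie in (0, 1]: a zero-probability outcome has no branch",
         call. = FALSE)
  }
  if (any(D <= 0)) stop("`D` must be > 0", call. = FALSE)
  x <- 2 * u / (p * D)
  out <- numeric(n)
  tiny <- abs(x) < 1e-8
  # series: u/(1 - e^{-x}) = (u/x) / (1 - x/2 + x^2/6 - ...) with u/x = pD/2
  out[tiny] <- log(p[tiny] * D[tiny] / 2) -
    log1p(-x[tiny] / 2 + x[tiny]^2 / 6)
  pos <- !tiny & x > 0
  # log u - log(1 - e^{-x})
  out[pos] <- log(u[pos]) - log1p(-exp(-x[pos]))
  neg <- !tiny & x < 0
  # u/(1 - e^{-x}) = (-u) e^{x} / (1 - e^{x}) for x < 0
  out[neg] <- log(-u[neg]) + x[neg] - log1p(-exp(x[neg]))
  out
}

#' Log effective utility under a finite time budget (Laplace weight)
#'
#' Conditioning the decision on occurring before time `T` replaces the
#' branch weight by its Laplace-domain flux at \eqn{s = 1/T}:
#' \deqn{\tilde U_p(u \mid T) = \frac{\lambda\, e^{u/(pD)}}
#'   {\sinh(\lambda/p)}, \qquad
#'   \lambda = \sqrt{(u/D)^2 + 2/(DT)}.}
#' As \eqn{T \to \infty} this recovers \eqn{(2/D)\,\tilde U_p(u)} (the
#' constant cancels in Luce ratios); for any finite `T` the weight of a
#' vanishing-probability branch goes to zero, removing the singular
#' \eqn{p \to 0} limit of the unconstrained model.
#'
#' `T = Inf` delegates to [log_effective_utility()] plus `log(2/D)` so the
#' two normalizations agree; timed and untimed weights are never mixed in
#' one distribution.
#'
#' @inheritParams log_effective_utility
#' @param T Time budget, `> 0` or `Inf`.
#' @return `log` of the timed weight; `-Inf` only in the `p -> 0`
#'   (finite-`T`) limit.
#' @examples
#' exp(log_effective_utility_timed(10, 0.5, 10, 1))    # ~ 1.83
#' exp(log_effective_utility_timed(10, 0.5, 10, Inf))  # (2/D) * 10.1866
#' @export
log_effective_utility_timed <- function(u, p, D, T) {
  n <- max(length(u), length(p), length(D), length(T))
  u <- rep_len(as.numeric(u), n)
  p <- rep_len(as.numeric(p), n)
  D <- rep_len(as.numeric(D), n)
  T <- rep_len(as.numeric(T), n)
  if (any(p <= 0 | p > 1)) {
    stop("`p` must lie in (0, 1]: a zero-probability outcome has no branch",
         call. = FALSE)
  }
  if (any(D <= 0)) stop("`D` must be > 0", call. = FALSE)
  if (any(T <= 0)) stop("`T` must be > 0 (Inf allowed)", call. = FALSE)
  out <- numeric(n)
  inf <- is.infinite(T)
  if (any(inf)) {
    out[inf] <- log(2 / D[inf]) +
      log_effective_utility(u[inf], p[inf], D[inf])
  }
  if (any(!inf)) {
    ui <- u[!inf]; pi_ <- p[!inf]; Di <- D[!inf]; Ti <- T[!inf]
    lambda <- sqrt((ui / Di)^2 + 2 / (Di * Ti))
    out[!inf] <- log(lambda) + ui / (pi_ * Di) - log_sinh(lambda / pi_)
  }
  out
}

# log(sinh(x)) for x > 0, stable for x up to ~1e6 and accurate near 0.
log_sinh <- function(x) {
  out <- numeric(length(x))
  big <- x > 30
  out[big] <- x[big] - log(2)
  mid <- !big & x > 1e-4
  out[mid] <- x[mid] - log(2) + log1p(-exp(-2 * x[mid]))
  small <- x <= 1e-4
  out[small] <- log(x[small]) + x[small]^2 / 6   # sinh x ~ x (1 + x^2/6)
  out
}

#' Probability-distorted (transformed) utility
#'
#' The effective utility of a CARA decision maker written as a function of
#' the raw outcome `o`:
#' \deqn{\tilde U_p(o) = \frac{(1 - e^{-ro})/r}
#'   {1 - \exp\{-(1 - e^{-ro}) / (r D_p)\}}, \qquad D_p = pD/2.}
#' It is identical to
#' `exp(log_effective_utility(utility(cara), p, D))`; that identity pins
#' the exponent convention and is enforced by a unit test.  The transform
#' turns an everywhere-concave utility into a convex (risk-seeking) one on
#' part of the loss domain: it flattens to 0 for large losses and
#' approaches `u` from above for large gains.
#'
#' @param o Outcome(s).
#' @param p Branch probability in `(0, 1]`.
#' @param r CARA coefficient `> 0` (use [log_effective_utility()] with a
#'   linear spec when r is 0).
#' @param D Diffusion coefficient `> 0`.
#' @return \eqn{\tilde U_p(o)}, positive.
#' @export
transformed_utility <- function(o, p, r, D) {
  stopifnot(r > 0, all(D > 0))
  u <- -expm1(-r * o) / r
  exp(log_effective_utility(u, p, D))
}

#' Inflection points of the derived weighting and value curves
#'
#' Two reference points of the theory: `p_star`, where the value-distorted
#' subjective probability crosses from over- to under-weighting,
#' \eqn{p^\ast = u(o_A) / (u(o_A) + u(o_B))} (closed form, requires both
#' utilities positive); and `o_star`, the outcome at which the transformed
#' CARA utility changes concavity (located numerically from the second
#' derivative of [transformed_utility()], typically in the loss domain).
#'
#' @param oA,oB Outcomes of the two branches (for `p_star`).
#' @param r CARA coefficient `> 0`.
#' @param D Diffusion coefficient `> 0`; `o_star` is computed at `p = 0.5`
#'   unless `p` is given (only \eqn{D_p = pD/2} matters).
#' @param p Branch probability used for `o_star` (default 0.5).
#' @param bracket Search interval in `o` for the curvature sign change.
#' @return A list with `p_star` and `o_star`.
#' @export
inflection_points <- function(oA, oB, r, D, p = 0.5,
                              bracket = c(-20 / r, 20 / r)) {
  uA <- -expm1(-r * oA) / r
  uB <- -expm1(-r * oB) / r
  if (uA <= 0 || uB <= 0) {
    stop("`p_star` requires u(oA) > 0 and u(oB) > 0", call. = FALSE)
  }
  p_star <- uA / (uA + uB)

  h <- 1e-4 * max(1, 1 / r)
  curv <- function(o) {
    (transformed_utility(o + h, p, r, D) -
       2 * transformed_utility(o, p, r, D) +
       transformed_utility(o - h, p, r, D)) / h^2
  }
  grid <- seq(bracket[1], bracket[2], length.out = 400)
  cv <- vapply(grid, curv, numeric(1))
  sgn <- sign(cv)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flip) == 0) {
    stop("no curvature sign change in bracket [",
         format(bracket[1]), ", ", format(bracket[2]), "]", call. = FALSE)
  }
  i <- flip[[1]]
  o_star <- stats::uniroot(curv, c(grid[i], grid[i + 1]),
                           tol = 1e-8)$root
  list(p_star = p_star, o_star = o_star)
}
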