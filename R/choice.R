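logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

branch_log_weights <- function(x, params) {
  x <- tibble::as_tibble(x)
  u <- utility(params$utility, x$outcome)
  lw <- if (is.infinite(params$T)) {
    log_effective_utility(u, x$probability, params$D)
  } else {
    log_effective_utility_timed(u, x$probability, params$D, params$T)
  }
  dplyr::mutate(x, u = u, log_weight = lw)
}

#' Log total weight of each lottery
#'
#' A lottery's worth is the sum of its branch effective utilities,
#' \eqn{U(L) = \sum_k \tilde U_{p_k}(u(o_k))}, aggregated with
#' log-sum-exp.  The per-branch weights are kept for conditional
#' (subjective-probability) calculations.
#'
#' @param x A lottery table.
#' @param params An [srdt_params()].
#' @return A tibble with one row per lottery: `lottery_id` (and `set_id`
#'   if present) and `log_weight`; branch-level weights in
#'   `attr(, "branches")`.
#' @export
lottery_log_weight <- function(x, params) {
  stopifnot(inherits(params, "srdt_params"))
  x <- as_lotteries(x)
  br <- branch_log_weights(x, params)
  grp <- if ("set_id" %in% names(x)) c("set_id", "lottery_id") else "lottery_id"
  out <- br |>
    dplyr::summarise(log_weight = logsumexp(.data$log_weight),
                     .by = dplyr::all_of(grp))
  attr(out, "branches") <- br
  out
}

#' Choice probabilities for a set of lotteries
#'
#' The Luce (ratio-scale) rule over lottery worths:
#' \deqn{P(L_j) = \frac{U(L_j)}{\sum_i U(L_i)},}
#' computed via log-sum-exp so that extreme utilities never overflow.  The
#' structure implies independence from irrelevant alternatives and strong
#' stochastic transitivity.  With a finite time budget the timed weights
#' are used throughout (never mixed with untimed ones).
#'
#' @param x A lottery table forming a choice set (>= 2 lotteries, not all
#'   degenerate).  A `set_id` column is honoured: probabilities are
#'   computed within each set.
#' @param params An [srdt_params()].
#' @return A tibble of class `srdt_choice`: one row per lottery with
#'   `log_weight` and `prob`.  `attr(, "branches")` holds per-branch
#'   log-weights and the conditional weight of each branch within its
#'   lottery (`cond_weight`); `attr(, "params")` echoes the parameters.
#' @examples
#' cs <- choice_set(
#'   lottery("L1", c(180, 20), c(0.5, 0.5)),
#'   lottery("L2", c(180, 30, 15), c(0.5, 0.25, 0.25))
#' )
#' choice_distribution(cs, srdt_params(D = 10))
#' @export
choice_distribution <- function(x, params) {
  stopifnot(inherits(params, "srdt_params"))
  x <- as_lotteries(x, choice_set = TRUE)
  lw <- lottery_log_weight(x, params)
  br <- attr(lw, "branches")
  grp_set <- if ("set_id" %in% names(x)) "set_id" else character()

  norm_one <- function(tab) {
    if (all(!is.finite(tab$log_weight))) {
      stop("degenerate choice distribution: every branch weight vanished ",
           "(tiny branch probabilities under a finite time budget)",
           call. = FALSE)
    }
    z <- logsumexp(tab$log_weight)
    dplyr::mutate(tab, prob = exp(.data$log_weight - z))
  }
  out <- if (length(grp_set)) {
    lw |>
      dplyr::group_split(.data$set_id) |>
      purrr::map_dfr(norm_one)
  } else {
    norm_one(lw)
  }

  grp_lot <- c(grp_set, "lottery_id")
  br <- br |>
    dplyr::mutate(
      cond_weight = exp(.data$log_weight - logsumexp(.data$log_weight)),
      .by = dplyr::all_of(grp_lot)
    )
  structure(out, branches = br, params = params,
            class = c("srdt_choice", class(out)))
}

# Fast per-(set, lottery) choice probabilities for repeated likelihood
# evaluations: no validation, no tibble splitting.  `sets` must already be
# a normalized lottery table with a set_id column.
choice_probs_fast <- function(sets, params) {
  u <- utility(params$utility, sets$outcome)
  lw <- if (is.infinite(params$T)) {
    log_effective_utility(u, sets$probability, params$D)
  } else {
    log_effective_utility_timed(u, sets$probability, params$D, params$T)
  }
  key <- paste(sets$set_id, sets$lottery_id, sep = "\r")
  ukey <- unique(key)
  m <- vapply(split(lw, factor(key, levels = ukey)), logsumexp, numeric(1))
  uset <- sub("\r.*$", "", ukey)
  z <- vapply(split(m, uset), logsumexp, numeric(1))
  tibble::tibble(set_id = uset,
                 lottery_id = sub("^.*\r", "", ukey),
                 prob = exp(m - z[uset]))
}

#' Value-distorted subjective probability of an outcome
#'
#' Within a binary lottery \eqn{\{o_A, p;\ o_B, 1-p\}}, the conditional
#' probability of being absorbed on the \eqn{o_A} branch given the lottery
#' is chosen:
#' \deqn{\pi(p) = \frac{\tilde U_p(u(o_A))}
#'   {\tilde U_p(u(o_A)) + \tilde U_{1-p}(u(o_B))}.}
#' This is the model's derived analogue of a probability weighting
#' function: \eqn{\pi(p) \to p} as \eqn{D \to \infty}, and for finite `D`
#' it takes the familiar inverse-S shape with inflection at
#' \eqn{p^\ast = u(o_A)/(u(o_A)+u(o_B))}.  With a finite time budget the
#' timed weights are substituted, which adds under-weighting of small and
#' over-weighting of large probabilities.
#'
#' @param p Probability (vector) in `(0, 1)`.
#' @param oA,oB Outcomes of the two branches.
#' @param params An [srdt_params()].
#' @return \eqn{\pi(p)} in `(0, 1)`, vectorized over `p`.
#' @export
subjective_probability <- function(p, oA, oB, params) {
  stopifnot(inherits(params, "srdt_params"))
  if (any(p <= 0 | p >= 1)) {
    stop("`p` must lie in (0, 1)", call. = FALSE)
  }
  uA <- utility(params$utility, oA)
  uB <- utility(params$utility, oB)
  pi_weight(p, uA, uB, params$D, params$T)
}

# Conditional branch weight from utility values (low-level, vectorized
# over p).
pi_weight <- function(p, uA, uB, D, T = Inf) {
  if (is.infinite(T)) {
    la <- log_effective_utility(uA, p, D)
    lb <- log_effective_utility(uB, 1 - p, D)
  } else {
    la <- log_effective_utility_timed(uA, p, D, T)
    lb <- log_effective_utility_timed(uB, 1 - p, D, T)
  }
  1 / (1 + exp(lb - la))
}

#' Asymptotic choice probabilities in the diffusion coefficient
#'
#' Closed-form limits of [choice_distribution()], evaluated without
#' exponentials at extreme arguments.
#'
#' For `D_to_inf` every branch weight tends to \eqn{p_k D/2}, so each
#' lottery's weight is proportional to its total probability: complete
#' lotteries become indistinguishable (uniform choice), the
#' probability-only decision maker.
#'
#' For `D_to_0` a gain branch contributes its bare utility while a loss
#' branch is exponentially suppressed: lotteries are weighted by their
#' sums of positive utilities (the value-only decision maker).  When every
#' lottery is all-loss, mass concentrates on the lottery whose slowest
#' branch decays least, i.e. smallest \eqn{\min_k 2|u_k|/p_k}; prefactor
#' ties are split by \eqn{|u|}.
#'
#' @param x A lottery table forming a choice set.
#' @param params An [srdt_params()] (utility spec is used; `D`, `T` are
#'   ignored in the limit).
#' @param which `"D_to_0"` or `"D_to_inf"`.
#' @return A tibble with `lottery_id` and `prob`.
#' @export
limit_choice_probabilities <- function(x, params,
                                       which = c("D_to_0", "D_to_inf")) {
  which <- match.arg(which)
  stopifnot(inherits(params, "srdt_params"))
  x <- as_lotteries(x, choice_set = TRUE)
  grp_set <- if ("set_id" %in% names(x)) "set_id" else character()
  grp_lot <- c(grp_set, "lottery_id")
  br <- tibble::as_tibble(x)
  br$u <- utility(params$utility, br$outcome)

  one_set <- function(tab) {
    if (which == "D_to_inf") {
      w <- tab |>
        dplyr::summarise(w = sum(.data$probability), .by = "lottery_id")
    } else {
      w <- tab |>
        dplyr::summarise(w = sum(pmax(.data$u, 0)), .by = "lottery_id")
      if (all(w$w == 0)) {
        # all-loss set: slowest exponential decay wins
        rate <- tab |>
          dplyr::summarise(rate = min(2 * abs(.data$u) / .data$probability),
                           pref = max(abs(.data$u)),
                           .by = "lottery_id")
        best <- rate$rate <= min(rate$rate) + 1e-12
        w$w <- ifelse(best, rate$pref, 0)
      }
    }
    dplyr::mutate(w, prob = .data$w / sum(.data$w))[, c("lottery_id", "prob")]
  }

  if (length(grp_set)) {
    br |>
      dplyr::group_split(.data$set_id, .keep = TRUE) |>
      purrr::map_dfr(~dplyr::mutate(one_set(.x), set_id = .x$set_id[[1]],
                                    .before = 1))
  } else {
    one_set(br)
  }
}
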