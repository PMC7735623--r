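#' Printed example choice sets
#'
#' The small library of decision tasks used throughout the results
#' pipelines: the Birnbaum–Navarrete dominance-violation pair, two
#' "evident" dominance tasks, the strong-risk-aversion (mean-preserving
#' spread) pair, and the time-pressure pair (the low-risk option first).
#'
#' @param name One of `"birnbaum"`, `"evident_A"`, `"evident_B"`,
#'   `"strong_risk"`, `"time_pressure"`.
#' @return An `srdt_lotteries` choice set.
#' @export
example_choice_set <- function(name = c("birnbaum", "evident_A", "evident_B",
                                        "strong_risk", "time_pressure")) {
  name <- match.arg(name)
  switch(
    name,
    birnbaum = choice_set(
      lottery("L1", c(96, 14, 12), c(0.90, 0.05, 0.05)),
      lottery("L2", c(96, 90, 12), c(0.85, 0.05, 0.10))
    ),
    evident_A = choice_set(
      lottery("L1", c(1, 3), c(0.5, 0.5)),
      lottery("L2", c(1, 2), c(0.5, 0.5))
    ),
    evident_B = choice_set(
      lottery("L3", c(11, 12), c(0.5, 0.5)),
      lottery("L4", 10, 1)
    ),
    strong_risk = choice_set(
      lottery("L5", c(0, 2), c(0.75, 0.25)),
      lottery("L6", c(0, 1), c(0.5, 0.5))
    ),
    time_pressure = choice_set(
      lottery("L1", c(180, 20), c(0.5, 0.5)),
      lottery("L2", c(180, 30, 15), c(0.5, 0.25, 0.25))
    )
  )
}

#' Parameter regime reproducing the canonical fourfold pattern
#'
#' The bundled regime in which [fourfold_curves()] plus
#' [fourfold_classify()] reproduce all four cells of the classic 2x2
#' gain/loss by low/high-probability table: CARA coefficient 6 on outcomes
#' scaled by 1/100, `D = 10`, `T = 2000`.  A finite time budget is
#' essential for the gain-side certainty cell; the loss-side certainty
#' cell needs `r` above roughly 5 at this `D` (see the methods
#' vignette).
#'
#' @return A named list of arguments for [fourfold_curves()].
#' @export
fourfold_preset <- function() {
  list(r = 6, D = 10, T = 2000, outcome_scale = 1 / 100, stake = 100)
}

#' Fourfold-pattern choice curves
#'
#' For each grid probability `p`, the probability of choosing the risky
#' lottery over its expected value paid for sure, on the gain side
#' (task A: \{stake, p; 0, 1-p\} vs \{stake p, 1\}) and the loss side
#' (task B: same with negated stake).  A CARA decision maker with
#' coefficient `r`; outcomes enter `u` through `outcome_scale` (default
#' 1/100, so a 100-unit stake enters as 1 — with unscaled outcomes the
#' CARA utility saturates and the interesting regimes are unreachable).
#'
#' @param r CARA coefficient (0 = linear).
#' @param D Diffusion coefficient.
#' @param T Time budget (`Inf` for the unconstrained model).
#' @param p_grid Grid of outcome probabilities in (0, 1).
#' @param stake Risky outcome magnitude (default 100).
#' @param outcome_scale Passed to [utility_spec()].
#' @return A tibble of class `srdt_curve`: `experiment`, `task`, `p`,
#'   `prob_risky`, with `r`, `D`, `T` echoed.
#' @export
fourfold_curves <- function(r = 1, D = 10, T = Inf,
                            p_grid = seq(0.005, 0.995, length.out = 199),
                            stake = 100, outcome_scale = 1 / 100) {
  stopifnot(all(p_grid > 0 & p_grid < 1))
  spec <- utility_spec(if (r > 0) "cara" else "linear", r = r,
                       outcome_scale = outcome_scale)
  lw <- function(u, p) {
    if (is.infinite(T)) log_effective_utility(u, p, D)
    else log_effective_utility_timed(u, p, D, T)
  }
  one_task <- function(sgn) {
    u_risk <- utility(spec, sgn * stake)
    u_zero <- utility(spec, 0)
    u_sure <- utility(spec, sgn * stake * p_grid)
    l_risky <- purrr::map2_dbl(lw(u_risk, p_grid), lw(u_zero, 1 - p_grid),
                               ~logsumexp(c(.x, .y)))
    l_sure <- lw(u_sure, 1)
    1 / (1 + exp(l_sure - l_risky))
  }
  out <- dplyr::bind_rows(
    tibble::tibble(task = "gain", p = p_grid, prob_risky = one_task(1)),
    tibble::tibble(task = "loss", p = p_grid, prob_risky = one_task(-1))
  ) |>
    dplyr::mutate(experiment = "fourfold", r = r, D = D, T = T, .before = 1)
  structure(out, class = c("srdt_curve", class(out)))
}

#' Classify the fourfold pattern from choice curves
#'
#' Risk-attitude labels are read from the choice-probability majority:
#' risky preferred (`prob_risky > 0.5`) means risk-seeking, the sure
#' equivalent preferred means risk-averse.  The canonical pattern is
#' risk-seeking for low-probability gains and moderate/high-probability
#' losses, risk-averse for high-probability gains and low-probability
#' losses.
#'
#' @param curves A [fourfold_curves()] table.
#' @param p_low,p_high Probe probabilities (linearly interpolated on the
#'   curve).
#' @return A tibble with one row per cell: `task`, `p`, `prob_risky`,
#'   `label`, `expected`, `pass`.
#' @export
fourfold_classify <- function(curves, p_low = 0.05, p_high = 0.95) {
  probe <- function(task, p) {
    sub <- curves[curves$task == task, ]
    stats::approx(sub$p, sub$prob_risky, xout = p)$y
  }
  cells <- tibble::tibble(
    task = c("gain", "gain", "loss", "loss"),
    regime = c("low_p", "high_p", "low_p", "high_p"),
    p = c(p_low, p_high, p_low, p_high),
    expected = c("risk-seeking", "risk-averse", "risk-averse", "risk-seeking")
  )
  cells$prob_risky <- purrr::map2_dbl(cells$task, cells$p, probe)
  cells$label <- ifelse(cells$prob_risky > 0.5, "risk-seeking", "risk-averse")
  cells$pass <- cells$label == cells$expected
  cells
}

#' Shape of the derived probability-weighting curve
#'
#' Classifies \eqn{\pi(p \mid T) - p} by its sign-change pattern on a
#' dense grid (dead band `1e-9` against spurious machine-precision
#' crossings): one interior crossing, over- then under-weighting, is the
#' classic inverse-S; the reverse order is an S; three crossings
#' (under, over, under, over) is the inverse double-S that combines
#' value distortion with finite-time neglect of extreme probabilities.
#'
#' @param uA,uB Utility values of the two branches.
#' @param D Diffusion coefficient.
#' @param T Time budget (`Inf` allowed).
#' @param p_grid Grid on (0, 1); at least 500 points recommended.
#' @return A list: `shape`, `crossings` (interpolated locations), and
#'   the `curve` tibble (`p`, `pi`, `delta`).
#' @export
weighting_shape <- function(uA = 10, uB = 10, D = 10, T = Inf,
                            p_grid = seq(0.001, 0.999, length.out = 999)) {
  pi_ <- pi_weight(p_grid, uA, uB, D, T)
  delta <- pi_ - p_grid
  s <- sign(delta)
  s[abs(delta) < 1e-9] <- 0
  nz <- which(s != 0)
  runs <- rle(s[nz])$values
  n_cross <- sum(runs[-1] != runs[-length(runs)])
  first <- if (length(runs)) runs[[1]] else 0

  shape <- if (n_cross == 1 && first > 0) {
    "inverse-S"
  } else if (n_cross == 1 && first < 0) {
    "S"
  } else if (n_cross == 3 && first < 0) {
    "double-inverse-S"
  } else if (n_cross == 0) {
    if (first > 0) "degenerate-overweighting"
    else if (first < 0) "degenerate-underweighting"
    else "flat"
  } else {
    paste0("other(", n_cross, " crossings)")
  }

  idx <- nz[which(s[nz][-1] != s[nz][-length(nz)])]
  crossings <- vapply(idx, function(i) {
    j <- i + 1
    p1 <- p_grid[i]; p2 <- p_grid[j]
    d1 <- delta[i]; d2 <- delta[j]
    p1 - d1 * (p2 - p1) / (d2 - d1)
  }, numeric(1))

  list(shape = shape, crossings = crossings,
       curve = tibble::tibble(p = p_grid, pi = pi_, delta = delta))
}

#' Stochastic-dominance suite
#'
#' Two behaviours in one report: the Birnbaum–Navarrete pair, where the
#' dominated lottery is preferred for value-oriented (small `D`) decision
#' makers; and the two "evident" dominance tasks, where the dominant
#' option is preferred at every `D`.
#'
#' @param D_grid Positive grid of diffusion coefficients (default
#'   log-spaced `1e-2 ... 1e4`).
#' @param utility A [utility_spec()] (default linear, as in the printed
#'   example).
#' @return A list: `birnbaum` tibble (`D`, `prob_dominated`, `violated`),
#'   `limit_prob_dominated` (exact `D -> 0` value), and `evident` tibble
#'   (`task`, `D`, `prob_dominant`, `ok`).
#' @export
dominance_suite <- function(D_grid = 10^seq(-2, 4, length.out = 25),
                            utility = utility_spec("linear")) {
  stopifnot(all(D_grid > 0))
  birn <- example_choice_set("birnbaum")
  p2 <- vapply(D_grid, function(D) {
    cd <- choice_distribution(birn, srdt_params(utility, D = D))
    cd$prob[cd$lottery_id == "L2"]
  }, numeric(1))
  lim <- limit_choice_probabilities(birn, srdt_params(utility, D = 1))
  ev <- purrr::map_dfr(
    list(c(task = "evident_A", dominant = "L1"),
         c(task = "evident_B", dominant = "L3")),
    function(spec_task) {
      cs <- example_choice_set(spec_task[["task"]])
      tibble::tibble(
        task = spec_task[["task"]],
        D = D_grid,
        prob_dominant = vapply(D_grid, function(D) {
          cd <- choice_distribution(cs, srdt_params(utility, D = D))
          cd$prob[cd$lottery_id == spec_task[["dominant"]]]
        }, numeric(1))
      )
    }
  ) |>
    dplyr::mutate(ok = .data$prob_dominant >= 0.5 - 1e-12)
  list(
    birnbaum = tibble::tibble(D = D_grid, prob_dominated = p2,
                              violated = p2 > 0.5),
    limit_prob_dominated = lim$prob[lim$lottery_id == "L2"],
    evident = ev
  )
}

#' Strong-risk-aversion (mean-preserving-spread) check
#'
#' Tests whether the riskier of two equal-mean lotteries
#' (\{0, .75; 2, .25\} vs \{0, .5; 1, .5\}) is dispreferred by a CARA
#' decision maker (coefficient 1) across a grid of `D`.  In the `D -> Inf`
#' limit the two complete lotteries become indistinguishable (probability
#' exactly 0.5).  Under this model's weights the safer option's
#' probability rises monotonically with `D` but approaches that boundary
#' from below — the mean-preserving spread is (weakly) preferred at every
#' finite `D`; see the methods vignette for the analysis.
#'
#' @param D_grid Grid with `min(D_grid) >= 1`.
#' @param r CARA coefficient (default 1).
#' @return A tibble: `D`, `prob_safer` (probability of the less risky
#'   lottery), `ok`.
#' @export
strong_risk_aversion_check <- function(D_grid = 10^seq(0, 4, length.out = 17),
                                       r = 1) {
  stopifnot(min(D_grid) >= 1)
  cs <- example_choice_set("strong_risk")
  spec <- utility_spec("cara", r = r)
  tibble::tibble(
    D = D_grid,
    prob_safer = vapply(D_grid, function(D) {
      cd <- choice_distribution(cs, srdt_params(spec, D = D))
      cd$prob[cd$lottery_id == "L6"]
    }, numeric(1))
  ) |>
    dplyr::mutate(ok = .data$prob_safer >= 0.5 - 1e-12)
}

#' Time-pressure preference-reversal curve
#'
#' Probability of the low-risk lottery of the time-pressure pair as a
#' function of the deliberation budget `T` (linear utility).  Without a
#' time constraint the higher-mean, riskier lottery is preferred
#' (`prob < 0.5`); shrinking `T` reverses the preference.  The crossing
#' `T*` of 0.5, when present inside the grid, is located by root finding
#' in `log T`.
#'
#' @param D Diffusion coefficient (default 10).
#' @param T_grid Log grid of budgets spanning several decades.
#' @return A tibble of class `srdt_curve` (`T`, `prob_low_risk`) with
#'   attributes `T_star` (NA if no crossing) and `prob_inf` (the
#'   unconstrained probability).
#' @export
time_pressure_curve <- function(D = 10,
                                T_grid = 10^seq(-4, 4, length.out = 81)) {
  cs <- example_choice_set("time_pressure")
  p_of_T <- function(T) {
    cd <- choice_distribution(cs, srdt_params(utility_spec("linear"),
                                              D = D, T = T))
    cd$prob[cd$lottery_id == "L1"]
  }
  probs <- vapply(T_grid, p_of_T, numeric(1))
  cd_inf <- choice_distribution(cs, srdt_params(utility_spec("linear"), D = D))
  prob_inf <- cd_inf$prob[cd_inf$lottery_id == "L1"]

  dd <- probs - 0.5
  flip <- which(dd[-1] * dd[-length(dd)] < 0)
  T_star <- if (length(flip)) {
    i <- flip[[length(flip)]]  # crossing closest to the unconstrained side
    exp(stats::uniroot(function(lt) p_of_T(exp(lt)) - 0.5,
                       c(log(T_grid[i]), log(T_grid[i + 1])),
                       tol = 1e-10)$root)
  } else {
    NA_real_
  }
  out <- tibble::tibble(experiment = "time_pressure", D = D,
                        T = T_grid, prob_low_risk = probs)
  structure(out, T_star = T_star, prob_inf = prob_inf,
            class = c("srdt_curve", class(out)))
}

#' Choice probability versus simulated response time
#'
#' For an ensemble of random binary choice sets, pairs each option's
#' closed-form choice probability with its simulated mean decision time
#' (standardized to a z-score within the ensemble) and reports the rank
#' correlation — the model predicts an inverse relation.  Also measures
#' both candidate readings of the conditional-time identity
#' (\eqn{E[T|choose] = E[T] \cdot P} vs \eqn{E[T] / P} — the product vs
#' quotient reading) and reports their median relative errors.
#'
#' @param n_pairs Number of random binary pairs.
#' @param params An [srdt_params()]; `T` must be `Inf` (times are
#'   unconditional absorption times).
#' @param n_walkers Walkers per pair.
#' @param seed Integer seed.
#' @param outcome_range Outcome interval for the random pairs.
#' @return A list: `table` (per option: `prob`, `mean_time`, `time_z`),
#'   `spearman`, and `eq32` (per-reading median relative error and a
#'   `verdict`).
#' @export
response_time_report <- function(n_pairs = 20,
                                 params = srdt_params(D = 10),
                                 n_walkers = 1e4, seed = 1L,
                                 outcome_range = c(1, 30)) {
  stopifnot(is.infinite(params$T))
  draws <- withr_seed(seed, {
    purrr::map(seq_len(n_pairs), function(i) {
      p1 <- stats::runif(1, 0.2, 0.8)
      p2 <- stats::runif(1, 0.2, 0.8)
      o <- stats::runif(4, outcome_range[1], outcome_range[2])
      list(cs = choice_set(lottery("L1", o[1:2], c(p1, 1 - p1)),
                           lottery("L2", o[3:4], c(p2, 1 - p2))),
           seed = sample.int(1e6, 1))
    })
  })
  rows <- purrr::imap_dfr(draws, function(d, i) {
    cd <- choice_distribution(d$cs, params)
    geom <- build_star_geometry(d$cs, params)
    walk <- run_star_walk(geom, n_walkers, seed = d$seed)
    ct <- conditional_mean_times(walk)
    overall <- attr(ct, "overall")[["mean"]]
    dplyr::left_join(tibble::as_tibble(cd)[, c("lottery_id", "prob")],
                     ct, by = "lottery_id") |>
      dplyr::mutate(pair = i, overall_mean = overall, .before = 1)
  })
  rows$time_z <- as.numeric(scale(rows$mean_time))

  err <- rows |>
    dplyr::mutate(product = abs(.data$mean_time -
                                  .data$overall_mean * .data$prob) /
                    .data$mean_time,
                  quotient = abs(.data$mean_time -
                                   .data$overall_mean / .data$prob) /
                    .data$mean_time)
  eq32 <- tibble::tibble(
    reading = c("product", "quotient"),
    median_rel_error = c(stats::median(err$product),
                         stats::median(err$quotient))
  )
  best <- eq32$reading[which.min(eq32$median_rel_error)]
  eq32$verdict <- ifelse(min(eq32$median_rel_error) < 0.2,
                         paste0("closest: ", best), "neither within 20%")

  list(table = rows,
       spearman = stats::cor(rows$prob, rows$mean_time, method = "spearman"),
       eq32 = eq32)
}
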