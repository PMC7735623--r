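#' Simulate trial-level choices
#'
#' Draws independent choices from each choice set's model distribution —
#' the forward model for likelihood fitting and parameter-recovery
#' studies.
#'
#' @param sets A lottery table with a `set_id` column (or a single set).
#' @param params An [srdt_params()].
#' @param n_per_set Trials per choice set.
#' @param seed Integer seed; fixed seed gives an identical dataset.
#' @return A tibble of class `srdt_trials`: `set_id`, `trial`, `chosen`
#'   (lottery id); generating parameters in `attr(, "params")`.
#' @export
simulate_choices <- function(sets, params, n_per_set, seed = 1L) {
  stopifnot(inherits(params, "srdt_params"), n_per_set >= 1)
  sets <- as_lotteries(sets, choice_set = TRUE)
  if (!"set_id" %in% names(sets)) {
    sets <- dplyr::mutate(sets, set_id = "set001", .before = 1)
  }
  cd <- choice_distribution(sets, params)
  out <- withr_seed(seed, {
    cd |>
      tibble::as_tibble() |>
      dplyr::group_split(.data$set_id) |>
      purrr::map_dfr(function(tab) {
        tibble::tibble(
          set_id = tab$set_id[[1]],
          trial = seq_len(n_per_set),
          chosen = sample(tab$lottery_id, n_per_set, replace = TRUE,
                          prob = tab$prob)
        )
      })
  })
  structure(out, params = params, seed = seed,
            class = c("srdt_trials", class(out)))
}

#' Negative log-likelihood of trial-level choices
#'
#' \eqn{-\sum_t \log P(\text{chosen}_t \mid \text{set}_t, \theta)} under
#' the model's Luce choice probabilities.  Finite whenever every chosen
#' option has positive probability; otherwise `Inf` is returned with a
#' warning naming the offending trials.
#'
#' @param trials A tibble with `set_id` and `chosen` columns.
#' @param sets The lottery table (with `set_id`) the trials refer to.
#' @param params An [srdt_params()].
#' @return A scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(trials, sets, params) {
  stopifnot(inherits(params, "srdt_params"))
  sets <- as_lotteries(sets, choice_set = TRUE)
  if (!"set_id" %in% names(sets)) {
    sets <- dplyr::mutate(sets, set_id = "set001", .before = 1)
  }
  counts <- tibble::as_tibble(trials) |>
    dplyr::count(.data$set_id, .data$chosen, name = "n_chosen")
  cd <- choice_probs_fast(sets, params)
  key <- dplyr::left_join(
    counts, cd,
    by = c(set_id = "set_id", chosen = "lottery_id")
  )
  if (anyNA(key$prob)) {
    stop("some trials reference a set_id/lottery_id absent from `sets`",
         call. = FALSE)
  }
  if (any(key$prob == 0)) {
    warning(sum(key$n_chosen[key$prob == 0]),
            " trial(s) chose a zero-probability option; likelihood is -Inf",
            call. = FALSE)
    return(Inf)
  }
  -sum(key$n_chosen * log(key$prob))
}

#' Fit model parameters by maximum likelihood
#'
#' Multi-start bounded minimization of [negative_log_likelihood()] in
#' log-parameter space (`L-BFGS-B` from a seeded Latin-hypercube of
#' starting points).  Any subset of `r`, `D`, `T` may be free; `T` is
#' only identifiable when the design varies time pressure, so it is fixed
#' at `Inf` unless requested.  The outcome scale is never free: it is
#' confounded with `r` and `D` (rescaling all outcomes by `k` while
#' dividing `r` by `k` and multiplying `D` by `k` leaves the linear-regime
#' likelihood unchanged).
#'
#' @param trials A trials table (see [simulate_choices()]).
#' @param sets The lottery table the trials refer to.
#' @param free Character subset of `c("r", "D", "T")`.
#' @param start An [srdt_params()] holding the fixed values (and the
#'   utility family); free parameters are started from the hypercube.
#' @param bounds Named list of length-2 bounds on the natural scale,
#'   default `[1e-3, 1e3]` for each free parameter.
#' @param n_starts Number of optimizer starts (default 8).
#' @param seed Integer seed for the start hypercube.
#' @param bootstrap Number of nonparametric bootstrap refits (0 = none);
#'   trials are resampled with replacement and refit from the best start.
#' @return An object of class `srdt_fit`: `estimate` (named vector),
#'   `params` (an [srdt_params()] at the optimum), `nll`, `starts`
#'   (per-start table), `convergence`, optional `bootstrap` draws and
#'   percentile intervals.  Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_srdt <- function(trials, sets, free = c("r", "D"),
                     start = srdt_params(utility_spec("cara", r = 1), D = 10),
                     bounds = NULL, n_starts = 8, seed = 1L,
                     bootstrap = 0) {
  free <- match.arg(free, c("r", "D", "T"), several.ok = TRUE)
  sets <- as_lotteries(sets, choice_set = TRUE)
  if (!"set_id" %in% names(sets)) {
    sets <- dplyr::mutate(sets, set_id = "set001", .before = 1)
  }
  default_bounds <- list(r = c(1e-3, 1e3), D = c(1e-3, 1e3),
                         T = c(1e-3, 1e3))
  bounds <- utils::modifyList(default_bounds, as.list(bounds %||% list()))

  make_params <- function(theta) {
    r <- if ("r" %in% free) theta[["r"]] else start$utility$r
    D <- if ("D" %in% free) theta[["D"]] else start$D
    T <- if ("T" %in% free) theta[["T"]] else start$T
    spec <- utility_spec(if (r > 0) "cara" else "linear", r = r,
                         outcome_scale = start$utility$outcome_scale)
    srdt_params(spec, D = D, T = T)
  }
  count_of <- function(tr) {
    dplyr::count(tibble::as_tibble(tr), .data$set_id, .data$chosen,
                 name = "n_chosen")
  }
  nll_of <- function(log_theta, dat) {
    theta <- stats::setNames(exp(log_theta), free)
    cd <- choice_probs_fast(sets, make_params(theta))
    p <- cd$prob[match(paste(dat$set_id, dat$chosen),
                       paste(cd$set_id, cd$lottery_id))]
    if (any(!is.finite(p)) || any(p <= 0)) return(1e10)
    -sum(dat$n_chosen * log(p))
  }

  lower <- log(vapply(free, function(f) bounds[[f]][1], numeric(1)))
  upper <- log(vapply(free, function(f) bounds[[f]][2], numeric(1)))
  starts <- withr_seed(seed, lhs::randomLHS(n_starts, length(free)))
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")

  run_one <- function(x0, dat) {
    tryCatch(
      stats::optim(x0, nll_of, dat = dat, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
  }
  counts <- count_of(trials)
  fits <- purrr::map(seq_len(n_starts), function(i) run_one(starts[i, ], counts))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop("all ", n_starts, " optimizer starts failed", call. = FALSE)
  }
  start_tab <- purrr::imap_dfr(fits, function(f, i) {
    if (is.null(f)) {
      tibble::tibble(start = i, nll = NA_real_, convergence = NA_integer_)
    } else {
      tibble::tibble(start = i, nll = f$value, convergence = f$convergence)
    }
  })
  best <- fits[ok][[which.min(vapply(fits[ok], `[[`, numeric(1), "value"))]]
  est <- stats::setNames(exp(best$par), free)

  boot <- NULL
  if (bootstrap > 0) {
    boot <- withr_seed(seed + 1L, {
      purrr::map_dfr(seq_len(bootstrap), function(b) {
        idx <- sample.int(nrow(trials), replace = TRUE)
        f <- run_one(best$par, count_of(trials[idx, , drop = FALSE]))
        if (is.null(f)) return(NULL)
        tibble::as_tibble(as.list(stats::setNames(exp(f$par), free))) |>
          dplyr::mutate(replicate = b, .before = 1)
      })
    })
  }

  structure(list(estimate = est, params = make_params(est),
                 nll = best$value, convergence = best$convergence,
                 starts = start_tab, free = free, bounds = bounds,
                 n_trials = nrow(trials), bootstrap = boot),
            class = "srdt_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.srdt_fit <- function(x, ...) {
  cat("<srdt_fit> ", x$n_trials, " trials; NLL = ", format(x$nll), "\n",
      sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a model fit
#'
#' @param x An `srdt_fit`.
#' @param conf_level Percentile-interval level when bootstrap draws are
#'   present.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   and `conf.low`/`conf.high` when bootstrapped.
#' @export
tidy.srdt_fit <- function(x, conf_level = 0.95, ...) {
  out <- tibble::tibble(term = x$free,
                        estimate = unname(x$estimate[x$free]))
  if (!is.null(x$bootstrap) && nrow(x$bootstrap) > 0) {
    a <- (1 - conf_level) / 2
    ci <- purrr::map_dfr(x$free, function(f) {
      qs <- stats::quantile(x$bootstrap[[f]], c(a, 1 - a), names = FALSE)
      tibble::tibble(term = f, conf.low = qs[1], conf.high = qs[2])
    })
    out <- dplyr::left_join(out, ci, by = "term")
  }
  out
}

#' Glance at a model fit
#'
#' @param x An `srdt_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `nll`, `logLik`, `n_trials`, `n_starts`,
#'   `convergence`.
#' @export
glance.srdt_fit <- function(x, ...) {
  tibble::tibble(nll = x$nll, logLik = -x$nll, n_trials = x$n_trials,
                 n_starts = nrow(x$starts), convergence = x$convergence)
}
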