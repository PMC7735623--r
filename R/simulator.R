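#' Discretize a choice set into a star lattice geometry
#'
#' Builds the lattice realization of the stochastic representation: one
#' branch per positive-probability branch across all lotteries in the
#' set, of length \eqn{\ell_k = 1/p_k} discretized at spacing `h`
#' (`n_sites = round(l/h)` lattice steps to the absorbing wall), with
#' drift-biased outward step probability
#' \eqn{q_k = \tfrac12 (1 + u_k h / D)} and time per step
#' \eqn{\tau = h^2 / D}, so that the lattice variance per unit time equals
#' the diffusion coefficient and the drift per unit time equals the branch
#' utility up to \eqn{O(h)}.
#'
#' @param x A lottery table (a single choice set).
#' @param params An [srdt_params()]; only the utility spec and `D` enter
#'   the geometry.
#' @param h Lattice spacing.  Default: the larger of what the drift bound
#'   \eqn{\max_k |u_k| h / D \le 0.1} and a minimum of 20 sites on the
#'   shortest branch allow.  An `h` with \eqn{\max_k |u_k| h / D \ge 0.5}
#'   is rejected (the biased step probability would leave \eqn{(0,1)}).
#' @return A tibble of class `srdt_geometry` with one row per branch
#'   (`branch_id`, `lottery_id`, `outcome`, `probability`, `u`, `length`,
#'   `n_sites`, `q`) and attributes `h`, `tau`, `D`.
#' @export
build_star_geometry <- function(x, params, h = NULL) {
  stopifnot(inherits(params, "srdt_params"))
  x <- as_lotteries(x)
  if ("set_id" %in% names(x) && length(unique(x$set_id)) > 1) {
    stop("geometry is built for one choice set at a time", call. = FALSE)
  }
  u <- utility(params$utility, x$outcome)
  len <- 1 / x$probability
  D <- params$D
  umax <- max(abs(u))
  if (is.null(h)) {
    h_drift <- if (umax > 0) 0.1 * D / umax else Inf
    h <- min(h_drift, min(len) / 20)
  }
  if (h <= 0) stop("`h` must be > 0", call. = FALSE)
  if (umax * h / D >= 0.5) {
    stop("lattice spacing too coarse: max |u| h / D = ",
         signif(umax * h / D, 4), " >= 0.5; use h <= ",
         signif(0.1 * D / umax, 4), call. = FALSE)
  }
  n_sites <- as.integer(round(len / h))
  if (min(n_sites) < 2) {
    stop("lattice spacing too coarse: shortest branch has < 2 sites; ",
         "use h <= ", signif(min(len) / 2, 4), call. = FALSE)
  }
  eps <- 1e-6
  q <- pmin(pmax(0.5 * (1 + u * h / D), eps), 1 - eps)
  geom <- tibble::tibble(
    branch_id = seq_len(nrow(x)),
    lottery_id = x$lottery_id,
    outcome = x$outcome,
    probability = x$probability,
    u = u,
    length = len,
    n_sites = n_sites,
    q = q
  )
  structure(geom, h = h, tau = h^2 / D, D = D,
            class = c("srdt_geometry", class(geom)))
}

#' Run walkers on a star geometry
#'
#' Independent lattice walkers, each started at the junction, stepped
#' until absorption at a branch end (or until `max_steps`, then reported
#' unabsorbed).  Seeded through R's RNG: a fixed seed gives bit-identical
#' results.
#'
#' @param geom An [build_star_geometry()] result.
#' @param n_walkers Number of walkers.
#' @param seed Integer seed.
#' @param max_steps Per-walker step budget; default scales with the
#'   squared site count of the longest branch (diffusive time scale).
#' @return A list of class `srdt_walk`: `geometry`, per-walker absorption
#'   `branch` (NA if unabsorbed) and `steps`, `tau`, `n_walkers`, `seed`.
#' @export
run_star_walk <- function(geom, n_walkers, seed = 1L, max_steps = NULL) {
  stopifnot(inherits(geom, "srdt_geometry"), n_walkers >= 1)
  if (is.null(max_steps)) {
    max_steps <- max(1e5, 200 * max(geom$n_sites)^2)
  }
  res <- withr_seed(seed, {
    walk_star_cpp(geom$n_sites, geom$q, as.integer(n_walkers),
                  as.numeric(max_steps))
  })
  unabsorbed <- sum(is.na(res$branch))
  if (unabsorbed > 0.01 * n_walkers) {
    warning(sprintf("%d of %d walkers (%.1f%%) unabsorbed at max_steps = %g",
                    unabsorbed, n_walkers, 100 * unabsorbed / n_walkers,
                    max_steps), call. = FALSE)
  }
  structure(list(geometry = geom, branch = res$branch, steps = res$steps,
                 tau = attr(geom, "tau"), n_walkers = n_walkers,
                 seed = seed, max_steps = max_steps),
            class = "srdt_walk")
}

#' @export
print.srdt_walk <- function(x, ...) {
  cat("<srdt_walk> ", x$n_walkers, " walkers on ",
      nrow(x$geometry), " branches; ",
      sum(is.na(x$branch)), " unabsorbed\n", sep = "")
  invisible(x)
}

#' Splitting-probability estimates from a walk
#'
#' Binomial point estimates and standard errors of the per-branch
#' absorption probabilities, with per-lottery sums (the Monte Carlo
#' estimate of each lottery's choice probability).
#'
#' @param walk An [run_star_walk()] result.
#' @return A tibble with one row per branch (`count`, `p_hat`, `se`);
#'   per-lottery sums in `attr(, "lotteries")`.
#' @export
splitting_estimates <- function(walk) {
  stopifnot(inherits(walk, "srdt_walk"))
  absorbed <- walk$branch[!is.na(walk$branch)]
  n <- length(absorbed)
  if (n == 0) stop("no walkers were absorbed", call. = FALSE)
  geom <- walk$geometry
  counts <- tabulate(absorbed, nbins = nrow(geom))
  out <- geom |>
    dplyr::select("branch_id", "lottery_id", "outcome", "probability") |>
    dplyr::mutate(count = counts,
                  p_hat = counts / n,
                  se = sqrt(.data$p_hat * (1 - .data$p_hat) / n))
  lot <- out |>
    dplyr::summarise(count = sum(.data$count), .by = "lottery_id") |>
    dplyr::mutate(p_hat = .data$count / n,
                  se = sqrt(.data$p_hat * (1 - .data$p_hat) / n))
  structure(out, lotteries = lot, n_absorbed = n)
}

#' Choice estimates conditioned on absorption before a deadline
#'
#' Empirical analogue of the time-budgeted choice probabilities: the
#' per-lottery shares among walkers absorbed at or before time `T`
#' (lattice steps times \eqn{\tau}).
#'
#' @param walk An [run_star_walk()] result.
#' @param T Deadline in model time units; `Inf` reproduces
#'   [splitting_estimates()] per lottery.
#' @return A tibble per lottery: `count`, `p_hat`, `se`, plus the number
#'   of qualifying walkers in `attr(, "n_before")`.
#' @export
conditional_before <- function(walk, T) {
  stopifnot(inherits(walk, "srdt_walk"), T > 0)
  keep <- !is.na(walk$branch) & walk$steps * walk$tau <= T
  n <- sum(keep)
  if (n == 0) {
    stop("no walkers absorbed before T = ", format(T), call. = FALSE)
  }
  geom <- walk$geometry
  counts <- tabulate(walk$branch[keep], nbins = nrow(geom))
  tibble::tibble(lottery_id = geom$lottery_id, count = counts) |>
    dplyr::summarise(count = sum(.data$count), .by = "lottery_id") |>
    dplyr::mutate(p_hat = .data$count / n,
                  se = sqrt(.data$p_hat * (1 - .data$p_hat) / n)) |>
    structure(n_before = n)
}

#' Mean decision times conditioned on the chosen lottery
#'
#' Sample means (and standard errors) of the absorption time among
#' walkers that ended on each lottery, plus the unconditional mean — the
#' quantities behind the model's inverse relation between choice
#' probability and response time.
#'
#' @param walk An [run_star_walk()] result.
#' @return A tibble per lottery: `n`, `mean_time`, `se_time`; overall
#'   mean and its SE in `attr(, "overall")`.
#' @export
conditional_mean_times <- function(walk) {
  stopifnot(inherits(walk, "srdt_walk"))
  ok <- !is.na(walk$branch)
  if (!any(ok)) stop("no walkers were absorbed", call. = FALSE)
  times <- walk$steps[ok] * walk$tau
  lot <- walk$geometry$lottery_id[walk$branch[ok]]
  out <- tibble::tibble(lottery_id = lot, time = times) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_time = mean(.data$time),
                     se_time = stats::sd(.data$time) / sqrt(dplyr::n()),
                     .by = "lottery_id")
  structure(out,
            overall = c(mean = mean(times),
                        se = stats::sd(times) / sqrt(length(times))))
}
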