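# Direct (non-log-space) effective utility: the independent reference the
# stable implementation is checked against, kept deliberately naive.
U_ref <- function(u, p, D) {
  ifelse(u == 0, p * D / 2, u / (1 - exp(-2 * u / (p * D))))
}

# Binary lottery pair with explicit probabilities, as a choice set.
binary_pair <- function(o1, p1, o2, p2) {
  choice_set(
    lottery("L1", o1, c(p1, 1 - p1)),
    lottery("L2", o2, c(p2, 1 - p2))
  )
}

# Random star instances for oracle-agreement tests: 2-5 branches, mixed
# drifts, branch probabilities normalized across the star.  Drift
# magnitudes are capped at 2D so the lattice (drift bound |u|h/D <= 0.1)
# stays small enough for a fast suite; sizes are documented in the
# methods vignette.
random_star_instances <- function(n, seed) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      k <- sample(2:5, 1)
      D <- stats::runif(1, 1, 100)
      umax <- min(20, 2 * D)
      p <- stats::runif(k, 0.05, 0.9)
      list(u = stats::runif(k, -umax, umax), p = p / sum(p), D = D,
           seed = sample.int(1e6, 1))
    })
  })
}

# Star geometry straight from branch vectors (no per-lottery probability
# constraint), mirroring the package's default h rule.
star_geometry_raw <- function(u, p, D) {
  len <- 1 / p
  h <- min(0.1 * D / max(abs(u)), min(len) / 20)
  tab <- tibble::tibble(
    branch_id = seq_along(u),
    lottery_id = rep(c("A", "B"), length.out = length(u)),
    outcome = u, probability = p, u = u, length = len,
    n_sites = as.integer(round(len / h)),
    q = 0.5 * (1 + u * h / D)
  )
  structure(tab, h = h, tau = h^2 / D, D = D,
            class = c("srdt_geometry", class(tab)))
}

# Random choice-set batch used by several property tests.
random_sets <- function(n, seed, outcome_range = c(-50, 50)) {
  generate_random_lotteries(n, outcome_range = outcome_range, seed = seed)
}
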