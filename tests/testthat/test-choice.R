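test_that("lottery weights aggregate branch effective utilities", {
  par <- srdt_params(D = 10)
  # single sure branch
  sure <- lottery("L", 7, 1)
  lw <- lottery_log_weight(sure, par)
  expect_equal(lw$log_weight, log_effective_utility(7, 1, 10))
  # two equal branches double the weight
  dup <- lottery("L", c(10, 10), c(0.5, 0.5))
  expect_equal(lottery_log_weight(dup, par)$log_weight,
               log(2) + log_effective_utility(10, 0.5, 10))
  # Birnbaum dominated lottery at small D: branch utilities sum
  birn2 <- lottery("L2", c(96, 90, 12), c(0.85, 0.05, 0.10))
  expect_equal(lottery_log_weight(birn2, srdt_params(D = 0.01))$log_weight,
               log(96 + 90 + 12), tolerance = 1e-9)
})

test_that("identical lotteries split choice evenly", {
  cs <- choice_set(lottery("A", c(10, 0), c(0.5, 0.5)),
                   lottery("B", c(10, 0), c(0.5, 0.5)))
  for (par in list(srdt_params(D = 3), srdt_params(D = 3, T = 0.5))) {
    cd <- choice_distribution(cs, par)
    expect_equal(cd$prob, c(0.5, 0.5))
  }
})

test_that("choice distributions normalize and stay positive (random sets)", {
  sets <- random_sets(250, seed = 11)
  for (par in list(srdt_params(D = 0.5), srdt_params(D = 20),
                   srdt_params(D = 20, T = 1),
                   srdt_params(utility_spec("cara", r = 0.5), D = 5))) {
    cd <- choice_distribution(sets, par)
    sums <- tapply(cd$prob, cd$set_id, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(cd$prob >= 0))
    br <- attr(cd, "branches")
    csum <- tapply(br$cond_weight, paste(br$set_id, br$lottery_id), sum)
    expect_true(all(abs(csum - 1) < 1e-9))
  }
})

test_that("Luce structure: IIA and strong stochastic transitivity", {
  par <- srdt_params(D = 8)
  pair <- binary_pair(c(30, -5), 0.4, c(12, 6), 0.7)
  cd2 <- choice_distribution(pair, par)
  third <- lottery("L3", c(50, -20), c(0.3, 0.7))
  cd3 <- choice_distribution(dplyr::bind_rows(pair, third), par)
  r2 <- cd2$prob[cd2$lottery_id == "L1"] / cd2$prob[cd2$lottery_id == "L2"]
  r3 <- cd3$prob[cd3$lottery_id == "L1"] / cd3$prob[cd3$lottery_id == "L2"]
  expect_equal(r2, r3, tolerance = 1e-12)

  # SST on 1000 random triples: P12 >= .5 & P23 >= .5 => P13 >= max
  sets <- generate_random_lotteries(1000, lotteries_per_set = 3,
                                    outcome_range = c(-40, 60), seed = 21)
  lw <- lottery_log_weight(sets, par)
  checked <- 0L
  for (tab in split(lw, lw$set_id)) {
    w <- tab$log_weight
    pij <- function(i, j) 1 / (1 + exp(w[j] - w[i]))
    perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                   c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    for (k in seq_len(nrow(perms))) {
      a <- perms[k, 1]; b <- perms[k, 2]; c_ <- perms[k, 3]
      if (pij(a, b) >= 0.5 && pij(b, c_) >= 0.5) {
        expect_gte(pij(a, c_), max(pij(a, b), pij(b, c_)) - 1e-12)
        checked <- checked + 1L
      }
    }
  }
  expect_gte(checked, 1000)
})

test_that("subjective probability has the documented limits and shape", {
  # D -> infinity: objective probability recovered
  expect_equal(subjective_probability(0.3, 30, 30, srdt_params(D = 1e9)),
               0.3, tolerance = 1e-6)
  ps <- seq(0.05, 0.95, by = 0.05)
  expect_equal(subjective_probability(ps, 30, 30, srdt_params(D = 1e8)),
               ps, tolerance = 1e-5)
  # symmetry at p = 1/2
  expect_equal(subjective_probability(0.5, 30, 30, srdt_params(D = 7)), 0.5)
  # strong overweighting at D = 20 (direct evaluation)
  expect_equal(subjective_probability(0.3, 30, 30, srdt_params(D = 20)),
               0.496546558691, tolerance = 1e-9)
  # inverse-S: above identity below p*, below identity above it
  pi_ <- subjective_probability(ps, 30, 30, srdt_params(D = 40))
  expect_true(all(pi_[ps < 0.5] > ps[ps < 0.5]))
  expect_true(all(pi_[ps > 0.5] < ps[ps > 0.5]))
  expect_error(subjective_probability(0, 30, 30, srdt_params(D = 1)), "0, 1")
})

test_that("asymptotic D limits match the closed forms", {
  par_lin <- srdt_params(D = 1)
  # all-gain: branch-utility sums (Birnbaum pair: 122 vs 198)
  birn <- example_choice_set("birnbaum")
  lim <- limit_choice_probabilities(birn, par_lin, "D_to_0")
  expect_equal(lim$prob[lim$lottery_id == "L2"], 198 / 320)
  # numeric small-D distribution converges to the limit for all-gain sets
  gains <- random_sets(40, seed = 31, outcome_range = c(1, 80))
  lim_g <- limit_choice_probabilities(gains, par_lin, "D_to_0")
  num <- choice_distribution(gains, srdt_params(D = 1e-4))
  expect_equal(num$prob, lim_g$prob, tolerance = 1e-3)
  # D -> infinity: complete lotteries become equivalent
  lim_inf <- limit_choice_probabilities(birn, par_lin, "D_to_inf")
  expect_equal(lim_inf$prob, c(0.5, 0.5))
  num_inf <- choice_distribution(birn, srdt_params(D = 1e9))
  expect_equal(num_inf$prob, c(0.5, 0.5), tolerance = 1e-6)
  # all-loss sets: mass concentrates on the slowest-decaying lottery
  losses <- binary_pair(c(-10, -20), 0.5, c(-30, -40), 0.5)
  lim_l <- limit_choice_probabilities(losses, par_lin, "D_to_0")
  expect_equal(lim_l$prob[lim_l$lottery_id == "L1"], 1)
  num_l <- choice_distribution(losses, srdt_params(D = 0.05))
  expect_equal(num_l$prob[num_l$lottery_id == "L1"], 1, tolerance = 1e-3)
})

test_that("time budgets: T = 1e12 matches T = Inf; tiny-p suppression errors", {
  sets <- random_sets(50, seed = 41)
  cd_inf <- choice_distribution(sets, srdt_params(D = 10))
  cd_big <- choice_distribution(sets, srdt_params(D = 10, T = 1e12))
  expect_equal(cd_big$prob, cd_inf$prob, tolerance = 1e-6)

  # tiny-p branches are crushed to astronomically small log weights under a
  # finite budget, yet the log-space Luce ratio stays well defined
  w <- log_effective_utility_timed(c(5, 3), c(1e-8, 1e-8), 1, 1e-3)
  expect_true(all(w < -1e8))
  crushed <- binary_pair(c(-1e6, -1e6), 0.5, c(-1e6, -1e6), 0.5)
  cd <- choice_distribution(crushed, srdt_params(D = 1, T = 1))
  expect_equal(cd$prob, c(0.5, 0.5))
})

test_that("printed pairs reproduce their closed-form values", {
  # time-pressure pair, linear utility, D = 10, unconstrained
  cs <- example_choice_set("time_pressure")
  cd <- choice_distribution(cs, srdt_params(D = 10))
  expect_equal(cd$prob[cd$lottery_id == "L1"], 0.470596493462,
               tolerance = 1e-9)
  # Birnbaum pair: dominated lottery probability flat at 198/320 for D <= 10
  birn <- example_choice_set("birnbaum")
  for (D in c(10, 1, 0.1, 0.01)) {
    cd <- choice_distribution(birn, srdt_params(D = D))
    expect_equal(cd$prob[cd$lottery_id == "L2"], 0.61875, tolerance = 1e-6)
  }
})
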