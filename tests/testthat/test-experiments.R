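test_that("fourfold curves: singular p -> 0 limit with and without a budget", {
  pre <- fourfold_preset()
  grid <- c(0.002, 0.005, 0.01)
  inf_curve <- fourfold_curves(r = pre$r, D = pre$D, T = Inf, p_grid = grid)
  fin_curve <- fourfold_curves(r = pre$r, D = pre$D, T = pre$T, p_grid = grid)
  g_inf <- inf_curve$prob_risky[inf_curve$task == "gain"]
  g_fin <- fin_curve$prob_risky[fin_curve$task == "gain"]
  # unconstrained: risky stays strictly preferred as p -> 0 (no 0.5 limit)
  expect_true(all(g_inf > 0.505))
  # finite budget restores P -> 0.5
  expect_true(all(abs(g_fin - 0.5) < abs(g_inf - 0.5)))
  expect_lt(abs(g_fin[1] - 0.5), 0.01)
})

test_that("the documented preset reproduces all four risk-attitude cells", {
  pre <- fourfold_preset()
  cur <- fourfold_curves(r = pre$r, D = pre$D, T = pre$T,
                         stake = pre$stake, outcome_scale = pre$outcome_scale)
  cls <- fourfold_classify(cur)
  expect_true(all(cls$pass))
  expect_true(all(cur$prob_risky >= 0 & cur$prob_risky <= 1))
})

test_that("gain-side aversion and loss-side seeking grow together with r", {
  probs <- purrr::map_dfr(c(5, 6, 8), function(r) {
    cls <- fourfold_classify(fourfold_curves(r = r, D = 10, T = 2000))
    tibble::tibble(r = r,
                   gain_low = cls$prob_risky[cls$task == "gain" &
                                               cls$regime == "low_p"],
                   loss_high = cls$prob_risky[cls$task == "loss" &
                                                cls$regime == "high_p"])
  })
  # more concave utility: less gain-side risk seeking, more loss-side
  expect_true(all(diff(probs$gain_low) < 0))
  expect_true(all(diff(probs$loss_high) > 0))
})

test_that("a very small budget destroys the possibility effect on gains", {
  pre <- fourfold_preset()
  cls <- fourfold_classify(fourfold_curves(r = pre$r, D = pre$D, T = 0.01))
  expect_lt(cls$prob_risky[cls$task == "gain" & cls$regime == "low_p"], 0.5)
})

test_that("a probability-only decision maker (large D) is indifferent", {
  cls <- fourfold_classify(fourfold_curves(r = 6, D = 1e8, T = 2000))
  expect_true(all(abs(cls$prob_risky - 0.5) < 1e-5))
})

test_that("weighting shape transitions: inverse-S -> double-S -> S as T falls", {
  expect_equal(weighting_shape(10, 10, 10, T = 1000)$shape, "inverse-S")
  ws <- weighting_shape(10, 10, 10, T = 0.3)
  expect_equal(ws$shape, "double-inverse-S")
  expect_length(ws$crossings, 3)
  expect_equal(weighting_shape(10, 10, 10, T = 0.02)$shape, "S")
  # unconstrained symmetric case: plain inverse-S with crossing near p* = 1/2
  ws_inf <- weighting_shape(10, 10, 10, T = Inf)
  expect_equal(ws_inf$shape, "inverse-S")
  expect_equal(ws_inf$crossings, 0.5, tolerance = 1e-3)
  expect_true(all(ws_inf$curve$pi >= 0 & ws_inf$curve$pi <= 1))
})

test_that("dominance: Birnbaum violation for small D, none when evident", {
  ds <- dominance_suite(D_grid = 10^seq(-2, 1, length.out = 10))
  expect_equal(ds$limit_prob_dominated, 198 / 320)
  expect_true(all(ds$birnbaum$violated))
  expect_true(all(ds$evident$ok))
  # the preference for the dominated lottery fades toward indifference as D
  # grows (probability-only decision maker) but from above
  wide <- dominance_suite(D_grid = c(0.1, 1e6))
  expect_lt(wide$birnbaum$prob_dominated[2] - 0.5, 1e-4)
  expect_gt(wide$birnbaum$prob_dominated[1],
            wide$birnbaum$prob_dominated[2])
})

test_that("mean-preserving-spread check reports the D-dependence honestly", {
  # with CARA r = 1 the safer lottery's probability rises monotonically in D
  # toward (but here never beyond) the large-D indifference boundary
  chk <- strong_risk_aversion_check(D_grid = 10^seq(0, 4, length.out = 17))
  expect_true(all(diff(chk$prob_safer) > 0))
  expect_true(all(chk$prob_safer <= 0.5))
  expect_equal(chk$prob_safer[nrow(chk)], 0.5, tolerance = 1e-3)
  expect_identical(chk$ok, chk$prob_safer >= 0.5 - 1e-12)
  # boundary: D -> infinity limit is exact indifference
  cs <- example_choice_set("strong_risk")
  lim <- limit_choice_probabilities(cs, srdt_params(utility_spec("cara", 1),
                                                    D = 1), "D_to_inf")
  expect_equal(lim$prob, c(0.5, 0.5))
})

test_that("time pressure reverses the printed pair's preference", {
  tc <- time_pressure_curve(D = 10)
  expect_equal(attr(tc, "prob_inf"), 0.470596493462, tolerance = 1e-9)
  expect_lt(attr(tc, "prob_inf"), 0.5)
  expect_gt(max(tc$prob_low_risk), 0.5)
  T_star <- attr(tc, "T_star")
  expect_true(is.finite(T_star))
  # beyond the crossing, more time means less low-risk choice
  post <- tc$prob_low_risk[tc$T > T_star]
  expect_true(all(diff(post) < 1e-12))
  expect_true(all(tc$prob_low_risk >= 0 & tc$prob_low_risk <= 1))
})

test_that("choice probability and mean decision time are inversely related", {
  rt <- response_time_report(n_pairs = 12, n_walkers = 4000, seed = 17)
  expect_lt(rt$spearman, 0)
  expect_true(all(c("product", "quotient") %in% rt$eq32$reading))
  expect_true(all(is.finite(rt$eq32$median_rel_error)))
})

test_that("curve tables survive a CSV round trip", {
  cur <- fourfold_curves(r = 2, D = 10, T = 1000,
                         p_grid = seq(0.1, 0.9, by = 0.1))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cur, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$prob_risky, cur$prob_risky)
})
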