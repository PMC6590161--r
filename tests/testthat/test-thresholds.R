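test_that("classic threshold is H/(B+H) with the expected boundary behaviour", {
  expect_equal(classic_threshold(0.1, 0.1)$value, 0.5)
  expect_equal(classic_threshold(0, 0.2)$value, 1)
  t <- classic_threshold(0.009652, 0.048)
  expect_equal(t$value, 0.048 / (0.009652 + 0.048), tolerance = 1e-12)
  expect_true(t$valid)
  expect_false(t$never_treat)
  expect_error(classic_threshold(0.1, 0), "net harm must be positive")
  expect_error(classic_threshold(0.1, -0.1), "net harm must be positive")
})

test_that("negative net benefit yields a never-treat result", {
  t <- classic_threshold(-0.05, 0.1)
  expect_true(t$never_treat)
  expect_false(t$valid)
  expect_match(t$note, "negative")
})

test_that("classic threshold is invariant to rescaling the utility units", {
  set.seed(3)
  for (i in 1:20) {
    b <- runif(1, 0, 0.5); h <- runif(1, 0.01, 0.5); k <- runif(1, 0.1, 10)
    expect_equal(classic_threshold(b, h)$value,
                 classic_threshold(k * b, k * h)$value, tolerance = 1e-12)
  }
})

test_that("evidence-based probability threshold reproduces the VTE example", {
  t <- ebm_probability_threshold(1, 0.048, 0.812, 0.071)
  expect_equal(round(100 * t$value), 83)
  # mortality variant: harmless in the metric used, threshold collapses to 0
  t0 <- ebm_probability_threshold(1, 0, 0.812, 0.002)
  expect_equal(t0$value, 0)
  expect_equal(ebm_probability_threshold(0.4, 0, 0.9, 0.3)$value, 0)
})

test_that("unavertable risk gives a never-treat probability threshold", {
  t <- ebm_probability_threshold(1, 0.05, 0, 0.1)
  expect_true(t$never_treat)
  expect_match(t$note, "does not affect")
  t2 <- ebm_probability_threshold(1, 0.05, 0.8, 0)
  expect_true(t2$never_treat)
  expect_match(t2$note, "no outcome risk")
})

test_that("thresholds above 1 are reported, flagged never_treat, not clamped", {
  t <- ebm_probability_threshold(1, 0.1, 0.5, 0.1)  # 0.1/0.05 = 2
  expect_equal(t$value, 2)
  expect_true(t$never_treat)
  expect_false(t$valid)
})

test_that("outcome-risk threshold reproduces the printed sensitivity range", {
  expect_equal(round(100 * outcome_threshold(1, 0.048, 0.812)$value, 1), 5.9)
  expect_equal(round(100 * outcome_threshold(0.75, 0.048, 0.812)$value, 1), 4.4)
  expect_equal(round(100 * outcome_threshold(0.045, 0.048, 0.812)$value, 1), 0.3)
  t <- outcome_threshold(1, 0.05, 0)
  expect_true(t$never_treat)
})

test_that("outcome threshold never depends on baseline risk or disease probability", {
  for (m in c(0.01, 0.2, 0.9)) {
    s <- ebm_scenario(baseline_risk = m, rrr = 0.7, harm_rx = 0.03,
                      disease_prob = m / 2, regime = "dependent")
    expect_equal(scenario_threshold(s, "outcome_risk")$value, 0.03 / 0.7)
  }
})

test_that("NNT/NNH threshold agrees with the effect-measure form", {
  nnt_ <- 1 / (0.071 * 0.812)
  nnh_ <- 1 / 0.048
  expect_equal(nnt_nnh_threshold(nnt_, nnh_)$value,
               ebm_probability_threshold(1, 0.048, 0.812, 0.071)$value,
               tolerance = 1e-12)
  expect_equal(nnt_nnh_threshold(15, 15)$value, 1)
  expect_equal(nnt_nnh_threshold(10, 20, rv_harm = 0.5)$value, 0.25)
  expect_error(nnt_nnh_threshold(-1, 10), "positive")
  expect_error(nnt_nnh_threshold(10, 0), "positive")
})

test_that("decision rule: treat above, withhold below, indifferent at equality", {
  mt <- outcome_threshold(1, 0.048, 0.812)
  expect_identical(decide(0.15, mt), "treat")
  expect_identical(decide(0.002, mt), "no_treat")
  expect_identical(decide(mt$value, mt), "indifferent")
  never <- outcome_threshold(1, 0.05, 0)
  expect_identical(decide(0.99, never), "no_treat")
})

test_that("decision rule refuses mismatched estimate and threshold kinds", {
  mt <- outcome_threshold(1, 0.048, 0.812)
  pt <- ebm_probability_threshold(1, 0.048, 0.812, 0.071)
  expect_error(decide(0.15, mt, estimate_kind = "disease_probability"),
               "kind mismatch")
  expect_error(decide(0.9, pt, estimate_kind = "outcome_risk"),
               "kind mismatch")
  expect_identical(decide(0.15, mt, estimate_kind = "outcome_risk"), "treat")
})

test_that("outcome threshold is monotone in preferences, harm, and efficacy", {
  rv_grid <- seq(0.05, 1.5, by = 0.05)
  vals <- sapply(rv_grid, function(rv) outcome_threshold(rv, 0.048, 0.812)$value)
  expect_true(all(diff(vals) > 0))
  h_grid <- seq(0.005, 0.2, by = 0.005)
  vals <- sapply(h_grid, function(h) outcome_threshold(0.75, h, 0.812)$value)
  expect_true(all(diff(vals) > 0))
  rrr_grid <- seq(0.05, 0.99, by = 0.01)
  vals <- sapply(rrr_grid, function(r) outcome_threshold(0.75, 0.048, r)$value)
  expect_true(all(diff(vals) < 0))
})

test_that("the outcome-risk threshold never exceeds the probability threshold", {
  scenarios <- generate_scenarios(1000, seed = 7)
  for (s in scenarios) {
    mt <- outcome_threshold(s$rv_harm, s$harm_rx, s$rrr)$value
    pt <- ebm_probability_threshold(s$rv_harm, s$harm_rx, s$rrr,
                                    s$baseline_risk)$value
    expect_lte(mt, pt + 1e-12)
    expect_equal(mt, pt * s$baseline_risk, tolerance = 1e-12)
  }
})

test_that("classic threshold on reconstructed utilities equals the EBM closed form", {
  scenarios <- generate_scenarios(1000, seed = 13)
  for (s in scenarios) {
    u <- utilities_from_ebm(s)
    lhs <- classic_threshold(net_benefit(u), net_harm(u))$value
    rhs <- ebm_probability_threshold(s$rv_harm, s$harm_rx, s$rrr,
                                     s$baseline_risk)$value
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("regime guard refuses the disease-probability threshold when the outcome defines disease", {
  s <- regime_check(einstein_scenario(regime = "independent"), TRUE)
  expect_identical(s$regime, "dependent")
  expect_error(scenario_threshold(s, "disease_probability"), "double counting")
  expect_silent(scenario_threshold(s, "outcome_risk"))

  indep <- regime_check(s, FALSE)
  expect_identical(indep$regime, "independent")
  expect_silent(scenario_threshold(indep, "disease_probability"))
})
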