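test_that("expected utilities collapse to the branch utilities at p = 0 and 1", {
  u <- toy_quadruple()
  expect_identical(expected_utility_treat(0, u), u$u_treat_nodisease)
  expect_identical(expected_utility_treat(1, u), u$u_treat_disease)
  expect_identical(expected_utility_notreat(0, u), u$u_notreat_nodisease)
  expect_identical(expected_utility_notreat(1, u), u$u_notreat_disease)
  expect_equal(expected_utility_treat(0.5, u), 0.85)
  expect_equal(expected_utility_notreat(0.5, u), 0.70)
  expect_error(expected_utility_treat(1.2, u), "probability")
})

test_that("expected utility is linear in the disease probability", {
  set.seed(11)
  for (i in 1:25) {
    u <- utility_quadruple(runif(1), runif(1), runif(1), runif(1))
    p <- runif(1)
    expect_equal(expected_utility_treat(p, u),
                 p * expected_utility_treat(1, u) +
                   (1 - p) * expected_utility_treat(0, u),
                 tolerance = 1e-15)
    expect_equal(expected_utility_notreat(p, u),
                 p * expected_utility_notreat(1, u) +
                   (1 - p) * expected_utility_notreat(0, u),
                 tolerance = 1e-15)
  }
})

test_that("net benefit and net harm are the diagonal utility differences", {
  u <- toy_quadruple()
  expect_equal(net_benefit(u), 0.4)
  expect_equal(net_harm(u), 0.1)
  flat <- utility_quadruple(0.5, 0.7, 0.5, 0.7)
  expect_equal(net_benefit(flat), 0)
  expect_equal(net_harm(flat), 0)
})

test_that("the EBM utility mapping reproduces the worked-example quadruple", {
  u <- utilities_from_ebm(einstein_rounded())
  expect_equal(u$u_notreat_nodisease, 1)
  expect_equal(u$u_notreat_disease, 1 - 0.071)
  expect_equal(u$u_treat_nodisease, 1 - 0.048)
  expect_equal(u$u_treat_disease, 1 - (1 - 0.812) * 0.071 - 0.048)
  # net benefit/harm in effect-measure terms: B = M*RRR - RV_H*H_rx, H = RV_H*H_rx
  expect_equal(net_benefit(u), 0.071 * 0.812 - 0.048, tolerance = 1e-12)
  expect_equal(net_harm(u), 0.048, tolerance = 1e-12)
})

test_that("degenerate scenarios map to the boundary utilities", {
  s0 <- ebm_scenario(baseline_risk = 0, rrr = 0.5, harm_rx = 0)
  u0 <- utilities_from_ebm(s0)
  expect_equal(unlist(u0[1:4], use.names = FALSE), rep(1, 4))
  s1 <- ebm_scenario(baseline_risk = 0.3, rrr = 1, harm_rx = 0)
  expect_equal(utilities_from_ebm(s1)$u_treat_disease, 1)
})

test_that("scenarios implying negative utilities are rejected, not clamped", {
  s <- ebm_scenario(baseline_risk = 0.2, rrr = 0.5, harm_rx = 0.9,
                    rv_harm = 1.5)
  expect_error(utilities_from_ebm(s), "negative terminal utility")
})

test_that("scenario constructor derives and cross-checks the effect inputs", {
  s <- einstein_scenario()
  expect_equal(s$rrr, (42 / 594 - 8 / 602) / (42 / 594), tolerance = 1e-12)
  s2 <- ebm_scenario(baseline_risk = 0.1, rrr = 0.4, harm_rx = 0)
  expect_equal(s2$treated_risk, 0.06)
  expect_error(ebm_scenario(baseline_risk = 0.1, treated_risk = 0.06,
                            rrr = 0.5, harm_rx = 0),
               "inconsistent")
  # consistent duplicates are accepted
  expect_silent(ebm_scenario(baseline_risk = 0.1, treated_risk = 0.06,
                             rrr = 0.4, harm_rx = 0))
  expect_error(ebm_scenario(baseline_risk = 0.1, harm_rx = 0),
               "treated_risk or rrr")
})

test_that("Monte Carlo estimate matches the closed-form expected utility", {
  s <- einstein_rounded()
  u <- utilities_from_ebm(s)

  # p = 0, no-treat arm: no events are possible, utility exactly 1
  est0 <- mc_expected_utility(s, "notreat", p = 0, n = 1000, seed = 1)
  expect_identical(est0$mean_utility, 1)
  expect_identical(est0$std_error, 0)

  est3 <- mc_expected_utility(s, "notreat", p = 1, n = 2e5, seed = 2)
  expect_lt(abs(est3$mean_utility - u$u_notreat_disease), 4 * est3$std_error)

  est1 <- mc_expected_utility(s, "treat", p = 1, n = 2e5, seed = 3)
  expect_lt(abs(est1$mean_utility - u$u_treat_disease), 4 * est1$std_error)
})

test_that("Monte Carlo runs are reproducible and leave the RNG untouched", {
  s <- einstein_rounded()
  set.seed(99)
  before <- .Random.seed
  a <- mc_expected_utility(s, "treat", p = 0.5, n = 1e4, seed = 7)
  b <- mc_expected_utility(s, "treat", p = 0.5, n = 1e4, seed = 7)
  expect_identical(a$mean_utility, b$mean_utility)
  expect_identical(.Random.seed, before)
})

test_that("Monte Carlo standard error shrinks like 1/sqrt(n)", {
  s <- einstein_rounded()
  small <- mc_expected_utility(s, "treat", p = 0.5, n = 1e4, seed = 5)
  big <- mc_expected_utility(s, "treat", p = 0.5, n = 16e4, seed = 6)
  # quadrupling the sample size in each of two steps halves the SE twice
  expect_equal(small$std_error / big$std_error, 4, tolerance = 0.15)
})

test_that("Monte Carlo stays within 4 SE of the closed form across many seeds", {
  s <- einstein_scenario()
  u <- utilities_from_ebm(s)
  p <- 0.6
  closed <- expected_utility_treat(p, u)
  hits <- vapply(1:100, function(seed) {
    est <- mc_expected_utility(s, "treat", p = p, n = 2e4, seed = seed)
    abs(est$mean_utility - closed) <= 4 * est$std_error
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
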