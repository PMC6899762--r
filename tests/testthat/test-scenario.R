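test_that("built-in scenario catalogue matches the benchmark setting", {
  scs <- builtin_scenarios()
  expect_length(scs, 9)
  s1 <- scs$scenario1
  expect_equal(s1$p_t, c(0.01, 0.15, 0.45, 0.65))
  expect_equal(s1$mu, c(0.5, -0.5, -1.5, -3.0))
  expect_equal(s1$obr, 2L)
  expect_equal(scs$scenario2$obr, 1L)
  expect_equal(scs$scenario3$obr, 4L)
  expect_true(is.na(scs$scenario5$obr))
  expect_true(is.na(scs$scenario6$obr))
  # combination scenario 9, dB1 row, and its OBR (dA2, dB1)
  s9 <- scs$scenario9
  expect_equal(s9$p_t[1:4], c(0.01, 0.15, 0.40, 0.50))
  expect_equal(s9$mu[1:4], c(0.0, -2.0, -2.0, -2.0))
  expect_equal(s9$obr, 2L)
  expect_equal(scs$scenario7$obr, 6L)   # (dA2, dB2)
  expect_equal(scs$scenario8$obr, 3L)   # (dA3, dB1)
  expect_true(all(vapply(scs, function(s) s$r == 0.2, logical(1))))
  expect_equal(builtin_scenarios(r = 0.8)$scenario4$r, 0.8)
})

test_that("outcome generator has exact margins for any correlation", {
  set.seed(101)
  n <- 1e5
  for (r in c(0, 0.5, -0.8)) {
    d <- draw_patient(p_t = 0.3, mu = -1.5, sigma = 1, r = r, n = n)
    se_t <- sqrt(0.3 * 0.7 / n)
    expect_lt(abs(mean(d$tox) - 0.3), 3 * se_t)
    expect_lt(abs(mean(d$eff) - (-1.5)), 3 / sqrt(n))
    expect_lt(abs(sd(d$eff) - 1), 3 / sqrt(2 * n))
  }
})

test_that("positive correlation couples toxicity with clinical response", {
  set.seed(102)
  d <- draw_patient(p_t = 0.5, mu = 0, r = 0.8, n = 1e5)
  # lower outcome values are better: toxic patients respond better
  expect_lt(cor(d$tox, d$eff), -0.3)
  d2 <- draw_patient(p_t = 0.5, mu = 0, r = -0.8, n = 1e5)
  expect_gt(cor(d2$tox, d2$eff), 0.3)
  # boundary: p_t = 0 yields no toxicities
  d0 <- draw_patient(p_t = 0, mu = 0, r = 0.2, n = 1000)
  expect_true(all(d0$tox == 0))
  expect_error(draw_patient(0.3, 0, r = 1), "strictly")
})

test_that("missing-on-toxicity removes only toxic patients' efficacy", {
  cfg <- we_design(N = 6)
  oracle <- fixed_oracle(list(c(1, 0, 0), 0, 0, 0),
                         list(-1, -1, -1, -1))
  tr <- run_trial(cfg, oracle, observation_model(missing_on_toxicity = TRUE),
                  seed = 1)
  # every cohort at regimen 1 contributes 1 toxicity, 2 efficacy values
  expect_equal(tr$state$eff_n[1], 2 / 3 * tr$n_per_regimen[1])
  expect_equal(tr$state$t[1], 1 / 3 * tr$n_per_regimen[1])
  base <- run_trial(cfg, oracle, observation_model(), seed = 1)
  expect_equal(base$state$eff_n[1], base$n_per_regimen[1])
  # the efficacy metric still averages over all treated patients
  expect_equal(length(tr$efficacy_values), tr$n_treated)
})

test_that("delayed efficacy lags the decisions by one cycle", {
  cfg <- we_design(N = 9)
  # regimen 1 looks bad on efficacy once observed
  oracle <- fixed_oracle(list(0, 0, 0, 0), list(3, -1, -1, -1))
  lagged <- run_trial(cfg, oracle, observation_model(delayed = TRUE),
                      seed = 5, log = TRUE)
  prompt <- run_trial(cfg, oracle, observation_model(), seed = 5, log = TRUE)
  # at the second decision the delayed trial has toxicity data but no
  # efficacy data: its criterion uses the updated toxicity estimate and
  # the prior efficacy mean, while the prompt trial has both updated
  p_hat <- (0 + 0.10) / (3 + 1)
  pe_prior <- transform_value(-1, cfg$transform)
  d_lag <- trade_off_marginal(p_hat, pe_prior, cfg$target)
  expect_equal(lagged$log[[2]]$delta[1], d_lag)
  expect_false(isTRUE(all.equal(prompt$log[[2]]$delta[1], d_lag)))
  # by the final analysis all efficacy is released in both cases
  expect_equal(lagged$state$eff_n[1], lagged$n_per_regimen[1])
})

test_that("replicated operating characteristics aggregate consistently", {
  cfg <- we_design()
  sc <- builtin_scenarios()[["scenario2"]]
  oc <- simulate_oc(sc, cfg, reps = 40, seed = 9)
  expect_equal(sum(oc$selection_pct) + oc$termination_pct, 100)
  expect_lte(oc$toxicity_pct / 100, max(sc$p_t) + 0.05)
  # bit-for-bit reproducibility
  oc2 <- simulate_oc(sc, cfg, reps = 40, seed = 9)
  expect_identical(oc, oc2)
  # a single replicate equals the corresponding run_trial
  oc1 <- simulate_oc(sc, cfg, reps = 1, seed = 4)
  tr <- run_trial(cfg, scenario_oracle(sc),
                  seed = wedesign:::replicate_seed(4, 1))
  if (tr$terminated) expect_equal(oc1$termination_pct, 100)
  else expect_equal(which(oc1$selection_pct == 100), tr$recommendation)
  expect_equal(oc1$mean_efficacy, mean(tr$efficacy_values))
})

test_that("layout mismatches between scenario and design are rejected", {
  expect_error(simulate_oc(builtin_scenarios()$scenario7, we_design(),
                           reps = 1, seed = 1), "layout")
})
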