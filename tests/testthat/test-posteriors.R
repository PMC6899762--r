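test_that("Beta posterior reproduces the conjugate mean formula", {
  post <- toxicity_posterior(nu = 0.10, strength = 1)
  expect_equal(mean(post), 0.10)                       # prior mean nu/strength
  post <- update_toxicity(post, new_tox = 1, new_n = 3)
  expect_equal(mean(post), (1 + 0.1) / (3 + 1))        # 0.275
  expect_error(update_toxicity(post, 2, 1), "new_tox")
  expect_error(toxicity_posterior(1.5, 1), "0 < nu")
})

test_that("sequential equals batch updating for both posteriors", {
  tox1 <- update_toxicity(update_toxicity(toxicity_posterior(0.1), 0, 1),
                          1, 2)
  tox2 <- update_toxicity(toxicity_posterior(0.1), 1, 3)
  expect_identical(tox1[c("t", "n")], tox2[c("t", "n")])

  x <- c(0.3, -1.2, 0.8, -0.4)
  e1 <- update_efficacy(update_efficacy(efficacy_posterior(-1), x[1:2]),
                        x[3:4])
  e2 <- update_efficacy(efficacy_posterior(-1), x)
  expect_equal(mean(e1), mean(e2))
  expect_equal(efficacy_mean_variance(e1), efficacy_mean_variance(e2))
})

test_that("efficacy posterior mean is the stated convex combination", {
  post <- update_efficacy(efficacy_posterior(mu0 = -1, lambda = 1), c(0, -2))
  expect_equal(mean(post), -1)                         # symmetric data
  post2 <- update_efficacy(efficacy_posterior(mu0 = -1, lambda = 1), 0)
  expect_equal(mean(post2), -0.5)                      # (1*(-1)+0)/(1+1)
  set.seed(11)
  for (i in 1:10) {
    mu0 <- rnorm(1); lam <- runif(1, 0.5, 4)
    x <- rnorm(sample(1:6, 1))
    p <- update_efficacy(efficacy_posterior(mu0, lambda = lam), x)
    wprior <- lam / (lam + length(x))
    expect_equal(mean(p), wprior * mu0 + (1 - wprior) * mean(x))
  }
  expect_error(update_efficacy(efficacy_posterior(0), c(1, NA)), "finite")
})

test_that("posterior toxicity mean lies between prior mean and data rate", {
  set.seed(12)
  for (i in 1:20) {
    nu <- runif(1, 0.05, 0.9); n <- sample(1:20, 1); t <- rbinom(1, n, 0.3)
    post <- update_toxicity(toxicity_posterior(nu, 1), t, n)
    lo <- min(nu, t / n); hi <- max(nu, t / n)
    if (lo < hi) expect_true(mean(post) > lo && mean(post) < hi)
  }
})

test_that("posterior mean agrees with a grid-integration oracle", {
  x <- c(0.4, -1.1, 0.2)
  post <- update_efficacy(efficacy_posterior(mu0 = -1, lambda = 1,
                                             zeta = 2, zeta_prime = 3), x)
  expect_equal(mean(post),
               oracle_nig_mean(x, -1, 1, 2, 3), tolerance = 1e-6)
  x2 <- c(-2.5, -3.4)
  post2 <- update_efficacy(efficacy_posterior(mu0 = -1.05, lambda = 1), x2)
  expect_equal(mean(post2),
               oracle_nig_mean(x2, -1.05, 1, 2, 3), tolerance = 1e-6)
})

test_that("toxicity exceedance equals the Beta upper tail", {
  flat <- toxicity_posterior(nu = 0.5, strength = 1)   # Beta(0.5, 0.5)
  # uniform case: Beta(1, 1) posterior after matching pseudo-data
  unif <- update_toxicity(toxicity_posterior(0.5, 1), 0.5, 1)
  expect_equal(toxicity_exceedance(unif, 0.3), 0.7, tolerance = 1e-12)
  post <- update_toxicity(toxicity_posterior(0.10, 1), 1, 3)
  expect_equal(toxicity_exceedance(post, 0.3),
               oracle_beta_tail(1.1, 2.9, 0.3), tolerance = 1e-4)
  phis <- seq(0.05, 0.95, by = 0.05)
  tails <- vapply(phis, function(p) toxicity_exceedance(post, p), numeric(1))
  expect_true(all(diff(tails) < 0))
  expect_error(toxicity_exceedance(post, 0), "phi")
})

test_that("futility probability follows the normal approximation", {
  prior <- efficacy_posterior(mu0 = -1, lambda = 1, zeta = 2, zeta_prime = 3)
  sd0 <- sqrt(3 / (2 * 1))
  expect_equal(efficacy_futility_prob(prior, psi_star = 0.2,
                                      higher_is_better = FALSE),
               pnorm(0.2, -1, sd0, lower.tail = FALSE), tolerance = 1e-12)
  # mu_hat at the threshold gives one half either way
  at <- efficacy_posterior(mu0 = 0.2)
  expect_equal(efficacy_futility_prob(at, 0.2, TRUE), 0.5)
  expect_equal(efficacy_futility_prob(at, 0.2, FALSE), 0.5)
  # far-off means saturate
  hi <- update_efficacy(efficacy_posterior(0), rep(50, 20))
  expect_gt(efficacy_futility_prob(hi, 0.2, FALSE), 0.999)
  expect_lt(efficacy_futility_prob(hi, 0.2, TRUE), 0.001)
})
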