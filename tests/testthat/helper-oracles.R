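# Independent oracles used to cross-check the implementation.

# Direct term-by-term evaluation of the trade-off criterion.
oracle_delta <- function(th1, th2, g1, g2) {
  g1^2 / th1 + g2^2 / th2 + (1 - g1 - g2)^2 / (1 - th1 - th2) - 1
}

# Brute-force Normal-inverse-Gamma posterior by 2-d grid integration
# over (mu, sigma^2): returns the posterior mean of mu.
oracle_nig_mean <- function(x, mu0, lambda, zeta, zeta_prime,
                            mu_lim = c(-60, 60), s2_lim = c(1e-4, 400),
                            n_mu = 2000, n_s2 = 500) {
  mu <- seq(mu_lim[1], mu_lim[2], length.out = n_mu)
  s2 <- exp(seq(log(s2_lim[1]), log(s2_lim[2]), length.out = n_s2))
  lp <- outer(mu, s2, function(m, v) {
    # NIG prior density x normal likelihood, log scale
    dnorm(m, mu0, sqrt(v / lambda), log = TRUE) +
      (-(zeta + 1) * log(v) - zeta_prime / v) +
      vapply(seq_along(m), function(i)
        sum(dnorm(x, m[i], sqrt(v[i]), log = TRUE)), numeric(1))
  })
  w <- exp(lp - max(lp))
  # trapezoid weights (log-spaced in sigma^2)
  ds2 <- c(diff(s2), 0) + c(0, diff(s2))
  w <- sweep(w, 2, ds2 / 2, `*`)
  sum(mu * rowSums(w)) / sum(w)
}

# Upper tail of a Beta density by numerical integration.
oracle_beta_tail <- function(shape1, shape2, phi) {
  stats::integrate(function(p) stats::dbeta(p, shape1, shape2),
                   lower = phi, upper = 1, rel.tol = 1e-10)$value
}

# A tiny deterministic oracle for engine tests: fixed per-regimen
# toxicity pattern and constant efficacy values.
fixed_oracle <- function(tox_by_regimen, eff_by_regimen) {
  function(j, n) list(tox = rep_len(tox_by_regimen[[j]], n),
                      eff = rep_len(eff_by_regimen[[j]], n))
}
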