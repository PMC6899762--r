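#' Beta posterior for a regimen's toxicity probability
#'
#' The toxicity probability of a regimen carries a Beta prior
#' parametrised by its prior mean mass `nu` and total prior strength
#' `strength` (in pseudo-observations), i.e. Beta(`nu`,
#' `strength - nu`) with prior mean `nu / strength`. After `t`
#' toxicities in `n` patients the posterior is
#' Beta(`nu + t`, `(strength - nu) + (n - t)`) with mean
#' `(t + nu) / (n + strength)`.
#'
#' @param nu Prior toxicity mass, `0 < nu < strength`.
#' @param strength Total prior mass (pseudo-observations), default 1.
#' @param t,n Accumulated toxicity count and evaluated patients.
#' @return An object of class `we_tox_post`.
#' @examples
#' toxicity_posterior(nu = 0.10)            # prior mean 0.10
#' update_toxicity(toxicity_posterior(0.10), new_tox = 1, new_n = 3)
#' @export
toxicity_posterior <- function(nu, strength = 1, t = 0, n = 0) {
  if (nu <= 0 || nu >= strength)
    stop("need 0 < nu < strength")
  if (t < 0 || n < 0 || t > n)
    stop("need 0 <= t <= n")
  structure(list(nu = nu, strength = strength, t = t, n = n),
            class = "we_tox_post")
}

#' Accumulate toxicity data into a Beta posterior
#'
#' @param post A [toxicity_posterior()] object.
#' @param new_tox,new_n New toxicity count and patient count,
#'   `0 <= new_tox <= new_n`.
#' @return The updated `we_tox_post`. Sequential updates are exactly
#'   equivalent to a single batch update (conjugacy additivity).
#' @export
update_toxicity <- function(post, new_tox, new_n) {
  stopifnot(inherits(post, "we_tox_post"))
  if (new_tox < 0 || new_n < 0 || new_tox > new_n)
    stop("need 0 <= new_tox <= new_n")
  post$t <- post$t + new_tox
  post$n <- post$n + new_n
  post
}

#' @export
mean.we_tox_post <- function(x, ...) (x$t + x$nu) / (x$n + x$strength)

tox_shapes <- function(post) {
  c(post$nu + post$t, (post$strength - post$nu) + (post$n - post$t))
}

#' Posterior probability that toxicity exceeds the safety bound
#'
#' Upper-tail mass of the Beta posterior above `phi`, the quantity the
#' safety constraint compares against the controlling probability
#' schedule: a regimen is declared unsafe when this tail reaches the
#' schedule value.
#'
#' @param post A [toxicity_posterior()] object.
#' @param phi Upper toxicity bound in (0, 1), e.g. 0.3.
#' @return The posterior probability `P(p_t > phi)`.
#' @examples
#' toxicity_exceedance(toxicity_posterior(0.5, 1), 0.3)  # Beta(0.5, 0.5) tail
#' @export
toxicity_exceedance <- function(post, phi) {
  stopifnot(inherits(post, "we_tox_post"))
  if (phi <= 0 || phi >= 1) stop("`phi` must lie in (0, 1)")
  sh <- tox_shapes(post)
  stats::pbeta(phi, sh[1], sh[2], lower.tail = FALSE)
}

#' Normal-inverse-Gamma posterior for a regimen's mean efficacy
#'
#' The continuous efficacy endpoint is modelled as Normal(`mu`,
#' `sigma^2`) with a conjugate Normal-inverse-Gamma prior on
#' `(mu, sigma^2)`: `mu0` is the prior mean, `lambda` its strength in
#' pseudo-observations, `zeta` the inverse-Gamma shape and `zeta_prime`
#' the rate (prior sum of squared deviations). Data enter through the
#' sufficient statistics only, so sequential and batch updating agree
#' exactly. The posterior mean of `mu` is the convex combination
#' `(lambda * mu0 + sum(x)) / (lambda + n)`.
#'
#' @param mu0 Prior mean of the efficacy outcome.
#' @param lambda Prior mean strength (> 0 pseudo-observations).
#' @param zeta Prior shape strength (> 0).
#' @param zeta_prime Prior sum-of-squares / rate (> 0).
#' @param n,sum_x,sum_x2 Accumulated observation count and sufficient
#'   statistics.
#' @return An object of class `we_eff_post`.
#' @examples
#' efficacy_posterior(mu0 = -1)
#' update_efficacy(efficacy_posterior(mu0 = -1), c(0, -2))
#' @export
efficacy_posterior <- function(mu0, lambda = 1, zeta = 2, zeta_prime = 3,
                               n = 0, sum_x = 0, sum_x2 = 0) {
  if (lambda <= 0 || zeta <= 0 || zeta_prime <= 0)
    stop("need lambda, zeta, zeta_prime > 0")
  structure(list(mu0 = mu0, lambda = lambda, zeta = zeta,
                 zeta_prime = zeta_prime,
                 n = n, sum_x = sum_x, sum_x2 = sum_x2),
            class = "we_eff_post")
}

#' Accumulate efficacy observations into the posterior
#'
#' @param post An [efficacy_posterior()] object.
#' @param x Numeric vector of new observations (may be empty; `NA`
#'   values are not allowed -- drop missing outcomes before updating).
#' @return The updated `we_eff_post`.
#' @export
update_efficacy <- function(post, x) {
  stopifnot(inherits(post, "we_eff_post"))
  if (length(x) == 0L) return(post)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("efficacy observations must be finite numbers")
  post$n <- post$n + length(x)
  post$sum_x <- post$sum_x + sum(x)
  post$sum_x2 <- post$sum_x2 + sum(x^2)
  post
}

# Posterior hyperparameters (mean, lambda_n, shape_n, rate_n) of the
# Normal-inverse-Gamma update, computed from the sufficient statistics.
eff_hyper <- function(post) {
  n <- post$n
  lambda_n <- post$lambda + n
  mu_hat <- (post$lambda * post$mu0 + post$sum_x) / lambda_n
  shape_n <- post$zeta + n / 2
  if (n > 0) {
    xbar <- post$sum_x / n
    ss <- max(post$sum_x2 - n * xbar^2, 0)
    rate_n <- post$zeta_prime + ss / 2 +
      n * post$lambda * (xbar - post$mu0)^2 / (2 * lambda_n)
  } else {
    rate_n <- post$zeta_prime
  }
  list(mu = mu_hat, lambda = lambda_n, shape = shape_n, rate = rate_n)
}

#' @export
mean.we_eff_post <- function(x, ...) eff_hyper(x)$mu

#' Marginal posterior variance of the mean efficacy
#'
#' The normal-approximation variance used by the futility constraint:
#' `rate_n / (shape_n * lambda_n)` in terms of the posterior
#' Normal-inverse-Gamma hyperparameters.
#'
#' @param post An [efficacy_posterior()] object.
#' @return A positive scalar variance.
#' @export
efficacy_mean_variance <- function(post) {
  h <- eff_hyper(post)
  h$rate / (h$shape * h$lambda)
}

#' Posterior probability that a regimen is futile
#'
#' Normal approximation to the posterior of the mean efficacy `mu`,
#' centred at the posterior mean with variance
#' [efficacy_mean_variance()]. When higher outcome values are better the
#' futility mass is `P(mu < psi_star)`; when lower values are better
#' (e.g. a change in log tumour-marker level, where decreases indicate
#' response) it is `P(mu > psi_star)`. A regimen is declared futile when
#' this mass reaches the futility controlling-probability schedule.
#'
#' @param post An [efficacy_posterior()] object.
#' @param psi_star Futility threshold on the original outcome scale.
#' @param higher_is_better Direction of clinical benefit.
#' @return The posterior futility probability.
#' @examples
#' efficacy_futility_prob(efficacy_posterior(mu0 = -1), psi_star = 0.2,
#'                        higher_is_better = FALSE)
#' @export
efficacy_futility_prob <- function(post, psi_star, higher_is_better = FALSE) {
  h <- eff_hyper(post)
  v <- h$rate / (h$shape * h$lambda)
  if (v <= 0) stop("non-positive posterior variance")
  stats::pnorm(psi_star, mean = h$mu, sd = sqrt(v),
               lower.tail = higher_is_better)
}
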