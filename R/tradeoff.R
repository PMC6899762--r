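#' Target toxicity-efficacy profile
#'
#' Builds the target outcome profile of the trade-off criterion from the
#' marginal target toxicity probability `gamma_t` and target efficacy
#' probability `gamma_e`. Under the working independence assumption the
#' three trinomial outcome targets are `gamma1 = (1 - gamma_t) * gamma_e`
#' ("efficacy, no toxicity"), `gamma2 = (1 - gamma_t) * (1 - gamma_e)`
#' ("no efficacy, no toxicity") and `gamma3 = gamma_t` ("toxicity").
#'
#' @param gamma_t Target toxicity probability, strictly in (0, 1).
#'   The default 0.01 encodes "very low toxicity risk".
#' @param gamma_e Target efficacy probability on the transformed (0, 1)
#'   scale. The default 0.99 encodes "as efficacious as possible".
#' @return An object of class `we_target` with fields `gamma_t`,
#'   `gamma_e`, `gamma1`, `gamma2`, `gamma3`.
#' @examples
#' target_profile()               # the default best-possible target
#' target_profile(0.2, 0.5)
#' @export
target_profile <- function(gamma_t = 0.01, gamma_e = 0.99) {
  if (!is.numeric(gamma_t) || length(gamma_t) != 1L ||
      gamma_t <= 0 || gamma_t >= 1)
    stop("`gamma_t` must be a single probability strictly in (0, 1)")
  if (!is.numeric(gamma_e) || length(gamma_e) != 1L ||
      gamma_e <= 0 || gamma_e >= 1)
    stop("`gamma_e` must be a single probability strictly in (0, 1)")
  structure(list(
    gamma_t = gamma_t,
    gamma_e = gamma_e,
    gamma1  = (1 - gamma_t) * gamma_e,
    gamma2  = (1 - gamma_t) * (1 - gamma_e),
    gamma3  = gamma_t
  ), class = "we_target")
}

#' @export
print.we_target <- function(x, ...) {
  cat("Target profile: gamma_t =", x$gamma_t, ", gamma_e =", x$gamma_e, "\n")
  cat("  trinomial targets:", signif(c(x$gamma1, x$gamma2, x$gamma3), 5), "\n")
  invisible(x)
}

#' Trade-off criterion on the trinomial outcome scale
#'
#' Scores the distance of a regimen's outcome probability triple
#' `theta = (theta1, theta2, theta3)` -- "efficacy and no toxicity",
#' "no efficacy and no toxicity", "toxicity" -- from the target profile:
#'
#' \deqn{\delta(\theta,\gamma) = \frac{\gamma_1^2}{\theta_1} +
#'   \frac{\gamma_2^2}{\theta_2} +
#'   \frac{(1-\gamma_1-\gamma_2)^2}{1-\theta_1-\theta_2} - 1.}
#'
#' The criterion is non-negative, equals zero exactly at
#' `theta == gamma`, and diverges as any component of `theta`
#' approaches zero, which penalises inefficacious, overly toxic and
#' zero-toxicity (underdosing) regimens alike. Optional weights
#' `(omega1, omega2)` raise the first two terms, and the third term by
#' the implied `3 - omega1 - omega2`; the default `c(1, 1)` gives the
#' unweighted criterion.
#'
#' @param theta Numeric triple of outcome probabilities, all strictly
#'   positive, summing to 1 (to numerical tolerance).
#' @param target A [target_profile()] object.
#' @param weights Numeric pair `(omega1, omega2)`, each in `[0, 1]`.
#' @return A single non-negative number (non-negativity is guaranteed
#'   for the unweighted criterion).
#' @examples
#' tg <- target_profile(0.01, 0.99)
#' trade_off_outcome(c(tg$gamma1, tg$gamma2, tg$gamma3), tg)  # 0
#' trade_off_outcome(c(0.4, 0.4, 0.2), tg)
#' @seealso [trade_off_marginal()] for the (p_t, p_e) parametrisation.
#' @export
trade_off_outcome <- function(theta, target, weights = c(1, 1)) {
  if (length(theta) != 3L || !is.numeric(theta))
    stop("`theta` must be a numeric triple")
  if (any(theta <= 0))
    stop("degenerate regimen profile: all components of `theta` must be > 0")
  if (abs(sum(theta) - 1) > 1e-8)
    stop("`theta` must sum to 1")
  stopifnot(inherits(target, "we_target"))
  check_weights(weights)
  g <- c(target$gamma1, target$gamma2, 1 - target$gamma1 - target$gamma2)
  th <- c(theta[1], theta[2], 1 - theta[1] - theta[2])
  w <- c(weights[1], weights[2], 3 - sum(weights))
  sum((g^2 / th)^w) - 1
}

check_weights <- function(weights) {
  if (length(weights) != 2L || !is.numeric(weights) ||
      any(weights < 0) || any(weights > 1))
    stop("`weights` must be two numbers in [0, 1]")
  invisible(weights)
}

#' Trade-off criterion on the marginal (toxicity, efficacy) scale
#'
#' Evaluates the trade-off criterion for a regimen with marginal toxicity
#' probability `p_t` and efficacy probability `p_e` (the continuous
#' endpoint after transformation to (0, 1)). Under independence the
#' trinomial mapping is `theta1 = (1 - p_t) * p_e`,
#' `theta2 = (1 - p_t) * (1 - p_e)`, `theta3 = p_t`, and the result
#' equals [trade_off_outcome()] applied to that triple. Vectorised over
#' `p_t` and `p_e`.
#'
#' @param p_t Toxicity probability (vector), strictly in (0, 1).
#' @param p_e Efficacy probability (vector), strictly in (0, 1).
#' @inheritParams trade_off_outcome
#' @return Non-negative numeric vector of criterion values.
#' @examples
#' tg <- target_profile()
#' trade_off_marginal(tg$gamma_t, tg$gamma_e, tg)  # 0 at the target
#' trade_off_marginal(0.2, 0.5, tg)
#' @export
trade_off_marginal <- function(p_t, p_e, target, weights = c(1, 1)) {
  if (any(p_t <= 0 | p_t >= 1))
    stop("`p_t` must lie strictly in (0, 1)")
  if (any(p_e <= 0 | p_e >= 1))
    stop("`p_e` must lie strictly in (0, 1)")
  stopifnot(inherits(target, "we_target"))
  check_weights(weights)
  g <- c(target$gamma1, target$gamma2, 1 - target$gamma1 - target$gamma2)
  w <- c(weights[1], weights[2], 3 - sum(weights))
  th1 <- (1 - p_t) * p_e
  th2 <- (1 - p_t) * (1 - p_e)
  (g[1]^2 / th1)^w[1] + (g[2]^2 / th2)^w[2] + (g[3]^2 / p_t)^w[3] - 1
}

#' Rank regimens by the trade-off criterion
#'
#' Orders the admissible regimens by ascending criterion value (smaller
#' is closer to the target). Ties are broken by the lower estimated
#' toxicity, then by the lower regimen index, giving a deterministic and
#' conservative ordering.
#'
#' @param delta Numeric vector of criterion values, one per regimen.
#' @param admissible Logical mask of the same length; inadmissible
#'   regimens are dropped.
#' @param tox Optional numeric vector of estimated toxicity
#'   probabilities used for tie-breaking (defaults to zeros, i.e. index
#'   tie-break only).
#' @return Integer vector of regimen indices, best first. An empty
#'   integer vector signals "no recommendation".
#' @examples
#' rank_regimens(c(3, 1, 2))                       # 2 3 1
#' rank_regimens(c(1, 1), tox = c(0.3, 0.1))       # 2 1
#' rank_regimens(c(1, 2), admissible = c(FALSE, FALSE))  # integer(0)
#' @export
rank_regimens <- function(delta, admissible = rep(TRUE, length(delta)),
                          tox = rep(0, length(delta))) {
  stopifnot(length(admissible) == length(delta),
            length(tox) == length(delta))
  idx <- which(admissible)
  if (length(idx) == 0L) return(integer(0))
  idx[order(delta[idx], tox[idx], idx)]
}
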