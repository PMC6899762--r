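#' Design configuration for the WE dose-finding trial
#'
#' Assembles every tuning constant of the design: the regimen layout
#' (single-agent dose ladder or a dual-agent combination grid ordered by
#' the product partial order on doses), the sample-size and cohort
#' settings, the target profile and endpoint transformation, per-regimen
#' conjugate prior parameters, and the safety/futility
#' controlling-probability schedules. Defaults reproduce the design
#' specification calibrated for the squamous-cell-carcinoma (SCCA)
#' setting: change in log SCCA level as efficacy endpoint (lower is
#' better), `phi = 0.3`, `psi_star = 0.20`, transformation anchors
#' `psi = 0`, `psi_prime = -4.5`, target `(gamma_t, gamma_e) =
#' (0.01, 0.99)`, cohort size 3, `N = 36` (single agent, 4 doses) or
#' `N = 72` (4 x 2 combination grid), calibrated linear prior-mean
#' ladders, and schedules `eta1(n) = max(0.95 - 0.02 n, 0.6)`,
#' `eta2(n) = max(0.8 - 0.02 n, 0.3)`.
#'
#' @param layout `"single"` (4 dose levels of one agent) or
#'   `"combination"` (4 doses of agent A crossed with 2 of agent B).
#' @param N Maximum number of patients (default 36 single / 72
#'   combination).
#' @param cohort_size Patients per cohort (default 3).
#' @param phi Upper toxicity bound.
#' @param psi_star Futility threshold on the original outcome scale.
#' @param gamma_t,gamma_e Target toxicity and (transformed) efficacy
#'   probabilities.
#' @param transform A [transform_spec()]; default is the SCCA logistic
#'   transformation.
#' @param prior_tox_mean Per-regimen prior toxicity means (default: the
#'   calibrated ladder 0.10 + 0.04 (j-1) along agent A, shifted by one
#'   step for the second level of agent B).
#' @param prior_tox_strength Total Beta prior mass per regimen
#'   (default 1).
#' @param prior_eff_mean Per-regimen prior efficacy means (default:
#'   -1.00 - 0.025 (j-1) along agent A, shifted likewise).
#' @param prior_eff_lambda Prior mean strength of the efficacy prior
#'   (default 1).
#' @param prior_zeta,prior_zeta_prime Shape and rate of the
#'   inverse-Gamma component (defaults 2 and 3; these affect the
#'   futility constraint only).
#' @param r_t,r_e Linear tightening rates of the safety and futility
#'   schedules.
#' @param eta1_0,eta1_bar Initial and final controlling probabilities of
#'   the safety schedule.
#' @param eta2_0,eta2_bar Initial and final controlling probabilities of
#'   the futility schedule.
#' @param lower_is_better Direction of the continuous endpoint (TRUE for
#'   the SCCA change where decreases indicate response).
#' @param weights Trade-off criterion weights, see [trade_off_outcome()].
#' @param use_constraints Enable the safety/futility constraints
#'   (disabled during prior calibration).
#' @param start_regimen Index of the mandatory first cohort's regimen
#'   (must be minimal in the toxicity ordering; default 1).
#' @return An object of class `we_design`.
#' @examples
#' we_design()                   # single-agent SCCA defaults
#' we_design("combination")
#' @export
we_design <- function(layout = c("single", "combination"),
                      N = NULL, cohort_size = 3,
                      phi = 0.3, psi_star = 0.20,
                      gamma_t = 0.01, gamma_e = 0.99,
                      transform = transform_spec(),
                      prior_tox_mean = NULL, prior_tox_strength = 1,
                      prior_eff_mean = NULL, prior_eff_lambda = 1,
                      prior_zeta = 2, prior_zeta_prime = 3,
                      r_t = 0.02, r_e = 0.02,
                      eta1_0 = 0.95, eta1_bar = 0.6,
                      eta2_0 = 0.8, eta2_bar = 0.3,
                      lower_is_better = TRUE,
                      weights = c(1, 1),
                      use_constraints = TRUE,
                      start_regimen = 1L) {
  layout <- match.arg(layout)
  if (layout == "single") {
    dose_a <- 1:4
    dose_b <- rep(1L, 4)
    if (is.null(N)) N <- 36
  } else {
    dose_a <- rep(1:4, times = 2)
    dose_b <- rep(1:2, each = 4)
    if (is.null(N)) N <- 72
  }
  m <- length(dose_a)
  label <- if (layout == "single") paste0("dA", dose_a)
           else paste0("(dA", dose_a, ",dB", dose_b, ")")

  # calibrated linear prior-mean ladders; the combination grid shifts
  # the ladder by one step for the second level of agent B
  step_idx <- (dose_a - 1) + (dose_b - 1)
  if (is.null(prior_tox_mean)) prior_tox_mean <- 0.10 + 0.04 * step_idx
  if (is.null(prior_eff_mean)) prior_eff_mean <- -1.00 - 0.025 * step_idx

  prior_tox_mean <- rep_len(prior_tox_mean, m)
  prior_tox_strength <- rep_len(prior_tox_strength, m)
  prior_eff_mean <- rep_len(prior_eff_mean, m)
  prior_eff_lambda <- rep_len(prior_eff_lambda, m)
  prior_zeta <- rep_len(prior_zeta, m)
  prior_zeta_prime <- rep_len(prior_zeta_prime, m)

  if (any(prior_tox_mean <= 0 | prior_tox_mean >= prior_tox_strength))
    stop("prior toxicity means must satisfy 0 < mean < strength")
  if (N %% cohort_size != 0)
    stop("`N` must be a multiple of `cohort_size`")
  if (phi <= 0 || phi >= 1) stop("`phi` must lie in (0, 1)")
  stopifnot(inherits(transform, "we_transform"))
  check_weights(weights)

  # known toxicity partial order: (a, b) <= (a', b') iff a <= a', b <= b'
  above <- lapply(seq_len(m), function(j)
    which((dose_a >= dose_a[j] & dose_b >= dose_b[j]) & seq_len(m) != j &
            (dose_a > dose_a[j] | dose_b > dose_b[j])))
  predecessors <- lapply(seq_len(m), function(j)
    which((dose_a == dose_a[j] - 1 & dose_b == dose_b[j]) |
          (dose_a == dose_a[j] & dose_b == dose_b[j] - 1)))
  if (length(predecessors[[start_regimen]]) != 0L)
    stop("`start_regimen` must be minimal in the toxicity ordering")

  structure(list(
    layout = layout, m = m, dose_a = dose_a, dose_b = dose_b,
    label = label, N = N, cohort_size = cohort_size,
    phi = phi, psi_star = psi_star,
    target = target_profile(gamma_t, gamma_e),
    transform = transform,
    prior = list(nu = prior_tox_mean * prior_tox_strength,
                 strength = prior_tox_strength,
                 mu0 = prior_eff_mean, lambda = prior_eff_lambda,
                 zeta = prior_zeta, zeta_prime = prior_zeta_prime),
    r_t = r_t, r_e = r_e,
    eta1_0 = eta1_0, eta1_bar = eta1_bar,
    eta2_0 = eta2_0, eta2_bar = eta2_bar,
    lower_is_better = lower_is_better,
    weights = weights,
    use_constraints = use_constraints,
    start_regimen = as.integer(start_regimen),
    above = above, predecessors = predecessors
  ), class = "we_design")
}

#' @export
print.we_design <- function(x, ...) {
  cat(sprintf("WE design: %s layout, %d regimens, N = %d, cohorts of %d\n",
              x$layout, x$m, x$N, x$cohort_size))
  cat(sprintf("  phi = %g, psi* = %g, target (%g, %g), constraints %s\n",
              x$phi, x$psi_star, x$target$gamma_t, x$target$gamma_e,
              if (x$use_constraints) "on" else "off"))
  cat("  prior toxicity means:", signif(x$prior$nu / x$prior$strength, 3), "\n")
  cat("  prior efficacy means:", x$prior$mu0, "\n")
  invisible(x)
}

#' Controlling-probability schedule
#'
#' Linear tightening of a controlling probability with the per-regimen
#' sample size: `max(eta0 - rate * n, eta_bar)`. The value at `n = 0` is
#' the lenient pre-data threshold; `eta_bar` is the strict floor applied
#' at the final recommendation.
#'
#' @param n Per-regimen number of patients (vectorised).
#' @param eta0 Controlling probability before any data.
#' @param rate Linear tightening rate per patient.
#' @param eta_bar Final (floor) controlling probability.
#' @return Numeric vector of schedule values.
#' @examples
#' eta_schedule(c(0, 5, 20), 0.95, 0.02, 0.6)  # 0.95 0.85 0.60
#' @export
eta_schedule <- function(n, eta0, rate, eta_bar) {
  if (any(n < 0)) stop("`n` must be non-negative")
  pmax(eta0 - rate * n, eta_bar)
}

#' Per-regimen accumulated trial state
#'
#' Flat sufficient-statistic representation of all regimens' posteriors
#' plus the absorbing unsafe/futile flags. Toxicity counts and efficacy
#' statistics are kept separately because the number of efficacy
#' observations may lag the number of treated patients under delayed or
#' missing observation models.
#'
#' @param config A [we_design()] object.
#' @param records Optional data frame of accumulated patient records
#'   with columns `regimen` (index), `toxicity` (0/1) and `efficacy`
#'   (numeric, `NA` when unobserved).
#' @return An object of class `we_state`: lists of per-regimen vectors
#'   `t`, `n`, `eff_n`, `eff_sx`, `eff_sx2` and logical flags `unsafe`,
#'   `futile`.
#' @examples
#' trial_state(we_design())
#' @export
trial_state <- function(config, records = NULL) {
  stopifnot(inherits(config, "we_design"))
  m <- config$m
  st <- structure(list(
    t = numeric(m), n = numeric(m),
    eff_n = numeric(m), eff_sx = numeric(m), eff_sx2 = numeric(m),
    unsafe = logical(m), futile = logical(m),
    blocked_above = integer(0)
  ), class = "we_state")
  if (!is.null(records)) {
    req <- c("regimen", "toxicity", "efficacy")
    if (!all(req %in% names(records)))
      stop("records need columns: ", paste(req, collapse = ", "))
    j <- as.integer(records$regimen)
    if (any(j < 1 | j > m)) stop("regimen index out of range")
    if (any(!records$toxicity %in% c(0, 1)))
      stop("`toxicity` must be 0 or 1")
    for (k in seq_len(nrow(records))) {
      st$t[j[k]] <- st$t[j[k]] + records$toxicity[k]
      st$n[j[k]] <- st$n[j[k]] + 1
      if (!is.na(records$efficacy[k])) {
        st$eff_n[j[k]] <- st$eff_n[j[k]] + 1
        st$eff_sx[j[k]] <- st$eff_sx[j[k]] + records$efficacy[k]
        st$eff_sx2[j[k]] <- st$eff_sx2[j[k]] + records$efficacy[k]^2
      }
    }
  }
  st
}

# Vectorised posterior summaries over all regimens.
state_posterior <- function(state, config) {
  pr <- config$prior
  p_hat <- (state$t + pr$nu) / (state$n + pr$strength)
  lam_n <- pr$lambda + state$eff_n
  mu_hat <- (pr$lambda * pr$mu0 + state$eff_sx) / lam_n
  shape_n <- pr$zeta + state$eff_n / 2
  xbar <- state$eff_sx / pmax(state$eff_n, 1)   # 0 when eff_n = 0
  ss <- pmax(state$eff_sx2 - state$eff_n * xbar^2, 0)
  extra <- state$eff_n * pr$lambda * (xbar - pr$mu0)^2 / (2 * lam_n)
  rate_n <- pr$zeta_prime + ss / 2 + extra
  var_mu <- rate_n / (shape_n * lam_n)
  sh1 <- pr$nu + state$t
  sh2 <- (pr$strength - pr$nu) + (state$n - state$t)
  safety_tail <- stats::pbeta(config$phi, sh1, sh2, lower.tail = FALSE)
  fut_prob <- stats::pnorm(config$psi_star, mean = mu_hat,
                           sd = sqrt(var_mu),
                           lower.tail = !config$lower_is_better)
  list(p_hat = p_hat, mu_hat = mu_hat, var_mu = var_mu,
       safety_tail = safety_tail, fut_prob = fut_prob)
}

# Update the absorbing unsafe/futile flags at given schedule thresholds
# and propagate unsafety upward along the known toxicity partial order.
update_flags <- function(state, config, eta1, eta2, post = NULL) {
  if (!config$use_constraints) return(state)
  if (is.null(post)) post <- state_posterior(state, config)
  state$unsafe <- state$unsafe | (post$safety_tail >= eta1)
  state$futile <- state$futile | (post$fut_prob >= eta2)
  for (k in which(state$unsafe))
    state$unsafe[config$above[[k]]] <- TRUE
  state
}

#' Admissible regimens under the safety and futility constraints
#'
#' Evaluates the time-varying constraints at the current per-regimen
#' sample sizes: regimen `j` is unsafe when its posterior probability of
#' exceeding the toxicity bound reaches `eta1(n_j)`, and futile when its
#' posterior futility mass reaches `eta2(n_j)`. Unsafety propagates
#' upward along the known toxicity partial order (regimens above an
#' unsafe one are unsafe as well); futility does not propagate, since no
#' efficacy ordering is assumed. Both flags are absorbing.
#'
#' @param state A [trial_state()] object.
#' @param config A [we_design()] object.
#' @return A list with the updated `state` (flags set) and the logical
#'   `admissible` mask.
#' @examples
#' st <- trial_state(we_design())
#' admissible_regimens(st, we_design())$admissible   # all TRUE at priors
#' @export
admissible_regimens <- function(state, config) {
  stopifnot(inherits(state, "we_state"), inherits(config, "we_design"))
  eta1 <- eta_schedule(state$n, config$eta1_0, config$r_t, config$eta1_bar)
  eta2 <- eta_schedule(state$n, config$eta2_0, config$r_e, config$eta2_bar)
  state <- update_flags(state, config, eta1, eta2)
  list(state = state, admissible = !(state$unsafe | state$futile))
}

#' Plug-in trade-off estimates for all regimens
#'
#' Evaluates the trade-off criterion at the posterior toxicity mean
#' `(t + nu) / (n + strength)` and the transformed posterior efficacy
#' mean `T(mu_hat)`. Posterior probabilities are clamped away from 0 and
#' 1 by a 1e-12 guard before division so finite-sample extremes cannot
#' produce spurious infinities.
#'
#' @inheritParams admissible_regimens
#' @return Numeric vector of per-regimen criterion values.
#' @examples
#' plug_in_delta(trial_state(we_design()), we_design())  # prior deltas
#' @export
plug_in_delta <- function(state, config) {
  stopifnot(inherits(state, "we_state"), inherits(config, "we_design"))
  post <- state_posterior(state, config)
  delta_from_post(post, config)
}

delta_from_post <- function(post, config) {
  eps <- 1e-12
  p_t <- pmin(pmax(post$p_hat, eps), 1 - eps)
  p_e <- pmin(pmax(transform_value(post$mu_hat, config$transform), eps),
              1 - eps)
  tg <- config$target
  w <- config$weights
  g3 <- 1 - tg$gamma1 - tg$gamma2
  (tg$gamma1^2 / ((1 - p_t) * p_e))^w[1] +
    (tg$gamma2^2 / ((1 - p_t) * (1 - p_e)))^w[2] +
    (g3^2 / p_t)^(3 - w[1] - w[2]) - 1
}

# Coherence filter: (a) an untried regimen is reachable only when all
# its immediate predecessors in the toxicity ordering have been tried;
# (b) no regimen strictly above a regimen whose last-cohort observed
# toxicity fraction reached phi may receive the next cohort.
coherence_filter <- function(cand, state, config) {
  for (j in which(cand & state$n == 0)) {
    pred <- config$predecessors[[j]]
    if (length(pred) && any(state$n[pred] == 0)) cand[j] <- FALSE
  }
  for (b in state$blocked_above)
    cand[config$above[[b]]] <- FALSE
  cand
}

#' Adaptive allocation of the next cohort
#'
#' Applies the admissibility and coherence filters, takes the two
#' candidates with the smallest plug-in trade-off values, and randomises
#' each patient of the next cohort between them with probabilities
#' proportional to the reciprocal criterion values (a single remaining
#' candidate receives probability 1; two candidates with criterion
#' numerically zero are split 50/50). The first cohort of a trial is
#' always allocated to the starting regimen.
#'
#' @inheritParams admissible_regimens
#' @param draw Draw the per-patient assignment vector (consumes one RNG
#'   call). With `draw = FALSE` only the candidate set and probabilities
#'   are returned, e.g. for interim decision support.
#' @param n_patients Cohort size to assign (defaults to the design's).
#' @return A list: `assignment` (integer vector of length `n_patients`,
#'   or `NULL` when `draw = FALSE`), `candidates`, `probabilities`,
#'   `delta`, `admissible`, `state` (flags updated), and `terminated`
#'   (TRUE when no candidate remains).
#' @examples
#' st <- trial_state(we_design())
#' allocate_next_cohort(st, we_design(), draw = FALSE)
#' @export
allocate_next_cohort <- function(state, config, draw = TRUE,
                                 n_patients = config$cohort_size) {
  post <- state_posterior(state, config)
  eta1 <- eta_schedule(state$n, config$eta1_0, config$r_t, config$eta1_bar)
  eta2 <- eta_schedule(state$n, config$eta2_0, config$r_e, config$eta2_bar)
  state <- update_flags(state, config, eta1, eta2, post = post)
  admissible <- !(state$unsafe | state$futile)
  out <- list(assignment = NULL, candidates = integer(0),
              probabilities = numeric(0),
              delta = rep(NA_real_, config$m),
              admissible = admissible, state = state,
              terminated = FALSE)
  if (!any(admissible)) {
    out$terminated <- TRUE
    return(out)
  }
  cand <- coherence_filter(admissible, state, config)
  if (!any(cand)) {
    out$terminated <- TRUE
    return(out)
  }
  delta <- delta_from_post(post, config)
  cidx <- which(cand)
  ord <- order(delta[cidx], post$p_hat[cidx], cidx)
  top <- cidx[ord][seq_len(min(2L, length(cidx)))]
  w <- 1 / pmax(delta[top], 1e-12)
  prob <- w / sum(w)
  out$delta <- delta
  out$candidates <- top
  out$probabilities <- prob
  if (draw)
    out$assignment <- if (length(top) == 1L) rep(top, n_patients) else
      top[sample.int(2L, n_patients, replace = TRUE, prob = prob)]
  out
}

#' Run one WE trial
#'
#' Executes the full sequential design: patients enter in cohorts,
#' starting at the lowest regimen, with posterior updating and
#' admissibility checks between cohorts; each patient of the next
#' cohort is randomised between the two best admissible regimens under
#' the coherence restrictions. The trial stops when `N` patients have
#' been treated or no admissible regimen remains. The final
#' recommendation is the tried regimen minimising the plug-in trade-off
#' among those passing the final safety (`eta1_bar`) and futility
#' (`eta2_bar`) checks and whose posterior toxicity estimate lies below
#' the bound `phi` (the recommended regimen must itself satisfy the
#' estimated optimal-biological-regimen definition); if none passes, the
#' trial result is early termination.
#'
#' Under the delayed observation model a cohort's efficacy outcomes
#' become available one decision cycle after its toxicity outcomes;
#' under the missing model, efficacy is never observed for patients with
#' a toxicity. All pending (delayed) efficacy outcomes are observed by
#' the final analysis; missing ones are not.
#'
#' @param config A [we_design()] object.
#' @param oracle Outcome generator: `function(regimen, n)` returning
#'   `list(tox = 0/1 vector, eff = numeric vector)` for `n` patients,
#'   e.g. [scenario_oracle()].
#' @param model An [observation_model()].
#' @param seed Optional integer seed (sets the RNG for the whole trial;
#'   per decision, the assignment vector is drawn first and outcomes are
#'   then drawn regimen-by-regimen in ascending index order, so a trial
#'   replays exactly under the same seed).
#' @param log Keep a per-decision log (assignments, candidate set,
#'   probabilities, criterion values, flags) for replay and audit.
#' @return An object of class `we_trial`: `recommendation` (index or
#'   `NA`), `terminated`, `n_per_regimen`, `tox_per_regimen`,
#'   `total_toxicity`, `efficacy_values` (all generated outcomes of
#'   treated patients, including any hidden by the observation model),
#'   `cohorts` (per-cohort assignment counts) and optionally `log`.
#' @examples
#' sc <- builtin_scenarios()[[1]]
#' run_trial(we_design(), scenario_oracle(sc), seed = 1)
#' @export
run_trial <- function(config, oracle, model = observation_model(),
                      seed = NULL, log = FALSE) {
  stopifnot(inherits(config, "we_design"), is.function(oracle),
            inherits(model, "we_obsmodel"))
  if (!is.null(seed)) set.seed(seed)
  m <- config$m
  n_cohorts <- config$N %/% config$cohort_size
  state <- trial_state(config)
  coh_eff <- vector("list", n_cohorts)   # observable efficacy per cohort
  coh_eff_reg <- vector("list", n_cohorts)
  coh_assign <- vector("list", n_cohorts)
  eff_released <- 0L
  all_eff <- numeric(0)
  dlog <- if (log) vector("list", n_cohorts) else NULL
  treated <- 0L
  terminated_early <- FALSE

  release_eff <- function(state, upto) {
    while (eff_released < upto) {
      i <- eff_released + 1L
      x <- coh_eff[[i]]
      jj <- coh_eff_reg[[i]]
      for (j in unique(jj)) {
        xs <- x[jj == j]
        state$eff_n[j] <- state$eff_n[j] + length(xs)
        state$eff_sx[j] <- state$eff_sx[j] + sum(xs)
        state$eff_sx2[j] <- state$eff_sx2[j] + sum(xs^2)
      }
      eff_released <<- i
      state
    }
    state
  }

  c_idx <- 0L
  while (c_idx < n_cohorts) {
    c_idx <- c_idx + 1L
    if (c_idx == 1L) {
      jvec <- rep(config$start_regimen, config$cohort_size)
      if (log) dlog[[1L]] <- list(cohort = 1L, assignment = jvec,
                                  candidates = config$start_regimen,
                                  probabilities = 1,
                                  delta = plug_in_delta(state, config),
                                  admissible = rep(TRUE, m),
                                  unsafe = state$unsafe,
                                  futile = state$futile)
    } else {
      # efficacy of cohort c-1 is visible now unless delayed by a cycle
      state <- release_eff(state, c_idx - 1L - as.integer(model$delayed))
      alloc <- allocate_next_cohort(state, config)
      state <- alloc$state
      if (alloc$terminated) {
        terminated_early <- TRUE
        c_idx <- c_idx - 1L
        break
      }
      jvec <- alloc$assignment
      if (log) dlog[[c_idx]] <- list(cohort = c_idx, assignment = jvec,
                                     candidates = alloc$candidates,
                                     probabilities = alloc$probabilities,
                                     delta = alloc$delta,
                                     admissible = alloc$admissible,
                                     unsafe = state$unsafe,
                                     futile = state$futile)
    }
    tox <- numeric(length(jvec))
    eff <- numeric(length(jvec))
    treated_reg <- unique(jvec)   # at most two regimens per cohort
    for (j in sort(treated_reg)) {
      sel <- which(jvec == j)
      out <- oracle(j, length(sel))
      tj <- as.numeric(out$tox)
      ej <- as.numeric(out$eff)
      if (length(tj) != length(sel) || length(ej) != length(sel) ||
          any(tj != 0 & tj != 1) || any(!is.finite(ej)))
        stop("oracle must return 0/1 toxicities and finite efficacies")
      tox[sel] <- tj
      eff[sel] <- ej
      state$t[j] <- state$t[j] + sum(tj)
      state$n[j] <- state$n[j] + length(sel)
    }
    keep <- if (model$missing_on_toxicity) tox == 0 else TRUE
    coh_eff[[c_idx]] <- eff[keep]
    coh_eff_reg[[c_idx]] <- jvec[keep]
    if (log) coh_assign[[c_idx]] <- jvec
    all_eff <- c(all_eff, eff)
    treated <- treated + length(jvec)
    # coherence: excessive observed toxicity at a regimen in this cohort
    # blocks escalation above it at the next decision
    state$blocked_above <-
      treated_reg[vapply(treated_reg, function(j)
        mean(tox[jvec == j]) >= config$phi, logical(1))]
  }

  # final analysis: all pending efficacy has been observed by now
  state <- release_eff(state, c_idx)
  state <- update_flags(state, config,
                        eta1 = config$eta1_bar, eta2 = config$eta2_bar)
  post <- state_posterior(state, config)
  final_adm <- !(state$unsafe | state$futile) & state$n > 0
  if (config$use_constraints)   # recommended regimen must look like an OBR
    final_adm <- final_adm & post$p_hat <= config$phi
  recommendation <- NA_integer_
  if (!terminated_early && any(final_adm)) {
    delta <- delta_from_post(post, config)
    recommendation <- rank_regimens(delta, final_adm, post$p_hat)[1L]
  }
  assign_tab <- if (log)
    t(vapply(coh_assign[seq_len(c_idx)], function(v)
      tabulate(v, nbins = m), integer(m)))
  structure(list(
    recommendation = recommendation,
    terminated = is.na(recommendation),
    n_per_regimen = state$n,
    tox_per_regimen = state$t,
    total_toxicity = sum(state$t),
    n_treated = treated,
    efficacy_values = all_eff,
    cohorts = assign_tab,
    state = state,
    log = if (log) dlog[seq_len(c_idx)] else NULL
  ), class = "we_trial")
}

#' @export
print.we_trial <- function(x, ...) {
  if (x$terminated) cat("WE trial: terminated early, no recommendation\n")
  else cat("WE trial: recommended regimen", x$recommendation, "\n")
  cat("  patients per regimen:", x$n_per_regimen, "\n")
  cat(sprintf("  toxicities: %d / %d treated\n",
              as.integer(x$total_toxicity), x$n_treated))
  invisible(x)
}
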