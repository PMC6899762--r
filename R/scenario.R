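#' Define a simulation scenario
#'
#' A scenario fixes the true generating parameters of a simulated trial:
#' per-regimen toxicity probabilities and mean efficacy outcomes, the
#' common efficacy standard deviation, the latent correlation between
#' the toxicity and efficacy outcomes, and the index of the true optimal
#' biological regimen (OBR), if one exists.
#'
#' @param p_t Per-regimen true toxicity probabilities in (0, 1).
#' @param mu Per-regimen true mean efficacy outcomes.
#' @param sigma Efficacy standard deviation (default 1).
#' @param r Latent-normal correlation between toxicity and efficacy in
#'   (-1, 1); positive `r` couples toxicity with larger outcome values.
#' @param obr Index of the true OBR, or `NA` when no regimen is both
#'   safe and efficacious.
#' @param layout `"single"` or `"combination"` (must match the design).
#' @param label Optional scenario name.
#' @return An object of class `we_scenario`.
#' @examples
#' we_scenario(p_t = c(0.05, 0.5, 0.6, 0.7),
#'             mu = c(-0.5, -0.6, -0.7, -0.8), obr = 1)
#' @export
we_scenario <- function(p_t, mu, sigma = 1, r = 0.2, obr = NA_integer_,
                        layout = c("single", "combination"),
                        label = NULL) {
  layout <- match.arg(layout)
  if (length(p_t) != length(mu))
    stop("`p_t` and `mu` must have equal length")
  if (any(p_t < 0 | p_t >= 1))
    stop("`p_t` must lie in [0, 1)")
  if (sigma <= 0) stop("`sigma` must be positive")
  if (abs(r) >= 1) stop("`r` must lie strictly in (-1, 1)")
  structure(list(p_t = p_t, mu = mu, sigma = sigma, r = r,
                 obr = as.integer(obr), layout = layout,
                 label = label %||% "scenario"),
            class = "we_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.we_scenario <- function(x, ...) {
  cat(sprintf("%s (%s, r = %g): OBR = %s\n", x$label, x$layout, x$r,
              if (is.na(x$obr)) "none" else x$obr))
  print(data.frame(regimen = seq_along(x$p_t), p_t = x$p_t, mu = x$mu))
  invisible(x)
}

#' Built-in simulation scenarios
#'
#' The nine benchmark scenarios of the SCCA setting: six single-agent
#' scenarios over doses dA1-dA4 (N = 36) and three 4 x 2 combination
#' scenarios (N = 72, regimens ordered dB1 row first: (dA1,dB1) ...
#' (dA4,dB1), (dA1,dB2) ... (dA4,dB2)). Efficacy outcomes are
#' Normal(mu_j, 1); the default latent correlation is `r = 0.2`.
#' Scenarios 1-3 have monotonically increasing toxicity and efficacy,
#' scenario 4 and 9 plateau in efficacy, and scenarios 5 (nothing
#' efficacious) and 6 (nothing safe) have no OBR.
#'
#' @param r Latent outcome correlation applied to every scenario.
#' @return A named list of nine [we_scenario()] objects.
#' @examples
#' builtin_scenarios()[["scenario2"]]
#' @export
builtin_scenarios <- function(r = 0.2) {
  single <- function(p_t, mu, obr, lab)
    we_scenario(p_t, mu, r = r, obr = obr, layout = "single", label = lab)
  combo <- function(p_b1, m_b1, p_b2, m_b2, obr, lab)
    we_scenario(c(p_b1, p_b2), c(m_b1, m_b2), r = r, obr = obr,
                layout = "combination", label = lab)
  list(
    scenario1 = single(c(0.01, 0.15, 0.45, 0.65), c(0.5, -0.5, -1.5, -3.0),
                       obr = 2, "scenario1"),
    scenario2 = single(c(0.05, 0.50, 0.60, 0.70), c(-0.5, -0.6, -0.7, -0.8),
                       obr = 1, "scenario2"),
    scenario3 = single(c(0.01, 0.03, 0.05, 0.08), c(0.5, -0.5, -1.5, -3.0),
                       obr = 4, "scenario3"),
    scenario4 = single(c(0.01, 0.10, 0.30, 0.60), c(0.5, -2.0, -2.0, -2.0),
                       obr = 2, "scenario4"),
    scenario5 = single(c(0.01, 0.05, 0.10, 0.15), c(2.0, 2.0, 2.0, 2.0),
                       obr = NA, "scenario5"),
    scenario6 = single(c(0.50, 0.60, 0.70, 0.80), c(0.0, -0.3, -0.7, -1.0),
                       obr = NA, "scenario6"),
    scenario7 = combo(c(0.01, 0.10, 0.40, 0.50), c(0.5, 0.0, -1.5, -2.5),
                      c(0.05, 0.15, 0.45, 0.55), c(-1.5, -2.0, -3.5, -4.5),
                      obr = 6, "scenario7"),     # (dA2, dB2)
    scenario8 = combo(c(0.01, 0.05, 0.15, 0.45), c(0.0, -0.5, -3.5, -5.5),
                      c(0.45, 0.50, 0.60, 0.90), c(-1.0, -1.5, -4.5, -6.5),
                      obr = 3, "scenario8"),     # (dA3, dB1)
    scenario9 = combo(c(0.01, 0.15, 0.40, 0.50), c(0.0, -2.0, -2.0, -2.0),
                      c(0.05, 0.20, 0.45, 0.55), c(0.0, -2.0, -2.0, -2.0),
                      obr = 2, "scenario9")      # (dA2, dB1)
  )
}

#' Draw correlated toxicity/efficacy outcomes for one regimen
#'
#' Latent bivariate-normal construction of a correlated binary toxicity
#' and continuous efficacy pair: draw `(u, v)` standard bivariate normal
#' with correlation `r`, set toxicity to 1 when `pnorm(u) > 1 - p_t`,
#' and set the efficacy outcome to `mu - sigma * v`. Positive `r` thus
#' couples toxicity with *clinical response* -- toxic patients tend to
#' draw lower (better, in the lower-is-better coding) outcome values, as
#' when a more active drug exposure drives both effects. The margins are
#' exactly Bernoulli(`p_t`) and Normal(`mu`, `sigma^2`) for any `r`.
#'
#' @param p_t True toxicity probability of the regimen, in [0, 1).
#' @param mu,sigma True efficacy mean and standard deviation.
#' @param r Latent correlation, strictly in (-1, 1).
#' @param n Number of patients to draw.
#' @return `list(tox = 0/1 integer vector, eff = numeric vector)`.
#' @examples
#' set.seed(1)
#' draw_patient(p_t = 0.3, mu = -1, r = 0.2, n = 5)
#' @export
draw_patient <- function(p_t, mu, sigma = 1, r = 0.2, n = 1) {
  if (abs(r) >= 1) stop("`r` must lie strictly in (-1, 1)")
  if (p_t < 0 || p_t >= 1) stop("`p_t` must lie in [0, 1)")
  u <- stats::rnorm(n)
  v <- r * u + sqrt(1 - r^2) * stats::rnorm(n)
  list(tox = as.integer(stats::pnorm(u) > 1 - p_t),
       eff = mu - sigma * v)
}

#' Outcome oracle for a scenario
#'
#' Wraps [draw_patient()] into the `function(regimen, n)` interface
#' expected by [run_trial()].
#'
#' @param scenario A [we_scenario()] object.
#' @return A function drawing outcomes from the scenario's true
#'   parameters.
#' @export
scenario_oracle <- function(scenario) {
  stopifnot(inherits(scenario, "we_scenario"))
  function(j, n) draw_patient(scenario$p_t[j], scenario$mu[j],
                              scenario$sigma, scenario$r, n)
}

#' Efficacy observation model
#'
#' Controls when efficacy outcomes enter the estimators. `delayed`
#' makes a cohort's efficacy available one decision cycle after its
#' toxicity (the endpoint takes twice as long to evaluate);
#' `missing_on_toxicity` drops the efficacy outcome of any patient with
#' a toxicity (treated off-protocol). Both `FALSE` reproduces the base
#' case where efficacy is observed immediately and regardless of
#' toxicity.
#'
#' @param delayed,missing_on_toxicity Logical flags.
#' @return An object of class `we_obsmodel`.
#' @examples
#' observation_model()                      # base case
#' observation_model(delayed = TRUE, missing_on_toxicity = TRUE)
#' @export
observation_model <- function(delayed = FALSE, missing_on_toxicity = FALSE) {
  stopifnot(is.logical(delayed), is.logical(missing_on_toxicity))
  structure(list(delayed = delayed,
                 missing_on_toxicity = missing_on_toxicity),
            class = "we_obsmodel")
}

# Deterministic sub-seed for replicate k of a master seed, so that
# replicates can be split or parallelised without changing results.
replicate_seed <- function(seed, k) {
  p <- 2147483647
  as.integer(((as.numeric(seed) %% p) * 48271 + k * 1299721) %% p)
}

#' Operating characteristics by Monte-Carlo replication
#'
#' Replicates [run_trial()] under a scenario and aggregates the
#' operating characteristics: per-regimen selection percentages, early
#' termination percentage, the pooled toxicity percentage (total
#' toxicities over total treated patients) and the mean efficacy
#' response over all treated patients (including outcomes hidden from
#' the estimators by the observation model, so the metric is comparable
#' across models). Replicate `k` runs under a deterministic sub-seed of
#' `seed`, making the report reproducible bit-for-bit.
#'
#' @param scenario A [we_scenario()] object.
#' @param config A [we_design()] object (layouts must match).
#' @param model An [observation_model()].
#' @param reps Number of replicated trials.
#' @param seed Master integer seed.
#' @return An object of class `we_oc` with fields `selection_pct`
#'   (per regimen), `termination_pct`, `toxicity_pct`, `mean_efficacy`,
#'   `mean_n_per_regimen`, `reps`, `seed`.
#' @examples
#' sc <- builtin_scenarios()[["scenario2"]]
#' simulate_oc(sc, we_design(), reps = 20, seed = 1)
#' @export
simulate_oc <- function(scenario, config, model = observation_model(),
                        reps = 1000, seed = 1) {
  stopifnot(inherits(scenario, "we_scenario"),
            inherits(config, "we_design"), reps >= 1)
  if (scenario$layout != config$layout)
    stop("scenario and design layouts differ")
  if (length(scenario$p_t) != config$m)
    stop("scenario has ", length(scenario$p_t), " regimens, design has ",
         config$m)
  oracle <- scenario_oracle(scenario)
  sel <- integer(config$m)
  term <- 0L
  tox_total <- 0
  n_total <- 0
  eff_sum <- 0
  eff_n <- 0
  n_reg <- numeric(config$m)
  for (k in seq_len(reps)) {
    tr <- run_trial(config, oracle, model, seed = replicate_seed(seed, k))
    if (tr$terminated) term <- term + 1L
    else sel[tr$recommendation] <- sel[tr$recommendation] + 1L
    tox_total <- tox_total + tr$total_toxicity
    n_total <- n_total + tr$n_treated
    eff_sum <- eff_sum + sum(tr$efficacy_values)
    eff_n <- eff_n + length(tr$efficacy_values)
    n_reg <- n_reg + tr$n_per_regimen
  }
  structure(list(
    scenario = scenario$label,
    regimen = config$label,
    selection_pct = 100 * sel / reps,
    termination_pct = 100 * term / reps,
    toxicity_pct = if (n_total > 0) 100 * tox_total / n_total else NA_real_,
    mean_efficacy = if (eff_n > 0) eff_sum / eff_n else NA_real_,
    mean_n_per_regimen = n_reg / reps,
    obr = scenario$obr,
    reps = reps, seed = seed
  ), class = "we_oc")
}

#' @export
print.we_oc <- function(x, digits = 1, ...) {
  cat(sprintf("Operating characteristics, %s (%d replicates, seed %d)\n",
              x$scenario, x$reps, x$seed))
  tab <- data.frame(regimen = x$regimen,
                    selection = round(x$selection_pct, digits),
                    mean_n = round(x$mean_n_per_regimen, digits))
  if (!is.na(x$obr))
    tab$regimen[x$obr] <- paste0(tab$regimen[x$obr], " *OBR*")
  print(tab, row.names = FALSE)
  cat(sprintf("termination %.1f%%, toxicity %.1f%%, mean efficacy %.2f\n",
              x$termination_pct, x$toxicity_pct, x$mean_efficacy))
  invisible(x)
}

#' Convert an operating-characteristics report to a data frame
#'
#' One row per regimen plus summary rows for termination, pooled
#' toxicity percentage and mean efficacy, convenient for CSV export.
#'
#' @param x A `we_oc` object.
#' @param ... Unused.
#' @return A data frame with columns `row`, `value`.
#' @export
as.data.frame.we_oc <- function(x, ...) {
  data.frame(
    row = c(paste0("selection_", x$regimen),
            "termination_pct", "toxicity_pct", "mean_efficacy"),
    value = c(x$selection_pct, x$termination_pct, x$toxicity_pct,
              x$mean_efficacy)
  )
}
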