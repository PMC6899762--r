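#' Linear prior-mean candidate
#'
#' A calibration candidate generates the per-regimen prior toxicity and
#' efficacy means as linear ladders:
#' `p_j = start_tox + (j - 1) * step_tox` and
#' `mu_j = start_eff + (j - 1) * step_eff`.
#'
#' @param start_tox,step_tox Intercept and step of the prior toxicity
#'   ladder.
#' @param start_eff,step_eff Intercept and step of the prior efficacy
#'   ladder.
#' @return An object of class `we_prior_candidate`.
#' @examples
#' prior_candidate(0.10, 0.04, -1.00, -0.025)   # the published choice
#' @export
prior_candidate <- function(start_tox, step_tox, start_eff, step_eff) {
  structure(list(start_tox = start_tox, step_tox = step_tox,
                 start_eff = start_eff, step_eff = step_eff),
            class = "we_prior_candidate")
}

candidate_means <- function(candidate, m) {
  j <- seq_len(m) - 1
  list(p = candidate$start_tox + j * candidate$step_tox,
       mu = candidate$start_eff + j * candidate$step_eff)
}

candidate_valid <- function(candidate, config) {
  cm <- candidate_means(candidate, config$m)
  all(cm$p > 0 & cm$p < 1)
}

candidate_design <- function(candidate, config) {
  cm <- candidate_means(candidate, config$m)
  config$prior$nu <- cm$p * config$prior$strength
  config$prior$mu0 <- cm$mu
  config
}

#' Does a prior candidate preserve the initial regimen ordering?
#'
#' The calibration search is restricted to prior parameters under which
#' the prior plug-in trade-off values are strictly increasing in the
#' regimen index -- the initial desirability ordering 1 < 2 < ... < m a
#' clinician specifies before the trial. Candidates generating invalid
#' toxicity means (outside (0, 1)) are rejected outright.
#'
#' @param candidate A [prior_candidate()].
#' @param config A [we_design()] whose transformation and target define
#'   the prior trade-off values.
#' @return `TRUE` when the candidate is valid and order-preserving.
#' @examples
#' preserves_ordering(prior_candidate(0.10, 0.04, -1.00, -0.025), we_design())
#' @export
preserves_ordering <- function(candidate, config) {
  stopifnot(inherits(candidate, "we_prior_candidate"),
            inherits(config, "we_design"))
  if (!candidate_valid(candidate, config)) return(FALSE)
  cfg <- candidate_design(candidate, config)
  d <- plug_in_delta(trial_state(cfg), cfg)
  all(diff(d) > 0)
}

#' Grid-search calibration of the prior means
#'
#' Scores every order-preserving candidate on a grid of prior-ladder
#' parameters by simulating the design -- with the safety and futility
#' constraints disabled -- under two pivot scenarios chosen so that the
#' OBR sits at opposite ends of the regimen range, and taking the
#' geometric mean of the two OBR-selection proportions. Common random
#' numbers (the same replicate sub-seeds for every candidate) reduce
#' ranking noise. Besides the full ranking, the set of candidates
#' scoring within `band` (default 1.5%) of the maximum is reported:
#' many prior choices are typically statistically indistinguishable.
#'
#' @param start_tox,step_tox,start_eff,step_eff Numeric vectors of grid
#'   values; the candidate grid is their Cartesian product.
#' @param pivot_scenarios List of (typically two) [we_scenario()]
#'   objects with an OBR annotation.
#' @param config Base [we_design()] (its constraints are disabled
#'   during calibration).
#' @param reps Replicates per candidate and pivot scenario.
#' @param seed Master seed (shared across candidates: common random
#'   numbers).
#' @param band Near-optimal band as a fraction of the maximum score.
#' @return A data frame (class `we_calibration`) with one row per
#'   admissible candidate: the four ladder parameters, per-pivot
#'   OBR-selection proportions, `score` (geometric mean), `rank`, and
#'   `near_optimal` (within the band of the maximum); sorted by rank.
#' @examples
#' \donttest{
#' scs <- builtin_scenarios()
#' calibrate_priors(step_tox = c(0.03, 0.05), step_eff = c(-0.025, -0.05),
#'                  pivot_scenarios = scs[c("scenario2", "scenario3")],
#'                  reps = 50, seed = 1)
#' }
#' @export
calibrate_priors <- function(start_tox = 0.10, step_tox,
                             start_eff = -1.00, step_eff,
                             pivot_scenarios,
                             config = we_design(),
                             reps = 500, seed = 1, band = 0.015) {
  stopifnot(inherits(config, "we_design"))
  grid <- expand.grid(start_tox = start_tox, step_tox = step_tox,
                      start_eff = start_eff, step_eff = step_eff,
                      KEEP.OUT.ATTRS = FALSE)
  config$use_constraints <- FALSE
  keep <- vapply(seq_len(nrow(grid)), function(i)
    preserves_ordering(do.call(prior_candidate, as.list(grid[i, ])), config),
    logical(1))
  if (!any(keep)) stop("no admissible candidate on the grid")
  grid <- grid[keep, , drop = FALSE]

  props <- matrix(NA_real_, nrow(grid), length(pivot_scenarios))
  for (s in seq_along(pivot_scenarios)) {
    sc <- pivot_scenarios[[s]]
    stopifnot(inherits(sc, "we_scenario"))
    if (is.na(sc$obr)) stop("pivot scenarios must have an OBR")
    for (i in seq_len(nrow(grid))) {
      cfg <- candidate_design(do.call(prior_candidate, as.list(grid[i, ])),
                              config)
      oc <- simulate_oc(sc, cfg, reps = reps, seed = seed)
      props[i, s] <- oc$selection_pct[sc$obr] / 100
    }
  }
  score <- exp(rowMeans(log(pmax(props, .Machine$double.xmin))))
  out <- cbind(grid,
               stats::setNames(as.data.frame(props),
                               paste0("prop_pivot", seq_len(ncol(props)))),
               score = score)
  out <- out[order(-score), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$near_optimal <- out$score >= max(score) * (1 - band)
  rownames(out) <- NULL
  class(out) <- c("we_calibration", "data.frame")
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  attr(out, "band") <- band
  out
}
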