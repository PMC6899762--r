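#' Save a design configuration to YAML or JSON
#'
#' Serialises every tuning constant of a [we_design()] (and the embedded
#' transformation) into a flat, schema-stable list written as YAML
#' (`.yml`/`.yaml`) or JSON (`.json`), chosen by the file extension.
#' [load_config()] restores an identical design.
#'
#' @param config A [we_design()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "we_design"))
  tr <- config$transform
  x <- list(
    layout = config$layout, N = config$N, cohort_size = config$cohort_size,
    phi = config$phi, psi_star = config$psi_star,
    gamma_t = config$target$gamma_t, gamma_e = config$target$gamma_e,
    transform = list(family = tr$family, psi = tr$psi,
                     psi_prime = tr$psi_prime, p_low = tr$p_low,
                     p_high = tr$p_high, alpha = tr$alpha, beta = tr$beta),
    prior_tox_mean = config$prior$nu / config$prior$strength,
    prior_tox_strength = config$prior$strength,
    prior_eff_mean = config$prior$mu0,
    prior_eff_lambda = config$prior$lambda,
    prior_zeta = config$prior$zeta,
    prior_zeta_prime = config$prior$zeta_prime,
    r_t = config$r_t, r_e = config$r_e,
    eta1_0 = config$eta1_0, eta1_bar = config$eta1_bar,
    eta2_0 = config$eta2_0, eta2_bar = config$eta2_bar,
    lower_is_better = config$lower_is_better,
    weights = config$weights,
    use_constraints = config$use_constraints,
    start_regimen = config$start_regimen
  )
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(x, path)
  invisible(path)
}

#' Load a design configuration from YAML or JSON
#'
#' Reads a configuration file written by [save_config()] or a minimal
#' hand-written one; fields left out fall back to the SCCA defaults of
#' [we_design()] for the stated layout. Every field is validated by the
#' design constructor, so schema violations fail with an error naming
#' the offending constraint.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A [we_design()] object.
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' save_config(we_design(), path)
#' load_config(path)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  if (!is.list(x)) stop("configuration must be a mapping")
  layout <- x$layout %||% "single"
  tr <- x$transform
  transform <- if (is.null(tr)) transform_spec() else
    transform_spec(family = tr$family %||% "logistic",
                   psi = tr$psi %||% 0, psi_prime = tr$psi_prime %||% -4.5,
                   p_low = tr$p_low %||% 0.01, p_high = tr$p_high %||% 0.9,
                   alpha = tr$alpha, beta = tr$beta)
  args <- list(
    layout = layout, N = x$N, cohort_size = x$cohort_size %||% 3,
    phi = x$phi %||% 0.3, psi_star = x$psi_star %||% 0.20,
    gamma_t = x$gamma_t %||% 0.01, gamma_e = x$gamma_e %||% 0.99,
    transform = transform,
    prior_tox_mean = x$prior_tox_mean, prior_tox_strength =
      x$prior_tox_strength %||% 1,
    prior_eff_mean = x$prior_eff_mean, prior_eff_lambda =
      x$prior_eff_lambda %||% 1,
    prior_zeta = x$prior_zeta %||% 2,
    prior_zeta_prime = x$prior_zeta_prime %||% 3,
    r_t = x$r_t %||% 0.02, r_e = x$r_e %||% 0.02,
    eta1_0 = x$eta1_0 %||% 0.95, eta1_bar = x$eta1_bar %||% 0.6,
    eta2_0 = x$eta2_0 %||% 0.8, eta2_bar = x$eta2_bar %||% 0.3,
    lower_is_better = x$lower_is_better %||% TRUE,
    weights = x$weights %||% c(1, 1),
    use_constraints = x$use_constraints %||% TRUE,
    start_regimen = x$start_regimen %||% 1L
  )
  do.call(we_design, args)
}

#' Read accumulated patient records
#'
#' CSV with mandatory header and columns `patient_id`, `regimen`
#' (index), `toxicity` (0/1) and `efficacy` (numeric; `NA` when the
#' outcome is missing or still pending).
#'
#' @param path Path to the records CSV.
#' @return A validated data frame.
#' @export
read_patient_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "regimen", "toxicity", "efficacy")
  miss <- setdiff(req, names(rec))
  if (length(miss))
    stop("records file lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!rec$toxicity %in% c(0, 1)))
    stop("`toxicity` must be coded 0/1")
  rec$efficacy <- as.numeric(rec$efficacy)
  rec
}

#' Interim decision support from accumulated records
#'
#' Rebuilds the trial state from patient records and reports the
#' posterior summaries, admissibility flags, plug-in trade-off values
#' and the next-cohort allocation candidates with their randomisation
#' probabilities. No allocation is drawn; the report is deterministic.
#'
#' @param records Data frame from [read_patient_records()] (or with the
#'   same columns).
#' @param config A [we_design()] object.
#' @return A list with elements `posterior` (per-regimen data frame),
#'   `candidates`, `probabilities` and `terminated`.
#' @export
decide_next_cohort <- function(records, config) {
  state <- trial_state(config, records)
  alloc <- allocate_next_cohort(state, config, draw = FALSE)
  post <- state_posterior(alloc$state, config)
  list(
    posterior = data.frame(
      regimen = config$label,
      n = alloc$state$n, toxicities = alloc$state$t,
      n_efficacy = alloc$state$eff_n,
      p_tox = post$p_hat, mu_eff = post$mu_hat,
      safety_tail = post$safety_tail, futility_prob = post$fut_prob,
      unsafe = alloc$state$unsafe, futile = alloc$state$futile,
      delta = alloc$delta),
    candidates = alloc$candidates,
    probabilities = alloc$probabilities,
    terminated = alloc$terminated
  )
}

# FNV-1a hash of a string, as an 8-hex-digit digest for run manifests.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (h exceeds integer range; b < 256)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # h * 16777619 mod 2^32 in 16-bit halves (stays within double precision)
    h <- (((h %/% 65536 * 16777619) %% 65536) * 65536 +
            (h %% 65536) * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Run manifest for reproducibility
#'
#' A small record identifying a stochastic run: a digest of every
#' design-relevant configuration field, the master seed, the replicate
#' count and a timestamp. Identical manifests (up to timestamp) imply
#' identical outputs.
#'
#' @param config A [we_design()] object.
#' @param seed Master seed of the run.
#' @param reps Replicate count.
#' @return A list with `config_digest`, `seed`, `reps`, `package_version`
#'   and `timestamp`.
#' @export
run_manifest <- function(config, seed, reps) {
  stopifnot(inherits(config, "we_design"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  list(config_digest = fnv1a(paste(readLines(tmp), collapse = "\n")),
       seed = seed, reps = reps,
       package_version = as.character(utils::packageVersion("wedesign")),
       timestamp = format(Sys.time(), tz = "UTC"))
}
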