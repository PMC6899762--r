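#' Solve transformation parameters from two anchor conditions
#'
#' The continuous efficacy endpoint `xi` is mapped to the probability
#' scale by `T(xi) = linkinv(alpha + beta * xi)`. The shift `alpha` and
#' slope `beta` are fixed by two clinical anchors: the lowest efficacy
#' bound `psi` maps to a small probability `p_low` and the highest
#' clinically feasible value `psi_prime` maps to `p_high`, i.e.
#' `T(psi) = p_low`, `T(psi_prime) = p_high`. For the logistic family
#' the solution is
#' `beta = (logit(p_high) - logit(p_low)) / (psi_prime - psi)` and
#' `alpha = logit(p_low) - beta * psi`; other families replace `logit`
#' by their own link. The sign of `beta` encodes the direction: when
#' lower outcome values are clinically better (`psi_prime < psi`),
#' `beta < 0`.
#'
#' @param psi Lowest efficacy bound on the original outcome scale.
#' @param psi_prime Highest clinically feasible outcome value.
#' @param p_low,p_high Probability anchors in (0, 1), `p_low < p_high`.
#' @param family Link family: `"logistic"` (default), `"probit"` or
#'   `"cloglog"`.
#' @return Named numeric vector `c(alpha = , beta = )`.
#' @examples
#' solve_anchors(psi = 0, psi_prime = -4.5)   # alpha ~ -4.60, beta ~ -1.51
#' @export
solve_anchors <- function(psi, psi_prime, p_low = 0.01, p_high = 0.9,
                          family = c("logistic", "probit", "cloglog")) {
  family <- match.arg(family)
  if (psi == psi_prime)
    stop("degenerate geometry: `psi` and `psi_prime` must differ")
  if (p_low <= 0 || p_low >= 1 || p_high <= 0 || p_high >= 1)
    stop("anchors must lie strictly in (0, 1)")
  if (p_low >= p_high)
    stop("`p_low` must be smaller than `p_high`")
  link <- link_fun(family)
  beta <- (link(p_high) - link(p_low)) / (psi_prime - psi)
  alpha <- link(p_low) - beta * psi
  c(alpha = alpha, beta = beta)
}

link_fun <- function(family) {
  switch(family,
    logistic = stats::qlogis,
    probit   = stats::qnorm,
    cloglog  = function(p) log(-log1p(-p)))
}

linkinv_fun <- function(family) {
  switch(family,
    logistic = stats::plogis,
    probit   = stats::pnorm,
    cloglog  = function(q) -expm1(-exp(q)))
}

#' Specification of the continuous-endpoint transformation
#'
#' Bundles the link family, the anchor bounds and the solved `(alpha,
#' beta)` parameters. By default the parameters are solved from the
#' anchors with the *logistic* link whatever the family, mirroring the
#' practice of carrying one set of parameters across link choices; set
#' `solve_with_family_link = TRUE` to re-solve the two-anchor system
#' with the family's own link instead. Explicit `alpha`/`beta` override
#' the anchor solve entirely.
#'
#' @inheritParams solve_anchors
#' @param alpha,beta Optional explicit parameters (both must be given
#'   together; `beta` must be non-zero).
#' @param solve_with_family_link Solve the anchors with the family's
#'   own link rather than the logistic link.
#' @return An object of class `we_transform`.
#' @examples
#' transform_spec()                             # the SCCA default
#' transform_spec(family = "probit")            # probit, logistic-solved pars
#' transform_spec(psi = 0, psi_prime = 1)
#' @export
transform_spec <- function(family = c("logistic", "probit", "cloglog"),
                           psi = 0, psi_prime = -4.5,
                           p_low = 0.01, p_high = 0.9,
                           alpha = NULL, beta = NULL,
                           solve_with_family_link = FALSE) {
  family <- match.arg(family)
  if (is.null(alpha) != is.null(beta))
    stop("supply both `alpha` and `beta`, or neither")
  if (is.null(alpha)) {
    solve_family <- if (solve_with_family_link) family else "logistic"
    ab <- solve_anchors(psi, psi_prime, p_low, p_high, family = solve_family)
    alpha <- ab[["alpha"]]
    beta <- ab[["beta"]]
  }
  if (beta == 0) stop("`beta` must be non-zero")
  structure(list(family = family, alpha = alpha, beta = beta,
                 psi = psi, psi_prime = psi_prime,
                 p_low = p_low, p_high = p_high),
            class = "we_transform")
}

#' @export
print.we_transform <- function(x, ...) {
  cat(sprintf("%s transformation: alpha = %.4f, beta = %.4f\n",
              x$family, x$alpha, x$beta))
  cat(sprintf("  anchors: T(%g) = %g, T(%g) = %g\n",
              x$psi, x$p_low, x$psi_prime, x$p_high))
  invisible(x)
}

#' Transform a continuous outcome to the probability scale
#'
#' Applies the configured link-inverse to `alpha + beta * xi`. The
#' logistic case uses `plogis`, which is overflow-safe for large
#' `|alpha + beta * xi|`; the output is clamped to lie strictly inside
#' (0, 1) so downstream criterion terms stay finite.
#'
#' @param xi Numeric vector of outcomes on the original scale.
#' @param spec A [transform_spec()] object.
#' @return Probabilities strictly in (0, 1), same length as `xi`.
#' @examples
#' sp <- transform_spec()
#' transform_value(c(0, -4.5), sp)   # the anchors: 0.01, 0.90
#' transform_value(-2.25, sp)
#' @export
transform_value <- function(xi, spec) {
  stopifnot(inherits(spec, "we_transform"))
  p <- linkinv_fun(spec$family)(spec$alpha + spec$beta * xi)
  pmin(pmax(p, 1e-15), 1 - 1e-15)
}

#' Map a probability back to the original outcome scale
#'
#' Inverse of [transform_value()]: returns the outcome value `xi` with
#' `transform_value(xi, spec) == p`. Useful for reporting probability
#' thresholds on the clinical scale.
#'
#' @param p Probabilities strictly in (0, 1).
#' @inheritParams transform_value
#' @return Numeric vector on the original outcome scale.
#' @examples
#' sp <- transform_spec()
#' inverse_transform(c(0.01, 0.9), sp)   # the anchors: 0, -4.5
#' @export
inverse_transform <- function(p, spec) {
  stopifnot(inherits(spec, "we_transform"))
  if (any(p <= 0 | p >= 1))
    stop("`p` must lie strictly in (0, 1)")
  (link_fun(spec$family)(p) - spec$alpha) / spec$beta
}
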