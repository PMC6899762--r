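---
title: "The WE design: methods and implementation notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The WE design: methods and implementation notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wedesign)
```

## The problem

Phase I/II trials of molecularly targeted agents evaluate a binary
toxicity endpoint and an efficacy endpoint together, because the
dose–efficacy curve of a targeted agent may plateau or even turn over:
toxicity is no longer a proxy for benefit. The goal is the *optimal
biological regimen* (OBR) — the regimen with toxicity probability below
an upper bound $\phi$ and the best efficacy among regimens clearing a
minimal-efficacy bound. `wedesign` implements a seamless Phase I/II
design for the common case where efficacy is *continuous* (the
motivating setting is the change in log SCCA tumour-marker level, where
more negative values mean better response), with no parametric or
monotonicity assumptions linking the regimens: each dose, combination
or schedule is modelled independently, so the design applies unchanged
to single-agent ladders and to combination grids where only the partial
ordering of toxicity is known.

## The trade-off criterion

Each regimen is summarised by a trinomial outcome probability vector
$\theta = (\theta_1,\theta_2,\theta_3)$ — "efficacy and no toxicity",
"no efficacy and no toxicity", "toxicity" (efficacy is only assessed in
the absence of toxicity, so the two toxic cells are merged). Given a
target $\gamma = (\gamma_1,\gamma_2,\gamma_3)$, the criterion

$$\delta(\theta,\gamma) \;=\; \frac{\gamma_1^2}{\theta_1} +
  \frac{\gamma_2^2}{\theta_2} +
  \frac{(1-\gamma_1-\gamma_2)^2}{1-\theta_1-\theta_2} \;-\; 1$$

is an information-theoretic distance derived from a weighted Shannon
entropy argument: it is zero exactly at $\theta=\gamma$ and diverges as
any component of $\theta$ approaches zero. The three poles give the
criterion its clinical shape: it penalises inefficacious regimens
($\theta_1 \to 0$), overly toxic regimens ($\theta_2 \to 0$), and
zero-toxicity "underdosing" regimens ($\theta_3 \to 0$). Under working
independence of the two endpoints, $\theta_1 = (1-p_t)p_e$,
$\theta_2 = (1-p_t)(1-p_e)$, $\theta_3 = p_t$, which is the marginal
form `trade_off_marginal(p_t, p_e, target)`. The default target is the
best possible profile $\gamma_t = 0.01$, $\gamma_e = 0.99$: allocation
is drawn toward high efficacy at near-zero toxicity, and the
safety/futility constraints (below) do the bound enforcement. A
weighted variant that raises each term to a power
$(\omega_1, \omega_2, 3-\omega_1-\omega_2)$ is exposed through
`weights`; the default `c(1, 1)` is used everywhere in the package's
reproduction suite and we make no claims about the weighted optimum.

## Mapping a continuous endpoint into the criterion

The continuous outcome $\xi$ enters the criterion through a logistic
transformation $T(\xi) = \mathrm{logit}^{-1}(\alpha + \beta\xi)$ onto
$(0,1)$. Rather than asking users for $\alpha,\beta$ directly, they are
solved from two clinical anchors: the lowest efficacy bound $\psi$ maps
to `p_low` (default 0.01) and the highest clinically feasible value
$\psi'$ maps to `p_high` (default 0.9). For the SCCA setting,
$\psi = 0$ (no change in the marker) and $\psi' = -4.5$ give
$\alpha \approx -4.60$, $\beta \approx -1.51$; the negative slope
encodes that lower outcomes are better. The anchors are defaults, not
dogma — `transform_spec()` accepts any anchor pair (e.g. mapping
$\psi$ to 0.5 instead of 0.01 re-shapes which efficacy range the
criterion discriminates best). Probit and complementary log-log links
are available; by default they reuse the logistic-solved $(\alpha,
\beta)$, and `solve_with_family_link = TRUE` re-solves the two-anchor
system in the family's own link. The logistic inverse is computed by
`plogis`, which is overflow-safe, and outputs are clamped to
$(10^{-15}, 1-10^{-15})$; plug-in probabilities are additionally
guarded at $10^{-12}$ before division so a degenerate posterior cannot
produce a spurious infinity.

## Conjugate models and constraints

Toxicity at regimen $j$ carries a Beta prior with mean mass $\nu_j$ and
total strength $\beta_j = 1$ pseudo-observation; after $t_j$
toxicities in $n_j$ patients the posterior mean is
$(t_j+\nu_j)/(n_j+\beta_j)$. The efficacy mean carries a
Normal-inverse-Gamma prior $(\mu_{0,j}, \lambda_j{=}1, \zeta_j{=}2,
\zeta'_j{=}3)$ updated by the standard conjugate rule; its posterior
mean is the convex combination
$(\lambda\mu_0 + \sum x)/(\lambda + n)$. The shape/rate constants
$\zeta, \zeta'$ only influence the futility tail and the design is
insensitive to them over a reasonable range.

Two time-varying constraints guard the trial. Regimen $j$ is **unsafe**
when its posterior probability of exceeding $\phi = 0.3$ reaches
$\eta_1(n_j) = \max(0.95 - 0.02\,n_j,\; 0.6)$, and **futile** when the
normal-approximation posterior probability that its mean efficacy is
worse than $\psi^* = 0.20$ (on the original outcome scale; for the
SCCA coding "worse" means above) reaches
$\eta_2(n_j) = \max(0.8 - 0.02\,n_j,\; 0.3)$. Both schedules start
lenient and tighten with the regimen's own sample size; the floors are
the controlling probabilities applied at the final recommendation.
Flags are absorbing, and unsafety propagates upward along the known
toxicity partial order — for a combination grid,
$(a,b) \preceq (a',b')$ iff $a \le a'$ and $b \le b'$ — while futility
does not propagate, because no efficacy ordering is assumed. We take
$\psi^*$ on the original outcome scale, since the futility integral is
written against the density of the mean outcome itself.

## Trial flow and the allocation rule

Patients enter in cohorts of 3. The first cohort is always treated at
the lowest regimen. Between cohorts the posteriors are updated, the
constraints evaluated, and the plug-in criterion
$\hat\delta_j = \delta(\hat p_{t,j},\, T(\hat\mu_j))$ computed for all
regimens (untried regimens carry their prior values). The candidate
set is the admissible regimens after two coherence restrictions with
respect to the known toxicity ordering: an untried regimen is reachable
only when all its immediate predecessors have been tried (no skipping),
and no regimen strictly above one whose last-cohort observed toxicity
fraction reached $\phi$ can be treated next (no escalation immediately
after excessive toxicity). **Each patient** of the next cohort is then
randomised between the two best candidates (smallest $\hat\delta$)
with probabilities proportional to $1/\hat\delta$.

Per-patient rather than whole-cohort randomisation is a deliberate
design choice. Randomising the cohort as a block leaves the runner-up
regimen untouched with probability equal to the favourite's share at
*every* decision; compounded over a trial this leaves the top dose of
a steep efficacy ladder untried in over a tenth of trials and visibly
degrades the correct-selection rate. Splitting the cohort patient-wise
keeps the same expected allocation proportions while guaranteeing that
a competitive runner-up accrues information quickly; simulated
operating characteristics under the benchmark scenarios supported this
reading decisively.

The trial stops when $N$ patients have been treated (36 for the
single-agent ladder, 72 for the $4\times2$ combination grid) or no
admissible regimen remains. The final recommendation is the tried
regimen minimising $\hat\delta$ among those that (i) pass the final
safety and futility checks at the floor controlling probabilities and
(ii) have posterior toxicity estimate at most $\phi$ — the recommended
regimen must itself satisfy the estimated OBR definition, a second
deliberate choice: without it a sparsely-sampled toxic regimen whose
few patients were lucky can sneak past the tail test, and the design's
ability to discard the just-above-OBR dose degrades by several
percentage points. Ties in $\hat\delta$ break toward the lower
toxicity estimate, then the lower index. If the admissible set is
empty, the trial ends with no recommendation ("termination") — the
correct outcome when nothing is both safe and efficacious.

## The synthetic-outcome generator

`draw_patient()` generates correlated binary-continuous outcomes from a
latent bivariate standard normal $(u, v)$ with correlation $r$:
toxicity is $\mathbf 1\{\Phi(u) > 1 - p_t\}$ and the outcome is
$\mu - \sigma v$. Margins are exactly Bernoulli$(p_t)$ and
N$(\mu,\sigma^2)$ for every $r$. The orientation — positive $r$
couples toxicity with *lower* (better) outcome values — encodes the
pharmacological reading that a hotter exposure drives both toxicity
and response, and it is the orientation under which the simulated
correlation sensitivity reproduces the direction reported for the
benchmark plateau scenario (positive correlation shifts selection
toward the start of the plateau). Because the margins are exact, the
correlation influences operating characteristics only through the
adaptive decisions, a second-order channel; its simulated magnitude in
this implementation is larger than the published one (see Limitations).

Nine benchmark scenarios ship in `builtin_scenarios()`: six
single-agent (including two with no OBR, exercising termination) and
three combination scenarios, with efficacy SD fixed at 1 and default
correlation $r = 0.2$. Observation models: `delayed` releases a
cohort's efficacy one decision cycle after its toxicity ("twice as
long to evaluate"), and `missing_on_toxicity` drops efficacy for toxic
patients permanently. Estimators use whatever is visible — the
independence of the two posteriors makes unequal sample sizes
unproblematic — and all delayed values are available by the final
analysis. The reported mean-efficacy operating characteristic averages
*all generated* outcomes of treated patients, including hidden ones,
so the metric is comparable across observation models.

What the generator does not emulate: patient heterogeneity beyond the
latent correlation, time-to-event structure, non-normal efficacy
distributions, and drift in the patient population. Passing the
simulation suite therefore certifies the decision logic under the
stated generating model, not robustness to violations of it.

## Prior calibration

The prior means are linear ladders $p_j = \texttt{start.tox} +
(j-1)\,\texttt{step.tox}$ and $\mu_{0,j} = \texttt{start.eff} +
(j-1)\,\texttt{step.eff}$. `calibrate_priors()` grid-searches these
four constants, keeping only candidates that *preserve the initial
ordering* — which we operationalise as: the prior plug-in
$\hat\delta_j$ sequence is strictly increasing in $j$, i.e. the
clinician's stated a-priori desirability ordering $1 \prec 2 \prec
\dots$ survives the transform. (This is the largest interpretive
choice in the module; the phrase is not formally defined in the
literature this follows.) Each admissible candidate is scored by
simulating the design with all constraints disabled under two pivot
scenarios whose OBRs sit at opposite ends of the ladder, and taking
the geometric mean of the two OBR-selection proportions; common random
numbers across candidates reduce ranking noise at desk scale. Many
candidates tie within ~1.5% of the maximum, so the result is reported
as a near-optimal band (width configurable) rather than a single
winner. The shipped defaults, `start.tox = 0.10`, `step.tox = 0.04`,
`start.eff = -1.00`, `step.eff = -0.025` (the combination grid shifts
the ladder one step along the second agent), sit inside that band.

## Numerical and reproducibility choices

Decisions are replayable: `run_trial(seed = )` seeds a single stream,
the per-cohort assignment vector is drawn first, and outcomes are then
drawn regimen-by-regimen in ascending index order. Replicate $k$ of
`simulate_oc()` uses the deterministic sub-seed
$(48271\,s + 1299721\,k) \bmod (2^{31}{-}1)$ of master seed $s$, so
replicate sets can be split or parallelised without changing results.
If both top-two candidates have $\hat\delta$ numerically zero the
split is 50/50 (the $10^{-12}$ clamp makes this the proportionality
limit). Degenerate inputs: $N = 0$ terminates immediately; an empty
efficacy update is a no-op; equal transformation bounds, probabilities
at $\{0,1\}$ and negative counts raise errors naming the violated
constraint.

Problem sizes used by the shipped checks: the package's own test suite
evaluates operating characteristics at 2,000 replicates per scenario —
at that size ±2.5 percentage points is about three Monte-Carlo
standard errors for the proportions involved — and the calibration
smoke test uses the 40-candidate step grid at 500 replicates per
candidate and pivot. `scripts/acceptance.R` re-runs the headline
characteristics at 10,000 replicates; its observation-model
sensitivity runs share replicate sub-seeds with the baseline runs
(common random numbers), which shrinks the variance of the selection
contrast the same way the calibration module does across candidates.

## Known limitations

* The correlation between toxicity and efficacy affects selection only
  through adaptive decisions; in this implementation the simulated
  effect of strong correlation ($r = \pm 0.8$) on the plateau scenario
  is directionally correct but roughly twice the published magnitude,
  reflecting how strongly the final safety filter conditions on lucky
  toxicity runs. Conclusions about correlation robustness should rest
  on the direction and monotone trend, not the point contrast.
* The criterion at true parameter values can prefer a toxic regimen to
  the OBR (efficacy dominates the unweighted criterion when
  $\gamma_t$ is small); the safety constraint system, not the
  criterion alone, carries the toxicity control. Disabling the
  constraints is therefore only meaningful for calibration.
* The normal approximation to the futility tail ignores the
  $t$-distribution tails of the posterior mean at very small $n$; this
  is the standard simplification and is conservative only on one side.
* Single-stream R implementation: ~4 ms per simulated single-agent
  trial; a 10,000-replicate scenario takes under a minute, the full
  acceptance surface about a quarter of an hour on one core.
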