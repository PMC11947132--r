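---
title: "Anchored MAIC: model, weighting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored MAIC: model, weighting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchormaic)
library(dplyr)
```

## The problem

Two adjuncts to levodopa for Parkinson's disease motor fluctuations —
safinamide and rasagiline — have each been tested against placebo in
separate randomized trials, but never head to head. An *anchored indirect
comparison* uses the shared placebo arm: each trial supplies an
active-versus-placebo contrast, and the difference of those contrasts
estimates active-versus-active. That difference is unbiased only if the two
trial populations agree on every *effect modifier* — a baseline variable
that changes the magnitude of the treatment effect. In the motivating
comparison the populations differ visibly (male proportion 58% vs 66%, BMI
23.9 vs 23.1 kg/m², baseline OFF time 5.7 vs 6.1 h/day), so a naive Bucher
comparison carries the modifier imbalance into the estimate.

Matching-adjusted indirect comparison (MAIC), as described in NICE DSU
Technical Support Document 18, corrects this when individual patient data
(IPD) are available for one trial and only published aggregates (AgD) for
the other: the IPD are reweighted so their baseline summaries match the
comparator's, the outcome models are refit with those weights, and the
weighted contrast is anchored against the comparator's published contrast.

## The weighting model

Let $x_i$ be patient $i$'s matched covariates (here age, sex, BMI and
baseline OFF time) and $\bar{x}_{AgD}$ the comparator's published pooled
means/proportions. MAIC assigns $w_i = \exp(\tilde{x}_i^\top \beta)$ with
$\tilde{x}_i = x_i - \bar{x}_{AgD}$. The method-of-moments $\beta$
minimizes the convex objective

$$Q(\beta) = \sum_i \exp(\tilde{x}_i^\top \beta),$$

whose gradient $\sum_i \tilde{x}_i e^{\tilde{x}_i^\top\beta}$ is exactly
the requirement that the *weighted* pooled mean of every matched covariate
equal its target. This is the standard exponential-tilting solution of the
propensity-style logistic model for trial enrolment: only the IPD side ever
enters the likelihood, because the AgD side is summarized by its means.

`estimate_weights()` solves $Q$ by Newton's method with the analytic
gradient and Hessian, step-halving on $Q$, an iteration cap of 500 and a
BFGS fallback if the Hessian solve fails; convergence requires the gradient
max-norm to fall below $10^{-10} n$. Weights are estimated once on the
pooled two-arm IPD against pooled targets (matching the pooled presentation
of the published baseline tables), and per-arm effective sample sizes are
reported from the within-arm weights.

Feasibility is checked before solving: each target must lie strictly inside
the range of the IPD values (a binary target of exactly 0 or 1 with both
levels present is therefore rejected), and collinear centered covariates
are rejected by name. Targets outside the convex hull of the covariate
cloud make $Q$ unbounded below along some direction; the solver detects the
diverging tilt and reports the infeasibility rather than returning a
half-converged weight set.

### Effective sample size

The published analyses report an ESS but, like most MAIC reports, not its
formula; we adopt the TSD 18 convention
$\mathrm{ESS} = (\sum_i w_i)^2 / \sum_i w_i^2$. It equals $n$ iff all
weights are equal, never exceeds $n$, and is invariant to rescaling all
weights by a positive constant — which is why `rescale_weights()` (raw /
sum-to-n / mean-one) is display cosmetics only.

## Outcome models

**Continuous endpoints** (change from baseline in daily OFF time, UPDRS
III, PDQ-39 summary and four dimension scores) are analysed by weighted
least squares of the change score on a treatment indicator, study-center
fixed effects and baseline OFF time — the covariance model behind published
least-squares means. With a single treatment coefficient and no
treatment-by-center interaction, that coefficient *is* the LSM difference.
The default standard error is the HC0 robust sandwich with weights treated
as fixed; `se_method = "bootstrap"` re-estimates the weights in every
patient-level resample. The sandwich is invariant to weight rescaling (the
bread scales as $1/c$ and the meat as $c^2$), and with unit weights the fit
reduces coefficient-for-coefficient to ordinary ANCOVA.

**Safety endpoints** (AE, SAE, DCAE flags) use a weighted 2×2 table of
*effective counts*: within each arm the weight sums by event status are
rescaled to total that arm's ESS, and the log odds ratio
$\log(ad/bc)$ gets $\mathrm{se} = \sqrt{1/a + 1/b + 1/c + 1/d}$. The ESS
rescaling keeps the precision honest — raw weight sums would overstate the
information in a heavily weighted sample — and makes the contrast invariant
to weight rescaling. A zero cell triggers the Haldane–Anscombe +0.5 on all
four cells, flagged in the output. A weighted logistic regression is a
reasonable alternative; the effective-count table was chosen because it
matches how event rates are reported and admits a closed-form oracle.

## The Bucher combination

For contrasts $d_1 \pm s_1$ (IPD, weighted) and $d_2 \pm s_2$ (published),
anchored on the same placebo:

$$\hat\Delta = d_1 - d_2, \qquad
  s = \sqrt{s_1^2 + s_2^2}, \qquad
  \mathrm{CI}_{95} = \hat\Delta \pm 1.959964\, s,$$

with a two-sided normal p-value. Odds-ratio endpoints combine identically
on the log-odds scale and are exponentiated afterwards. The normal quantile
is fixed (no t-correction) because the AgD degrees of freedom are unknown;
the published CIs are consistent with 1.96. Orientation is active-minus-
comparator throughout, so negative differences favor the IPD treatment on
all (lower-is-better) efficacy endpoints.

Feeding the two trials' published per-endpoint contrasts through this
combination reproduces the published indirect mean differences exactly at
one decimal, and the CI bounds that are stable under input rounding
(OFF-time lower bound −1.40; UPDRS III −5.28/−0.52; mobility −7.84/0.84).
Two published bounds are *not* recoverable from the rounded inputs: the
OFF-time upper bound prints −0.02 where the rounded inputs give −0.002
(−0.00 at two decimals), and the PDQ-39-family bounds are off by 0.01–0.05
— the original analysis evidently carried unrounded intermediates. We do
not force agreement there.

Two more published numbers deserve a note. First, the per-trial safety
values are printed ambiguously; reading them as odds ratios with SEs on the
log-odds scale reproduces the published combined SAE (1.1) and DCAE (0.7)
odds ratios at printed precision, but gives 1.73 for AEs where 1.6 is
printed. Both readings are documented; neither is forced in tests. Second,
the Wald test on the printed pooled BMI summaries (23.9, SD 3.0, n = 305
vs 23.1, SD 3.2, n = 321) gives z = 3.23, p = 0.0012 — significant at the
table's own p < 0.01 marking, though the accompanying text reports
p < 0.001, which would require unrounded means.

## Balance tables

`balance_table()` reproduces the before/after-matching baseline tables:
Wald tests from summary statistics for continuous covariates, and for
binary covariates a Pearson chi-square without continuity correction when
all expected counts are ≥ 5, otherwise the Fisher exact test (two-sided by
summation of tables no more probable than the observed — `stats::fisher.test`'s
rule). Counts behind an aggregate proportion are reconstructed as
$\mathrm{round}(p \times n)$, as AgD reports print percentages only. After
matching, the ESS replaces $n$ in every test (the publications are silent
on this; using raw $n$ would overstate the precision of a weighted sample),
and the weighted SD uses the ESS-based small-sample factor
$\mathrm{ESS}/(\mathrm{ESS}-1)$ so unit weights reproduce the ordinary
unbiased SD.

## What the simulator emulates — and what it does not

`trial_scenario()` / `simulate_trial()` generate a two-arm multicenter
trial. Defaults emulate the IPD-like trial: 151/154 patients per arm, age
61.6 (9.3) years, 58% male, BMI 23.9 (3.0) kg/m², baseline OFF time 5.7
(3.0) h/day truncated at the 1.5 h/day inclusion threshold, and a
−1.1 h/day true OFF-time effect. `make_paired_scenarios()` adds a
comparator with the observed cross-trial shift (62.2 (9.4) years, 66%
male, BMI 23.1 (3.2), OFF 6.1 (2.6) h/day, threshold 1.0 h/day; arms
163/158). Choices the publications do not determine, fixed once:

* **Endpoint model.** change = effect·treat + slope·OFF₀ +
  Σ modifier·(covariate·treat) + center effect + noise. Residual SDs
  (2.4 h for OFF change up to ≈17 points for PDQ-39 stigma) are
  back-computed from the published per-arm standard errors at ≈150
  patients/arm. Baseline-OFF slopes default to small negative values (more
  OFF time at baseline, more room to improve).
* **Truncation** by rejection sampling (cap 1,000 retries per patient),
  preserving the configured mean/SD shape near the untruncated case; age
  and BMI are truncated at physiologic bounds (18–90 years, 13–45 kg/m²).
  Note the truncation means the *realized* OFF-time mean exceeds the
  configured normal mean; tests compare against the truncated-normal
  closed form.
* **Centers.** 10 centers (the trial is multicenter but the count is
  unreported), effects drawn once per scenario from N(0, 0.2·noise SD).
* **Correlation.** Endpoints share a latent per-patient severity factor
  (loading 0.3) so PDQ-39 dimensions co-move; marginal SDs are preserved.
* **Safety.** Bernoulli flags with arm-specific probabilities (defaults
  0.50/0.60 AE, 0.04/0.06 SAE, 0.05/0.04 DCAE), independent of the
  efficacy residuals.
* **Effect modification** defaults to zero — the published baselines give
  no modifier coefficients. The calibration experiments switch it on
  explicitly (below).

The generator matches first and second moments and the qualitative design
of the real trials, nothing more: no patient-diary time course, no
dropout or missingness, no AE-severity structure, no attempt to mimic the
real joint covariate distribution beyond independent marginals. Passing
tests therefore demonstrate the *method's* properties under a faithful
stylized design, not agreement with the proprietary patient-level data —
in particular the published ESS of 271 from N = 305 depends on the real
covariate joint distribution and is checked only qualitatively (ESS < N
under the published shift; `scripts/acceptance.R` reports the ESS its own
synthetic run produces).

## Calibration experiments

Two simulation studies back the pipeline (sizes chosen to make Monte-Carlo
error a small fraction of the quantities being checked):

* **Null coverage.** 500 paired replicates at the published trial sizes
  with shared effects and no modification — the true anchored difference
  is 0 by construction. The 95% Bucher CI for the primary endpoint should
  miss 0 about 5% of the time; the suite requires 4–6%.
* **Modifier bias.** 200 paired replicates with effect modification of the
  OFF-time effect by sex (+1.0 h/day for men), BMI (−0.15 h/day per
  kg/m²) and baseline OFF time (+0.8 h/day per hour) under the observed
  covariate shift. The modifiers are sized so the naive Bucher bias
  (≈0.25 h/day, an order of magnitude above simulation noise) is the kind
  of distortion the method exists to remove — sex modification in
  particular is motivated by the IPD trial's own post-hoc sex-difference
  signal. The suite requires the MAIC bias to be under 25% of the naive
  bias.

## Degenerate inputs and numerical conventions

* Exact balance is asserted at $10^{-8}$ relative tolerance; the solver
  typically reaches $10^{-13}$ in 4–6 Newton steps on four covariates.
* Covariates constant in the IPD are tolerated only if already on target;
  constant-and-off-target is reported as infeasible at centering time.
* Zero weights are allowed (patients drop out of the weighted fits); a
  whole arm at zero weight is an error.
* Missing matched covariates: complete-case with a logged count
  (`drop_incomplete()`), mirroring the absence of any reported missingness
  handling.
* All artifacts are UTF-8; numbers are serialized at full precision and
  rounded only for display. Pipeline runs are deterministic given
  (config, seed): the global seed fans out as IPD = seed,
  comparator = seed + 1, bootstrap = seed + 2.

## Known limitations

Unanchored MAIC, simulated treatment comparison, matching on variances or
higher moments, network meta-analysis over more than two trials,
random-effects combination and multiplicity adjustment across endpoints
are all out of scope. The bootstrap treats the AgD side as fixed, as the
data situation dictates: uncertainty in the comparator's published
summaries cannot be resampled.
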