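# anchormaic

Anchored matching-adjusted indirect comparison (MAIC) for two treatments
studied in separate placebo-controlled trials, with a paired-trial
simulator for validating every stage of the pipeline.

## The problem

Safinamide and rasagiline, both MAO-B-inhibitor adjuncts to levodopa for
Parkinson's disease motor fluctuations, have each been compared with
placebo in a randomized trial of Chinese patients — but never with each
other. With individual patient data (IPD) from one trial and only
published aggregate data (AgD) from the other, an *anchored* indirect
comparison goes through the shared placebo arm. Its validity hinges on
the two trial populations agreeing on effect modifiers, and they visibly
do not (male proportion 58% vs 66%, BMI 23.9 vs 23.1 kg/m², baseline OFF
time 5.7 vs 6.1 h/day).

MAIC, per NICE DSU Technical Support Document 18, reweights the IPD so
its baseline summaries match the comparator's published means and
proportions. With centered covariates
$\tilde{x}_i = x_i - \bar{x}_{\mathrm{AgD}}$, the weights
$w_i = \exp(\tilde{x}_i^\top \beta)$ take the method-of-moments $\beta$
minimizing $Q(\beta) = \sum_i \exp(\tilde{x}_i^\top \beta)$, whose
stationarity condition is exact mean matching. The effective sample size
$(\sum w_i)^2 / \sum w_i^2$ prices the reweighting. Weighted ANCOVA
(treatment + center + baseline OFF time, robust sandwich SEs) gives the
IPD trial's least-squares-mean contrast per endpoint; weighted 2×2
effective-count tables give safety log odds ratios; and the Bucher rule

$$\hat\Delta = d_1 - d_2,\qquad s = \sqrt{s_1^2 + s_2^2},\qquad
\mathrm{CI} = \hat\Delta \pm 1.96\,s$$

combines each IPD contrast with the comparator's published contrast into
the anchored mean difference (or odds ratio, on the log scale).

See `vignettes/anchored-maic.Rmd` for the full model, the solver, and
every design choice.

## Worked example

Recombining the two trials' published arm-vs-placebo contrasts
(`safinamide_rasagiline_example()` carries the published numbers):

```r
library(anchormaic)
ex  <- safinamide_rasagiline_example()
res <- compare_all(ex$ipd_contrasts, ex$comparator_agd)
tidy(res)
#>    endpoint             scale estimate ci_low ci_high se_combined      z p_value
#>  1 off_change           diff…   -0.7   -1.40   -0.002       0.356 -1.97    0.049
#>  2 updrs3_change        diff…   -2.9   -5.28   -0.524       1.21  -2.39    0.017
#>  3 pdq39_summary_change diff…   -2.2   -5.25    0.849       1.56  -1.41    0.157
#>  ...
#>  9 sae                  odds…    1.07   0.197   5.81        0.863  0.08    0.936
#> 10 dcae                 odds…    0.667  0.136   3.26        0.809 -0.501   0.616
```

Safinamide beats rasagiline on OFF time by 0.7 h/day (95% CI −1.40 to
−0.002) and on UPDRS III by 2.9 points; the quality-of-life differences
are directionally favorable but not significant, and the safety odds
ratios straddle 1 — the published conclusions, reproduced from the
published per-trial inputs.

The same pipeline runs end to end on synthetic paired trials with known
truth (here the comparator's true OFF-time effect is set to −0.5 against
the IPD trial's −1.1, so the true anchored difference is −0.6):

```r
pair <- make_paired_scenarios(comparator_effects = c(off_change = -0.5))
ipd  <- simulate_trial(pair$ipd, seed = 42)
agd  <- aggregate_trial(simulate_trial(pair$comparator, seed = 43),
                        endpoints = "off_change")
w <- estimate_weights(ipd, agd)
glance(w)
#>       n ess_total ess_anchor ess_active converged iterations gradient_norm
#>     305      274.       138.       136. TRUE               4      1.05e-13
tidy(bucher_difference(weighted_ancova(ipd, w, "off_change"),
                       agd$contrasts[1, ]))
#>   endpoint   scale      estimate ci_low ci_high se_combined     z p_value
#> 1 off_change difference   -0.914  -1.68  -0.146       0.392 -2.33  0.0196
```

Matching the 305-patient trial to the shifted comparator baselines costs
effective sample size (ESS 274 of 305), the weighted pooled covariate
means hit the targets to machine precision (`check_balance()`), and the
anchored estimate −0.91 covers the construction truth −0.6 within its CI.
`balance_table()` reproduces the before/after baseline tables,
`autoplot()` draws weight distributions, balance dot plots and forest
plots, and `run_pipeline(run_config(...))` writes the whole artifact set
(weights CSV, balance TSV/JSON, contrasts JSON, results table, run log)
deterministically from one seed.

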