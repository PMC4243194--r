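# crtpair

Cluster-level analysis of **pair-matched cluster randomized trials (CRTs)
with binary survey outcomes**, built for community-intervention evaluations
in which a handful of communities (e.g. 8 sites in 4 matched pairs) are
randomized and outcomes are composite indicators constructed from
individual questionnaire items — the design used by community mobilization
trials on intimate partner violence (IPV) and HIV-risk behaviour.

## Who it is for

Biostatisticians and epidemiologists who need the classic Donner–Klar
two-stage ("cluster summary") machinery end to end: from item-level survey
records to publication-style risk-ratio tables, with a synthetic trial
generator so the whole pipeline is testable by simulation even when the
original trial data are not deposited.

## The statistics

For each composite outcome the analysis reduces individual records to one
summary per site and works on the log scale:

- **Crude risk ratio.** Site prevalences `p_i = n1_i / n_i` enter a
  weighted ANOVA: `log p_i ~ arm + pair`, with weights inversely
  proportional to the delta-method variance of `log p_i`, i.e.
  `w_i = n_i p_i / (1 − p_i)`. `RR = exp(arm coefficient)`; the 95% CI uses
  a t quantile on the residual df `2P − P − 1` (3 when `P = 4` pairs). A
  zero numerator receives a 0.5 continuity correction so the log exists.
- **Adjusted risk ratio (observed/expected).** A logistic model
  `outcome ~ age + marital status + baseline EA prevalence` is fitted to
  control-arm individuals and predicts each site's expected count `E` in
  the absence of intervention; site `log(O/E)` ratios (weights `O`) enter
  the same pair + arm ANOVA.
- **Sensitivity t-test.** The same site log measures compared by an
  equal-variance unpaired t-test on `2P − 2` df.
- **Between-cluster variation.** `k̂² = max(0, (s² − p̄(1−p̄)/ñ) / p̄²)`,
  the coefficient of variation of true prevalence between clusters after
  removing binomial sampling noise (`ñ` = harmonic mean denominator).
- **Exposure analysis.** Threshold intervention exposure (all three
  contact routes at least once, or one route once plus a different route
  at least a few times) is modelled by logistic propensity scores;
  exposed respondents are matched 1:1 without replacement to controls by
  an exact assignment algorithm, and the adjusted pipeline reruns on the
  matched subset.
- **Design precision.**
  `var(log RR̂) = (1/c)[(1−p₁)/(p₁n) + k²] + (1/c)[(1−p₀)/(p₀n) + k²]`.

## Worked example

```r
library(crtpair)
ds <- simulate_trial(sim_config(), seed = 7)   # 4 pairs, 150/sex/site FU
spec <- default_outcome_specs()$physical_ipv
s <- summarize_sites(ds, spec)
crude_effect(s)
adjusted_effect(ds, spec)
estimate_cv(s[s$arm == "control", ], arm_set = "control_only")
precision_estimate(c = 4, n = 150, p0 = 0.22, rr = 0.5, k = 0.2)
```

prints (default generator: past-year physical IPV, 22% control prevalence,
true RR 0.48, k = 0.45):

```
<crt_effect> physical_ipv [crude]: RR 0.488 (95% CI 0.425 to 0.560), df = 3
<crt_effect> physical_ipv [adjusted]: RR 0.493 (95% CI 0.438 to 0.555), df = 3
<cv_estimate> physical_ipv (followup, control_only): k = 0.166
design CI: 0.50 (0.34 to 0.74)
```

The crude/adjusted lines are the cluster-level prevalence ratios
(intervention vs control) with t-based CIs on 3 df; `k` is the estimated
between-cluster coefficient of variation among the four control sites of
this particular replicate; the design line is the CI width one should
expect from such a trial before running it.

Full report tables (one row per outcome with baseline/follow-up `n1/n (%)`
cells per arm, crude/adjusted/t-test RRs, control-arm k):

```sh
Rscript -e 'crtpair::cli_run()' simulate --seed 7 --out trial.csv
Rscript -e 'crtpair::cli_run()' analyze --data trial.csv --report report/ --seed 7
Rscript -e 'crtpair::cli_run()' match --data trial.csv --report report/
```

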