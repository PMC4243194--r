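---
title: "Cluster-level analysis of pair-matched trials: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-level analysis of pair-matched trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtpair)
```

# The problem

Community mobilization interventions against intimate partner violence
(IPV) and HIV risk are evaluated by randomizing *communities*, not people.
With very few clusters — here eight sites in four matched pairs — the only
analysis that honestly respects the randomization unit is a two-stage
cluster-summary analysis: reduce each site to one number, then compare
arms with the site as the unit of inference. This package implements that
pipeline from raw questionnaire items upward, together with the design and
simulation tooling needed to validate it.

# Composite outcomes

Six primary indicators are built from item-level responses. Each outcome
is a denominator predicate plus an item set and a rule:

| outcome | denominator | rule |
|---|---|---|
| `accept_violence` | all respondents (reported by sex) | any of 12 justification scenarios answered yes |
| `accept_refuse_sex` | all respondents (by sex) | the single refusal item yes |
| `physical_ipv` | women partnered (regular/casual) in past year | any of 7 acts |
| `sexual_ipv` | same | either of 2 acts |
| `community_response` | women whose *constructed* physical-or-sexual IPV value is true | helped gate yes AND any of 6 response types yes |
| `concurrency` | non-polygamous men with a regular partner in past year | the single concurrency item yes |

**Missingness.** An any-yes outcome is true on any yes, false only when
*every* item was answered no, and missing otherwise. This is the
conservative reading: a respondent who skipped some items and reported no
yes is not assumed outcome-free. The community-response conjunction uses
three-valued logic: a definite no on either side settles the value even if
the other side is missing. Denominators count only respondents with a
non-missing value, so distinguishing "not asked" from "answered no" in the
data files matters; CSV empty strings are parsed as missing, never as no.

**Attitude items.** The attitude indicators are treated as follow-up-only
measures (the instrument was revised between rounds); their baseline
namesakes exist in the data solely to serve as the closest-proxy covariate
for the adjustment model. The same proxy mechanism covers the
community-response outcome, whose adjustment covariate is a baseline
disclosed-and-helped measure.

# The estimators

## Crude

Stage one: per site, prevalence $p_i = n_{1i}/n_i$. Stage two: weighted
least squares of $\log p_i$ on an intervention indicator and pair
indicators. Weights are the inverse delta-method variance of $\log p_i$
under binomial sampling, $w_i = n_i p_i/(1-p_i)$, so larger and
higher-prevalence sites count more; the fit is invariant to rescaling all
weights. $\widehat{RR} = \exp(\hat\beta_{\text{arm}})$; the CI uses
$t_{P-1}$ (3 df at $P=4$), the residual df of a model with $2P$
observations and $P+1$ parameters. Fewer than two pairs is an error —
there are no residual df to estimate uncertainty from.

## Adjusted (observed/expected)

An individual-level logistic model `outcome ~ age + marital status +
baseline EA prevalence` is fitted to control-arm follow-up respondents
(complete-case on the three covariates) and predicts, for every site in
both arms, the expected count $E_i$ = sum of predicted probabilities over
that site's eligible respondents. The site measures $\log(O_i/E_i)$ then
enter the identical pair + arm weighted ANOVA. The weight is the
continuity-corrected $O_i$: treating $E_i$ as fixed, the delta-method
variance of $\log O_i$ is $1/O_i$. Whether the original analyses reused
prevalence-based weights here is not documented anywhere we could check;
the choice is isolated in one place and pluggable.

## Numerical edge cases

- **Zero events** in a site: 0.5 is added to the numerator only (the
  denominator is untouched) so the log exists; the flag
  `continuity_applied` and the analysis log record every such correction.
- **Prevalence 1** in a site: the log-scale variance is 0 and the weight
  infinite; this is an error rather than a silent cap.
- **Aliased covariates** (e.g. a baseline prevalence constant across EAs):
  the aliased coefficient is dropped (set to 0), reproducing
  intercept-only behaviour for that term.
- **Non-convergence** of the logistic fit falls back to a ridge-penalized
  IRLS ($\lambda = 10^{-4}$) with a warning; an outcome constant in the
  control arm raises a separation error instead of being regularized into
  an answer.
- **Ties** everywhere are broken deterministically (respondent id order);
  every stochastic operation takes an explicit seed and restores the
  caller's RNG state.

## Sensitivity t-test and k

The unpaired t-test compares the same site log measures between arms with
pooled variance on $2P-2$ df, trading the pairing for df — useful when
pair matching was weak. The between-cluster coefficient of variation is
estimated as
$\hat k^2 = \max\{0, (s^2 - \bar p(1-\bar p)/\tilde n)/\bar p^2\}$,
removing the within-site binomial component ($\tilde n$ = harmonic mean
denominator) from the empirical variance of site prevalences. Truncation
at zero means $\hat k$ is reported as exactly 0 whenever sampling noise
explains all observed spread — and, conversely, that $\hat k$ is not
mean-unbiased near $k = 0$.

# Propensity-matched exposure analysis

Threshold exposure — all three contact routes (materials, activities,
multimedia) at least once, or one route at least once plus a *different*
route at least a few times — is modelled among intervention-arm
respondents by logistic regression on demographic, residence and
neighbourhood covariates. Matching is 1:1 without replacement, minimizing
the total absolute difference in the *logit* score (the standard scale for
propensity matching). Because the score is scalar and the cost is L1, the
assignment problem has an optimal monotone (non-crossing) solution, so a
sort-order dynamic program finds the exact global optimum — including the
partial-matching case where one side is larger — without a general
Hungarian solver; the test suite verifies equality with exhaustive
enumeration on all instances up to 6×6. This replaces variable-ratio
"full matching": 1:1 optimal matching is deterministic, simpler, and
sufficient to exercise the downstream pipeline, but it discards
unmatched controls, which full matching would have used. Matching can be
restricted within matched pairs (`within_pair = TRUE`); the default
instead includes pair as a model covariate. No caliper is applied by
default; one is available.

# Design-stage precision

`precision_estimate()` uses the standard unmatched-CRT variance of a log
risk ratio, $(1/c)[(1-p_1)/(p_1 n) + k^2] + (1/c)[(1-p_0)/(p_0 n) + k^2]$,
with normal quantiles — the design-stage convention, deliberately not the
$t_3$ quantile of the analysis (at design time $k$ itself is a guess and
matched-pair efficiency is unknowable). A matched-pair variant of $k$
(within-pair CV) is intentionally not implemented: the estimates this
supports are unmatched-study values.

# What the generator emulates — and what it does not

`simulate_trial()` produces the stated world of the trial this package is
patterned on: 8 sites in 4 pairs; 150 respondents per sex per site at
follow-up, 100 at baseline; follow-up control prevalences, risk ratios and
between-cluster CVs per outcome at the reported values (e.g. physical IPV:
22% control prevalence, RR 0.48, k = 0.45; concurrency: 45%, 0.57, k = 0);
covariate marginals matching the reported respondent characteristics
(age ≈ 29 ± 7.8 truncated to 18–49, ~55% married/cohabiting, ~80%
partnered in the past year); and exposure rates of 91%/68% (men/women,
any route) and 85%/53% (threshold) in the intervention arm versus 2%/1%
contact in controls (exposure misclassification only — control exposure
carries no outcome effect).

Mechanics and the choices behind them:

- **Logit-normal cluster effects**, moment-matched by quadrature so the CV
  of true site prevalences equals the target $k$ exactly (a bounded
  outcome caps feasible $k$ at $\sqrt{(1-p)/p}$; infeasible requests
  error). Logit-normal rather than beta-binomial because it composes
  additively with the individual-level logistic covariate effects the
  adjustment model assumes.
- **Pair structure**: half of the between-site logit variance (default
  `pair_share = 0.5`) is shared within a matched pair — pairs resemble
  each other, which is what pair matching exploits.
- **Rounds**: site effects correlate 0.7 across rounds and small
  enumeration-area effects (SD 0.1 logit) persist entirely, so the
  baseline EA prevalence covariate is genuinely predictive, as the
  adjustment model requires. These two constants are realism choices made
  once; nothing in the reported values pins them down.
- **Intervention effect** is injected on the risk-ratio scale
  ($p \mapsto RR \cdot p$ per site, capped at 0.995) because the estimand
  is a prevalence ratio; the cap means near-ceiling outcomes (e.g. male
  sex-refusal acceptability at 0.75 × 1.31) realize slightly less than the
  nominal RR.
- **Items are back-filled** from the drawn composite value (one uniformly
  chosen item yes, the rest no; all no when false), so re-evaluating the
  composites reproduces the generated values exactly — the
  generation/evaluation round trip is a tested invariant.

Not emulated: within-respondent correlation across items (a respondent
with one violent act reported is not more likely to report a second),
partial item response among eligibles, household structure (one respondent
per household by construction), covariate dependence beyond independent
marginals, and any longitudinal linkage of individuals across rounds (the
design is repeat cross-sectional). A green simulation test therefore
establishes that the *estimators* behave as claimed under the assumed
cluster model — not that real questionnaire data satisfy that model.

# What the simulations establish

The test suite recomputes, each run: exact agreement (1e-10) of both
ANOVA estimators with brute-force weighted normal-equation solutions on
all small instances; invariance to pair relabeling, weight rescaling, and
arm swapping (RR → 1/RR with reversed CI); 95% CI coverage of the null in
[0.90, 0.99] over 500 simulated trials; and recovery of $k \in \{0,
0.25\}$ and of known logistic coefficients.

One property deserves honest emphasis: with estimated weights
$w_i = n_i \hat p_i/(1-\hat p_i)$, the weight is positively correlated
with $\hat p_i$, which biases the weighted mean of $\log \hat p_i$ upward,
more strongly in the low-prevalence arm. In the recovery scenario (true
RR 0.5 at 22% control prevalence, ~125 eligible women per site) the suite
measures a mean log-RR bias of about +0.03 (crude) and +0.025 (adjusted)
— a ~3% relative overestimate of the RR — while the same world analyzed
with equal weights shows no detectable positive bias. This is a
small-sample property of the inverse-variance-weighted cluster-summary
estimator itself, shared by any faithful implementation; at these site
sizes it is well inside the estimator's noise (empirical SE ≈ 0.17) but
detectable over 500 replicates, and the corresponding acceptance check is
deliberately left failing rather than loosened.

# Known limitations

- No individual-level GLMM/GEE alternatives, survey weights, or
  multiple-testing adjustment — all out of scope by design.
- The t-based CI on 3 df is honest but wide; single-trial inference with
  four pairs is intrinsically imprecise.
- Matching discards surplus controls; effect estimates on the matched
  subset answer a different (per-protocol-flavoured) question than the
  intention-to-treat pipeline.
- CSV numerics round-trip exactly at up to 15 significant digits (R's
  default character conversion); generator output is rounded well below
  that.
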