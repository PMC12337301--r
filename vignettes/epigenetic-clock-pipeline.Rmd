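---
title: "Methods: epigenetic clock construction and aging-rate analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic clock construction and aging-rate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`epiclock` implements a complete analysis path from pooled
bisulfite-sequencing CpG counts to an epigenetic clock, treatment-specific
epigenetic aging rates, and a survival-based interpretation of epigenetic
age differences. This vignette is the package's account of the statistics
behind each stage: the models and their assumptions, the tunable
parameters and why their defaults are what they are, the design of the
synthetic-data generator, and the numerical conventions that matter when
reproducing results.

## The data and their statistical unit

The experimental unit throughout is the *library*: DNA pooled from several
individuals (10 by default) sequenced together after bisulfite conversion.
For CpG site $i$ and library $\ell$ the data are a methylated read count
$m_{i\ell}$ and a total count $n_{i\ell}$. A total of zero means *no
coverage* and is treated as missing, never as 0% methylation. Ages are
chronological days post-emergence; the default design samples two
treatment groups at days 6, 12, 18, 24 and 30 with four replicate pools
per cell (40 libraries).

Because each library is a pool, counts are overdispersed relative to
binomial: individuals within a pool differ in methylation state, which
induces an intra-class correlation $\rho$ among reads. All count models in
the package either accommodate this (quasi-binomial fallback in the age
scan) or are calibrated against it (the synthetic generator draws
beta-binomial counts).

## Stage 1: conversion-error calibration

Bisulfite conversion is imperfect: an unmethylated cytosine survives
conversion with small probability $e$ and then reads as methylated. A
fully unmethylated spike-in (lambda phage DNA) measures $e$ directly: the
estimate is the pooled ratio of methylated to total spike-in reads across
all sites and libraries, with per-library ratios reported for QC. Only
one-way error (unmethylated read as methylated) is modelled; there is no
spike-in control for the reverse direction, so over-conversion of
methylated cytosines is ignored.

## Stage 2: methylation calling

A site is called methylated if its counts are inconsistent with the null
hypothesis that *all* apparent methylation is non-conversion noise. Per
site, libraries with coverage below `min_coverage` (default 10 reads) are
excluded; sites with fewer than `min_samples` qualifying libraries
(default: half the libraries) are dropped before testing and do not enter
the multiple-testing family. In the default `"pooled"` mode the qualifying
counts are summed and tested once per site with the one-sided binomial
tail $P(X \ge m \mid n, e)$ — the more powerful choice when libraries are
themselves pools; a `"per_library"` mode instead requires per-library
significance in at least `min_samples` libraries. P-values are
Benjamini–Hochberg corrected across sites at `fdr_q` (default 0.05).
These thresholds are conventional for WGBS rather than prescribed by any
single study, and are exposed in the configuration.

## Stage 3: age-related differential methylation

Each retained site is fit with a binomial GLM (logit link) of
$(m_{i\ell}, n_{i\ell} - m_{i\ell})$ on age in days, and the age term is
tested by a 1-df likelihood-ratio test against the intercept-only model.
Age is continuous (days), matching the downstream clock; treatment is
*not* in the default model — the scan targets age-related sites using all
libraries — but `adjust_treatment = TRUE` adds it to both the null and the
alternative model, and a `libraries =` argument supports control-only
sensitivity scans.

Pooled libraries make the plain binomial LRT anti-conservative: with
coverage $n$ and intra-class correlation $\rho$ the Pearson dispersion is
roughly $1 + (n-1)\rho$, about 1.6 at the generator defaults. The scan
therefore switches to a quasi-binomial F test (statistic divided by the
estimated dispersion, F on 1 and $n-2$ df) whenever the estimated
dispersion exceeds `dispersion_threshold = 1`. Sites whose GLM does not
converge, or whose fitted slope diverges (|slope| > 50 per day, i.e.
separation), are flagged and excluded from the BH family rather than
assigned p = 1. Significance is BH at q ≤ 0.05 by default.

## Stage 4: correlation filter

Clock features should track age *linearly in proportion space* in the
reference condition. The filter computes the Pearson correlation between
methylation proportion and age over control libraries only and keeps sites
with $|r| \ge 0.3$ and uncorrected two-sided $p \le 0.05$ (t test on
$n-2$ df). Sites with undefined correlation (zero variance, or fewer than
three covered control libraries) are excluded with a log entry.
Correlations are unweighted by coverage; the preceding count-based scan
already accounts for coverage, and the filter mirrors the conventional
"Pearson r on proportions" construction.

## Stage 5: the elastic-net clock

The clock is a penalized linear regression of chronological age on
methylation proportions over the filtered sites, minimizing

$$\frac{1}{2n}\sum_\ell (y_\ell - \beta_0 - x_\ell^\top\beta)^2 +
  \lambda\left(\alpha\lVert\beta\rVert_1 +
  \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right)$$

with the mixing parameter fixed at $\alpha = 0.5$. Training uses the
*control* libraries only: the filter is defined on controls, the clock is
then applied to the treated group as a transfer test. (Training on all
libraries is a defensible alternative; control-only keeps the treated
group fully out of model selection, which is what makes the transfer
metrics meaningful.)

Choices that matter for reproducibility:

* **Penalty scale.** Features are standardized internally (1/n standard
  deviations) and the solver is `glmnet`, whose gaussian path also
  standardizes the response internally; the stored $\lambda$ is therefore
  in the field-standard `glmnet` convention. The test suite pins this
  down by matching the solution against an independent coordinate-descent
  implementation of exactly that objective to $10^{-6}$.
* **Grid.** 100 log-spaced $\lambda$ values from $\lambda_{\max}$ (the
  smallest penalty zeroing all coefficients, computed from the
  standardized score) down to $10^{-3}\lambda_{\max}$.
* **Cross-validation.** 10-fold, 3 repeats, the *library* as CV unit
  (pools are the statistical unit; individuals never cross folds because
  they are never observed individually). Folds are stratified by age, and
  any fold assignment that would leave a training split without age
  variation is redrawn. $\lambda^\*$ minimizes the mean over repeats of
  the per-repeat out-of-fold RMSE; ties resolve to the *largest*
  (sparsest) $\lambda$. The final model is refit on all control libraries
  at $\lambda^\*$.
* **Reported control metrics are cross-validated:** $R^2$ and RMSE come
  from the held-out predictions at $\lambda^\*$, averaged over repeats per
  library. $R^2$ is $1 - SS_{res}/SS_{tot}$ against chronological age, so
  it can be negative for a useless model.
* **Prediction** is `intercept + sum(coef * proportion)`. A missing or
  uncovered panel site is an error by default; `impute_missing = TRUE`
  substitutes the training-set mean proportion and logs it.

The panel is the set of nonzero-coefficient CpGs. Along the path the panel
grows as the penalty relaxes, up to transient single-variable active-set
exchanges that coordinate-descent paths genuinely produce; the tests
assert monotonicity up to that caveat.

## Stage 6: aging-rate trajectory

Predicted epigenetic age is modelled by OLS as
`age_epi ~ day * treatment`. The interaction coefficient is the difference
in epigenetic aging rates (days of epigenetic age per chronological day),
tested on $n - 4$ residual df (36 for the default 40-library design). Day
is centered at the first sampling day internally for conditioning; all
reported intercepts are back-transformed to the day-0 scale.

For the training (control) group the trajectory uses the *held-out
cross-validated* predictions, and for the treated group the direct
predictions — the same convention as the validation metrics. In-sample
control predictions would be overfit: their residuals understate the
prediction error while the shared clock-estimation error correlates them,
which biases the model's standard errors downward. With held-out controls
the delta-method confidence interval of the percent slowdown attains its
nominal coverage in the package's replicate tests.

Derived quantities:

* `contrast_at_day(fit, d)` — model-based group means at day $d$
  (estimated marginal means), their difference and its t test from the
  coefficient covariance (pooled residual variance, as a single OLS model
  implies). Contrasts at different days are not multiplicity-adjusted.
* `percent_slowdown(s_c, s_t)` $= (1 - s_t/s_c)\times 100$;
  `slowdown_ci()` adds a delta-method CI on the trajectory's residual df.
* `convergence_day(fit)` — the intersection of the two fitted lines,
  $(b_{0,2}-b_{0,1})/(s_1-s_2)$; slopes equal within $10^{-12}$ return
  `NA` flagged `"parallel"` (or `"identical"`).
* `extrapolate_group_age()` — projects a group mean along its fitted rate.

No heteroscedasticity correction is applied by default (plain linear-model
t statistics); mixed-effects or spline trajectories are out of scope.

## Stage 7: survival and the hazard translation

Kaplan–Meier curves are computed per group with Greenwood variance and
log-log 95% bands; the median is the smallest time with $\hat S \le 0.5$
and its CI comes from where the band crosses 0.5. The treatment effect is
a Cox proportional-hazards fit with Efron tie handling — daily monitoring
guarantees heavily tied event times, where Efron is the accurate standard
— and a two-sided Wald test.

The hazard translation asks: *if* the treatment's survival benefit (hazard
ratio $HR$) were entirely mediated by a $\Delta$-day reduction in
epigenetic age, under a hazard that rises exponentially with epigenetic
age, what per-day hazard increment does that imply? Then
$\beta = -\ln(HR)/\Delta$ and each epigenetic day multiplies the hazard by
$e^\beta$, reported as $(e^\beta - 1)\times 100$ percent. This is an
interpretive identity, not a fitted model: hazard is deliberately not
regressed on per-individual epigenetic age (pools, not individuals, carry
the methylation measurements).

## The synthetic generator: what it emulates, and what it does not

`generate_methylation_dataset()` plants a known truth under the default
study design. For clock CpG $i$ in group $g$ at age $a$, the latent
proportion is

$$p_{i\ell} = \mathrm{logit}^{-1}\!\big(b_i + s_i \, a^*_g(a)\big),
\qquad a^*_g(a) = r_g\,(a + o_g),$$

with $r_g$ the treatment rate ratio (1 for controls) and $o_g$ the
intercept offset in days (0 for controls). The latent epigenetic age
$a^*$ is *defined* as the age at which the control trajectory matches the
library's expected clock methylation, so a control-trained clock estimates
exactly $a^*$ — the generator's truth and the clock's output share a
scale. Null CpGs have $s_i = 0$. Observed counts add one-way conversion
error ($p' = p + (1-p)e$) and are beta-binomial with intra-class
correlation $\rho$ on negative-binomial coverage floored at one read.

Default calibration (chosen once, as the package's reference scenario):

* 50 clock CpGs among 1,000; treatment rate ratio 0.708 (a ~29% slower
  epigenetic aging rate) and intercept offset +2.8 d — effect sizes of the
  magnitude reported for diapause-induced aging plasticity in insects.
* Clock baselines uniform on logit $[-1, 1]$: age-drifting CpGs sit at
  intermediate methylation, since a site near 0 or 100% has no room to
  drift; null baselines span logit $[-2, 2]$.
* Clock drift magnitudes uniform on 0.05–0.10 logit/day, random sign:
  clock-panel-grade sites whose total drift over the 24-day window is
  1.2–2.4 logit. A power calculation at coverage 30, $\rho = 0.02$, 40
  libraries and the ~0.85 slope attenuation induced by scanning both
  treatment groups puts per-site detection power above 90% across this
  range, which is what makes planted-truth recovery a sharp test rather
  than a coin flip.
* Coverage: negative-binomial, mean 30, dispersion 0.2; non-conversion
  0.005 with a 1% unmethylated spike-in; $\rho = 0.02$ for pools of 10.

The survival generator draws exponential (optionally Weibull) event times
calibrated to a true hazard ratio of 0.35 with cohort sizes 101 and 71.
Exponential groups cannot simultaneously match that hazard ratio and the
22- vs 30-day medians such a ratio might accompany in real, non-constant
hazards; the scenario targets the hazard ratio, so simulated medians are
wider apart than real ones would be.

What the generator deliberately does **not** emulate — and what passing
tests therefore do not establish about real data: genomic context (all
sites are independent; no neighbour correlation, no regions), truly
unmethylated genomic CpGs (all planted sites are methylated above the
error floor, so the calling stage's discrimination is exercised separately
with error-only fixtures), read- and alignment-level artefacts, the
diapause period itself (ages are adult days; the treatment enters only as
a rate ratio and an offset), and any nonlinearity of the aging trajectory.

## Numerical conventions and degenerate inputs

* Binomial tails are exact (`pbinom`), matched to brute-force summation to
  $10^{-12}$ in tests; BH is `p.adjust`.
* Bismark coverage positions are 1-based inclusive; BED exports are
  0-based half-open. Opposite-strand CpG counts are assumed pre-merged.
* Coordinate site ids (`contig:pos`) survive write→read round trips
  exactly, counts included.
* The Cox Newton iterations run to a $10^{-9}$ tolerance; monotone
  likelihoods are flagged, not silently reported.
* Degenerate inputs fail loudly: zero spike-in coverage, all-censored
  cohorts at time zero, rank-deficient trajectory designs (the collinear
  term is named), zero-variance validation ages, missing panel sites.
* Every random step (generation, fold assignment) is governed by one seed;
  a pipeline seed fans out to per-stage seeds by hashing the stage name,
  so stages are independently reproducible and a rerun is byte-identical.

## Problem sizes used by the test suite

The suite validates at deliberately modest scales: 1,000-site matrices for
scan-level properties (recovery, false-discovery control), 100 replicates
of a 250-site generate→filter→fit→predict→trajectory chain for the
slowdown coverage and slope-ordering properties, 10,000-per-group cohorts
for Cox consistency, and $10^5$ draws for distributional checks. These
sizes give the Monte-Carlo assertions comfortable margins while keeping a
full run in the low minutes on one CPU.

## Known limitations

* Per-site GLMs are independent; no spatial smoothing or region calling.
* The quasi-binomial dispersion is estimated per site on few residual df
  and is itself noisy; a hierarchical dispersion model would be stronger.
* The clock is linear in proportions with a single fixed $\alpha$;
  alternative learners are out of scope.
* The hazard translation is an identity under an assumed exponential
  hazard–age link, not an estimate with uncertainty.
* Transfer metrics for the treated group inherit any control-specific
  feature-selection bias; they are reported as direct (not
  cross-validated) application, which is the honest but optimistic-free
  reading.
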