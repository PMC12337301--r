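# epiclock

Build and interrogate DNA-methylation epigenetic clocks from pooled
whole-genome bisulfite sequencing (WGBS), and quantify how a treatment —
such as an early-life developmental arrest — changes the *rate* of
epigenetic aging and, through survival analysis, the mortality hazard.

`epiclock` is aimed at researchers working with short-lived organisms that
have functional DNA methylation systems (insects such as the jewel wasp
*Nasonia vitripennis* are the motivating case), where libraries are pools
of individuals, ages are measured in days, and the question is whether the
methylome's aging trajectory is plastic.

## What it computes

Starting from per-CpG methylated/total read counts (Bismark-style coverage
files) and a sample sheet, the pipeline runs:

1. **Conversion-error calibration** — the bisulfite non-conversion rate
   estimated from an unmethylated (lambda) spike-in as the pooled fraction
   of apparently methylated spike-in reads.
2. **Methylation calling** — per site, a one-sided binomial test of the
   methylated count against the null that all signal is non-conversion,
   Benjamini–Hochberg corrected across sites.
3. **Age-DML scan** — per site, a binomial GLM (logit link) of counts on
   chronological age with a likelihood-ratio test, falling back to a
   quasi-binomial F test whenever the Pearson dispersion exceeds 1 (pools
   are overdispersed); BH across sites.
4. **Correlation filter** — Pearson |r| ≥ 0.3 and uncorrected p ≤ 0.05
   between methylation proportion and age, on control libraries only.
5. **Elastic-net clock** — age regressed on methylation proportions with
   penalty `λ(α‖β‖₁ + (1−α)/2‖β‖₂²)` at fixed α = 0.5, λ selected by
   10-fold, 3-repeat cross-validation minimizing RMSE; the CpGs with
   nonzero coefficients form the clock panel.
6. **Aging-rate trajectory** — OLS of predicted epigenetic age on day ×
   treatment: per-group aging rates, the interaction test, estimated
   marginal means at chosen days, the percent slowdown
   `(1 − slope_trt/slope_ctrl) × 100`, and the day the trajectories
   converge.
7. **Survival** — Kaplan–Meier medians with log-log CIs, a Cox
   proportional-hazards fit (Efron ties) for the treatment hazard ratio,
   and the translation of an epigenetic-age difference Δ into a per-day
   hazard increment via `β = −ln(HR)/Δ`, reported as
   `(e^β − 1) × 100` percent per day.

A synthetic-data module generates the whole study design (2 treatments × 5
timepoints × 4 replicate pools of 10 individuals; clock CpGs drifting at
treatment-specific rates; beta-binomial counts; spike-in; survival
cohorts) with planted ground truth, so every stage is testable end to end.

## Worked example

```r
library(epiclock)
report <- epiclock_demo(seed = 1)   # synthetic end-to-end run
print(report)
```

```
epigenetic clock pipeline report
  funnel: 1000 sites -> 1000 methylated -> 54 age-DML -> 51 filtered -> 29 panel
  conversion error: 0.0046; lambda = 0.01533 (alpha = 0.5)
  control CV:  R^2 = 0.944, RMSE = 2.00 d
  treatment:   R^2 = 0.744, RMSE = 4.29 d
  slopes: control = 0.94438, diapause = 0.84172; slowdown = 10.9% (95% CI -9.5-31.2)
  interaction: t = -1.025, d.f. = 36, P = 0.3121; convergence day -12.5
  survival: HR = 0.251 (0.175-0.360), median extension 242.2%, hazard/day 37.3%
```

Reading the report: of 1,000 simulated CpGs, 54 show significant
age-related differential methylation, 51 survive the control-only
correlation filter, and the cross-validated elastic net keeps a 29-CpG
panel — here all 29 are truly planted clock CpGs. The clock explains 94%
of chronological-age variance in held-out control pools (RMSE 2.0 d) and
74% when transferred to the treated group. The treated group's fitted
epigenetic aging rate (0.84 d/d) is below the control rate (0.94 d/d); a
single 40-library realization estimates the slowdown noisily (10.9%, CI
−9.5 to 31.2%, planted truth 29.2%), which is why the package's validation
aggregates over replicates. The survival block recovers the planted hazard
ratio (0.25, true value 0.35 inside the CI at these cohort sizes).

The same pipeline runs on real data from a YAML config pointing at a
coverage directory, sample sheet and survival CSV
(`run_pipeline("config.yaml")`), or from the shell via the installed
script: `epiclock run --config config.yaml`, `epiclock demo --out dir`
(found at `system.file("exec", "epiclock", package = "epiclock")`).

Analytic helpers are exported directly, e.g.:

```r
percent_slowdown(0.78812, 0.55828)        # 29.2 (% slower epigenetic aging)
median_extension_percent(30, 22)          # 36.4 (% median lifespan extension)
hazard_per_epigenetic_day(0.35, 2.7)      # +47.5% hazard per epigenetic day
```

## Documentation

The methods vignette (`vignettes/epigenetic-clock-pipeline.Rmd`) describes
the statistical model of every stage, the synthetic generator's
assumptions and calibration, and known limitations.
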