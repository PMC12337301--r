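test_that("default design yields 40 libraries and identity latent age for controls", {
  des <- study_design(seed = 5)
  arch <- clock_architecture(n_clock_cpgs = 5, n_null_cpgs = 15)
  sim <- generate_methylation_dataset(des, arch)

  expect_equal(nrow(sim$samples), 40)
  expect_equal(ncol(sim$counts$meth), 40)
  expect_equal(nrow(sim$counts$meth), 20)
  expect_setequal(sim$truth$clock_cpg_ids,
                  sim$truth$sites$site_id[sim$truth$sites$is_clock])
  expect_length(sim$truth$clock_cpg_ids, 5)

  ## reference-group latent epigenetic age is chronological age
  ctrl <- sim$truth$libraries$treatment == "control"
  expect_equal(sim$truth$libraries$latent_age[ctrl],
               sim$truth$libraries$age_days[ctrl])
})

test_that("generation is deterministic in the seed", {
  des <- study_design(seed = 11)
  arch <- clock_architecture(n_clock_cpgs = 3, n_null_cpgs = 10)
  a <- generate_methylation_dataset(des, arch)
  b <- generate_methylation_dataset(des, arch)
  expect_identical(a, b)
  c <- generate_methylation_dataset(study_design(seed = 12), arch)
  expect_false(identical(a$counts$meth, c$counts$meth))
})

test_that("treated-group latent age follows the rate-ratio definition", {
  des <- study_design(seed = 2)
  arch <- clock_architecture(n_clock_cpgs = 2, n_null_cpgs = 2,
                             treatment_rate_ratio = 0.708,
                             treatment_intercept_offset_days = 2.8)
  sim <- generate_methylation_dataset(des, arch)
  lib <- sim$truth$libraries
  d6 <- lib[lib$age_days == 6, ]
  diff6 <- mean(d6$latent_age[d6$treatment == "diapause"]) -
    mean(d6$latent_age[d6$treatment == "control"])
  ## a* = r*(a + o) for the treated group, a for controls
  expect_equal(diff6, 0.708 * (6 + 2.8) - 6, tolerance = 1e-12)
  expect_equal(lib$latent_age[lib$treatment == "diapause"],
               latent_epigenetic_age(lib$age_days[lib$treatment == "diapause"],
                                     2, arch))
})

test_that("no-signal infinite-coverage limit recovers the baseline proportions", {
  des <- study_design(seed = 3)
  arch <- clock_architecture(n_clock_cpgs = 1, n_null_cpgs = 19,
                             slope_logit_range = c(0, 0),
                             clock_baseline_logit_range = c(-1, 1),
                             overdispersion_rho = 0, conversion_error = 0,
                             mean_coverage = 2e6, coverage_dispersion = 0)
  sim <- generate_methylation_dataset(des, arch)
  props <- methylation_proportions(sim$counts)
  expected <- plogis(sim$truth$sites$intercept_logit)
  err <- abs(props - expected)   # recycled per column
  expect_lt(max(err), 1e-2)
  ## and age columns are exchangeable: per-site range across libraries small
  expect_lt(max(apply(props, 1, function(r) diff(range(r)))), 5e-3)
})

test_that("counts are exactly binomial when overdispersion is zero", {
  ## chi-square goodness of fit against Binomial(30, 0.5) on draws whose
  ## coverage happens to equal its mean
  des <- study_design(replicates_per_cell = 20, seed = 17)  # 200 libraries
  arch <- clock_architecture(n_clock_cpgs = 1, n_null_cpgs = 199,
                             slope_logit_range = c(0, 0),
                             baseline_logit_range = c(0, 0),
                             clock_baseline_logit_range = c(0, 0),
                             overdispersion_rho = 0, conversion_error = 0,
                             mean_coverage = 30, coverage_dispersion = 0)
  sim <- generate_methylation_dataset(des, arch)
  k <- sim$counts$meth[sim$counts$total == 30]
  expect_gt(length(k), 2000)
  probs <- dbinom(0:30, 30, 0.5)
  ## pool tail bins so all expected counts are >= 5
  lo <- max(which(cumsum(probs) * length(k) < 5))
  hi <- 31 - lo
  bins <- pmin(pmax(k, lo), hi)
  obs <- table(factor(bins, levels = lo:hi))
  pb <- probs[(lo:hi) + 1]
  pb[1] <- pbinom(lo, 30, 0.5)
  pb[length(pb)] <- pbinom(hi - 1, 30, 0.5, lower.tail = FALSE)
  gof <- suppressWarnings(chisq.test(obs, p = pb))
  expect_gt(gof$p.value, 0.01)
})

test_that("coverage matches its negative-binomial mean", {
  des <- study_design(replicates_per_cell = 20, seed = 29)  # 200 libraries
  arch <- clock_architecture(n_clock_cpgs = 1, n_null_cpgs = 499,
                             mean_coverage = 30, coverage_dispersion = 0.2)
  sim <- generate_methylation_dataset(des, arch)   # 1e5 coverage draws
  expect_gt(length(sim$counts$total), 1e5 - 1)
  expect_lt(abs(mean(sim$counts$total) - 30) / 30, 0.02)
})

test_that("overdispersed counts exceed binomial variance", {
  des <- study_design(replicates_per_cell = 20, seed = 31)
  arch0 <- clock_architecture(n_clock_cpgs = 1, n_null_cpgs = 99,
                              slope_logit_range = c(0, 0),
                              baseline_logit_range = c(0, 0),
                              clock_baseline_logit_range = c(0, 0),
                              overdispersion_rho = 0.1, conversion_error = 0,
                              mean_coverage = 30, coverage_dispersion = 0)
  sim <- generate_methylation_dataset(des, arch0)
  k <- sim$counts$meth[sim$counts$total == 30]
  ## var of beta-binomial(30, .5, rho=.1) = n p q (1 + (n-1) rho) = 29.25
  expect_gt(var(k), 30 * 0.25 * (1 + 29 * 0.05))
})

test_that("spike-in counts reflect only the conversion error", {
  des <- study_design(seed = 4)
  arch0 <- clock_architecture(conversion_error = 0)
  spike0 <- generate_spikein_counts(des, arch0, n_lambda_cpgs = 20)
  expect_true(all(spike0$meth == 0))
  expect_true(all(spike0$sites$contig == "lambda_spikein"))

  arch <- clock_architecture(conversion_error = 0.005, mean_coverage = 30)
  spike <- generate_spikein_counts(des, arch, n_lambda_cpgs = 100)
  expect_equal(dim(spike$meth), c(100, 40))
  total <- sum(spike$total)
  expect_gt(total, 1e5)
  frac <- sum(spike$meth) / total
  se <- sqrt(0.005 * 0.995 / total)
  expect_lt(abs(frac - 0.005), 4 * se)
})

test_that("architecture and design parameters are validated", {
  expect_error(clock_architecture(treatment_rate_ratio = 0), "rate_ratio")
  expect_error(clock_architecture(conversion_error = 0.2), "conversion_error")
  expect_error(clock_architecture(overdispersion_rho = 1), "overdispersion")
  expect_error(clock_architecture(n_clock_cpgs = 0), "n_clock_cpgs")
  expect_error(study_design(timepoints = c(6, 6, 12)), "strictly")
  expect_error(study_design(timepoints = c(-1, 5)), "strictly positive")
  expect_error(survival_scenario(censoring_time = 0), "censoring_time")
})

test_that("survival cohorts recover planted hazards", {
  ## null case: identical hazards, log-HR within 3 SE of zero
  sc0 <- survival_scenario(rates = c(0.05, 0.05),
                           n_per_group = c(500, 500), seed = 8)
  fit0 <- cox_fit(generate_survival_cohort(sc0))
  expect_lt(abs(fit0$log_hr), 3 * fit0$se)

  ## planted HR 0.35 at large n recovered tightly
  sc <- survival_scenario(rates = c(0.05, 0.35 * 0.05),
                          n_per_group = c(10000, 10000), seed = 9)
  cohort <- generate_survival_cohort(sc)
  expect_identical(cohort, generate_survival_cohort(sc))
  fit <- cox_fit(cohort)
  expect_gt(fit$hr, 0.32)
  expect_lt(fit$hr, 0.38)

  ## administrative censoring caps times and flags events
  scc <- survival_scenario(censoring_time = 10, seed = 10)
  cc <- generate_survival_cohort(scc)
  expect_true(all(cc$time_days <= 10))
  expect_true(all(cc$event[cc$time_days < 10] == 1))
})
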