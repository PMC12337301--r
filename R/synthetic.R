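#' Study design for synthetic bisulfite-sequencing experiments
#'
#' Describes a two-treatment, multi-timepoint design in which each
#' treatment x timepoint cell is sequenced as several replicate libraries,
#' each library a pool of individuals. The default mirrors a common insect
#' aging design: 2 treatments x 5 adult ages (days 6, 12, 18, 24, 30) x 4
#' replicate pools of 10 individuals, i.e. 40 libraries.
#'
#' @param treatments character vector of exactly two group labels; the first
#'   is the reference (untreated/control) group.
#' @param timepoints chronological ages in days at sampling; strictly
#'   positive and strictly increasing.
#' @param replicates_per_cell libraries per treatment x timepoint cell.
#' @param pool_size individuals pooled per library.
#' @param seed integer RNG seed used by the generators.
#' @return A `study_design` list.
#' @export
study_design <- function(treatments = c("control", "diapause"),
                         timepoints = c(6, 12, 18, 24, 30),
                         replicates_per_cell = 4,
                         pool_size = 10,
                         seed = 1L) {
  if (length(treatments) != 2 || anyDuplicated(treatments)) {
    fail("exactly two distinct treatment labels are required")
  }
  if (any(!is.finite(timepoints)) || any(timepoints <= 0) ||
      is.unsorted(timepoints, strictly = TRUE)) {
    fail("timepoints must be strictly positive and strictly increasing")
  }
  if (replicates_per_cell < 1 || pool_size < 1) {
    fail("replicates_per_cell and pool_size must be >= 1")
  }
  structure(
    list(treatments = as.character(treatments),
         timepoints = as.numeric(timepoints),
         replicates_per_cell = as.integer(replicates_per_cell),
         pool_size = as.integer(pool_size),
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Architecture of the planted epigenetic clock
#'
#' Parameters of the generative model for synthetic CpG methylation. A
#' minority of "clock" CpGs drift linearly with age on the logit scale; the
#' second treatment modifies that drift through a rate ratio applied to all
#' clock slopes and through an epigenetic-age intercept offset. The
#' remaining CpGs carry no age signal. Observed counts are beta-binomial
#' (pool-level overdispersion) on negative-binomial coverage, with a one-way
#' bisulfite non-conversion error that turns unmethylated reads into
#' apparently methylated ones.
#'
#' The defaults plant 50 clock CpGs among 1,000, a treatment rate ratio of
#' 0.708 (the treated group ages epigenetically ~29% more slowly) and a
#' +2.8-day epigenetic-age offset of the treated group at emergence.
#'
#' @param n_clock_cpgs number of age-responsive CpGs (>= 1).
#' @param n_null_cpgs number of age-independent CpGs.
#' @param baseline_logit_range interval for per-CpG baseline methylation on
#'   the logit scale.
#' @param clock_baseline_logit_range baseline interval for clock CpGs.
#'   Age-drifting CpGs sit at intermediate methylation (a site near 0 or
#'   100% methylation has no room to drift), so their baselines default to
#'   the central `[-1, 1]` logit band while null sites span the full range.
#' @param slope_logit_range interval of per-day logit drift magnitudes for
#'   clock CpGs; each site's sign is drawn at random.
#' @param treatment_rate_ratio multiplier on clock-CpG drift in the second
#'   treatment (> 0; 1 means no rate difference).
#' @param treatment_intercept_offset_days epigenetic-age offset (days) of
#'   the second treatment at emergence.
#' @param overdispersion_rho beta-binomial intra-class correlation in
#'   `[0, 1)`; 0 gives exactly binomial counts.
#' @param conversion_error probability an unmethylated cytosine reads as
#'   methylated (bisulfite non-conversion), in `[0, 0.05]`.
#' @param mean_coverage expected reads per CpG per library.
#' @param coverage_dispersion negative-binomial dispersion of coverage
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson coverage.
#' @return A `clock_architecture` list.
#' @export
clock_architecture <- function(n_clock_cpgs = 50,
                               n_null_cpgs = 950,
                               baseline_logit_range = c(-2, 2),
                               clock_baseline_logit_range = c(-1, 1),
                               slope_logit_range = c(0.05, 0.10),
                               treatment_rate_ratio = 0.708,
                               treatment_intercept_offset_days = 2.8,
                               overdispersion_rho = 0.02,
                               conversion_error = 0.005,
                               mean_coverage = 30,
                               coverage_dispersion = 0.2) {
  num1 <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)
  if (!num1(n_clock_cpgs) || n_clock_cpgs < 1) {
    fail("n_clock_cpgs must be a finite count >= 1")
  }
  if (!num1(n_null_cpgs) || n_null_cpgs < 0) {
    fail("n_null_cpgs must be a finite count >= 0")
  }
  if (!num1(treatment_rate_ratio) || treatment_rate_ratio <= 0) {
    fail("treatment_rate_ratio must be > 0")
  }
  if (!num1(conversion_error) || conversion_error < 0 ||
      conversion_error > 0.05) {
    fail("conversion_error must lie in [0, 0.05]")
  }
  if (!num1(overdispersion_rho) || overdispersion_rho < 0 ||
      overdispersion_rho >= 1) {
    fail("overdispersion_rho must lie in [0, 1)")
  }
  if (!num1(treatment_intercept_offset_days)) {
    fail("treatment_intercept_offset_days must be a finite number")
  }
  if (!num1(mean_coverage) || mean_coverage <= 0) {
    fail("mean_coverage must be > 0")
  }
  if (!num1(coverage_dispersion) || coverage_dispersion < 0) {
    fail("coverage_dispersion must be >= 0")
  }
  stopifnot(length(baseline_logit_range) == 2, length(slope_logit_range) == 2,
            length(clock_baseline_logit_range) == 2,
            all(is.finite(baseline_logit_range)),
            all(is.finite(clock_baseline_logit_range)),
            all(is.finite(slope_logit_range)),
            all(slope_logit_range >= 0))
  structure(
    list(n_clock_cpgs = as.integer(n_clock_cpgs),
         n_null_cpgs = as.integer(n_null_cpgs),
         baseline_logit_range = as.numeric(baseline_logit_range),
         clock_baseline_logit_range = as.numeric(clock_baseline_logit_range),
         slope_logit_range = as.numeric(sort(slope_logit_range)),
         treatment_rate_ratio = treatment_rate_ratio,
         treatment_intercept_offset_days = treatment_intercept_offset_days,
         overdispersion_rho = overdispersion_rho,
         conversion_error = conversion_error,
         mean_coverage = mean_coverage,
         coverage_dispersion = coverage_dispersion),
    class = "clock_architecture"
  )
}

#' Latent epigenetic age implied by the generative model
#'
#' The latent epigenetic age of a library is the age at which the
#' reference-group methylation trajectory matches the library's expected
#' clock-CpG methylation: for the reference group it equals chronological
#' age, and for the second treatment it is
#' `rate_ratio * (age + intercept_offset)`. Predicted ages from a clock
#' trained on the reference group estimate exactly this quantity, making the
#' generator's truth directly comparable to clock output.
#'
#' @param age_days chronological age(s) in days.
#' @param group_index 1 for the reference treatment, 2 for the second.
#' @param arch a [clock_architecture()].
#' @return Latent epigenetic age(s) in days.
#' @export
latent_epigenetic_age <- function(age_days, group_index, arch) {
  r <- ifelse(group_index == 2, arch$treatment_rate_ratio, 1)
  o <- ifelse(group_index == 2, arch$treatment_intercept_offset_days, 0)
  r * (age_days + o)
}

## sample sheet implied by a design
design_sample_sheet <- function(design) {
  grid <- expand.grid(
    replicate = seq_len(design$replicates_per_cell),
    age_days = design$timepoints,
    treatment = design$treatments,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[, c("treatment", "age_days", "replicate")]
  grid$library_id <- sprintf("%s_d%02d_r%d", grid$treatment, grid$age_days,
                             grid$replicate)
  grid$pool_size <- design$pool_size
  grid[, c("library_id", "treatment", "age_days", "replicate", "pool_size")]
}

## vectorized beta-binomial draws; rho = 0 degenerates to binomial
rbetabinom <- function(n, size, prob, rho) {
  prob <- rep_len(prob, n)
  size <- rep_len(size, n)
  if (rho <= 0) return(rbinom(n, size, prob))
  k <- (1 - rho) / rho
  theta <- numeric(n)
  inner <- prob > 0 & prob < 1
  theta[inner] <- rbeta(sum(inner), prob[inner] * k, (1 - prob[inner]) * k)
  theta[!inner] <- prob[!inner]
  rbinom(n, size, theta)
}

## per-library coverage draws, floored at one read
rcoverage <- function(n, mu, dispersion) {
  x <- if (dispersion <= 0) {
    rpois(n, mu)
  } else {
    rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  pmax(x, 1L)
}

#' Generate a synthetic methylation dataset with planted ground truth
#'
#' Simulates per-CpG methylated/total read counts for every library of a
#' study design under the generative model of [clock_architecture()]. For a
#' clock CpG `i` in a library of group `g` at age `a`, the latent
#' methylation proportion is `plogis(b_i + s_i * a*)` with
#' `a* = r_g * (a + o_g)` the latent epigenetic age ([latent_epigenetic_age()]);
#' null CpGs have `s_i = 0`. Bisulfite non-conversion inflates the observed
#' proportion to `p + (1 - p) * conversion_error`; counts are beta-binomial
#' on negative-binomial coverage. Deterministic given `design$seed`.
#'
#' @param design a [study_design()].
#' @param arch a [clock_architecture()].
#' @return A list with elements:
#'   \describe{
#'     \item{counts}{a [cpg_counts()] matrix, sites x libraries;}
#'     \item{samples}{the sample sheet data.frame;}
#'     \item{truth}{planted ground truth: `clock_cpg_ids`, per-site
#'       `sites` table (intercept and slope on the logit scale, clock flag)
#'       and per-library `libraries` table with the latent epigenetic age.}
#'   }
#' @export
generate_methylation_dataset <- function(design, arch) {
  stopifnot(inherits(design, "study_design"),
            inherits(arch, "clock_architecture"))
  samples <- design_sample_sheet(design)
  n_lib <- nrow(samples)
  n_site <- arch$n_clock_cpgs + arch$n_null_cpgs

  with_seed(design$seed, {
    pos <- sort(sample.int(n_site * 50L, n_site))
    sites <- data.frame(contig = "synth1", pos = pos,
                        site_id = sprintf("synth1:%d", pos))
    clock_idx <- sort(sample.int(n_site, arch$n_clock_cpgs))
    b <- runif(n_site, arch$baseline_logit_range[1],
               arch$baseline_logit_range[2])
    b[clock_idx] <- runif(arch$n_clock_cpgs,
                          arch$clock_baseline_logit_range[1],
                          arch$clock_baseline_logit_range[2])
    s <- numeric(n_site)
    s[clock_idx] <- runif(arch$n_clock_cpgs, arch$slope_logit_range[1],
                          arch$slope_logit_range[2]) *
      sample(c(-1, 1), arch$n_clock_cpgs, replace = TRUE)

    grp <- match(samples$treatment, design$treatments)
    astar <- latent_epigenetic_age(samples$age_days, grp, arch)
    p <- invlogit(outer(s, astar) + b)                  # sites x libraries
    p_obs <- p + (1 - p) * arch$conversion_error

    total <- matrix(
      rcoverage(n_site * n_lib, arch$mean_coverage, arch$coverage_dispersion),
      n_site, n_lib
    )
    meth <- matrix(
      rbetabinom(n_site * n_lib, total, p_obs, arch$overdispersion_rho),
      n_site, n_lib
    )

    truth <- list(
      clock_cpg_ids = sites$site_id[clock_idx],
      sites = data.frame(site_id = sites$site_id,
                         is_clock = seq_len(n_site) %in% clock_idx,
                         intercept_logit = b, slope_logit = s),
      libraries = data.frame(library_id = samples$library_id,
                             treatment = samples$treatment,
                             age_days = samples$age_days,
                             latent_age = astar)
    )
    list(counts = cpg_counts(sites, meth, total,
                             library_ids = samples$library_id),
         samples = samples, truth = truth)
  })
}

#' Generate unmethylated spike-in counts
#'
#' Simulates counts for a fully unmethylated spike-in (e.g. lambda phage
#' DNA) in every library of the design: methylated reads arise only through
#' bisulfite non-conversion at rate `arch$conversion_error`. Sites are
#' placed on the reserved contig `"lambda_spikein"` so they can be split
#' from genomic sites downstream.
#'
#' @param design a [study_design()].
#' @param arch a [clock_architecture()].
#' @param n_lambda_cpgs number of spike-in CpG sites (>= 1).
#' @return A [cpg_counts()] matrix of spike-in counts.
#' @export
generate_spikein_counts <- function(design, arch, n_lambda_cpgs = 100) {
  stopifnot(inherits(design, "study_design"),
            inherits(arch, "clock_architecture"))
  if (n_lambda_cpgs < 1) fail("n_lambda_cpgs must be >= 1")
  samples <- design_sample_sheet(design)
  n_lib <- nrow(samples)
  n <- as.integer(n_lambda_cpgs)
  with_seed(derive_seed(design$seed, "spikein"), {
    sites <- data.frame(contig = "lambda_spikein",
                        pos = seq(1L, by = 50L, length.out = n),
                        site_id = sprintf("lambda_spikein:%d", seq(1L, by = 50L, length.out = n)))
    total <- matrix(
      rcoverage(n * n_lib, arch$mean_coverage, arch$coverage_dispersion),
      n, n_lib
    )
    meth <- matrix(rbinom(n * n_lib, total, arch$conversion_error), n, n_lib)
    cpg_counts(sites, meth, total, library_ids = samples$library_id)
  })
}

#' Survival simulation scenario
#'
#' Two-group time-to-event scenario with Weibull (default exponential)
#' hazards. Group survival is `S(t) = exp(-(rate * t)^shape)`; with a common
#' `shape` the groups are proportional-hazards with hazard ratio
#' `(rate2 / rate1)^shape`. Defaults calibrate the reference group to a
#' 22-day median exponential lifespan and the second group to a true hazard
#' ratio of 0.35, with cohort sizes 101 and 71.
#'
#' @param groups two group labels (first = reference).
#' @param rates per-group Weibull rate parameters (strictly positive).
#' @param shape common Weibull shape (1 = exponential).
#' @param n_per_group per-group cohort sizes (>= 1).
#' @param censoring_time administrative censoring day (> 0) or `NULL` for
#'   none.
#' @param seed integer RNG seed.
#' @return A `survival_scenario` list.
#' @export
survival_scenario <- function(groups = c("control", "diapause"),
                              rates = c(log(2) / 22, 0.35 * log(2) / 22),
                              shape = 1,
                              n_per_group = c(101, 71),
                              censoring_time = NULL,
                              seed = 1L) {
  if (length(groups) != 2 || anyDuplicated(groups)) {
    fail("exactly two distinct group labels are required")
  }
  if (length(rates) != 2 || any(!is.finite(rates)) || any(rates <= 0)) {
    fail("rates must be two strictly positive numbers")
  }
  if (length(n_per_group) != 2 || any(n_per_group < 1)) {
    fail("n_per_group must be two counts >= 1")
  }
  if (!is.null(censoring_time) &&
      (!is.finite(censoring_time) || censoring_time <= 0)) {
    fail("censoring_time must be > 0 (all records would be censored at 0)")
  }
  if (!is.finite(shape) || shape <= 0) fail("shape must be > 0")
  structure(
    list(groups = as.character(groups), rates = as.numeric(rates),
         shape = shape, n_per_group = as.integer(n_per_group),
         censoring_time = censoring_time, seed = as.integer(seed)),
    class = "survival_scenario"
  )
}

#' Generate a synthetic survival cohort
#'
#' Draws per-individual event times from the scenario's group hazards and
#' applies administrative censoring. Deterministic given `scenario$seed`.
#'
#' @param scenario a [survival_scenario()].
#' @return A data.frame with columns `id`, `time_days`, `event`
#'   (1 = death observed, 0 = censored) and `group`.
#' @export
generate_survival_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "survival_scenario"))
  with_seed(scenario$seed, {
    times <- unlist(lapply(1:2, function(g) {
      rweibull(scenario$n_per_group[g], shape = scenario$shape,
               scale = 1 / scenario$rates[g])
    }))
    group <- rep(scenario$groups, scenario$n_per_group)
    cens <- if (is.null(scenario$censoring_time)) Inf else
      scenario$censoring_time
    data.frame(
      id = sprintf("ind_%04d", seq_along(times)),
      time_days = pmin(times, cens),
      event = as.integer(times <= cens),
      group = group
    )
  })
}
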