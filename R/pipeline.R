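## canonical config template: every legal key with its default
default_config <- function() {
  list(
    paths = list(coverage_dir = NULL, sample_sheet = NULL,
                 survival_file = NULL, output_dir = NULL),
    params = list(
      spikein_contig = "lambda_spikein",
      min_coverage = 10, call_fdr_q = 0.05, min_samples = NULL,
      dml_fdr_q = 0.05, adjust_treatment = FALSE,
      r_min = 0.3, p_max = 0.05,
      alpha = 0.5, k_folds = 10, repeats = 3, nlambda = 100,
      contrast_days = c(6, 30),
      conversion_error = NULL,    # fallback when no spike-in is provided
      seed = 1L
    ),
    synthetic = list(
      enabled = FALSE,
      design = list(treatments = c("control", "diapause"),
                    timepoints = c(6, 12, 18, 24, 30),
                    replicates_per_cell = 4, pool_size = 10),
      architecture = list(
        n_clock_cpgs = 50, n_null_cpgs = 950,
        baseline_logit_range = c(-2, 2),
        clock_baseline_logit_range = c(-1, 1),
        slope_logit_range = c(0.05, 0.10),
        treatment_rate_ratio = 0.708, treatment_intercept_offset_days = 2.8,
        overdispersion_rho = 0.02, conversion_error = 0.005,
        mean_coverage = 30, coverage_dispersion = 0.2
      ),
      n_lambda_cpgs = 100,
      survival = list(rates = c(log(2) / 22, 0.35 * log(2) / 22), shape = 1,
                      n_per_group = c(101, 71), censoring_time = NULL)
    )
  )
}

## merge user values over defaults, rejecting unknown keys recursively
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    fail("unknown config key(s)%s: %s",
         if (nzchar(path)) paste0(" under '", path, "'") else "",
         paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "/"))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Build a pipeline configuration
#'
#' Returns the full resolved configuration: defaults overridden by the
#' supplied values. Unknown keys are rejected at any nesting level.
#'
#' @param ... named overrides mirroring the config structure (`paths`,
#'   `params`, `synthetic`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- merge_config(default_config(), list(...))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file mirroring the config structure.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  structure(merge_config(default_config(), user), class = "pipeline_config")
}

#' Run the full epigenetic-clock pipeline
#'
#' Executes import -> spike-in calibration -> methylation calling ->
#' age-DML scan -> correlation filter -> clock fit -> prediction ->
#' aging-rate trajectory -> survival analysis from a single configuration,
#' either on Bismark-style coverage files or in synthetic mode with planted
#' ground truth. A stage failure aborts with the stage name and cause;
#' outputs of completed stages are retained with a MANIFEST when an output
#' directory is configured.
#'
#' @param config a [pipeline_config()], or a path to a YAML config file.
#' @return A `pipeline_report` list with the funnel counts at every stage,
#'   the conversion-error estimate, clock panel and validation metrics,
#'   trajectory slopes/contrasts/slowdown/convergence, survival summaries
#'   and the hazard translation; plus (in synthetic mode) the planted
#'   ground truth under `truth`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  out_dir <- config$paths$output_dir
  manifest <- character()
  note <- function(stage) {
    manifest <<- c(manifest, sprintf("%s\tdone", stage))
    if (!is.null(out_dir)) {
      writeLines(manifest, file.path(out_dir, "MANIFEST"))
    }
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      fail("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  ## --- import ------------------------------------------------------------
  truth <- NULL
  imported <- run_stage("import", {
    if (isTRUE(config$synthetic$enabled)) {
      des <- do.call(study_design,
                     c(config$synthetic$design,
                       list(seed = derive_seed(p$seed, "generate"))))
      arch <- do.call(clock_architecture, config$synthetic$architecture)
      sim <- generate_methylation_dataset(des, arch)
      spike <- generate_spikein_counts(des, arch,
                                       config$synthetic$n_lambda_cpgs)
      scen <- do.call(survival_scenario,
                      c(list(groups = des$treatments),
                        config$synthetic$survival,
                        list(seed = derive_seed(p$seed, "survival"))))
      truth <- sim$truth
      list(genome = sim$counts, spikein = spike, samples = sim$samples,
           cohort = generate_survival_cohort(scen))
    } else {
      if (is.null(config$paths$coverage_dir) ||
          is.null(config$paths$sample_sheet)) {
        fail("coverage_dir and sample_sheet are required outside synthetic mode")
      }
      samples <- read_sample_sheet(config$paths$sample_sheet)
      paths <- list.files(config$paths$coverage_dir,
                          pattern = "\\.(cov|txt)(\\.gz)?$",
                          full.names = TRUE)
      counts <- read_coverage_files(paths, samples)
      parts <- split_spikein(counts, p$spikein_contig)
      cohort <- if (!is.null(config$paths$survival_file)) {
        utils::read.csv(config$paths$survival_file, stringsAsFactors = FALSE)
      }
      list(genome = parts$genome, spikein = parts$spikein,
           samples = samples, cohort = cohort)
    }
  })
  note("import")

  ## --- spike-in calibration ----------------------------------------------
  conversion <- run_stage("conversion_calibration", {
    if (nrow(imported$spikein$meth) > 0 && sum(imported$spikein$total) > 0) {
      estimate_conversion_error(imported$spikein)
    } else if (!is.null(p$conversion_error)) {
      message("no spike-in coverage; using configured conversion error ",
              p$conversion_error)
      p$conversion_error
    } else {
      fail("no spike-in counts and no configured conversion_error")
    }
  })
  note("conversion_calibration")

  ## --- methylation calling -----------------------------------------------
  called <- run_stage("methylation_calling", {
    call_methylated_sites(imported$genome, conversion,
                          min_coverage = p$min_coverage,
                          fdr_q = p$call_fdr_q, min_samples = p$min_samples)
  })
  note("methylation_calling")

  ## --- age-DML scan -------------------------------------------------------
  meth_counts <- subset_counts(imported$genome, sites = called$site_ids)
  dml <- run_stage("age_dml", {
    run_dml_scan(meth_counts, imported$samples, fdr_q = p$dml_fdr_q,
                 adjust_treatment = p$adjust_treatment)
  })
  note("age_dml")

  ## --- correlation filter -------------------------------------------------
  dml_counts <- subset_counts(meth_counts, sites = dml$site_ids)
  corr <- run_stage("correlation_filter", {
    correlation_filter(dml_counts, imported$samples,
                       r_min = p$r_min, p_max = p$p_max)
  })
  note("correlation_filter")
  filtered_ids <- attr(corr, "site_ids")

  ## --- clock fit -----------------------------------------------------------
  clock <- run_stage("clock_fit", {
    fit_elastic_net_clock(dml_counts, imported$samples,
                          site_ids = filtered_ids, alpha = p$alpha,
                          k_folds = p$k_folds, repeats = p$repeats,
                          nlambda = p$nlambda,
                          seed = derive_seed(p$seed, "clock_cv"))
  })
  note("clock_fit")
  panel <- clock_panel(clock$model)

  ## --- prediction ----------------------------------------------------------
  predicted <- run_stage("prediction", {
    predict_epigenetic_age(clock$model, imported$genome,
                           impute_missing = TRUE)
  })
  note("prediction")
  samples <- imported$samples
  treat2 <- setdiff(unique(samples$treatment), samples$treatment[1])
  idx2 <- samples$library_id[samples$treatment == treat2]
  validation_treatment <- validate_clock(
    predicted[idx2], samples$age_days[match(idx2, samples$library_id)],
    group = treat2
  )

  ## --- aging-rate trajectory ----------------------------------------------
  ## training-group libraries enter the trajectory with their held-out
  ## cross-validated predictions (their direct predictions are in-sample
  ## and would understate the residual variance)
  traj_pred <- predicted
  cvp <- clock$model$cv$predictions
  traj_pred[names(cvp)] <- cvp
  traj <- run_stage("trajectory", {
    ord <- match(samples$library_id, names(traj_pred))
    fit_trajectory(unname(traj_pred[ord]), samples$age_days,
                   samples$treatment)
  })
  note("trajectory")
  contrasts <- lapply(p$contrast_days, function(d) {
    suppressWarnings(contrast_at_day(traj, d))
  })
  names(contrasts) <- paste0("day_", p$contrast_days)
  slowdown <- slowdown_ci(traj)
  conv_day <- convergence_day(traj)

  ## --- survival -------------------------------------------------------------
  surv <- run_stage("survival", {
    if (is.null(imported$cohort)) return(NULL)
    km <- km_fit(imported$cohort)
    cx <- cox_fit(imported$cohort)
    grp <- km$medians$group
    ref <- as.character(imported$cohort$group[1])
    med_ctrl <- km$medians$median[grp == ref]
    med_trt <- km$medians$median[grp != ref]
    last_day <- max(p$contrast_days)
    delta <- -contrasts[[length(contrasts)]]$difference
    list(km = km, cox = cx,
         median_extension_percent =
           if (all(is.finite(c(med_trt, med_ctrl)))) {
             median_extension_percent(med_trt, med_ctrl)
           } else NA_real_,
         hazard_reduction_percent = hazard_reduction_percent(cx$hr),
         hazard_translation = if (is.finite(delta) && delta != 0) {
           hazard_per_epigenetic_day(cx$hr, delta)
         },
         translation_day = last_day)
  })
  note("survival")

  report <- structure(
    list(
      seed = p$seed,
      funnel = c(total_sites = nrow(imported$genome$meth),
                 methylated = length(called$site_ids),
                 age_dml = length(dml$site_ids),
                 correlation_filtered = length(filtered_ids),
                 panel = length(panel)),
      conversion_error = if (inherits(conversion, "conversion_estimate")) {
        conversion$error_rate
      } else conversion,
      lambda = clock$model$lambda,
      alpha = clock$model$alpha,
      panel = panel,
      validation_control = clock$validation[c("group", "n", "r_squared",
                                              "rmse")],
      validation_treatment = validation_treatment[c("group", "n",
                                                    "r_squared", "rmse")],
      slopes = traj$slopes,
      interaction = traj$interaction,
      contrasts = lapply(contrasts, function(ct) {
        ct[c("day", "means", "difference", "se", "t", "df", "p")]
      }),
      percent_slowdown = slowdown,
      convergence_day = as.numeric(conv_day),
      survival = if (!is.null(surv)) list(
        medians = surv$km$medians,
        median_extension_percent = surv$median_extension_percent,
        hazard_ratio = surv$cox$hr, hazard_ratio_ci = surv$cox$ci,
        wald_p = surv$cox$p,
        hazard_reduction_percent = surv$hazard_reduction_percent,
        hazard_percent_per_day =
          if (!is.null(surv$hazard_translation)) {
            surv$hazard_translation$percent_per_day
          } else NA_real_
      )
    ),
    class = "pipeline_report"
  )

  if (!is.null(out_dir)) {
    run_stage("write_outputs", {
      utils::write.csv(called$sites,
                       file.path(out_dir, "methylation_calls.csv"),
                       row.names = FALSE)
      utils::write.csv(dml$results, file.path(out_dir, "age_dml.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(corr),
                       file.path(out_dir, "correlation_filter.csv"),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(site_id = names(panel), coefficient = unname(panel)),
        file.path(out_dir, "clock_panel.csv"), row.names = FALSE)
      write_clock_model(clock$model, file.path(out_dir, "clock_model.json"))
      write_clock_panel(clock$model, imported$genome$sites,
                        file.path(out_dir, "clock_panel.bed"))
      cvcol <- rep(NA_real_, length(predicted))
      cvcol[match(names(cvp), names(predicted))] <- cvp
      utils::write.csv(
        data.frame(library_id = names(predicted),
                   predicted_age = unname(predicted),
                   cv_predicted_age = cvcol),
        file.path(out_dir, "predicted_ages.csv"), row.names = FALSE)
      jsonlite::write_json(report_to_json(report),
                           file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      yaml::write_yaml(unclass(config),
                       file.path(out_dir, "resolved_config.yaml"))
      note("write_outputs")
    })
  }
  if (!is.null(truth)) attr(report, "truth") <- truth
  report
}

## flatten a report into JSON-friendly structures
report_to_json <- function(report) {
  r <- unclass(report)
  r$funnel <- as.list(r$funnel)
  r$panel <- as.list(r$panel)
  r$slopes <- as.list(r$slopes)
  r$contrasts <- lapply(r$contrasts, function(ct) {
    ct$means <- as.list(ct$means)
    ct
  })
  if (!is.null(r$survival)) {
    r$survival$medians <- lapply(
      split(r$survival$medians, seq_len(nrow(r$survival$medians))),
      as.list)
  }
  r
}

#' @export
print.pipeline_report <- function(x, ...) {
  f <- x$funnel
  cat("epigenetic clock pipeline report\n")
  cat(sprintf("  funnel: %d sites -> %d methylated -> %d age-DML -> %d filtered -> %d panel\n",
              f["total_sites"], f["methylated"], f["age_dml"],
              f["correlation_filtered"], f["panel"]))
  cat(sprintf("  conversion error: %.4f; lambda = %.4g (alpha = %g)\n",
              x$conversion_error, x$lambda, x$alpha))
  cat(sprintf("  control CV:  R^2 = %.3f, RMSE = %.2f d\n",
              x$validation_control$r_squared, x$validation_control$rmse))
  cat(sprintf("  treatment:   R^2 = %.3f, RMSE = %.2f d\n",
              x$validation_treatment$r_squared, x$validation_treatment$rmse))
  cat(sprintf("  slopes: %s = %.5f, %s = %.5f; slowdown = %.1f%% (95%% CI %.1f-%.1f)\n",
              names(x$slopes)[1], x$slopes[1], names(x$slopes)[2],
              x$slopes[2], x$percent_slowdown$estimate,
              x$percent_slowdown$lower, x$percent_slowdown$upper))
  cat(sprintf("  interaction: t = %.3f, d.f. = %d, P = %.4g; convergence day %.1f\n",
              x$interaction$t, x$interaction$df, x$interaction$p,
              x$convergence_day))
  if (!is.null(x$survival)) {
    cat(sprintf("  survival: HR = %.3f (%.3f-%.3f), median extension %.1f%%, hazard/day %.1f%%\n",
                x$survival$hazard_ratio, x$survival$hazard_ratio_ci[1],
                x$survival$hazard_ratio_ci[2],
                x$survival$median_extension_percent,
                x$survival$hazard_percent_per_day))
  }
  invisible(x)
}

#' One-command synthetic end-to-end demonstration
#'
#' Runs the whole pipeline in synthetic mode with planted ground truth
#' under the default study design (2 treatments x 5 timepoints x 4
#' replicate pools of 10; 50 clock CpGs among 1,000).
#'
#' @param out_dir optional output directory for tables and the report.
#' @param seed integer seed.
#' @param ... overrides forwarded to the synthetic config block, e.g.
#'   `architecture = list(n_null_cpgs = 200)`.
#' @return The [run_pipeline()] report (with the ground truth attached as
#'   attribute `"truth"`).
#' @export
epiclock_demo <- function(out_dir = NULL, seed = 1L, ...) {
  syn <- merge_config(default_config()$synthetic,
                      c(list(enabled = TRUE), list(...)))
  cfg <- pipeline_config(paths = list(output_dir = out_dir),
                         params = list(seed = as.integer(seed)),
                         synthetic = syn)
  run_pipeline(cfg)
}
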