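#' Binomial regression of one CpG's methylation on chronological age
#'
#' Fits a binomial GLM with logit link of (methylated, unmethylated) read
#' counts on age in days, and tests the age term by a 1-df likelihood-ratio
#' test against the intercept-only model. When the Pearson dispersion of the
#' age model exceeds `dispersion_threshold`, the test falls back to a
#' quasi-binomial F test (flagged in the result), guarding against
#' overdispersed pooled libraries.
#'
#' @param meth,total methylated and total read counts across libraries.
#' @param ages chronological ages in days, one per library.
#' @param covariate optional factor adjusted for in both the null and the
#'   age model (e.g. treatment).
#' @param dispersion_threshold Pearson-dispersion value above which the
#'   quasi-binomial fallback is used. Pooled libraries are overdispersed
#'   relative to binomial (a pool of `m` individuals with intra-class
#'   correlation `rho` has dispersion about `1 + (coverage - 1) * rho`), so
#'   the default applies the adjustment whenever the estimated dispersion
#'   exceeds 1, keeping the test calibrated rather than anti-conservative.
#' @return A one-row data.frame: `slope` (logit change per day), `se`,
#'   `stat` (LRT or quasi-F statistic), `p`, `n_used`, `converged`,
#'   `dispersion`, `quasi`.
#' @export
fit_age_glm <- function(meth, total, ages, covariate = NULL,
                        dispersion_threshold = 1) {
  use <- total > 0
  out <- data.frame(slope = NA_real_, se = NA_real_, stat = NA_real_,
                    p = NA_real_, n_used = sum(use), converged = FALSE,
                    dispersion = NA_real_, quasi = FALSE)
  if (sum(use) < 3 || length(unique(ages[use])) < 2) return(out)
  y <- cbind(meth[use], total[use] - meth[use])
  age <- ages[use]
  dat <- data.frame(age = age)
  null_rhs <- "1"
  if (!is.null(covariate)) {
    cv <- factor(covariate[use])
    if (nlevels(droplevels(cv)) > 1) {
      dat$cov <- droplevels(cv)
      null_rhs <- "cov"
    }
  }
  f_alt <- as.formula(paste("y ~", null_rhs, "+ age"))
  f_null <- as.formula(paste("y ~", null_rhs))
  fit <- tryCatch(
    withCallingHandlers(
      glm(f_alt, family = binomial(), data = dat),
      warning = function(w) invokeRestart("muffleWarning")
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) return(out)
  b <- coef(fit)["age"]
  ## near-separation: absurd slope magnitude means the MLE is diverging
  if (!is.finite(b) || abs(b) > 50) return(out)
  null_fit <- withCallingHandlers(
    glm(f_null, family = binomial(), data = dat),
    warning = function(w) invokeRestart("muffleWarning")
  )
  lrt <- max(null_fit$deviance - fit$deviance, 0)
  df_res <- fit$df.residual
  phi <- sum(residuals(fit, type = "pearson")^2) / max(df_res, 1)
  out$slope <- unname(b)
  out$se <- sqrt(diag(vcov(fit)))["age"]
  out$n_used <- sum(use)
  out$converged <- TRUE
  out$dispersion <- phi
  if (is.finite(phi) && phi > dispersion_threshold && df_res >= 1) {
    out$quasi <- TRUE
    out$stat <- lrt / phi
    out$p <- pf(out$stat, 1, df_res, lower.tail = FALSE)
    out$se <- out$se * sqrt(phi)
  } else {
    out$stat <- lrt
    out$p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  out
}

#' Scan all sites for age-related differential methylation
#'
#' Applies [fit_age_glm()] to every site of a count matrix (typically
#' restricted to sites classified as methylated) and corrects p-values by
#' Benjamini-Hochberg across the converged sites. Sites whose GLM does not
#' converge are excluded from the multiple-testing family and counted in
#' `n_unconverged`.
#'
#' @param counts a [cpg_counts()] matrix.
#' @param samples sample sheet covering the libraries.
#' @param fdr_q Benjamini-Hochberg threshold defining the significant set.
#' @param adjust_treatment adjust both null and age models for treatment.
#' @param libraries optional library ids to restrict the scan to (e.g.
#'   control libraries for a sensitivity analysis); default all.
#' @param dispersion_threshold passed to [fit_age_glm()].
#' @return A `dml_scan` list: `results` data.frame (site_id, slope, se,
#'   stat, p, q, significant, ...), `site_ids` of the significant set,
#'   `n_unconverged`, and parameters.
#' @export
run_dml_scan <- function(counts, samples, fdr_q = 0.05,
                         adjust_treatment = FALSE, libraries = NULL,
                         dispersion_threshold = 1) {
  stopifnot(inherits(counts, "cpg_counts"))
  samples <- check_sample_sheet(samples, counts)
  if (!is.null(libraries)) counts <- subset_counts(counts, libraries = libraries)
  libs <- library_ids(counts)
  si <- match(libs, samples$library_id)
  ages <- samples$age_days[si]
  treat <- if (adjust_treatment) samples$treatment[si] else NULL

  n <- nrow(counts$meth)
  if (n == 0) {
    res <- data.frame(site_id = character(), slope = numeric(),
                      se = numeric(), stat = numeric(), p = numeric(),
                      q = numeric(), n_used = integer(),
                      converged = logical(), quasi = logical(),
                      significant = logical())
    return(structure(list(results = res, site_ids = character(),
                          n_unconverged = 0L, fdr_q = fdr_q,
                          adjust_treatment = adjust_treatment),
                     class = "dml_scan"))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- fit_age_glm(counts$meth[i, ], counts$total[i, ], ages,
                             covariate = treat,
                             dispersion_threshold = dispersion_threshold)
  }
  res <- do.call(rbind, rows)
  res <- cbind(site_id = counts$sites$site_id, res)
  ok <- res$converged & !is.na(res$p)
  res$q <- NA_real_
  res$q[ok] <- p.adjust(res$p[ok], method = "BH")
  res$significant <- !is.na(res$q) & res$q <= fdr_q
  structure(
    list(results = res, site_ids = res$site_id[res$significant],
         n_unconverged = sum(!ok), fdr_q = fdr_q,
         adjust_treatment = adjust_treatment),
    class = "dml_scan"
  )
}

#' @export
print.dml_scan <- function(x, ...) {
  cat(sprintf(
    "age-DML scan: %d of %d sites significant at q <= %g (%d unconverged)\n",
    length(x$site_ids), nrow(x$results), x$fdr_q, x$n_unconverged))
  invisible(x)
}
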