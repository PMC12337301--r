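#' Kaplan-Meier survival estimate by group
#'
#' Product-limit survival curves per group with Greenwood variance and
#' log-log 95% confidence bands; the median is the smallest time at which
#' the survival estimate drops to 0.5 or below, with its confidence
#' interval from the times where the CI band crosses 0.5. Groups whose
#' curve never reaches 0.5 get an undefined (NA) median and are flagged.
#'
#' @param cohort data.frame with columns `time_days`, `event` (1 = death,
#'   0 = censored) and `group`.
#' @param conf_level confidence level for the bands and median CI.
#' @return A `km_estimate` list: `curves` (per-group data.frame of time,
#'   n.risk, n.event, n.censor, surv, greenwood_var, lower, upper),
#'   `medians` (group, n, events, median, lower, upper, `defined` flag).
#' @export
km_fit <- function(cohort, conf_level = 0.95) {
  cohort <- check_cohort(cohort)
  sf <- survival::survfit(
    survival::Surv(time_days, event) ~ group, data = cohort,
    conf.type = "log-log", conf.int = conf_level
  )
  strata <- rep(names(sf$strata), sf$strata)
  grp <- sub("^group=", "", strata)
  curves <- data.frame(
    group = grp, time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, surv = sf$surv,
    greenwood_var = (sf$surv * sf$std.err)^2,   # std.err is SE of log S
    lower = sf$lower, upper = sf$upper
  )
  tab <- summary(sf)$table
  lcl <- grep("LCL$", colnames(tab), value = TRUE)
  ucl <- grep("UCL$", colnames(tab), value = TRUE)
  ## median: smallest time at which the survival estimate is <= 0.5
  med <- vapply(sub("^group=", "", rownames(tab)), function(g) {
    cv <- curves[curves$group == g, ]
    t0 <- cv$time[cv$surv <= 0.5]
    if (length(t0)) min(t0) else NA_real_
  }, numeric(1))
  medians <- data.frame(
    group = sub("^group=", "", rownames(tab)),
    n = tab[, "records"], events = tab[, "events"],
    median = med, lower = tab[, lcl], upper = tab[, ucl]
  )
  medians$defined <- !is.na(medians$median)
  rownames(medians) <- NULL
  if (any(medians$events == 0)) {
    warning("group(s) without events: ",
            paste(medians$group[medians$events == 0], collapse = ", "))
  }
  if (any(!medians$defined)) {
    warning("median survival undefined (curve never reaches 0.5) for: ",
            paste(medians$group[!medians$defined], collapse = ", "))
  }
  structure(list(curves = curves, medians = medians,
                 conf_level = conf_level, survfit = sf),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier survival by group:\n")
  for (i in seq_len(nrow(x$medians))) {
    m <- x$medians[i, ]
    cat(sprintf("  %s: n = %d, events = %d, median = %s d (%g%% CI: %s-%s)\n",
                m$group, m$n, m$events, format(m$median),
                100 * x$conf_level, format(m$lower), format(m$upper)))
  }
  invisible(x)
}

#' Cox proportional-hazards fit for the treatment effect
#'
#' Maximizes the partial likelihood with Efron handling of tied event times
#' (the accurate standard for daily-resolution monitoring). The hazard
#' ratio is treatment versus the reference (first) group; inference is the
#' two-sided Wald test.
#'
#' @param cohort data.frame with `time_days`, `event`, `group`; the first
#'   group label encountered (or first factor level) is the reference.
#' @return A `cox_fit` list: `log_hr`, `se`, `hr`, `ci` (95%), `z`, `p`,
#'   `groups`, `flagged` (TRUE if the fit is suspect, e.g. monotone
#'   likelihood), plus the underlying `coxph` object.
#' @export
cox_fit <- function(cohort) {
  cohort <- check_cohort(cohort)
  if (any(tapply(cohort$event, cohort$group, sum) == 0)) {
    fail("both groups need at least one observed event")
  }
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time_days, event) ~ group, data = cohort,
                    ties = "efron", control = survival::coxph.control(
                      eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  b <- unname(coef(fit))
  se <- unname(sqrt(diag(vcov(fit))))
  if (!is.finite(b) || abs(b) > 15) flagged <- TRUE
  structure(
    list(log_hr = b, se = se, hr = exp(b),
         ci = exp(b + c(-1, 1) * qnorm(0.975) * se),
         z = b / se, p = 2 * pnorm(abs(b / se), lower.tail = FALSE),
         groups = levels(cohort$group), flagged = flagged, coxph = fit),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "Cox PH (%s vs %s): HR = %.3f (95%% CI: %.3f-%.3f), Wald P = %.3g%s\n",
    x$groups[2], x$groups[1], x$hr, x$ci[1], x$ci[2], x$p,
    if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Percent hazard reduction implied by a hazard ratio
#' @param hr hazard ratio (> 0).
#' @return `(1 - hr) * 100`.
#' @export
hazard_reduction_percent <- function(hr) {
  if (!is.finite(hr) || hr <= 0) fail("hazard ratio must be > 0")
  (1 - hr) * 100
}

#' Percent extension of median lifespan
#'
#' @param median_treatment,median_control group median survivals in days
#'   (both > 0).
#' @return `(median_treatment / median_control - 1) * 100`.
#' @export
median_extension_percent <- function(median_treatment, median_control) {
  if (!is.finite(median_control) || median_control <= 0) {
    fail("control median must be > 0")
  }
  if (!is.finite(median_treatment) || median_treatment <= 0) {
    fail("treatment median must be > 0")
  }
  (median_treatment / median_control - 1) * 100
}

#' Translate a treatment hazard ratio into a per-day epigenetic-age hazard
#'
#' Under a simplified Cox model in which the mortality hazard increases
#' exponentially with epigenetic age, a treatment that acts purely by
#' shifting epigenetic age by `delta_days` and carries hazard ratio `hr`
#' implies a per-day log-hazard coefficient `beta = -log(hr) / delta_days`,
#' i.e. each additional day of epigenetic age multiplies the hazard by
#' `exp(beta)`.
#'
#' @param hr treatment hazard ratio (> 0).
#' @param delta_days epigenetic-age difference attributed to the treatment
#'   (nonzero; positive = treatment group epigenetically younger).
#' @return A `hazard_translation` list: `hazard_ratio`, `delta_days`,
#'   `coefficient` (per-day log hazard) and `percent_per_day`
#'   (`(exp(coefficient) - 1) * 100`).
#' @export
hazard_per_epigenetic_day <- function(hr, delta_days) {
  if (!is.finite(hr) || hr <= 0) fail("hazard ratio must be > 0")
  if (!is.finite(delta_days) || delta_days == 0) {
    fail("delta_days must be nonzero")
  }
  beta <- -log(hr) / delta_days
  structure(
    list(hazard_ratio = hr, delta_days = delta_days, coefficient = beta,
         percent_per_day = (exp(beta) - 1) * 100),
    class = "hazard_translation"
  )
}

#' @export
print.hazard_translation <- function(x, ...) {
  cat(sprintf(
    "hazard translation: HR %.3f over %.2f d => %+.1f%% hazard per day of epigenetic age\n",
    x$hazard_ratio, x$delta_days, x$percent_per_day))
  invisible(x)
}

## validate a survival cohort data.frame
check_cohort <- function(cohort) {
  cohort <- as.data.frame(cohort)
  need <- c("time_days", "event", "group")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    fail("cohort is missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(cohort$time_days)) || any(cohort$time_days <= 0)) {
    fail("survival times must be positive and finite")
  }
  if (!all(cohort$event %in% c(0, 1))) {
    fail("event must be 0 (censored) or 1 (death)")
  }
  cohort$group <- if (is.factor(cohort$group)) droplevels(cohort$group) else
    factor(cohort$group, levels = unique(cohort$group))
  if (nlevels(cohort$group) != 2) fail("exactly two groups required")
  cohort
}
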