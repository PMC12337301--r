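#' Linear trajectory of epigenetic age over chronological day by treatment
#'
#' Ordinary least squares of predicted epigenetic age on chronological day,
#' treatment, and their interaction. Day is centered at the first sampled
#' day internally for conditioning; all reported intercepts are on the
#' original day scale. The interaction coefficient is the slope difference
#' (treatment minus reference) in days of epigenetic age per chronological
#' day, tested on the residual `n - 4` degrees of freedom.
#'
#' @param predicted_age predicted epigenetic ages (days).
#' @param day chronological days.
#' @param treatment treatment labels (exactly two); the first factor level
#'   (first label encountered, or the factor's level order) is the
#'   reference group.
#' @return A `trajectory_fit` list: `groups`, per-group `slopes` and
#'   `intercepts` (day-0 scale), `interaction` (estimate, se, t, df, p),
#'   `sigma2`, `vcov` (4 x 4, centered parameterization), `center` (the
#'   centering day), `day_range`, `n`, and the underlying `lm` fit.
#' @export
fit_trajectory <- function(predicted_age, day, treatment) {
  n <- length(predicted_age)
  stopifnot(length(day) == n, length(treatment) == n)
  treatment <- if (is.factor(treatment)) droplevels(treatment) else
    factor(treatment, levels = unique(treatment))
  if (nlevels(treatment) != 2) fail("exactly two treatment groups required")
  for (g in levels(treatment)) {
    if (length(unique(day[treatment == g])) < 2) {
      fail("group '%s' must span >= 2 distinct days", g)
    }
  }
  center <- min(day)
  dat <- data.frame(y = predicted_age, dayc = day - center,
                    treatment = treatment)
  fit <- lm(y ~ dayc * treatment, data = dat)
  if (fit$rank < 4) {
    bad <- names(which(is.na(coef(fit))))
    fail("rank-deficient trajectory design (collinear term: %s)",
         paste(bad, collapse = ", "))
  }
  cf <- coef(fit)
  g2 <- levels(treatment)[2]
  b_treat <- cf[paste0("treatment", g2)]
  b_int <- cf[paste0("dayc:treatment", g2)]
  se_int <- sqrt(diag(vcov(fit)))[paste0("dayc:treatment", g2)]
  df <- fit$df.residual
  tval <- b_int / se_int
  slopes <- c(cf["dayc"], cf["dayc"] + b_int)
  intercepts_c <- c(cf["(Intercept)"], cf["(Intercept)"] + b_treat)
  names(slopes) <- names(intercepts_c) <- levels(treatment)
  structure(
    list(groups = levels(treatment),
         slopes = slopes,
         intercepts = intercepts_c - slopes * center,  # day-0 scale
         interaction = list(estimate = unname(b_int), se = unname(se_int),
                            t = unname(tval), df = df,
                            p = unname(2 * pt(abs(tval), df,
                                              lower.tail = FALSE))),
         sigma2 = sum(residuals(fit)^2) / df,
         vcov = vcov(fit), center = center, day_range = range(day),
         n = n, lm = fit),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "epigenetic aging trajectory (n = %d):\n  %s slope = %.5f, %s slope = %.5f d/d\n  interaction t = %.3f, d.f. = %d, P = %.4g\n",
    x$n, x$groups[1], x$slopes[1], x$groups[2], x$slopes[2],
    x$interaction$t, x$interaction$df, x$interaction$p))
  invisible(x)
}

#' Group contrast of fitted epigenetic age at a chosen day
#'
#' Evaluates both fitted lines at `day` (model-based estimated marginal
#' means) and tests their difference (treatment minus reference) with the
#' standard error from the coefficient covariance, on the model's residual
#' degrees of freedom.
#'
#' @param fit a [fit_trajectory()] result.
#' @param day chronological day at which to contrast the groups.
#' @return A `day_contrast` list: `day`, `means` (per group), `difference`,
#'   `se`, `t`, `df`, `p`.
#' @export
contrast_at_day <- function(fit, day) {
  stopifnot(inherits(fit, "trajectory_fit"), length(day) == 1)
  if (day < fit$day_range[1] || day > fit$day_range[2]) {
    warning(sprintf("day %g lies outside the observed range [%g, %g]",
                    day, fit$day_range[1], fit$day_range[2]))
  }
  d <- day - fit$center
  means <- fit$intercepts + fit$slopes * day
  L <- c(0, 0, 1, d)                    # (b0, day, treat, day:treat)
  diff <- means[2] - means[1]
  se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
  tval <- diff / se
  df <- fit$interaction$df
  structure(
    list(day = day, means = means, difference = unname(diff), se = se,
         t = unname(tval), df = df,
         p = unname(2 * pt(abs(tval), df, lower.tail = FALSE))),
    class = "day_contrast"
  )
}

#' @export
print.day_contrast <- function(x, ...) {
  cat(sprintf(
    "day %g: %s = %.2f d vs %s = %.2f d; diff = %.2f d (t = %.3f, d.f. = %d, P = %.4g)\n",
    x$day, names(x$means)[2], x$means[2], names(x$means)[1], x$means[1],
    x$difference, x$t, x$df, x$p))
  invisible(x)
}

#' Percent slowdown of epigenetic aging
#'
#' The fractional reduction of the treatment group's epigenetic aging rate
#' relative to the reference group: `(1 - treatment_slope / control_slope)
#' * 100`.
#'
#' @param control_slope reference-group slope (epigenetic days per
#'   chronological day); must be nonzero.
#' @param treatment_slope treatment-group slope.
#' @return Percent slowdown (positive = slower epigenetic aging).
#' @export
percent_slowdown <- function(control_slope, treatment_slope) {
  if (!is.finite(control_slope) || control_slope == 0) {
    fail("control slope must be nonzero")
  }
  (1 - treatment_slope / control_slope) * 100
}

#' Percent slowdown with a delta-method confidence interval
#'
#' @param fit a [fit_trajectory()] result.
#' @param level confidence level.
#' @return A list: `estimate` (percent), `se`, `lower`, `upper`.
#' @export
slowdown_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "trajectory_fit"))
  sc <- fit$slopes[1]
  st <- fit$slopes[2]
  ## slopes in the centered parameterization: sc = b_day, st = b_day + b_int
  ## g = (1 - st/sc) * 100; gradient wrt (b0, b_day, b_tr, b_int)
  grad <- c(0, (st / sc^2 - 1 / sc) * 100, 0, -100 / sc)
  v <- drop(t(grad) %*% fit$vcov %*% grad)
  est <- percent_slowdown(sc, st)
  z <- qt(1 - (1 - level) / 2, df = fit$interaction$df)
  list(estimate = unname(est), se = sqrt(v),
       lower = unname(est - z * sqrt(v)), upper = unname(est + z * sqrt(v)))
}

#' Day at which the two fitted aging trajectories intersect
#'
#' Solves `(intercept2 - intercept1) / (slope1 - slope2)` on the original
#' day scale. Returns `NA` when the slopes are equal within `tolerance`
#' (parallel lines never converge; identical lines are flagged in the
#' `"reason"` attribute).
#'
#' @param fit a [fit_trajectory()] result.
#' @param tolerance slope-difference tolerance below which lines are
#'   treated as parallel.
#' @return The convergence day, or `NA` with attribute `"reason"` set to
#'   `"parallel"` or `"identical"`.
#' @export
convergence_day <- function(fit, tolerance = 1e-12) {
  stopifnot(inherits(fit, "trajectory_fit"))
  line_intersection_day(fit$intercepts[1], fit$slopes[1],
                        fit$intercepts[2], fit$slopes[2],
                        tolerance = tolerance)
}

#' @rdname convergence_day
#' @param intercept1,slope1,intercept2,slope2 line parameters on the
#'   original day scale (intercept = value at day 0).
#' @export
line_intersection_day <- function(intercept1, slope1, intercept2, slope2,
                                  tolerance = 1e-12) {
  if (abs(slope1 - slope2) <= tolerance) {
    reason <- if (abs(intercept1 - intercept2) <= tolerance) "identical" else
      "parallel"
    return(structure(NA_real_, reason = reason))
  }
  (intercept2 - intercept1) / (slope1 - slope2)
}

#' Extrapolate a group's fitted epigenetic age along its line
#'
#' `anchor_mean + slope * (target_day - anchor_day)`: projects a group mean
#' observed (or estimated) at one day to another day using the group's
#' fitted aging rate.
#'
#' @param anchor_day day at which `anchor_mean` applies.
#' @param anchor_mean epigenetic age (days) at the anchor day.
#' @param slope epigenetic aging rate (days per day).
#' @param target_day day to extrapolate to.
#' @return Extrapolated epigenetic age in days.
#' @export
extrapolate_group_age <- function(anchor_day, anchor_mean, slope,
                                  target_day) {
  stopifnot(is.finite(anchor_day), is.finite(anchor_mean),
            is.finite(slope), is.finite(target_day))
  anchor_mean + slope * (target_day - anchor_day)
}

#' Plot the fitted aging trajectories
#'
#' @param x a `trajectory_fit`.
#' @param ... passed to [plot()].
#' @export
plot.trajectory_fit <- function(x, ...) {
  dat <- x$lm$model
  day <- dat$dayc + x$center
  cols <- c("#1b6ca8", "#c0392b")
  plot(day, dat$y, col = cols[as.integer(dat$treatment)], pch = 16,
       xlab = "chronological day", ylab = "predicted epigenetic age (d)",
       ...)
  for (g in 1:2) {
    abline(a = x$intercepts[g], b = x$slopes[g], col = cols[g], lwd = 2)
  }
  legend("topleft", legend = x$groups, col = cols, pch = 16, bty = "n")
  invisible(x)
}
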