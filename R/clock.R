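#' Correlation filter of age-DML sites against chronological age
#'
#' Computes the Pearson correlation between per-library methylation
#' proportion and chronological age on the reference-group (control)
#' libraries only, and retains sites with `|r| >= r_min` and two-sided
#' uncorrected `p <= p_max` (t test on `n - 2` df). Sites with undefined
#' correlation (zero variance, or fewer than 3 covered control libraries)
#' are excluded.
#'
#' @param counts a [cpg_counts()] matrix (typically restricted to
#'   significant age-DML sites).
#' @param samples sample sheet covering the libraries.
#' @param control_label treatment label of the reference group; default the
#'   first treatment in the sheet's order of appearance.
#' @param r_min minimum absolute Pearson correlation.
#' @param p_max maximum uncorrected two-sided p-value.
#' @return A data.frame (site_id, n, r, p, retained); attribute
#'   `"site_ids"` holds the retained ids in input order.
#' @export
correlation_filter <- function(counts, samples, control_label = NULL,
                               r_min = 0.3, p_max = 0.05) {
  stopifnot(inherits(counts, "cpg_counts"))
  if (r_min <= 0 || r_min >= 1) fail("r_min must lie in (0, 1)")
  if (p_max <= 0 || p_max >= 1) fail("p_max must lie in (0, 1)")
  samples <- check_sample_sheet(samples, counts)
  if (is.null(control_label)) control_label <- samples$treatment[1]
  ctrl <- samples$library_id[samples$treatment == control_label]
  ctrl <- intersect(library_ids(counts), ctrl)
  if (length(ctrl) < 3) fail("need >= 3 control libraries")
  cc <- subset_counts(counts, libraries = ctrl)
  props <- methylation_proportions(cc)
  ages <- samples$age_days[match(ctrl, samples$library_id)]

  stats <- t(vapply(seq_len(nrow(props)), function(i) {
    x <- props[i, ]
    use <- !is.na(x)
    n <- sum(use)
    if (n < 3 || sd(x[use]) == 0 || sd(ages[use]) == 0) {
      return(c(n = n, r = NA_real_, p = NA_real_))
    }
    r <- cor(x[use], ages[use])
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(n = n, r = r, p = 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE))
  }, numeric(3)))

  out <- data.frame(site_id = cc$sites$site_id, n = as.integer(stats[, "n"]),
                    r = stats[, "r"], p = stats[, "p"])
  out$retained <- !is.na(out$r) & abs(out$r) >= r_min & out$p <= p_max
  attr(out, "site_ids") <- out$site_id[out$retained]
  out
}

new_clock_model <- function(intercept, coefficients, alpha, lambda,
                            feature_center, feature_scale,
                            training_libraries, seed, cv = NULL) {
  structure(
    list(intercept = intercept, coefficients = coefficients, alpha = alpha,
         lambda = lambda, feature_center = feature_center,
         feature_scale = feature_scale,
         training_libraries = training_libraries, seed = seed, cv = cv),
    class = "clock_model"
  )
}

#' Nonzero clock coefficients (the CpG panel)
#' @param model a `clock_model`.
#' @return Named numeric vector of nonzero coefficients (days per unit
#'   methylation proportion).
#' @export
clock_panel <- function(model) {
  stopifnot(inherits(model, "clock_model"))
  model$coefficients[model$coefficients != 0]
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(
    "epigenetic clock: %d-CpG panel (alpha = %g, lambda = %.5g), intercept %.3f d\n",
    length(clock_panel(x)), x$alpha, x$lambda, x$intercept))
  invisible(x)
}

## age-stratified fold assignment; refold until every training split spans
## at least two distinct ages
make_folds <- function(ages, k, max_tries = 100) {
  n <- length(ages)
  for (try in seq_len(max_tries)) {
    ord <- order(ages, runif(n))
    folds <- integer(n)
    folds[ord] <- rep_len(sample.int(k), n)
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(ages[folds != f])) >= 2 && sum(folds == f) >= 1
    }, logical(1)))
    if (ok) return(folds)
  }
  fail("could not build %d folds with age variation in every training split",
       k)
}

## training feature matrix (libraries x sites) with per-site mean imputation
## of uncovered cells
feature_matrix <- function(counts, site_ids, libraries) {
  cc <- subset_counts(counts, sites = site_ids, libraries = libraries)
  x <- t(methylation_proportions(cc))
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[!nas, j])
  }
  x
}

#' Fit the elastic-net epigenetic clock by repeated cross-validation
#'
#' Regresses chronological age (days) on per-CpG methylation proportions of
#' the reference-group libraries with an elastic-net penalty at fixed
#' mixing `alpha`, selecting the regularization strength `lambda` by
#' repeated k-fold cross-validation minimizing RMSE over a log-spaced grid
#' of 100 values spanning `[1e-3 * lambda_max, lambda_max]`. Ties in CV
#' RMSE resolve to the largest (sparsest) `lambda`. The final model is
#' refit on all reference libraries at the selected `lambda`; the reported
#' reference-group validation uses the held-out CV predictions at that
#' `lambda`, averaged over repeats per library. Folds are stratified by
#' age; all randomness is governed by `seed`.
#'
#' @param counts a [cpg_counts()] matrix containing the candidate sites.
#' @param samples sample sheet covering the libraries.
#' @param site_ids candidate feature sites (e.g. the correlation-filtered
#'   set); default all sites in `counts`.
#' @param control_label treatment label of the training (reference) group;
#'   default the sheet's first treatment.
#' @param alpha elastic-net mixing parameter in `[0, 1]` (0.5 = equal
#'   lasso/ridge mix).
#' @param k_folds folds per repeat (capped at the number of training
#'   libraries).
#' @param repeats CV repeats.
#' @param nlambda grid size.
#' @param lambda optional explicit lambda grid (decreasing), overriding the
#'   automatic one; useful for fixed-penalty fits.
#' @param seed integer RNG seed for fold assignment.
#' @return A list: `model` (a `clock_model` whose `cv` element stores the
#'   lambda grid, CV RMSE curve and held-out predictions) and `validation`
#'   (a [validate_clock()] result for the training group, computed from the
#'   cross-validated predictions).
#' @export
fit_elastic_net_clock <- function(counts, samples, site_ids = NULL,
                                  control_label = NULL, alpha = 0.5,
                                  k_folds = 10, repeats = 3, nlambda = 100,
                                  lambda = NULL, seed = 1L) {
  stopifnot(inherits(counts, "cpg_counts"))
  if (alpha < 0 || alpha > 1) fail("alpha must lie in [0, 1]")
  samples <- check_sample_sheet(samples, counts)
  if (is.null(control_label)) control_label <- samples$treatment[1]
  ctrl <- intersect(library_ids(counts),
                    samples$library_id[samples$treatment == control_label])
  if (length(ctrl) < 3) fail("need >= 3 training libraries")
  if (is.null(site_ids)) site_ids <- counts$sites$site_id
  if (length(site_ids) < 1) fail("need at least one candidate feature site")
  x <- feature_matrix(counts, site_ids, ctrl)
  y <- samples$age_days[match(ctrl, samples$library_id)]
  n <- length(y)
  k_folds <- min(k_folds, n)

  ## glmnet requires >= 2 columns; pad single-feature problems with a
  ## constant (zero-coefficient) column
  padded <- ncol(x) == 1
  if (padded) x <- cbind(x, `.pad.` = 0)

  ## glmnet-convention lambda grid: lambda_max is the smallest lambda
  ## zeroing every coefficient
  sdn <- function(v) sqrt(mean((v - mean(v))^2))
  sds <- apply(x, 2, sdn)
  xs <- sweep(x, 2, colMeans(x), "-")
  pos <- sds > 0
  xs[, pos] <- sweep(xs[, pos, drop = FALSE], 2, sds[pos], "/")
  xs[, !pos] <- 0
  if (is.null(lambda)) {
    lambda_max <- max(abs(crossprod(xs, y - mean(y)))) / n / max(alpha, 1e-3)
    grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-3),
                    length.out = nlambda))
  } else {
    grid <- sort(as.numeric(lambda), decreasing = TRUE)
    nlambda <- length(grid)
  }

  cv_pred <- array(NA_real_, c(n, nlambda, repeats))
  with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      folds <- make_folds(y, k_folds)
      for (f in seq_len(k_folds)) {
        tr <- folds != f
        fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], alpha = alpha,
                              lambda = grid, standardize = TRUE,
                              thresh = 1e-12)
        cv_pred[!tr, , rep_i] <- predict(fit, x[!tr, , drop = FALSE],
                                         s = grid)
      }
    }
  })
  rmse_rep <- apply(cv_pred, 3, function(m) {
    sqrt(colMeans((m - y)^2))
  })                                                    # nlambda x repeats
  cv_rmse <- rowMeans(rmse_rep)
  best <- min(cv_rmse)
  lambda_star <- grid[which(cv_rmse <= best + 1e-12)[1]]  # largest lambda

  final <- glmnet::glmnet(x, y, alpha = alpha, lambda = grid,
                          standardize = TRUE, thresh = 1e-12)
  beta <- as.matrix(coef(final, s = lambda_star))[, 1]
  intercept <- beta[1]
  coefs <- beta[-1]
  if (padded) coefs <- coefs[names(coefs) != ".pad."]
  nz <- coefs[coefs != 0]

  li <- which(grid == lambda_star)
  heldout <- rowMeans(cv_pred[, li, , drop = FALSE], dims = 1)
  names(heldout) <- ctrl
  model <- new_clock_model(
    intercept = unname(intercept), coefficients = nz, alpha = alpha,
    lambda = lambda_star,
    feature_center = colMeans(x)[names(nz)],
    feature_scale = sds[names(nz)],
    training_libraries = ctrl, seed = as.integer(seed),
    cv = list(lambda = grid, cv_rmse = cv_rmse, predictions = heldout,
              panel_size = final$df, n_features = length(coefs))
  )
  validation <- validate_clock(heldout, y, group = control_label)
  list(model = model, validation = validation)
}

#' Predict epigenetic age from a fitted clock
#'
#' Applies `intercept + sum(coefficient * proportion)` over the panel sites.
#' By default every panel site must be covered (total > 0) in every library;
#' with `impute_missing = TRUE` uncovered or absent panel sites fall back to
#' their training-set mean proportion (logged via a message).
#'
#' @param model a `clock_model`.
#' @param counts a [cpg_counts()] matrix, or a sites x libraries proportion
#'   matrix with site ids as rownames.
#' @param impute_missing impute missing panel sites with training means.
#' @return Named numeric vector of predicted ages (days) per library.
#' @export
predict_epigenetic_age <- function(model, counts, impute_missing = FALSE) {
  stopifnot(inherits(model, "clock_model"))
  panel <- clock_panel(model)
  if (length(panel) == 0) {
    libs <- if (inherits(counts, "cpg_counts")) library_ids(counts) else
      colnames(counts)
    out <- rep(model$intercept, length(libs))
    names(out) <- libs
    return(out)
  }
  props <- if (inherits(counts, "cpg_counts")) {
    methylation_proportions(counts)
  } else {
    as.matrix(counts)
  }
  have <- intersect(names(panel), rownames(props))
  p <- matrix(NA_real_, length(panel), ncol(props),
              dimnames = list(names(panel), colnames(props)))
  p[have, ] <- props[have, , drop = FALSE]
  if (anyNA(p)) {
    bad <- names(panel)[apply(is.na(p), 1, any)]
    if (!impute_missing) {
      fail("panel site(s) missing or uncovered: %s",
           paste(bad, collapse = ", "))
    }
    message("imputing training means for panel site(s): ",
            paste(bad, collapse = ", "))
    for (s in bad) p[s, is.na(p[s, ])] <- model$feature_center[s]
  }
  drop(model$intercept + crossprod(p, panel)[, 1])
}

#' Validate clock predictions against chronological age
#'
#' @param predicted predicted epigenetic ages (days).
#' @param ages chronological ages (days), same length and order.
#' @param group group label carried into the result.
#' @return A `clock_validation` list: `group`, `n`, `r_squared`
#'   (`1 - SS_res / SS_tot`), `rmse` (days) and the per-library table.
#' @export
validate_clock <- function(predicted, ages, group = NA_character_) {
  if (length(predicted) != length(ages)) {
    fail("'predicted' and 'ages' must have equal length")
  }
  if (length(ages) < 3) fail("need >= 3 libraries to validate")
  if (sd(ages) == 0) fail("chronological ages have zero variance")
  ss_res <- sum((predicted - ages)^2)
  ss_tot <- sum((ages - mean(ages))^2)
  structure(
    list(group = group, n = length(ages),
         r_squared = 1 - ss_res / ss_tot,
         rmse = sqrt(mean((predicted - ages)^2)),
         table = data.frame(age_days = ages, predicted = as.numeric(predicted))),
    class = "clock_validation"
  )
}

#' @export
print.clock_validation <- function(x, ...) {
  cat(sprintf("clock validation [%s]: n = %d, R^2 = %.3f, RMSE = %.2f d\n",
              x$group, x$n, x$r_squared, x$rmse))
  invisible(x)
}
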