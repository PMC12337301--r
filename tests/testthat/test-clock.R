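## helper: counts whose proportions are exact (total chosen so that
## round(p * total) / total == p)
exact_counts <- function(props, samples, total = 1000L) {
  toy_counts(samples, props, total = total)
}

test_that("correlation filter retains linear sites and drops constant ones", {
  samples <- toy_samples(ages = c(6, 12, 18, 24, 30), reps = 2)
  n_ctrl <- sum(samples$treatment == "control")
  props <- matrix(0.5, 3, nrow(samples))
  props[1, ] <- samples$age_days / 100          # exactly linear in age
  props[3, ] <- rep(c(0.2, 0.8), length.out = nrow(samples))  # age-free
  counts <- exact_counts(props, samples)
  res <- correlation_filter(counts, samples)
  expect_true(res$retained[1])
  expect_equal(res$r[1], 1, tolerance = 1e-12)
  expect_false(res$retained[2])                 # constant: excluded, r NA
  expect_true(is.na(res$r[2]))
  expect_false(res$retained[3])
})

test_that("correlation r and p match cor.test exactly", {
  set.seed(99)
  samples <- toy_samples(ages = c(6, 12, 18, 24, 30), reps = 4)
  ctrl <- samples$treatment == "control"
  n_sites <- 12
  props <- matrix(round(runif(n_sites * nrow(samples)), 3), n_sites)
  counts <- exact_counts(props, samples)
  res <- correlation_filter(counts, samples, r_min = 0.3, p_max = 0.05)
  ages <- samples$age_days[ctrl]
  for (i in seq_len(n_sites)) {
    ct <- cor.test(props[i, ctrl], ages)
    expect_equal(res$r[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(res$p[i], ct$p.value, tolerance = 1e-10)
  }
  expect_setequal(attr(res, "site_ids"),
                  res$site_id[abs(res$r) >= 0.3 & res$p <= 0.05 &
                                !is.na(res$r)])
})

test_that("a single perfect feature interpolates ages as lambda -> 0", {
  samples <- toy_samples(ages = c(6, 12, 18, 24, 30), reps = 4)
  props <- matrix(samples$age_days / 100, 1, nrow(samples))
  counts <- exact_counts(props, samples)
  fit <- fit_elastic_net_clock(counts, samples, k_folds = 5, repeats = 2,
                               lambda = c(1e-7, 1e-8), seed = 42)
  ctrl <- samples$treatment == "control"
  pred <- predict_epigenetic_age(fit$model, counts)
  expect_lt(max(abs(pred[samples$library_id[ctrl]] -
                      samples$age_days[ctrl])), 1e-6)
  expect_equal(fit$validation$rmse, 0, tolerance = 1e-6)
  expect_equal(fit$validation$r_squared, 1, tolerance = 1e-10)
})

test_that("a saturating penalty shrinks the panel to zero and predicts the mean", {
  set.seed(7)
  samples <- toy_samples(ages = c(6, 12, 18, 24, 30), reps = 4)
  props <- matrix(round(runif(5 * nrow(samples)), 3), 5)
  counts <- exact_counts(props, samples)
  fit <- fit_elastic_net_clock(counts, samples, k_folds = 5, repeats = 2,
                               lambda = c(1e4, 0.99e4), seed = 42)
  expect_length(clock_panel(fit$model), 0)
  ctrl <- samples$treatment == "control"
  pred <- predict_epigenetic_age(fit$model, counts)
  expect_equal(unname(pred[samples$library_id[ctrl]]),
               rep(mean(samples$age_days[ctrl]), sum(ctrl)),
               tolerance = 1e-8)
  expect_lte(fit$validation$r_squared, 0 + 1e-8)
})

test_that("the penalized solution matches an independent coordinate-descent oracle", {
  set.seed(123)
  samples <- toy_samples(ages = c(6, 12, 18, 24, 30), reps = 2)
  ctrl <- samples$treatment == "control"          # 10 training libraries
  props <- matrix(round(runif(3 * nrow(samples)), 3), 3)
  ## give the features some age signal so the solution is nontrivial
  props[1, ] <- pmin(pmax(samples$age_days / 40 +
                            round(rnorm(nrow(samples), 0, 0.02), 3), 0), 1)
  counts <- exact_counts(props, samples)
  fit <- fit_elastic_net_clock(counts, samples, k_folds = 5, repeats = 1,
                               lambda = c(0.5, 0.1), seed = 1)
  lam <- fit$model$lambda
  x <- t(props[, ctrl])
  colnames(x) <- counts$sites$site_id
  y <- samples$age_days[ctrl]
  oracle <- oracle_enet(x, y, lambda = lam, alpha = 0.5)
  full <- setNames(numeric(3), counts$sites$site_id)
  full[names(fit$model$coefficients)] <- fit$model$coefficients
  expect_lt(max(abs(unname(full) - unname(oracle$beta))), 1e-6)
  expect_lt(abs(fit$model$intercept - oracle$intercept), 1e-6)
})

test_that("predictions are invariant to affine rescaling of the features", {
  set.seed(31)
  samples <- toy_samples(ages = c(6, 12, 18, 24, 30), reps = 4)
  n <- nrow(samples)
  props <- matrix(round(runif(6 * n, 0.1, 0.9), 2), 6)
  props[1, ] <- round(samples$age_days / 50 + 0.1, 2)
  counts_a <- exact_counts(props, samples, total = 100L)
  counts_b <- exact_counts(props / 2 + 0.25, samples, total = 200L)
  fa <- fit_elastic_net_clock(counts_a, samples, k_folds = 5, repeats = 2,
                              seed = 5)
  fb <- fit_elastic_net_clock(counts_b, samples, k_folds = 5, repeats = 2,
                              seed = 5)
  pa <- predict_epigenetic_age(fa$model, counts_a)
  pb <- predict_epigenetic_age(fb$model, counts_b)
  expect_equal(pa, pb, tolerance = 1e-8)
  expect_equal(fa$model$lambda, fb$model$lambda)
})

test_that("panel size never grows as the penalty increases", {
  des <- study_design(seed = 81)
  arch <- clock_architecture(n_clock_cpgs = 20, n_null_cpgs = 80)
  sim <- generate_methylation_dataset(des, arch)
  fit <- fit_elastic_net_clock(sim$counts, sim$samples, k_folds = 5,
                               repeats = 1, nlambda = 40, seed = 3)
  sizes <- fit$model$cv$panel_size      # along decreasing lambda
  ## nondecreasing as the penalty relaxes, up to transient single-variable
  ## active-set exchanges that coordinate-descent paths genuinely produce
  expect_true(all(cummax(sizes) - sizes <= 2))
  expect_gte(sizes[length(sizes)], sizes[1])
  expect_equal(sizes[1], 0)             # lambda_max zeroes the panel
})

test_that("prediction errors on missing panel sites unless imputation is on", {
  model <- epiclock:::new_clock_model(
    intercept = 2, coefficients = c(sA = 10, sB = -5), alpha = 0.5,
    lambda = 0.1, feature_center = c(sA = 0.4, sB = 0.6),
    feature_scale = c(sA = 0.1, sB = 0.1), training_libraries = "x",
    seed = 1L
  )
  props <- matrix(c(0.5, 0.5), 1, 2,
                  dimnames = list("sA", c("L1", "L2")))
  expect_error(predict_epigenetic_age(model, props), "sB")
  expect_message(
    pred <- predict_epigenetic_age(model, props, impute_missing = TRUE),
    "sB")
  expect_equal(unname(pred), rep(2 + 10 * 0.5 - 5 * 0.6, 2))

  ## all-zero model predicts the intercept everywhere
  model0 <- epiclock:::new_clock_model(
    intercept = 17.5, coefficients = numeric(0), alpha = 0.5, lambda = 1,
    feature_center = numeric(0), feature_scale = numeric(0),
    training_libraries = "x", seed = 1L)
  expect_equal(unname(predict_epigenetic_age(model0, props)), c(17.5, 17.5))
})

test_that("validation metrics match hand-computed sums", {
  ages <- c(6, 12, 18, 24, 30)
  ## predictions identical to ages
  v1 <- validate_clock(ages, ages, "g")
  expect_equal(v1$r_squared, 1)
  expect_equal(v1$rmse, 0)
  ## predictions equal to the mean
  v0 <- validate_clock(rep(mean(ages), 5), ages, "g")
  expect_equal(v0$r_squared, 0)
  ## arbitrary 5-point fixture against explicit sums
  pred <- c(7.1, 10.4, 19.0, 22.8, 31.5)
  v <- validate_clock(pred, ages, "g")
  ss_res <- sum((pred - ages)^2)
  ss_tot <- sum((ages - mean(ages))^2)
  expect_equal(v$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-12)
  expect_equal(v$rmse, sqrt(mean((pred - ages)^2)), tolerance = 1e-12)
  expect_error(validate_clock(pred, rep(6, 5), "g"), "zero variance")
})
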