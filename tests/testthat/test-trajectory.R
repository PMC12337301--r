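## exact two-group lines used by several blocks
two_lines <- function(noise = 0, seed = 1) {
  set.seed(seed)
  day <- rep(rep(c(6, 12, 18, 24, 30), each = 4), 2)
  treatment <- rep(c("control", "diapause"), each = 20)
  y <- ifelse(treatment == "control", 1.2 + 0.8 * day, 5.0 + 0.55 * day) +
    rnorm(40, 0, noise)
  list(y = y, day = day, treatment = treatment)
}

test_that("noise-free lines are recovered exactly", {
  d <- two_lines(noise = 0)
  ## lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(fit_trajectory(d$y, d$day, d$treatment))
  expect_equal(unname(fit$slopes), c(0.8, 0.55), tolerance = 1e-10)
  expect_equal(unname(fit$intercepts), c(1.2, 5.0), tolerance = 1e-10)
  expect_equal(fit$interaction$estimate, -0.25, tolerance = 1e-10)
  expect_equal(fit$interaction$df, 36)
  cd <- convergence_day(fit)
  expect_equal(as.numeric(cd), (5.0 - 1.2) / (0.8 - 0.55), tolerance = 1e-8)
})

test_that("identical group data give a zero interaction with p = 1", {
  set.seed(4)
  day <- rep(c(6, 12, 18, 24, 30), each = 4)
  y <- 2 + 0.7 * day + rnorm(20, 0, 1)
  fit <- fit_trajectory(c(y, y), c(day, day),
                        rep(c("a", "b"), each = 20))
  expect_equal(fit$interaction$estimate, 0, tolerance = 1e-12)
  expect_equal(fit$interaction$p, 1, tolerance = 1e-10)
  expect_true(is.na(convergence_day(fit)))
})

test_that("coefficients, SEs and contrasts match the normal-equations oracle", {
  d <- two_lines(noise = 1.5, seed = 10)
  fit <- fit_trajectory(d$y, d$day, d$treatment)
  tr <- as.integer(d$treatment == "diapause")
  X <- cbind(1, d$day, tr, d$day * tr)
  o <- oracle_ols(X, d$y)
  expect_equal(unname(fit$slopes["control"]), o$beta[2], tolerance = 1e-8)
  expect_equal(unname(fit$slopes["diapause"]), o$beta[2] + o$beta[4],
               tolerance = 1e-8)
  expect_equal(unname(fit$intercepts["control"]), o$beta[1],
               tolerance = 1e-8)
  expect_equal(fit$interaction$estimate, o$beta[4], tolerance = 1e-8)
  expect_equal(fit$interaction$se, o$se[4], tolerance = 1e-8)
  expect_equal(fit$interaction$t, o$t[4], tolerance = 1e-8)
  expect_equal(fit$interaction$p, o$p[4], tolerance = 1e-8)
  expect_equal(fit$sigma2, o$sigma2, tolerance = 1e-8)

  ## contrast at day 12 from the oracle covariance
  ct <- contrast_at_day(fit, 12)
  L <- c(0, 0, 1, 12)
  expect_equal(ct$difference, sum(L * o$beta), tolerance = 1e-8)
  expect_equal(ct$se, sqrt(drop(t(L) %*% o$vcov %*% L)), tolerance = 1e-8)
  expect_equal(ct$df, o$df)

  ## OLS residuals orthogonal to the design
  r <- d$y - X %*% o$beta
  expect_lt(max(abs(t(X) %*% r)), 1e-8)
})

test_that("contrasts agree with emmeans post hoc estimates", {
  d <- two_lines(noise = 2, seed = 12)
  fit <- fit_trajectory(d$y, d$day, d$treatment)
  em <- emmeans::emmeans(fit$lm, ~ treatment | dayc,
                         at = list(dayc = 30 - fit$center))
  pr <- as.data.frame(emmeans::contrast(em, "revpairwise"))
  ct <- suppressWarnings(contrast_at_day(fit, 30))
  expect_equal(ct$difference, pr$estimate, tolerance = 1e-8)
  expect_equal(ct$se, pr$SE, tolerance = 1e-8)
  expect_equal(ct$p, pr$p.value, tolerance = 1e-8)
})

test_that("the contrast crosses zero exactly at the convergence day", {
  d <- two_lines(noise = 1, seed = 13)
  fit <- fit_trajectory(d$y, d$day, d$treatment)
  cd <- as.numeric(convergence_day(fit))
  ct <- suppressWarnings(contrast_at_day(fit, cd))
  expect_lt(abs(ct$difference), 1e-8)
  ## and the contrast is linear in day
  c1 <- suppressWarnings(contrast_at_day(fit, 10))
  c2 <- suppressWarnings(contrast_at_day(fit, 20))
  c3 <- suppressWarnings(contrast_at_day(fit, 30))
  expect_equal(c2$difference - c1$difference, c3$difference - c2$difference,
               tolerance = 1e-10)
})

test_that("percent slowdown handles the limiting cases", {
  expect_equal(percent_slowdown(0.5, 0.5), 0)
  expect_equal(percent_slowdown(0.5, 0), 100)
  expect_error(percent_slowdown(0, 0.5), "nonzero")
  expect_equal(percent_slowdown(0.78812, 0.55828), 29.16307,
               tolerance = 1e-5)
})

test_that("parallel and identical lines report no convergence", {
  p1 <- line_intersection_day(1, 0.5, 3, 0.5)
  expect_true(is.na(p1))
  expect_equal(attr(p1, "reason"), "parallel")
  p2 <- line_intersection_day(1, 0.5, 1, 0.5)
  expect_equal(attr(p2, "reason"), "identical")
})

test_that("extrapolation follows the line and warns outside the range", {
  expect_equal(extrapolate_group_age(6, 10, 0, 30), 10)
  expect_equal(extrapolate_group_age(6, 8.53, 0.78812, 6), 8.53)
  d <- two_lines(noise = 1, seed = 15)
  fit <- fit_trajectory(d$y, d$day, d$treatment)
  expect_warning(contrast_at_day(fit, 40), "outside")
})

test_that("the planted slowdown is recovered within its confidence interval", {
  ## direct trajectory recovery from latent-age truth plus clock-scale noise
  set.seed(61)
  cover <- 0
  for (i in 1:40) {
    day <- rep(rep(c(6, 12, 18, 24, 30), each = 4), 2)
    grp <- rep(1:2, each = 20)
    latent <- ifelse(grp == 1, day, 0.708 * (day + 2.8))
    y <- latent + rnorm(40, 0, 1.5)
    fit <- fit_trajectory(y, day, c("control", "diapause")[grp])
    ci <- slowdown_ci(fit)
    cover <- cover + (ci$lower <= 29.2 && 29.2 <= ci$upper)
  }
  expect_gte(cover / 40, 0.85)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_trajectory(1:6, c(6, 6, 6, 12, 12, 12),
                              rep(c("a", "b"), 3)), NA)
  expect_error(fit_trajectory(1:6, rep(6, 6), rep(c("a", "b"), 3)),
               "distinct days")
  expect_error(fit_trajectory(1:6, c(6, 12, 18, 24, 30, 36), rep("a", 6)),
               "two treatment")
})
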