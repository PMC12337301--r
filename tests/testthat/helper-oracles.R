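## Independent brute-force oracles used to check the package's numerics.
## These deliberately avoid the code paths (and, where possible, the
## library calls) they are checking.

## exact upper binomial tail P(X >= k) by direct summation
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  sum(vapply(k:n, function(x) {
    choose(n, x) * p^x * (1 - p)^(n - x)
  }, numeric(1)))
}

## OLS via explicit normal equations: coefficients, SEs, t, two-sided p
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  r <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(r^2) / df
  V <- s2 * solve(XtX)
  se <- unname(sqrt(diag(V)))
  beta <- unname(drop(beta))
  tt <- beta / se
  list(beta = beta, se = se, t = tt,
       p = 2 * pt(abs(tt), df, lower.tail = FALSE),
       vcov = unname(V), sigma2 = s2, df = df)
}

## Elastic-net gaussian solution by coordinate descent under the
## field-standard convention: features and response standardized by their
## 1/n standard deviations, objective
##   1/(2n) * RSS + lambda * (alpha*|b|_1 + (1-alpha)/2 * |b|_2^2)
## solved on the standardized scale (lambda interpreted on that scale),
## coefficients returned on the original scale.
oracle_enet <- function(x, y, lambda, alpha, tol = 1e-13, maxit = 1e5) {
  sy <- sqrt(mean((y - mean(y))^2))
  sol <- oracle_enet_raw(x, y / sy, lambda / sy, alpha, tol, maxit)
  list(intercept = sol$intercept * sy, beta = sol$beta * sy)
}

oracle_enet_raw <- function(x, y, lambda, alpha, tol = 1e-13, maxit = 1e5) {
  n <- nrow(x)
  xm <- colMeans(x)
  xs <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  xs[xs == 0] <- 1
  xc <- sweep(sweep(x, 2, xm, "-"), 2, xs, "/")
  ym <- mean(y)
  yc <- y - ym
  p <- ncol(x)
  b <- numeric(p)
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  r <- yc
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      bj_old <- b[j]
      z <- mean(xc[, j] * r) + bj_old          # since mean(xc_j^2) = 1
      bj <- soft(z, lambda * alpha) / (1 + lambda * (1 - alpha))
      if (bj != bj_old) {
        r <- r - xc[, j] * (bj - bj_old)
        delta <- max(delta, abs(bj - bj_old))
      }
      b[j] <- bj
    }
    if (delta < tol) break
  }
  beta <- b / xs
  list(intercept = ym - sum(beta * xm), beta = beta)
}

## Cox log partial likelihood for a binary covariate, no tied event times
oracle_cox_loglik <- function(beta, time, event, z) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * z[i] - log(sum(exp(beta * z[risk])))
  }
  ll
}

## maximize by three-stage grid refinement
oracle_cox_grid <- function(time, event, z, lo = -5, hi = 5) {
  for (step in 1:4) {
    grid <- seq(lo, hi, length.out = 401)
    ll <- vapply(grid, oracle_cox_loglik, numeric(1),
                 time = time, event = event, z = z)
    best <- grid[which.max(ll)]
    w <- (hi - lo) / 40
    lo <- best - w
    hi <- best + w
  }
  best
}

## hand product-limit estimator with Greenwood variance
oracle_km <- function(time, event) {
  tt <- sort(unique(time))
  n <- length(time)
  surv <- numeric(0)
  gw <- numeric(0)
  s <- 1
  acc <- 0
  out_t <- numeric(0)
  for (t in tt) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / at_risk)
    if (d > 0) acc <- acc + d / (at_risk * (at_risk - d))
    out_t <- c(out_t, t)
    surv <- c(surv, s)
    gw <- c(gw, s^2 * acc)
  }
  data.frame(time = out_t, surv = surv, greenwood_var = gw)
}

## beta-binomial sampler independent of the package's generator
oracle_rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(rbinom(n, size, prob))
  k <- (1 - rho) / rho
  rbinom(n, size, rbeta(n, prob * k, (1 - prob) * k))
}
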