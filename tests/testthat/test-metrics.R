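# NRMSE, Brier, downstream model evaluation, Rubin pooling, coverage

test_that("nrmse follows the standardized Frobenius formula", {
  # identity
  X <- data.frame(a = rnorm(10), b = runif(10))
  expect_equal(nrmse(X, X), 0)

  # hand example: n=2, p=1, original (0,2), imputed (0,0); sample SD sqrt(2)
  expect_equal(nrmse(data.frame(x = c(0, 0)), data.frame(x = c(0, 2))), 1.0)

  # scale invariance when parameters are recomputed from the doubled table
  set.seed(200)
  A <- data.frame(x = rnorm(20), y = rnorm(20))
  B <- A; B$x[1:5] <- B$x[1:5] + 1
  expect_equal(nrmse(B, A), nrmse(B * 2, A * 2), tolerance = 1e-12)

  # p = 1 reduces to the ordinary standardized RMSE
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(nrmse(data.frame(x = a), data.frame(x = b)),
               sqrt(mean(((a - b) / sd(b))^2)), tolerance = 1e-12)

  # masked version normalizes over the imputed cells only
  M <- matrix(c(TRUE, FALSE), 2, 1)
  expect_equal(nrmse(data.frame(x = c(1, 2)), data.frame(x = c(0, 2)),
                     mask = M),
               abs(1 / sd(c(0, 2))), tolerance = 1e-12)

  # zero-SD column errors
  expect_error(nrmse(data.frame(x = c(1, 1)), data.frame(x = c(2, 2))),
               "zero-SD")
})

test_that("brier score arithmetic", {
  y <- c(1, 0, 1)
  expect_equal(brier_score(y, y), 0)
  expect_equal(brier_score(rep(0.5, 4), c(0, 1, 0, 1)), 0.25)
  expect_equal(brier_score(c(0.8, 0.3), c(1, 0)), 0.065)
})

test_that("downstream logistic evaluation is deterministic and sane", {
  set.seed(201)
  st <- sim_study(400, 4, "normal", "linear", "MCAR", 0.2, seed = 202)
  # intercept-only model scores the base rate
  b0 <- downstream_brier(st$train[, 0], st$y_train, st$train[, 0], st$y_train)
  ybar <- mean(st$y_train)
  expect_equal(as.numeric(b0), mean((ybar - st$y_train)^2), tolerance = 1e-6)

  b1 <- downstream_brier(st$train, st$y_train, st$test, st$y_test)
  b2 <- downstream_brier(st$train, st$y_train, st$test, st$y_test)
  expect_identical(b1, b2)

  # complete data never scores worse than random imputation (majority vote)
  wins <- 0
  for (s in 1:20) {
    st <- sim_study(300, 4, "normal", "linear", "MCAR", 0.4, seed = 210 + s)
    r_tr <- impute_random(st$train_mis, seed = 230 + s)
    r_te <- impute_random(st$test_mis, seed = 250 + s)
    bc <- downstream_brier(st$train, st$y_train, st$test, st$y_test)
    br <- downstream_brier(r_tr, st$y_train, r_te, st$y_test)
    wins <- wins + (bc <= br)
  }
  expect_gt(wins, 10)

  # separation triggers the flagged ridge fallback instead of failing
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  bs <- downstream_brier(data.frame(x = xs), ys, data.frame(x = xs), ys)
  expect_identical(attr(bs, "flag"), "ridge")
  expect_lt(as.numeric(bs), 0.1)
})

test_that("Rubin pooling reproduces the hand-computed example", {
  p <- rubin_pool(c(1, 3), c(1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$se, 2)                         # total variance 4
  expect_equal(p$df, 16 / 9)
  expect_lt(p$lower, p$estimate); expect_gt(p$upper, p$estimate)

  # identical estimates: between-variance 0, normal quantile
  p0 <- rubin_pool(rep(1.5, 5), rep(0.3, 5))
  expect_equal(p0$se, 0.3)
  expect_identical(p0$df, Inf)
  expect_equal(p0$upper - p0$lower, 2 * qnorm(0.975) * 0.3, tolerance = 1e-12)

  # m = 1 is flagged and returns the single estimate with its own SE
  p1 <- rubin_pool(2, 0.5)
  expect_identical(attr(p1, "flag"), "single-imputation")
  expect_equal(p1$estimate, 2)
  expect_equal(p1$se, 0.5)

  # matrix input pools per column
  pm <- rubin_pool(cbind(a = c(1, 3), b = c(0, 0)), cbind(c(1, 1), c(2, 2)))
  expect_equal(pm$estimate, c(a = 2, b = 0), ignore_attr = TRUE)
  expect_equal(pm$se[1], 2)
})

test_that("pooled intervals equal complete-data intervals when imputation is exact", {
  set.seed(220)
  st <- sim_study(500, 4, "normal", "linear", "MCAR", 0.2, seed = 221)
  f <- arfimpute:::fit_logistic_inference(as.matrix(st$train), st$y_train)
  m <- 10
  pooled <- rubin_pool(matrix(rep(f$coef, each = m), m),
                       matrix(rep(f$se, each = m), m))
  expect_equal(pooled$estimate, f$coef, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(pooled$se, f$se, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("complete-data confidence intervals attain nominal coverage", {
  # calibrates the harness itself: correctly specified logistic data with no
  # missingness should cover the true coefficients at ~95%
  K <- 200
  p <- 4
  beta <- equi_beta(p)
  hits <- matrix(NA, K, p)
  for (k in seq_len(K)) {
    set.seed(230 + k)
    X <- sim_copula_data(400, p, "normal")
    y <- sim_outcome(X, beta, "linear")
    f <- arfimpute:::fit_logistic_inference(as.matrix(X), y)
    lo <- f$coef - qnorm(0.975) * f$se
    hi <- f$coef + qnorm(0.975) * f$se
    hits[k, ] <- lo[-1] < beta & beta < hi[-1]
  }
  cov <- mean(hits)
  mc_se <- sqrt(0.95 * 0.05 / (K * p))
  expect_lt(abs(cov - 0.95), 3 * mc_se + 0.01)
})

test_that("coverage, width and coefficient RMSE arithmetic", {
  lo <- c(0, 0, 0, 2); hi <- c(1, 1, 1, 3)
  expect_equal(coverage_rate(lo, hi, 0.5), 0.75)
  expect_equal(coverage_rate(lo, hi, 10), 0)
  expect_equal(coverage_rate(c(-1, -1), c(1, 1), 0), 1)
  expect_equal(avg_ci_width(c(0, 0), c(1, 3)), 2)
  expect_equal(avg_ci_width(lo + 5, hi + 5), avg_ci_width(lo, hi))
  expect_equal(coef_rmse(c(1, -1), 0), 1)
  expect_equal(coef_rmse(rep(0.3, 5), 0.3), 0)
  # RMSE dominates absolute bias
  est <- rnorm(20, 0.1, 0.2)
  expect_gte(coef_rmse(est, 0), abs(mean(est)))
})
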