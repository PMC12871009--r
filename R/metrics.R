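#' Normalized root mean squared error between an imputed and a complete table
#'
#' Both tables are standardized column-wise by the mean and (sample, n-1
#' divisor) standard deviation of the *original* complete table, then the
#' Frobenius-norm RMSE is taken:
#' \deqn{\mathrm{NRMSE} = \sqrt{\frac{1}{n p} \sum_{ij}
#'   (\tilde{\dot x}_{ij} - \tilde x_{ij})^2}.}
#' With a `mask` of the imputed cells, the sum runs over the masked cells and
#' is normalized by their count instead of \eqn{n p}; since observed cells
#' pass through imputation unchanged, the two versions differ only in the
#' normalizing constant. Categorical columns must be numerically coded (e.g.
#' 0/1) before calling; the error enters numerically like any other column.
#'
#' @param imputed,original data.frames or matrices of identical shape with
#'   numeric columns; `original` is complete.
#' @param mask Optional logical matrix marking the imputed (originally
#'   missing) cells.
#' @param mu,sigma Optional standardization parameters; default column means
#'   and SDs of `original`.
#' @return A non-negative number.
#' @examples
#' nrmse(data.frame(x = c(0, 0)), data.frame(x = c(0, 2)))  # 1
#' @export
nrmse <- function(imputed, original, mask = NULL, mu = NULL, sigma = NULL) {
  Xi <- as.matrix(as.data.frame(imputed))
  Xo <- as.matrix(as.data.frame(original))
  storage.mode(Xi) <- "double"; storage.mode(Xo) <- "double"
  stopifnot(identical(dim(Xi), dim(Xo)))
  if (anyNA(Xo)) stop("original table must be complete")
  if (is.null(mu)) mu <- colMeans(Xo)
  if (is.null(sigma)) sigma <- apply(Xo, 2, stats::sd)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("zero-SD column: standardization undefined for column(s) ",
         paste(which(sigma <= 0), collapse = ", "))
  D <- sweep(Xi, 2, mu) - sweep(Xo, 2, mu)
  D <- sweep(D, 2, sigma, "/")
  if (is.null(mask)) {
    sqrt(mean(D^2))
  } else {
    mask <- as.matrix(mask)
    stopifnot(identical(dim(mask), dim(D)))
    if (!any(mask)) return(0)
    sqrt(mean(D[mask]^2))
  }
}

#' Brier score of predicted probabilities
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes, \eqn{\frac{1}{n}\sum_i (\hat\pi_i - y_i)^2}.
#'
#' @param prob Predicted probabilities in \[0, 1\].
#' @param y Binary outcomes (0/1).
#' @return A number in \[0, 1\].
#' @export
brier_score <- function(prob, y) {
  stopifnot(length(prob) == length(y))
  mean((prob - as.numeric(y))^2)
}

#' Downstream prediction score of an imputed dataset
#'
#' Fits a maximum-likelihood logistic regression of `y_train` on the imputed
#' training features, predicts probabilities on the imputed test features,
#' and returns the Brier score against `y_test`. Under (quasi-)separation or
#' non-convergence the fit falls back to a lightly ridge-penalized logistic
#' likelihood (penalty `ridge` on the slopes) and the result is flagged via
#' `attr(, "flag")`.
#'
#' @param train,test data.frames/matrices of numeric features (possibly zero
#'   columns for an intercept-only model).
#' @param y_train,y_test Binary outcomes.
#' @param ridge Ridge penalty used by the separation fallback.
#' @return The Brier score, with attribute `flag` (`""` or `"ridge"`).
#' @export
downstream_brier <- function(train, y_train, test, y_test, ridge = 1e-3) {
  Xtr <- as.matrix(as.data.frame(train))
  Xte <- as.matrix(as.data.frame(test))
  storage.mode(Xtr) <- "double"; storage.mode(Xte) <- "double"
  fit <- fit_logistic(Xtr, as.numeric(y_train), ridge = ridge)
  eta <- drop(cbind(1, Xte) %*% fit$coef)
  out <- brier_score(stats::plogis(eta), y_test)
  attr(out, "flag") <- fit$flag
  out
}

# logistic fit with separation fallback; returns coef (intercept first)
fit_logistic <- function(X, y, ridge = 1e-3) {
  df <- data.frame(y = y)
  ok <- TRUE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()),
    warning = function(w) {
      ok <<- FALSE
      invokeRestart("muffleWarning")
    })
  sep <- !fit$converged || any(abs(fit$coefficients) > 20) ||
    any(fit$fitted.values < 1e-12) || any(fit$fitted.values > 1 - 1e-12)
  if (ok && !sep) return(list(coef = fit$coefficients, flag = ""))
  # ridge-penalized logistic likelihood (intercept unpenalized)
  Z <- cbind(1, X)
  q <- ncol(Z)
  nll <- function(b) {
    eta <- drop(Z %*% b)
    -sum(y * eta - log1p(exp(eta))) + ridge * sum(b[-1]^2)
  }
  gr <- function(b) {
    p <- stats::plogis(drop(Z %*% b))
    g <- -drop(crossprod(Z, y - p))
    g[-1] <- g[-1] + 2 * ridge * b[-1]
    g
  }
  opt <- stats::optim(rep(0, q), nll, gr, method = "BFGS",
                      control = list(maxit = 500))
  list(coef = opt$par, flag = "ridge")
}

# logistic fit returning coefficients and standard errors (for pooling);
# same separation fallback
fit_logistic_inference <- function(X, y, ridge = 1e-3) {
  Z <- cbind(1, X)
  ok <- TRUE
  fit <- withCallingHandlers(
    stats::glm.fit(Z, y, family = stats::binomial()),
    warning = function(w) { ok <<- FALSE; invokeRestart("muffleWarning") })
  sep <- !fit$converged || any(abs(fit$coefficients) > 20) ||
    any(fit$fitted.values < 1e-12) || any(fit$fitted.values > 1 - 1e-12)
  flag <- ""
  if (!ok || sep) {
    co <- fit_logistic(X, y, ridge = ridge)$coef
    pr <- stats::plogis(drop(Z %*% co))
    flag <- "ridge"
  } else {
    co <- fit$coefficients
    pr <- fit$fitted.values
  }
  W <- pr * (1 - pr)
  info <- crossprod(Z * sqrt(W))
  se <- sqrt(diag(solve(info + diag(1e-12, ncol(Z)))))
  list(coef = co, se = se, flag = flag)
}

#' Pool repeated-imputation estimates by Rubin's rules
#'
#' Given `m` per-imputation coefficient estimates and standard errors, the
#' pooled estimate is the mean \eqn{\bar\beta}; the total variance combines
#' the within-imputation variance \eqn{\bar W} (mean squared SE) and the
#' between-imputation variance \eqn{B} (sample variance of the estimates):
#' \eqn{T = \bar W + (1 + 1/m) B}. Confidence intervals use the classical
#' degrees of freedom \eqn{(m-1)\,(1 + \bar W / ((1+1/m) B))^2}; when
#' \eqn{B = 0} (or `m = 1`, which is flagged) the normal quantile is used.
#'
#' @param estimates An `m x q` matrix (or length-`m` vector) of coefficient
#'   estimates, one row per imputation.
#' @param ses Matching matrix/vector of standard errors.
#' @param alpha Confidence level is `1 - alpha` (default 0.05).
#' @return A data.frame with columns `estimate`, `se`, `df`, `lower`,
#'   `upper`, one row per coefficient, with attribute
#'   `flag = "single-imputation"` when `m = 1`.
#' @examples
#' rubin_pool(c(1, 3), c(1, 1))  # se 2, df 16/9
#' @export
rubin_pool <- function(estimates, ses, alpha = 0.05) {
  est <- if (is.matrix(estimates)) estimates else matrix(estimates, ncol = 1)
  se <- if (is.matrix(ses)) ses else matrix(ses, ncol = 1)
  stopifnot(identical(dim(est), dim(se)))
  m <- nrow(est); q <- ncol(est)
  beta_bar <- colMeans(est)
  W <- colMeans(se^2)
  flag <- ""
  if (m == 1L) {
    tot <- W
    df <- rep(Inf, q)
    flag <- "single-imputation"
  } else {
    B <- apply(est, 2, stats::var)
    tot <- W + (1 + 1 / m) * B
    df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  }
  qq <- ifelse(is.finite(df), stats::qt(1 - alpha / 2, df),
               stats::qnorm(1 - alpha / 2))
  out <- data.frame(estimate = beta_bar, se = sqrt(tot), df = df,
                    lower = beta_bar - qq * sqrt(tot),
                    upper = beta_bar + qq * sqrt(tot))
  rownames(out) <- colnames(est)
  attr(out, "flag") <- flag
  out
}

#' Coverage rate of replicated confidence intervals
#'
#' Fraction of replications whose interval contains the true parameter,
#' \eqn{\frac{1}{K}\sum_k 1\{a^{(k)} < \beta < b^{(k)}\}}.
#'
#' @param lower,upper Vectors of interval bounds over `K` replications.
#' @param beta_true The true parameter value.
#' @return A number in \[0, 1\].
#' @export
coverage_rate <- function(lower, upper, beta_true) {
  stopifnot(length(lower) == length(upper))
  mean(lower < beta_true & beta_true < upper)
}

#' Average width of replicated confidence intervals
#'
#' @inheritParams coverage_rate
#' @return The mean of `upper - lower`.
#' @export
avg_ci_width <- function(lower, upper) {
  stopifnot(length(lower) == length(upper))
  mean(upper - lower)
}

#' Root mean squared error of replicated coefficient estimates
#'
#' \eqn{\sqrt{\frac{1}{K} \sum_k (\hat\beta^{(k)} - \beta)^2}} over `K`
#' replications.
#'
#' @param estimates Vector of pooled estimates over replications.
#' @param beta_true The true coefficient.
#' @return A non-negative number.
#' @export
coef_rmse <- function(estimates, beta_true) {
  sqrt(mean((estimates - beta_true)^2))
}
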