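# Gaussian-copula benchmark data, binary outcomes, MCAR/MAR/MNAR amputation,
# and the replicated evaluation grid.

#' Correlated features from a Gaussian copula
#'
#' Draws a latent multivariate normal with Toeplitz correlation
#' \eqn{\mathrm{Corr}(Z)_{ij} = 0.5^{|i-j|}} (so neighboring features are the
#' most correlated), maps it through the standard normal CDF and then through
#' the inverse CDF of the requested marginal. Marginals: standard normal,
#' Bernoulli(0.5) (`"binary"`), Poisson(2), Gamma(shape 2, rate 0.5), and
#' Uniform(-1, 1).
#'
#' @param n,p Rows and columns.
#' @param marginal One of `"normal"`, `"binary"`, `"poisson"`, `"gamma"`,
#'   `"uniform"`.
#' @param rho Base of the Toeplitz correlation (default 0.5).
#' @param seed Optional integer seed.
#' @return An `n x p` data.frame of numeric columns `x1..xp` (binary coded
#'   0/1).
#' @export
sim_copula_data <- function(n, p,
                            marginal = c("normal", "binary", "poisson",
                                         "gamma", "uniform"),
                            rho = 0.5, seed = NULL) {
  marginal <- match.arg(marginal)
  if (!is.null(seed)) set.seed(seed)
  S <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
  Z <- matrix(stats::rnorm(n * p), n, p) %*% chol(S)
  U <- stats::pnorm(Z)
  X <- switch(marginal,
    normal  = stats::qnorm(U),
    binary  = stats::qbinom(U, 1, 0.5),
    poisson = stats::qpois(U, 2),
    gamma   = stats::qgamma(U, shape = 2, rate = 0.5),
    uniform = stats::qunif(U, -1, 1))
  X <- matrix(as.numeric(X), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  as.data.frame(X)
}

#' Equidistant effect sizes
#'
#' The coefficient vector \eqn{\beta = (-0.5, \dots, 0.5)} of length `p` with
#' constant step \eqn{1/(p-1)}.
#'
#' @param p Number of features.
#' @return A numeric vector of length `p`.
#' @export
equi_beta <- function(p) seq(-0.5, 0.5, length.out = p)

#' Binary outcome with linear or squared feature effects
#'
#' Draws \eqn{y_i \sim \mathrm{Bernoulli}(\pi_i)} with
#' \eqn{\pi_i = \sigma(x_i \beta)} (linear) or
#' \eqn{\pi_i = \sigma(x_i^2 \beta)} (element-wise squared features), where
#' \eqn{\sigma} is the standard logistic function.
#'
#' @param X Feature matrix/data.frame (numeric).
#' @param beta Coefficient vector of length `ncol(X)`.
#' @param effect `"linear"` or `"squared"`.
#' @param seed Optional integer seed.
#' @return An integer 0/1 vector of length `nrow(X)`.
#' @export
sim_outcome <- function(X, beta, effect = c("linear", "squared"),
                        seed = NULL) {
  effect <- match.arg(effect)
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(as.data.frame(X))
  stopifnot(length(beta) == ncol(X))
  eta <- if (effect == "linear") drop(X %*% beta) else drop((X^2) %*% beta)
  stats::rbinom(nrow(X), 1, stats::plogis(eta))
}

#' Introduce missing values by MCAR, MAR or MNAR median-split deletion
#'
#' Missingness is introduced in half of the features (the odd-indexed
#' columns); the even-indexed columns stay fully observed. Per target column
#' exactly `round(rate * n)` cells are deleted:
#'
#' * MCAR: uniformly at random;
#' * MAR: rows are split at the median of the paired fully observed control
#'   column (the right neighbor, the most correlated one under the Toeplitz
#'   structure); one side is chosen at random and all deletions fall there;
#' * MNAR: as MAR but the split is at the median of the target column itself.
#'
#' Rows equal to the median belong to the lower side; if the chosen side is
#' smaller than the deletion count (possible for discrete marginals), the
#' remaining deletions spill into the tied rows at random.
#'
#' @param X Complete data.frame.
#' @param pattern `"MCAR"`, `"MAR"` or `"MNAR"`.
#' @param rate Missingness proportion per target column, in (0, 0.5].
#' @param targets Indices of columns to ampute; default the odd columns.
#' @param seed Optional integer seed.
#' @return A list with `data` (the amputed data.frame) and `mask` (logical
#'   matrix, `TRUE` where deleted).
#' @export
sim_ampute <- function(X, pattern = c("MCAR", "MAR", "MNAR"), rate,
                       targets = NULL, seed = NULL) {
  pattern <- match.arg(pattern)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(rate > 0, rate <= 0.5)
  X <- as.data.frame(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(targets)) targets <- seq(1, p, by = 2)
  k <- round(rate * n)
  mask <- matrix(FALSE, n, p, dimnames = list(NULL, names(X)))
  if (k == 0) return(list(data = X, mask = mask))
  for (j in targets) {
    if (pattern == "MCAR") {
      rows <- sample.int(n, k)
    } else {
      ref <- if (pattern == "MAR") {
        ctrl <- if (j < p) j + 1L else j - 1L
        as.numeric(X[[ctrl]])
      } else as.numeric(X[[j]])
      med <- stats::median(ref)
      lower <- which(ref <= med)        # ties belong to the lower side
      upper <- which(ref > med)
      side <- if (stats::runif(1) < 0.5) lower else upper
      if (length(side) >= k) {
        rows <- side[sample.int(length(side), k)]
      } else {
        ties <- setdiff(which(ref == med), side)
        extra <- ties[sample.int(length(ties), k - length(side))]
        rows <- c(side, extra)
      }
    }
    mask[rows, j] <- TRUE
    X[rows, j] <- NA
  }
  list(data = X, mask = mask)
}

#' Simulate one complete benchmark study
#'
#' Bundles one replicate of the benchmark design: a Gaussian-copula training
#' table and an equally sized test table, binary outcomes with equidistant
#' effects, and separate amputation of both tables.
#'
#' @inheritParams sim_copula_data
#' @param effect `"linear"` or `"squared"`.
#' @param pattern,rate Amputation pattern and per-column missingness rate.
#' @param seed Optional integer seed.
#' @return A list with `train`, `test` (complete), `y_train`, `y_test`,
#'   `train_mis`, `test_mis` (amputed), `mask_train`, `mask_test`, and
#'   `beta`.
#' @export
sim_study <- function(n, p, marginal = "normal", effect = "linear",
                      pattern = "MCAR", rate = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  beta <- equi_beta(p)
  train <- sim_copula_data(n, p, marginal)
  test <- sim_copula_data(n, p, marginal)
  y_train <- sim_outcome(train, beta, effect)
  y_test <- sim_outcome(test, beta, effect)
  atr <- sim_ampute(train, pattern, rate)
  ate <- sim_ampute(test, pattern, rate)
  list(train = train, test = test, y_train = y_train, y_test = y_test,
       train_mis = atr$data, test_mis = ate$data,
       mask_train = atr$mask, mask_test = ate$mask,
       beta = beta, marginal = marginal, effect = effect,
       pattern = pattern, rate = rate, n = n, p = p)
}

# deterministic substream seeds: mixes the master seed with tokens (numbers
# or strings) so that changing one grid dimension never shifts another's
# random stream; stays below 2^31
substream_seed <- function(master, ...) {
  h <- as.double(master %% 2147483629)
  for (tok in list(...)) {
    if (is.character(tok)) tok <- sum(utf8ToInt(tok) * seq_along(utf8ToInt(tok)))
    h <- (h * 69069 + as.double(tok) + 1) %% 2147483629
  }
  as.integer(h) + 1L
}

#' Built-in imputers with the plug-in signature
#'
#' An imputer is a `function(data, m, seed)` returning a list of `m`
#' completed data.frames; it may attach a `"single"` attribute holding the
#' method's preferred single imputation (used for the single-imputation
#' metrics), otherwise the first completion is used. `imputer_arf()` trains
#' one ARF per call and derives the expectation-mode single imputation and
#' all `m` sampled completions from that one fit. Binary 0/1 columns are
#' handled as categorical inside the ARF and returned as numeric.
#'
#' @param ... For `imputer_arf`, arguments passed to [arf()] (e.g.
#'   `num_trees`, `min_node_size`).
#' @return A function with the plug-in signature.
#' @export
imputer_arf <- function(...) {
  arf_args <- list(...)
  function(data, m, seed) {
    if (!is.null(seed)) set.seed(seed)
    binary <- vapply(data, function(x)
      is.numeric(x) && all(x %in% c(0, 1, NA)), TRUE)
    d <- data
    for (j in which(binary)) d[[j]] <- factor(d[[j]], levels = c(0, 1))
    model <- do.call(arf, c(list(data = d), arf_args))
    single <- impute(model, d)
    sets <- impute(model, d, m = m, n_model_fits = 1L)
    back <- function(x) {
      for (j in which(binary)) x[[j]] <- as.numeric(as.character(x[[j]]))
      x
    }
    out <- lapply(sets, back)
    attr(out, "single") <- back(single)
    attr(out, "n_model_fits") <- attr(sets, "n_model_fits")
    attr(out, "n_zero_mass") <- attr(sets, "n_zero_mass")
    out
  }
}

#' @rdname imputer_arf
#' @export
imputer_random <- function() {
  function(data, m, seed) {
    sets <- impute_random(data, m = m, seed = seed)
    out <- unclass(sets)
    attributes(out) <- list()
    out
  }
}

#' @rdname imputer_arf
#' @export
imputer_median <- function() {
  f <- function(data, m, seed) {
    single <- impute_median(data)
    out <- list(single)
    attr(out, "single") <- single
    out
  }
  attr(f, "supports_multiple") <- FALSE
  f
}

#' Run the replicated benchmark grid
#'
#' For every combination of the design lists and every replicate: simulate a
#' study ([sim_study()]), run each imputer on the amputed training and test
#' tables, and score single imputation (NRMSE over the deleted cells,
#' downstream Brier via logistic regression) and, when the imputer supports
#' it, multiple imputation (per-feature Rubin-pooled coefficients and
#' confidence intervals, ready for [summarize_benchmark()]). Random streams
#' are derived deterministically per (setting, replicate, imputer), so the
#' result table is reproducible and independent of imputer order.
#'
#' @param marginals,ns,ps,effects,patterns,rates Vectors of design values;
#'   their full crossing is run.
#' @param K Replicates per design cell.
#' @param imputers Named list of plug-in imputers (see [imputer_arf()]).
#' @param m Number of multiple imputations (default 20).
#' @param seed Master seed.
#' @param inference Compute the multiple-imputation metrics (default TRUE).
#' @param score Which metric families to compute: `"all"`, `"single"`
#'   (NRMSE and downstream Brier only), or `"inference"` (pooled
#'   coefficients/intervals only, skipping the test-set imputation).
#' @param verbose Print progress.
#' @return A long-format data.frame with one row per setting, replicate,
#'   imputer, and metric (inference metrics additionally per feature).
#' @export
benchmark_grid <- function(marginals = "normal", ns = 500, ps = 4,
                           effects = "linear", patterns = "MCAR",
                           rates = 0.2, K = 1,
                           imputers = list(arf = imputer_arf()),
                           m = 20, seed = 1, inference = TRUE,
                           score = c("all", "single", "inference"),
                           verbose = FALSE, skip = NULL) {
  score <- match.arg(score)
  if (score == "single") inference <- FALSE
  grid <- expand.grid(marginal = marginals, n = ns, p = ps, effect = effects,
                      pattern = patterns, rate = rates,
                      stringsAsFactors = FALSE)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cfg <- grid[g, ]
    for (k in seq_len(max(K, 0))) {
      data_seed <- substream_seed(seed, "data", cfg$marginal, cfg$n, cfg$p,
                                  cfg$effect, cfg$pattern,
                                  round(cfg$rate * 1000), k)
      study <- sim_study(cfg$n, cfg$p, cfg$marginal, cfg$effect,
                         cfg$pattern, cfg$rate, seed = data_seed)
      for (nm in names(imputers)) {
        if (!is.null(skip) && nrow(skip) &&
            any(skip$marginal == cfg$marginal & skip$n == cfg$n &
                skip$p == cfg$p & skip$effect == cfg$effect &
                skip$pattern == cfg$pattern &
                abs(skip$rate - cfg$rate) < 1e-12 &
                skip$replicate == k & skip$imputer == nm)) next
        imp_seed <- substream_seed(seed, "imp", nm, cfg$marginal, cfg$n,
                                   cfg$p, cfg$effect, cfg$pattern,
                                   round(cfg$rate * 1000), k)
        rr <- tryCatch(
          score_replicate(study, imputers[[nm]], m, imp_seed, inference,
                          single = score != "inference"),
          error = function(e) data.frame(metric = "error", feature = NA,
                                         value = NA_real_,
                                         flag = conditionMessage(e)))
        rr$marginal <- cfg$marginal; rr$n <- cfg$n; rr$p <- cfg$p
        rr$effect <- cfg$effect; rr$pattern <- cfg$pattern
        rr$rate <- cfg$rate; rr$replicate <- k; rr$imputer <- nm
        rows[[length(rows) + 1L]] <- rr
        if (verbose)
          message(sprintf("[%d/%d] rep %d %s done", g, nrow(grid), k, nm))
      }
    }
  }
  cols <- c("marginal", "n", "p", "effect", "pattern", "rate", "replicate",
            "imputer", "metric", "feature", "value", "flag")
  if (!length(rows)) {
    out <- data.frame(marginal = character(0), n = numeric(0), p = numeric(0),
                      effect = character(0), pattern = character(0),
                      rate = numeric(0), replicate = integer(0),
                      imputer = character(0), metric = character(0),
                      feature = numeric(0), value = numeric(0),
                      flag = character(0))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, cols]
}

# one (study, imputer) evaluation -> long metric rows
score_replicate <- function(study, imputer, m, seed, inference,
                            single = TRUE) {
  supports_m <- !identical(attr(imputer, "supports_multiple"), FALSE)
  mm <- if (supports_m && inference) m else 1L
  sets_tr <- imputer(study$train_mis, mm, substream_seed(seed, "train"))
  single_tr <- attr(sets_tr, "single")
  if (is.null(single_tr)) single_tr <- sets_tr[[1]]

  res <- list()
  add <- function(metric, value, feature = NA, flag = "")
    res[[length(res) + 1L]] <<- data.frame(metric = metric, feature = feature,
                                           value = value, flag = flag)

  if (single) {
    sets_te <- imputer(study$test_mis, 1L, substream_seed(seed, "test"))
    single_te <- attr(sets_te, "single")
    if (is.null(single_te)) single_te <- sets_te[[1]]
    add("nrmse", nrmse(single_tr, study$train, mask = study$mask_train))
    db <- downstream_brier(single_tr, study$y_train, single_te, study$y_test)
    add("brier", as.numeric(db), flag = attr(db, "flag"))
  }

  if (inference && supports_m) {
    p <- study$p
    est <- matrix(NA_real_, mm, p + 1)
    ses <- matrix(NA_real_, mm, p + 1)
    flags <- character(mm)
    for (q in seq_len(mm)) {
      f <- fit_logistic_inference(as.matrix(sets_tr[[q]]), study$y_train)
      est[q, ] <- f$coef; ses[q, ] <- f$se; flags[q] <- f$flag
    }
    pooled <- rubin_pool(est, ses)
    fl <- if (any(nzchar(flags))) "ridge" else ""
    for (j in seq_len(p)) {          # skip the intercept
      add("coef", pooled$estimate[j + 1], feature = j, flag = fl)
      add("ci_lower", pooled$lower[j + 1], feature = j, flag = fl)
      add("ci_upper", pooled$upper[j + 1], feature = j, flag = fl)
    }
  }
  do.call(rbind, res)
}

#' Aggregate benchmark results into a summary table
#'
#' Produces the customary aggregate view: mean (SD) of NRMSE and Brier score
#' over replicates and settings per imputer, and for multiple imputation the
#' median (IQR) of the per-setting, per-feature coverage rate, average CI
#' width, and coefficient RMSE, where coverage/width/RMSE are first computed
#' per (setting, feature) across the K replicates against the equidistant
#' true coefficients.
#'
#' @param results A result table from [benchmark_grid()].
#' @return A data.frame with one row per imputer.
#' @export
summarize_benchmark <- function(results) {
  imps <- unique(results$imputer)
  out <- list()
  for (nm in imps) {
    r <- results[results$imputer == nm, ]
    nr <- r$value[r$metric == "nrmse"]
    br <- r$value[r$metric == "brier"]
    row <- data.frame(imputer = nm,
                      nrmse_mean = mean(nr, na.rm = TRUE),
                      nrmse_sd = stats::sd(nr),
                      brier_mean = mean(br, na.rm = TRUE),
                      brier_sd = stats::sd(br))
    inf <- r[r$metric %in% c("coef", "ci_lower", "ci_upper"), ]
    if (nrow(inf)) {
      key <- interaction(inf$marginal, inf$n, inf$p, inf$effect, inf$pattern,
                         inf$rate, inf$feature, drop = TRUE)
      cov <- wid <- rms <- numeric(0)
      for (kk in levels(key)) {
        s <- inf[key == kk, ]
        lo <- s$value[s$metric == "ci_lower"]
        hi <- s$value[s$metric == "ci_upper"]
        es <- s$value[s$metric == "coef"]
        bt <- equi_beta(s$p[1])[s$feature[1]]
        cov <- c(cov, coverage_rate(lo, hi, bt))
        wid <- c(wid, avg_ci_width(lo, hi))
        rms <- c(rms, coef_rmse(es, bt))
      }
      row$coverage_median <- stats::median(cov) * 100
      row$coverage_iqr <- stats::IQR(cov) * 100
      row$width_median <- stats::median(wid)
      row$width_iqr <- stats::IQR(wid)
      row$coef_rmse_median <- stats::median(rms)
      row$coef_rmse_iqr <- stats::IQR(rms)
    } else {
      row$coverage_median <- row$coverage_iqr <- NA_real_
      row$width_median <- row$width_iqr <- NA_real_
      row$coef_rmse_median <- row$coef_rmse_iqr <- NA_real_
    }
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}
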