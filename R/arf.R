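#' Fit an adversarial random forest density model
#'
#' Trains an adversarial random forest (ARF) on a mixed continuous/categorical
#' table that may contain missing values, and turns the converged forest into
#' a generative mixture model over the leaves. The adversarial loop alternates
#' two steps: (i) grow a random-forest discriminator that tries to tell the
#' real rows (label 1) from synthetic rows (label 0), using
#' missingness-incorporated-in-attributes (MIA) splits so that `NA` cells are
#' routed to a learned child; (ii) regenerate the synthetic table by
#' bootstrapping each feature independently *within each leaf* of the current
#' forest. The loop stops as soon as the out-of-bag (OOB) accuracy of the
#' discriminator falls below `0.5 + delta`, i.e. as soon as real and synthetic
#' rows are statistically indistinguishable; that forest is returned.
#'
#' At convergence, features are treated as locally independent within each
#' leaf, so the joint density factorizes leaf-wise into univariate densities:
#' a maximum-likelihood truncated Gaussian on the leaf interval for continuous
#' features and a multinomial over the admissible levels for categorical ones.
#' The fitted object is the mixture over all leaves, weighted by
#' \eqn{\omega_l = n_{tl} / (T n_t)}, the share of real training rows falling
#' into leaf \eqn{l} averaged over the \eqn{T} trees.
#'
#' @param data A data.frame (or matrix) with `NA` for missing cells.
#' @param num_trees Number of trees in the discriminator forest (default 100).
#' @param min_node_size Minimum number of in-bag samples per leaf (default 10).
#' @param delta Convergence slack: training stops when OOB accuracy drops
#'   below `0.5 + delta`. Default 0.
#' @param max_iters Cap on adversarial rounds (default 10). If the loop does
#'   not converge, the round with the lowest OOB accuracy is returned with a
#'   warning.
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param seed Optional integer seed; fixing it makes the fit bit-reproducible.
#' @param schema Optional [arf_schema()] overriding the inferred feature kinds.
#' @param alpha Pseudo-count added to categorical leaf frequencies (default 0).
#' @return An object of class `arf` with components `forest` (the trees and
#'   OOB record), `leaves` (bounds, weights, fitted distributions), `schema`,
#'   `config`, `oob_history`, `converged`, and the final synthetic table
#'   (`last_synth`).
#' @seealso [impute()], [simulate.arf()], [predict.arf()], [adjust_weights()]
#' @examples
#' d <- data.frame(x = rnorm(300), y = rnorm(300))
#' fit <- arf(d, num_trees = 20, seed = 1)
#' fit
#' @export
arf <- function(data, num_trees = 100, min_node_size = 10, delta = 0,
                max_iters = 10, mtry = NULL, seed = NULL, schema = NULL,
                alpha = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schema)) schema <- arf_schema(data)
  stopifnot(num_trees >= 1, min_node_size >= 1, delta >= 0, delta < 0.5,
            max_iters >= 1, alpha >= 0)
  X <- encode_data(data, schema)
  n <- nrow(X); p <- ncol(X)
  if (n < 1L) stop("empty table")
  ftype <- schema_ftype(schema)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  mtry <- as.integer(mtry)
  if (mtry < 1L || mtry > p) stop("mtry must be in [1, p]")
  all_na <- vapply(seq_len(p), function(j) all(is.na(X[, j])), TRUE)
  if (any(all_na))
    stop("column(s) entirely missing: ",
         paste(schema$names[all_na], collapse = ", "))

  synth <- naive_synthetic_matrix(X)
  y <- c(rep(1L, n), rep(0L, n))
  history <- numeric(0)
  best <- NULL
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    fit <- cpp_grow_forest(rbind(X, synth), y, as.integer(num_trees),
                           as.integer(min_node_size), mtry, ftype)
    acc <- fit$oob_accuracy
    history <- c(history, acc)
    if (is.null(best) || acc < best$acc)
      best <- list(trees = fit$trees, acc = acc, synth = synth)
    if (acc < 0.5 + delta) {
      best <- list(trees = fit$trees, acc = acc, synth = synth)
      converged <- TRUE
      break
    }
    if (it == max_iters) break
    membership <- cpp_route(fit$trees, X, ftype)
    members <- leaf_member_lists(fit$trees, membership)
    synth <- cpp_leafwise_synth(X, membership, members)
  }
  if (!converged)
    warning("ARF did not converge within max_iters = ", max_iters,
            "; returning the round with lowest OOB accuracy (",
            signif(best$acc, 4), ")")

  model <- build_leaf_model(best$trees, X, ftype, schema, alpha)
  structure(list(
    forest = list(trees = best$trees, num_trees = num_trees),
    leaves = model$leaves,
    cpp = model$cpp,
    marg = model$marg,
    schema = schema,
    ftype = ftype,
    n = n, p = p,
    config = list(num_trees = num_trees, min_node_size = min_node_size,
                  delta = delta, max_iters = max_iters, mtry = mtry,
                  seed = seed, alpha = alpha),
    oob_history = history,
    oob_accuracy = best$acc,
    converged = converged,
    last_synth = decode_data(best$synth, schema)
  ), class = "arf")
}

# naive synthetic table: independent with-replacement bootstrap per column;
# missing markers are ordinary drawable cells, so each column's missingness
# rate is preserved in expectation
naive_synthetic_matrix <- function(X) {
  n <- nrow(X)
  out <- X
  for (j in seq_len(ncol(X)))
    out[, j] <- X[sample.int(n, n, replace = TRUE), j]
  out
}

#' Naive synthetic data from the product of marginals
#'
#' Draws each column independently with replacement from the original cells
#' (including missing markers), i.e. a sample from the product of the
#' empirical marginals. This is the round-zero generator of the adversarial
#' loop.
#'
#' @param data A data.frame with at least one row.
#' @param schema Optional [arf_schema()].
#' @return A data.frame of the same shape and schema.
#' @export
naive_synthetic <- function(data, schema = NULL) {
  if (is.null(schema)) schema <- arf_schema(data)
  X <- encode_data(data, schema)
  if (nrow(X) < 1L) stop("empty table")
  decode_data(naive_synthetic_matrix(X), schema)
}

# per-tree lists of 0-based real-row indices per leaf (for leaf-wise synthesis)
leaf_member_lists <- function(trees, membership) {
  lapply(seq_along(trees), function(t) {
    nl <- trees[[t]]$n_leaves
    mem <- membership[, t] + 1L
    unname(lapply(split(seq_len(nrow(membership)) - 1L,
                        factor(mem, levels = seq_len(nl))), as.integer))
  })
}

# harvest leaves of a forest into the flat arrays used by the conditional
# machinery, and fit the per-leaf univariate distributions
build_leaf_model <- function(trees, X, ftype, schema, alpha) {
  p <- ncol(X)
  leaves <- cpp_extract_leaves(trees, ftype)
  membership <- cpp_route(trees, X, ftype)
  marg_mean <- numeric(p); marg_sd <- numeric(p)
  marg_cat <- vector("list", p)
  for (j in seq_len(p)) {
    v <- X[, j][!is.na(X[, j])]
    if (ftype[j] == 0L) {
      marg_mean[j] <- if (length(v)) mean(v) else 0
      marg_sd[j] <- if (length(v) > 1) stats::sd(v) else 0
    } else {
      cnt <- tabulate(as.integer(v), nbins = ftype[j])
      marg_cat[[j]] <- if (sum(cnt) > 0) cnt / sum(cnt)
                       else rep(1 / ftype[j], ftype[j])
      marg_mean[j] <- NA_real_; marg_sd[j] <- NA_real_
    }
  }
  sigma_floor <- ifelse(is.na(marg_sd) | marg_sd == 0, 1e-9, 1e-6 * marg_sd)
  fitted <- cpp_fit_leaves(leaves, membership, X, ftype, marg_mean, marg_sd,
                           marg_cat, alpha, sigma_floor)
  cpp <- list(lo = leaves$lo, hi = leaves$hi, mu = fitted$mu,
              sigma = fitted$sigma, emp_mean = fitted$emp_mean,
              w = fitted$w, ftype = ftype, cat_probs = fitted$cat_probs)
  list(
    leaves = list(lo = leaves$lo, hi = leaves$hi, na_ok = leaves$na_ok,
                  admiss = leaves$admiss, tree = leaves$tree + 1L,
                  n_tl = fitted$n_tl, w = fitted$w, mu = fitted$mu,
                  sigma = fitted$sigma, emp_mean = fitted$emp_mean,
                  cat_probs = fitted$cat_probs),
    cpp = cpp,
    marg = list(mean = marg_mean, sd = marg_sd, cat = marg_cat,
                sigma_floor = sigma_floor)
  )
}

#' @export
print.arf <- function(x, ...) {
  cat("Adversarial random forest density model\n")
  cat("  features:", x$p, "(",
      sum(x$schema$kind == "continuous"), "continuous,",
      sum(x$schema$kind == "categorical"), "categorical )\n")
  cat("  training rows:", x$n, "\n")
  cat("  trees:", x$forest$num_trees, " leaves:", length(x$leaves$w), "\n")
  cat("  OOB accuracy by round:",
      paste(signif(x$oob_history, 4), collapse = ", "), "\n")
  cat("  converged:", x$converged,
      sprintf("(threshold %.3f)\n", 0.5 + x$config$delta))
  invisible(x)
}

#' @export
summary.arf <- function(object, ...) {
  s <- list(
    n = object$n, p = object$p,
    num_trees = object$forest$num_trees,
    n_leaves = length(object$leaves$w),
    leaf_sizes = summary(object$leaves$n_tl),
    weight_total = sum(object$leaves$w),
    oob_history = object$oob_history,
    converged = object$converged,
    config = object$config
  )
  class(s) <- "summary.arf"
  s
}

#' @export
print.summary.arf <- function(x, ...) {
  cat("ARF density model:", x$num_trees, "trees,", x$n_leaves, "leaves over",
      x$n, "rows x", x$p, "features\n")
  cat("Real rows per leaf:\n"); print(x$leaf_sizes)
  cat("Total leaf weight:", format(x$weight_total, digits = 15), "\n")
  cat("OOB accuracy by round:",
      paste(signif(x$oob_history, 4), collapse = ", "), "\n")
  cat("Converged:", x$converged, "\n")
  invisible(x)
}

#' Mixture density of complete rows
#'
#' Evaluates the fitted ARF mixture density
#' \eqn{\hat p(x) = \sum_l \omega_l \prod_j \hat p_{lj}(x_j)} at complete
#' rows; leaves whose bounds exclude the row contribute zero.
#'
#' @param object A fitted [arf()] model.
#' @param newdata A data.frame of complete rows (no missing cells).
#' @param type `"density"` or `"logdensity"`.
#' @param ... Unused.
#' @return A numeric vector, one value per row.
#' @export
predict.arf <- function(object, newdata,
                        type = c("density", "logdensity"), ...) {
  type <- match.arg(type)
  X <- encode_data(as.data.frame(newdata), object$schema)
  if (anyNA(X))
    stop("newdata must be complete; use impute() for rows with missing cells")
  ld <- cpp_mix_logdens(object$cpp, X)
  if (type == "density") exp(ld) else ld
}

#' Draw synthetic rows from a fitted ARF
#'
#' Unconditional generation: per row, a leaf is drawn with probability
#' \eqn{\omega_l}, then every feature is sampled independently from the leaf's
#' fitted distribution (truncated Gaussian within the leaf interval;
#' multinomial over admissible levels).
#'
#' @param object A fitted [arf()] model.
#' @param nsim Number of rows to generate.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data.frame of `nsim` synthetic rows.
#' @export
simulate.arf <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  blank <- matrix(NA_real_, nsim, object$p,
                  dimnames = list(NULL, object$schema$names))
  res <- cpp_impute_rows(object$cpp, blank, 1L, 1L,
                         object$marg$mean, object$marg$cat)
  decode_data(res$tables[[1]], object$schema)
}
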