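# Conditioning the leaf mixture on observed values. Evidence is a single row
# with NA in the unobserved positions; all products over observed features are
# accumulated in log space and normalized by log-sum-exp.

# coerce evidence (1-row data.frame, named list, or named vector) to the
# encoded numeric row convention
encode_evidence <- function(object, evidence) {
  if (is.null(evidence) || (is.list(evidence) && length(evidence) == 0))
    return(stats::setNames(rep(NA_real_, object$p), object$schema$names))
  if (is.numeric(evidence) && !is.null(names(evidence)))
    evidence <- as.data.frame(as.list(evidence))
  if (is.list(evidence) && !is.data.frame(evidence)) {
    evidence <- lapply(evidence, function(v) if (is.null(v)) NA else v)
    evidence <- as.data.frame(evidence, optional = TRUE)
  }
  evidence <- as.data.frame(evidence)
  if (nrow(evidence) != 1L) stop("evidence must be a single row")
  missing_cols <- setdiff(object$schema$names, names(evidence))
  for (nm in missing_cols) evidence[[nm]] <- NA
  evidence <- evidence[object$schema$names]
  for (j in seq_along(evidence)) {
    if (object$schema$kind[j] == "categorical" && !is.factor(evidence[[j]]))
      evidence[[j]] <- factor(as.character(evidence[[j]]),
                              levels = object$schema$levels[[j]])
    if (object$schema$kind[j] == "continuous")
      evidence[[j]] <- as.numeric(evidence[[j]])
  }
  drop(encode_data(evidence, object$schema))
}

#' Adjusted leaf weights given partial evidence
#'
#' Conditions the fitted leaf mixture on the observed entries of a row:
#' each leaf weight is rescaled by the leaf's density of the observed values
#' and renormalized,
#' \eqn{\tilde\omega_l \propto \omega_l \prod_{j \in C} \hat p_{lj}(x_j)},
#' computed in log space. Leaves whose bounds exclude any observed value get
#' exactly zero weight. If no leaf at all is compatible with the evidence
#' (possible for out-of-range values), the unadjusted weights are returned
#' with `compatible = FALSE`, so that imputation always produces a value.
#'
#' @param object A fitted [arf()] model.
#' @param evidence A single row: 1-row data.frame, named list, or named
#'   vector, with `NA` (or absent names) marking the unobserved features.
#' @return A list with `w` (normalized weights over all leaves),
#'   `log_evidence` (the log marginal density of the observed values), and
#'   `compatible`.
#' @examples
#' fit <- arf(data.frame(x = rnorm(200), y = rnorm(200)),
#'            num_trees = 10, seed = 1)
#' aw <- adjust_weights(fit, list(x = 0.5))
#' sum(aw$w)
#' @export
adjust_weights <- function(object, evidence) {
  stopifnot(inherits(object, "arf"))
  x <- encode_evidence(object, evidence)
  cpp_adjust_weights(object$cpp, x)
}

#' Conditional density of missing features given evidence
#'
#' Evaluates \eqn{\sum_l \tilde\omega_l \prod_{j \in \bar C} \hat p_{lj}(x_j)},
#' the mixture density of the unobserved features under the adjusted leaf
#' weights. With no unobserved features the empty product gives 1.
#'
#' @inheritParams adjust_weights
#' @param values Named list/vector with values for (a subset of) the missing
#'   features.
#' @return A non-negative number.
#' @export
conditional_density <- function(object, evidence, values) {
  stopifnot(inherits(object, "arf"))
  x <- encode_evidence(object, evidence)
  # encode the completed row
  vrow <- x
  vals <- as.list(values)
  if (length(vals)) {
    idx <- match(names(vals), object$schema$names)
    if (anyNA(idx)) stop("unknown feature in `values`")
    for (q in seq_along(idx)) {
      j <- idx[q]
      if (!is.na(x[j])) stop("feature ", names(vals)[q], " is already observed")
      if (object$schema$kind[j] == "categorical") {
        code <- match(as.character(vals[[q]]), object$schema$levels[[j]])
        if (is.na(code)) stop("unknown level for feature ", names(vals)[q])
        vrow[j] <- code
      } else vrow[j] <- as.numeric(vals[[q]])
    }
  }
  aw_full <- cpp_adjust_weights(object$cpp, vrow)
  aw_ev <- cpp_adjust_weights(object$cpp, x)
  if (!aw_ev$compatible) return(0)
  exp(aw_full$log_evidence - aw_ev$log_evidence)
}

#' Sample completions of a partially observed row
#'
#' Draws `k` completions of a row with missing cells: for each completion one
#' leaf is drawn from the adjusted weights (a fresh leaf per completion, so
#' within-row dependence among several missing features is carried by the
#' leaf identity), then every missing feature is sampled independently from
#' that leaf's fitted distribution. Observed cells pass through unchanged.
#'
#' @inheritParams adjust_weights
#' @param k Number of completions.
#' @param seed Optional integer seed.
#' @return A data.frame with `k` completed rows.
#' @export
sample_conditional <- function(object, evidence, k = 1, seed = NULL) {
  stopifnot(inherits(object, "arf"))
  if (!is.null(seed)) set.seed(seed)
  x <- encode_evidence(object, evidence)
  X <- matrix(rep(x, each = k), nrow = k,
              dimnames = list(NULL, object$schema$names))
  res <- cpp_impute_rows(object$cpp, X, 1L, 1L,
                         object$marg$mean, object$marg$cat)
  decode_data(res$tables[[1]], object$schema)
}

#' Conditional expectation of a missing continuous feature
#'
#' Imputes by the expected value of the conditional mixture,
#' \eqn{\sum_l \tilde\omega_l \mu_{lj}}, where \eqn{\mu_{lj}} is the leaf's
#' empirical mean of real non-missing values of feature `j` (leaves without
#' such values contribute the global marginal mean).
#'
#' @inheritParams adjust_weights
#' @param feature Name (or index) of a continuous feature missing in the
#'   evidence.
#' @return A number.
#' @export
conditional_expectation <- function(object, evidence, feature) {
  stopifnot(inherits(object, "arf"))
  j <- resolve_feature(object, feature)
  if (object$schema$kind[j] != "continuous")
    stop("feature must be continuous; use conditional_mode()")
  x <- encode_evidence(object, evidence)
  if (!is.na(x[j])) stop("feature is observed in the evidence")
  aw <- cpp_adjust_weights(object$cpp, x)
  mu <- object$leaves$emp_mean[, j]
  mu[is.na(mu)] <- object$marg$mean[j]
  sum(aw$w * mu)
}

#' Conditional mode of a missing categorical feature
#'
#' Imputes by the most frequent category across the compatible leaves,
#' weighted by the adjusted leaf weights: the argmax over non-missing levels
#' of \eqn{\sum_l \tilde\omega_l \hat p_{lj}(\mathrm{level})}. Ties go to the
#' earlier declared level.
#'
#' @inheritParams conditional_expectation
#' @return The imputed level (character).
#' @export
conditional_mode <- function(object, evidence, feature) {
  stopifnot(inherits(object, "arf"))
  j <- resolve_feature(object, feature)
  if (object$schema$kind[j] != "categorical")
    stop("feature must be categorical; use conditional_expectation()")
  x <- encode_evidence(object, evidence)
  if (!is.na(x[j])) stop("feature is observed in the evidence")
  aw <- cpp_adjust_weights(object$cpp, x)
  score <- drop(crossprod(object$leaves$cat_probs[[j]], aw$w))
  object$schema$levels[[j]][which.max(score)]
}

resolve_feature <- function(object, feature) {
  if (is.character(feature)) {
    j <- match(feature, object$schema$names)
    if (is.na(j)) stop("unknown feature: ", feature)
    j
  } else as.integer(feature)
}
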