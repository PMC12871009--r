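#' Impute missing values with an adversarial random forest
#'
#' The two-call workflow of the package: `impute(data)` returns one completed
#' dataset (single imputation), `impute(data, m = 20)` returns 20 (multiple
#' imputation). A single ARF is trained on the incomplete data (MIA splits
#' route the missing cells), and every missing cell is filled from the
#' conditional leaf mixture given the row's observed values:
#'
#' * single imputation (default `mode = "expectation"`): continuous cells get
#'   the conditional expectation \eqn{\sum_l \tilde\omega_l \mu_{lj}},
#'   categorical cells the weighted modal level;
#' * `mode = "sample"`, and always for multiple imputation: each completion
#'   draws one fresh leaf per incomplete row from the adjusted weights and
#'   samples every missing feature from that leaf. The model is fitted once
#'   regardless of `m`, so multiple imputation costs no extra training.
#'
#' Observed cells are never modified. The `arf` method imputes from an
#' already fitted model instead of training one.
#'
#' @param data A data.frame with `NA` for missing cells (or, for the `arf`
#'   method, a fitted model as first argument and the data second).
#' @param m Number of imputations; `NULL` (default) for single imputation.
#' @param mode `"expectation"` (conditional expectation / weighted mode;
#'   single imputation default) or `"sample"` (a conditional draw).
#' @param seed Optional integer master seed.
#' @param ... For the data.frame method, arguments passed to [arf()]
#'   (`num_trees`, `min_node_size`, `delta`, `max_iters`, `mtry`, `schema`...).
#' @return For `m = NULL` a completed data.frame; otherwise an object of
#'   class `imputation_set`: a list of `m` completed data.frames with
#'   provenance attributes (`method`, `config`, `seed`, `n_model_fits`,
#'   `n_zero_mass`).
#' @examples
#' d <- data.frame(x = rnorm(200), y = rnorm(200))
#' d$y[1:20] <- NA
#' filled <- impute(d, num_trees = 20, seed = 1)
#' sets <- impute(d, m = 5, num_trees = 20, seed = 1)
#' length(sets)
#' @export
impute <- function(data, ...) UseMethod("impute")

#' @rdname impute
#' @export
impute.data.frame <- function(data, m = NULL,
                              mode = c("expectation", "sample"),
                              seed = NULL, ...) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  model <- arf(data, ...)
  impute(model, data, m = m, mode = mode, seed = NULL,
         n_model_fits = 1L)
}

#' @rdname impute
#' @param n_model_fits Internal provenance counter (how many ARF trainings
#'   produced this result); users need not set it.
#' @export
impute.arf <- function(data, ..., m = NULL,
                       mode = c("expectation", "sample"),
                       seed = NULL, n_model_fits = 0L) {
  object <- data
  args <- list(...)
  if (!length(args)) stop("supply the data to impute")
  newdata <- as.data.frame(args[[1]])
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  X <- encode_data(newdata, object$schema)
  p <- ncol(X)
  all_na <- vapply(seq_len(p), function(j) all(is.na(X[, j])), TRUE)
  if (any(all_na))
    stop("column(s) entirely missing: ",
         paste(object$schema$names[all_na], collapse = ", "))
  multiple <- !is.null(m)
  if (multiple) stopifnot(m >= 1)
  use_sample <- multiple || mode == "sample"
  res <- cpp_impute_rows(object$cpp, X,
                         if (use_sample) 1L else 0L,
                         if (multiple) as.integer(m) else 1L,
                         object$marg$mean, object$marg$cat)
  tables <- lapply(res$tables, decode_data, schema = object$schema)
  if (!multiple) return(tables[[1]])
  structure(tables, class = "imputation_set",
            method = "arf", mode = "sample", m = m,
            config = object$config, seed = seed,
            n_model_fits = n_model_fits,
            n_zero_mass = res$n_zero_mass)
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Imputation set:", length(x), "completed dataset(s), method =",
      attr(x, "method"), "\n")
  nz <- attr(x, "n_zero_mass")
  if (!is.null(nz) && nz > 0)
    cat("  rows imputed from unconditional weights (zero-mass evidence):",
        nz, "\n")
  invisible(x)
}

#' Random imputation from the marginal empirical distributions
#'
#' Each missing cell is filled with a uniform draw from the observed values of
#' its column, independently per cell and per imputation. The simplest
#' stochastic baseline.
#'
#' @param data A data.frame with `NA` for missing cells.
#' @param m Number of imputations; `NULL` for a single completed data.frame.
#' @param seed Optional integer seed.
#' @return A data.frame (`m = NULL`) or an `imputation_set` of length `m`.
#' @export
impute_random <- function(data, m = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data <- as.data.frame(data)
  check_not_all_missing(data)
  mm <- if (is.null(m)) 1L else as.integer(m)
  stopifnot(mm >= 1)
  out <- vector("list", mm)
  for (q in seq_len(mm)) {
    d <- data
    for (j in seq_len(ncol(d))) {
      mis <- is.na(d[[j]])
      if (!any(mis)) next
      obs <- d[[j]][!mis]
      d[[j]][mis] <- obs[sample.int(length(obs), sum(mis), replace = TRUE)]
    }
    out[[q]] <- d
  }
  if (is.null(m)) return(out[[1]])
  structure(out, class = "imputation_set", method = "random", m = mm,
            seed = seed, n_model_fits = 0L, n_zero_mass = 0L)
}

#' Median / most-frequent-level imputation
#'
#' Continuous missing cells are filled with the column median of the observed
#' values; categorical ones with the most frequent observed level (ties go to
#' the earlier declared level). A deterministic single-imputation baseline.
#'
#' @param data A data.frame with `NA` for missing cells.
#' @return A completed data.frame.
#' @export
impute_median <- function(data) {
  data <- as.data.frame(data)
  check_not_all_missing(data)
  for (j in seq_len(ncol(data))) {
    x <- data[[j]]
    mis <- is.na(x)
    if (!any(mis)) next
    if (is.numeric(x)) {
      data[[j]][mis] <- stats::median(x[!mis])
    } else {
      tab <- table(x[!mis])
      if (is.factor(x)) {
        data[[j]][mis] <- factor(names(tab)[which.max(tab)], levels = levels(x))
      } else {
        lev <- sort(unique(as.character(x[!mis])))
        tab <- tab[lev]
        data[[j]][mis] <- lev[which.max(tab)]
      }
    }
  }
  data
}

check_not_all_missing <- function(data) {
  all_na <- vapply(data, function(x) all(is.na(x)), TRUE)
  if (any(all_na))
    stop("column(s) entirely missing: ",
         paste(names(data)[all_na], collapse = ", "))
  invisible(TRUE)
}
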