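#' Feature schema of a mixed table
#'
#' Describes, for each column of a rectangular dataset, whether it is
#' continuous or categorical, and for categorical features the declared
#' levels. A schema is inferred automatically from a data.frame (numeric
#' columns are continuous; factor, character and logical columns are
#' categorical), or can be supplied explicitly to override inference, e.g.
#' to treat 0/1-coded columns as categorical.
#'
#' @param data A data.frame (or matrix) with named columns. Missing cells are
#'   `NA`.
#' @param kinds Optional character vector (`"continuous"` or `"categorical"`),
#'   recycled or named by column, overriding inference.
#' @param levels Optional named list of level vectors for categorical columns;
#'   defaults to the observed levels in declared order (factor levels, or
#'   sorted unique values for character columns).
#' @return An object of class `arf_schema`: a list with `names`, `kind`, and
#'   `levels`.
#' @examples
#' d <- data.frame(x = c(1.2, NA, 3), g = factor(c("a", "b", NA)))
#' arf_schema(d)
#' @export
arf_schema <- function(data, kinds = NULL, levels = NULL) {
  data <- as.data.frame(data)
  if (is.null(names(data)) || any(!nzchar(names(data))))
    stop("all columns must be named")
  p <- ncol(data)
  if (p < 1L || nrow(data) < 1L) stop("empty table")
  kind <- character(p)
  levs <- vector("list", p)
  for (j in seq_len(p)) {
    x <- data[[j]]
    if (is.factor(x)) {
      kind[j] <- "categorical"; levs[[j]] <- base::levels(x)
    } else if (is.character(x) || is.logical(x)) {
      kind[j] <- "categorical"
      levs[[j]] <- sort(unique(as.character(x[!is.na(x)])))
    } else if (is.numeric(x)) {
      kind[j] <- "continuous"
    } else stop("unsupported column type in column ", names(data)[j])
  }
  if (!is.null(kinds)) {
    if (!is.null(names(kinds))) {
      idx <- match(names(kinds), names(data))
      if (anyNA(idx)) stop("unknown columns in `kinds`")
      kind[idx] <- kinds
    } else kind <- rep_len(kinds, p)
    stopifnot(all(kind %in% c("continuous", "categorical")))
    for (j in which(kind == "categorical")) {
      if (is.null(levs[[j]]))
        levs[[j]] <- sort(unique(as.character(data[[j]][!is.na(data[[j]])])))
    }
    for (j in which(kind == "continuous")) levs[j] <- list(NULL)
  }
  if (!is.null(levels)) {
    idx <- match(names(levels), names(data))
    if (anyNA(idx)) stop("unknown columns in `levels`")
    for (q in seq_along(idx)) levs[[idx[q]]] <- as.character(levels[[q]])
  }
  structure(list(names = names(data), kind = kind, levels = levs),
            class = "arf_schema")
}

#' @export
print.arf_schema <- function(x, ...) {
  cat("Schema with", length(x$names), "features\n")
  for (j in seq_along(x$names)) {
    if (x$kind[j] == "continuous") cat("  ", x$names[j], ": continuous\n")
    else cat("  ", x$names[j], ": categorical {",
             paste(x$levels[[j]], collapse = ", "), "}\n")
  }
  invisible(x)
}

# integer codes of feature kinds for the compiled core:
# 0 = continuous, k = categorical with k levels
schema_ftype <- function(schema) {
  ifelse(schema$kind == "continuous", 0L,
         vapply(schema$levels, length, 1L))
}

# encode a data.frame as the numeric matrix convention used by the core
encode_data <- function(data, schema) {
  data <- as.data.frame(data)
  if (!identical(names(data), schema$names))
    stop("column names do not match the schema")
  n <- nrow(data)
  mat <- matrix(NA_real_, n, length(schema$names),
                dimnames = list(NULL, schema$names))
  for (j in seq_along(schema$names)) {
    x <- data[[j]]
    if (schema$kind[j] == "continuous") {
      if (!is.numeric(x)) stop("column ", schema$names[j], " must be numeric")
      mat[, j] <- as.numeric(x)
    } else {
      x <- as.character(x)
      code <- match(x, schema$levels[[j]])
      bad <- which(!is.na(x) & is.na(code))
      if (length(bad))
        stop("unknown level '", x[bad[1]], "' in column ", schema$names[j],
             " (row ", bad[1], ")")
      mat[, j] <- as.numeric(code)
    }
  }
  mat
}

# decode the matrix convention back to a data.frame
decode_data <- function(mat, schema) {
  out <- vector("list", ncol(mat))
  for (j in seq_along(schema$names)) {
    if (schema$kind[j] == "continuous") out[[j]] <- mat[, j]
    else out[[j]] <- factor(schema$levels[[j]][as.integer(mat[, j])],
                            levels = schema$levels[[j]])
  }
  names(out) <- schema$names
  as.data.frame(out, optional = TRUE)
}
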