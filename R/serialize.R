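# JSON serialization of a fitted ARF model: trees as nested node objects,
# leaves as flat arrays with bounds, weights and distribution parameters.
# Infinities are encoded as the strings "Inf"/"-Inf" (JSON has no such
# numbers); everything else is written at full double precision.

inf_encode <- function(x) {
  x[x == Inf] <- .Machine$double.xmax
  x[x == -Inf] <- -.Machine$double.xmax
  x
}
inf_decode <- function(x) {
  x <- as.matrix(x)
  x[x >= .Machine$double.xmax] <- Inf
  x[x <= -.Machine$double.xmax] <- -Inf
  x
}

node_to_json <- function(tl, node) {
  nodes <- tl$nodes
  if (nodes[node, "feature"] < 0) {
    return(list(leaf = nodes[node, "leaf_id"],
                n1 = nodes[node, "n1"], n0 = nodes[node, "n0"]))
  }
  list(feature = nodes[node, "feature"] + 1L,
       threshold = tl$thr[node],
       na_left = nodes[node, "na_left"] == 1L,
       left_levels = as.integer(tl$leftlev[[node]]),
       left = node_to_json(tl, nodes[node, "left"] + 1L),
       right = node_to_json(tl, nodes[node, "right"] + 1L))
}

json_to_tree <- function(obj) {
  feature <- integer(0); left <- integer(0); right <- integer(0)
  na_left <- integer(0); leaf_id <- integer(0); n1 <- integer(0)
  n0 <- integer(0); thr <- numeric(0); leftlev <- list()
  new_node <- function() {
    k <- length(feature) + 1L
    feature[k] <<- -1L; left[k] <<- -1L; right[k] <<- -1L
    na_left[k] <<- 1L; leaf_id[k] <<- -1L; n1[k] <<- 0L; n0[k] <<- 0L
    thr[k] <<- NA_real_; leftlev[[k]] <<- integer(0)
    k
  }
  build <- function(o) {
    k <- new_node()
    if (!is.null(o$leaf)) {
      leaf_id[k] <<- o$leaf; n1[k] <<- o$n1; n0[k] <<- o$n0
    } else {
      feature[k] <<- o$feature - 1L
      thr[k] <<- if (is.null(o$threshold)) NA_real_ else o$threshold
      na_left[k] <<- as.integer(isTRUE(o$na_left))
      leftlev[[k]] <<- as.integer(o$left_levels)
      l <- build(o$left); r <- build(o$right)
      left[k] <<- l - 1L; right[k] <<- r - 1L
    }
    k
  }
  build(obj)
  nodes <- cbind(feature = feature, left = left, right = right,
                 na_left = na_left, leaf_id = leaf_id, n1 = n1, n0 = n0)
  list(nodes = nodes, thr = thr, leftlev = leftlev,
       n_leaves = sum(feature < 0))
}

#' Save / load a fitted ARF model as JSON
#'
#' Writes the full model — trees as nested split-node objects, leaves with
#' bounds, weights and fitted distribution parameters, the schema and the
#' configuration — to a documented JSON layout, and reads it back into an
#' object equivalent for density evaluation, sampling and imputation.
#'
#' @param object A fitted [arf()] model.
#' @param path File path.
#' @return `read_arf()` returns an object of class `arf`; `write_arf()`
#'   returns `path` invisibly.
#' @export
write_arf <- function(object, path) {
  stopifnot(inherits(object, "arf"))
  trees <- lapply(object$forest$trees, function(tl) node_to_json(tl, 1L))
  lv <- object$leaves
  payload <- list(
    format = "arfimpute-model",
    version = 1L,
    schema = list(names = object$schema$names, kind = object$schema$kind,
                  levels = object$schema$levels),
    config = object$config,
    n = object$n, p = object$p,
    oob_history = object$oob_history,
    converged = object$converged,
    trees = trees,
    leaves = list(lo = inf_encode(lv$lo), hi = inf_encode(lv$hi),
                  na_ok = lv$na_ok, tree = lv$tree, n_tl = lv$n_tl,
                  w = lv$w, mu = lv$mu, sigma = lv$sigma,
                  emp_mean = lv$emp_mean,
                  cat_probs = lv$cat_probs,
                  admiss = lv$admiss),
    marg = object$marg
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_arf
#' @export
read_arf <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "arfimpute-model"))
    stop("not an arfimpute model file")
  schema <- structure(list(names = obj$schema$names, kind = obj$schema$kind,
                           levels = lapply(obj$schema$levels, as.character)),
                      class = "arf_schema")
  p <- obj$p
  ftype <- schema_ftype(schema)
  trees <- lapply(obj$trees, json_to_tree)
  lv <- obj$leaves
  as_mat <- function(x) {
    x <- as.matrix(x); storage.mode(x) <- "double"; dimnames(x) <- NULL; x
  }
  lo <- inf_decode(as_mat(lv$lo)); hi <- inf_decode(as_mat(lv$hi))
  mu <- as_mat(lv$mu); sigma <- as_mat(lv$sigma)
  emp_mean <- as_mat(lv$emp_mean)
  cat_probs <- lapply(seq_len(p), function(j) {
    cp <- lv$cat_probs[[j]]
    if (is.null(cp) || length(cp) == 0) NULL else as_mat(cp)
  })
  marg_cat <- lapply(seq_len(p), function(j) {
    g <- obj$marg$cat[[j]]
    if (is.null(g) || length(g) == 0) NULL else as.numeric(g)
  })
  cpp <- list(lo = lo, hi = hi, mu = mu, sigma = sigma, emp_mean = emp_mean,
              w = as.numeric(lv$w), ftype = ftype, cat_probs = cat_probs)
  structure(list(
    forest = list(trees = trees, num_trees = length(trees)),
    leaves = list(lo = lo, hi = hi, na_ok = as.matrix(lv$na_ok),
                  admiss = lv$admiss, tree = as.integer(lv$tree),
                  n_tl = as.numeric(lv$n_tl), w = as.numeric(lv$w),
                  mu = mu, sigma = sigma, emp_mean = emp_mean,
                  cat_probs = cat_probs),
    cpp = cpp,
    marg = list(mean = as.numeric(obj$marg$mean),
                sd = as.numeric(obj$marg$sd), cat = marg_cat,
                sigma_floor = as.numeric(obj$marg$sigma_floor)),
    schema = schema, ftype = ftype,
    n = obj$n, p = p,
    config = obj$config,
    oob_history = as.numeric(obj$oob_history),
    oob_accuracy = utils::tail(as.numeric(obj$oob_history), 1),
    converged = isTRUE(obj$converged),
    last_synth = NULL
  ), class = "arf")
}
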