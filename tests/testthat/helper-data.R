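# shared fixtures, all generated in code

# two well-separated Gaussian clusters around (-1, 1) and (1, -1)
make_clusters <- function(n_per = 100, sd = 0.1, seed = 1) {
  set.seed(seed)
  data.frame(
    x1 = c(rnorm(n_per, -1, sd), rnorm(n_per, 1, sd)),
    x2 = c(rnorm(n_per, 1, sd), rnorm(n_per, -1, sd))
  )
}

# hand-built leaf model (bypasses training) for conditional-arithmetic
# oracles: continuous features only, one tree, L leaves given by rectangles
# with weights and Gaussian parameters
make_toy_model <- function(lo, hi, w, mu, sigma, emp_mean = mu) {
  L <- length(w); p <- ncol(lo)
  schema <- structure(list(names = paste0("x", seq_len(p)),
                           kind = rep("continuous", p),
                           levels = rep(list(NULL), p)),
                      class = "arf_schema")
  cpp <- list(lo = lo, hi = hi, mu = mu, sigma = sigma, emp_mean = emp_mean,
              w = w, ftype = rep(0L, p), cat_probs = rep(list(NULL), p))
  structure(list(
    forest = list(trees = list(), num_trees = 1L),
    leaves = list(lo = lo, hi = hi, w = w, n_tl = w, mu = mu, sigma = sigma,
                  emp_mean = emp_mean, cat_probs = rep(list(NULL), p)),
    cpp = cpp,
    marg = list(mean = colMeans(mu), sd = rep(1, p),
                cat = rep(list(NULL), p)),
    schema = schema, ftype = rep(0L, p),
    n = 1L, p = p,
    config = list(), oob_history = numeric(0), converged = TRUE
  ), class = "arf")
}

# brute-force R reference for the MIA split search on one numeric column:
# enumerate every observed threshold x {NA left, NA right}
brute_mia_numeric <- function(x, y, min_node) {
  n <- length(x)
  gini <- function(yy) {
    if (!length(yy)) return(0)
    p1 <- mean(yy)
    1 - p1^2 - (1 - p1)^2
  }
  best <- list(valid = FALSE, impurity = Inf)
  for (s in sort(unique(x[!is.na(x)]))) {
    for (na_left in c(TRUE, FALSE)) {
      left <- ifelse(is.na(x), na_left, x <= s)
      nl <- sum(left); nr <- n - nl
      if (nl < min_node || nr < min_node) next
      imp <- (nl * gini(y[left]) + nr * gini(y[!left])) / n
      if (imp < best$impurity - 1e-12) {
        best <- list(valid = TRUE, impurity = imp, threshold = s,
                     na_left = na_left)
      }
    }
  }
  if (best$valid && gini(y) - best$impurity <= 1e-12) best$valid <- FALSE
  best
}

# brute-force best binary partition of categorical levels (NA as level 0)
brute_mia_categorical <- function(x, y, nlev, min_node) {
  n <- length(x)
  lv <- ifelse(is.na(x), 0L, as.integer(x))
  present <- sort(unique(lv))
  gini <- function(yy) {
    if (!length(yy)) return(0)
    p1 <- mean(yy)
    1 - p1^2 - (1 - p1)^2
  }
  best <- list(valid = FALSE, impurity = Inf)
  G <- length(present)
  if (G >= 2) {
    for (mask in 1:(2^G - 2)) {
      sel <- present[as.logical(bitwAnd(mask, 2^(seq_len(G) - 1)))]
      left <- lv %in% sel
      nl <- sum(left); nr <- n - nl
      if (nl < min_node || nr < min_node) next
      imp <- (nl * gini(y[left]) + nr * gini(y[!left])) / n
      if (imp < best$impurity - 1e-12)
        best <- list(valid = TRUE, impurity = imp, left = sel)
    }
  }
  if (best$valid && gini(y) - best$impurity <= 1e-12) best$valid <- FALSE
  best
}

# rejection sampler from a fitted model: unconditional draws filtered to a
# window around the evidence value of feature 1
rejection_completions <- function(model, x1_value, k, tol = 0.1,
                                  seed = 99, batch = 5000, max_batches = 200) {
  out <- numeric(0)
  set.seed(seed)
  for (b in seq_len(max_batches)) {
    s <- simulate(model, nsim = batch)
    keep <- abs(s$x1 - x1_value) < tol
    out <- c(out, s$x2[keep])
    if (length(out) >= k) break
  }
  out[seq_len(min(k, length(out)))]
}
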