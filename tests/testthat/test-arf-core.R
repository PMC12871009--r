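# adversarial training: naive synthesis, MIA discriminator, convergence

test_that("naive synthetic data bootstraps each column marginal", {
  set.seed(1)
  d <- data.frame(a = rep(7, 50), b = rnorm(50), g = factor(sample(letters[1:3], 50, TRUE)))
  d$b[1:10] <- NA
  s <- naive_synthetic(d)
  expect_identical(dim(s), dim(d))
  expect_true(all(s$a == 7))                          # single-support column
  expect_true(all(s$b[!is.na(s$b)] %in% d$b))         # bootstrap support
  expect_true(all(as.character(s$g) %in% levels(d$g)))

  # {0,1} column: synthetic fraction of ones inside the central 99.9%
  # binomial band of the observed fraction
  n <- 10000
  set.seed(2)
  d2 <- data.frame(z = rbinom(n, 1, 0.3))
  q <- mean(d2$z)
  s2 <- naive_synthetic(d2)
  band <- qbinom(c(5e-4, 1 - 5e-4), n, q)
  expect_gte(sum(s2$z), band[1])
  expect_lte(sum(s2$z), band[2])
})

test_that("discriminator OOB accuracy separates what it should", {
  set.seed(3)
  # indistinguishable classes (iid draws from the same distribution):
  # accuracy ~ 0.5, and never better than chance beyond noise
  n <- 400
  X2 <- matrix(rnorm(4 * n), ncol = 2)
  y <- c(rep(1L, n), rep(0L, n))
  f <- arfimpute:::cpp_grow_forest(X2, y, 50L, 10L, 1L, c(0L, 0L))
  expect_lt(abs(f$oob_accuracy - 0.5), 0.08)

  # class 0 an exact copy of class 1: no signal, so accuracy cannot beat
  # chance (OOB voting with duplicated rows is in fact pessimistic)
  Xd <- matrix(rnorm(2 * n), ncol = 2)
  fd <- arfimpute:::cpp_grow_forest(rbind(Xd, Xd), y, 50L, 10L, 1L, c(0L, 0L))
  expect_lt(fd$oob_accuracy, 0.5 + 5 * sqrt(0.25 / (2 * n)))

  # separable classes -> accuracy ~ 1
  Xs <- rbind(matrix(runif(n * 2, 1, 2), ncol = 2),
              matrix(runif(n * 2, -2, -1), ncol = 2))
  ys <- c(rep(1L, n), rep(0L, n))
  fs <- arfimpute:::cpp_grow_forest(Xs, ys, 50L, 10L, 1L, c(0L, 0L))
  expect_gt(fs$oob_accuracy, 0.97)

  # XOR dependence vs column-shuffled copy: dependence is learnable
  set.seed(4)
  m <- 500
  a <- sample(c(-1, 1), m, TRUE); b <- sample(c(-1, 1), m, TRUE)
  xor_real <- cbind(a * b + rnorm(m, 0, 0.1), a, b)
  shuf <- apply(xor_real, 2, sample)
  yx <- c(rep(1L, m), rep(0L, m))
  fx <- arfimpute:::cpp_grow_forest(rbind(xor_real, shuf), yx, 50L, 10L, 3L,
                                    c(0L, 0L, 0L))
  se2 <- sqrt(0.25 / (2 * m))
  expect_gt(fx$oob_accuracy, 0.5 + 3 * se2)
})

test_that("MIA split search matches exhaustive enumeration", {
  # NA perfectly predicts the class: some split routes NA right with
  # impurity 0
  res <- arfimpute:::cpp_best_mia_split(c(1, 2, 3, NA, NA),
                                        c(0L, 0L, 0L, 1L, 1L), 0L, 1L)
  expect_true(res$valid)
  expect_equal(res$impurity, 0)
  expect_false(res$na_left)

  # pure node -> no split
  res0 <- arfimpute:::cpp_best_mia_split(c(1, 2, NA, 4), rep(1L, 4), 0L, 1L)
  expect_false(res0$valid)

  # random numeric nodes vs brute force
  set.seed(10)
  for (rep in 1:30) {
    n <- sample(8:50, 1)
    x <- sample(c(rnorm(n), rep(NA, n)), n)
    y <- as.integer(runif(n) < 0.5)
    mn <- sample(1:3, 1)
    got <- arfimpute:::cpp_best_mia_split(x, y, 0L, mn)
    want <- brute_mia_numeric(x, y, mn)
    expect_equal(got$valid, want$valid)
    if (want$valid) {
      expect_equal(got$impurity, want$impurity, tolerance = 1e-12)
    }
  }

  # random categorical nodes (NA as an own level) vs subset brute force
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    k <- sample(2:4, 1)
    x <- sample(c(seq_len(k), NA), n, TRUE)
    y <- as.integer(runif(n) < 0.5)
    got <- arfimpute:::cpp_best_mia_split(as.numeric(x), y, as.integer(k), 2L)
    want <- brute_mia_categorical(x, y, k, 2L)
    expect_equal(got$valid, want$valid)
    if (want$valid)
      expect_equal(got$impurity, want$impurity, tolerance = 1e-12)
  }
})

test_that("adversarial loop converges immediately on independent columns", {
  set.seed(12)
  d <- as.data.frame(matrix(rnorm(2000 * 4), ncol = 4))
  names(d) <- paste0("x", 1:4)
  fit <- arf(d, num_trees = 50, delta = 0.02, seed = 13)
  expect_length(fit$oob_history, 1)
  expect_true(fit$converged)
  expect_lt(fit$oob_accuracy, 0.52)
})

test_that("training is deterministic given the seed and bounded by max_iters", {
  d <- make_clusters(60, seed = 20)
  f1 <- arf(d, num_trees = 20, seed = 21)
  f2 <- arf(d, num_trees = 20, seed = 21)
  expect_identical(f1$forest$trees, f2$forest$trees)
  expect_identical(f1$leaves, f2$leaves)
  expect_identical(f1$last_synth, f2$last_synth)
  expect_lte(length(f1$oob_history), f1$config$max_iters)
})

test_that("every row reaches exactly one leaf per tree, min node size holds", {
  set.seed(22)
  d <- data.frame(x = c(rnorm(150), rep(NA, 30)),
                  g = factor(sample(c("a", "b", NA), 180, TRUE)),
                  z = rnorm(180))
  fit <- arf(d, num_trees = 25, min_node_size = 10, seed = 23)
  X <- arfimpute:::encode_data(d, fit$schema)
  X <- rbind(X, NA)  # an all-missing row must also route
  mem <- arfimpute:::cpp_route(fit$forest$trees, X, fit$ftype)
  expect_identical(dim(mem), c(nrow(X), 25L))
  for (t in seq_len(25)) {
    nl <- fit$forest$trees[[t]]$n_leaves
    expect_true(all(mem[, t] >= 0 & mem[, t] < nl))
    # in-bag samples per leaf >= min_node_size
    nodes <- fit$forest$trees[[t]]$nodes
    leaves <- nodes[, "feature"] < 0
    expect_true(all(nodes[leaves, "n1"] + nodes[leaves, "n0"] >= 10))
  }
})

test_that("leaf-wise synthesis respects leaf membership and reduces mixing", {
  # stump forest (huge min_node_size): leaf-wise synthesis == naive bootstrap
  d <- make_clusters(100, seed = 30)
  X <- as.matrix(d)
  set.seed(31)
  stump <- arfimpute:::cpp_grow_forest(rbind(X, as.matrix(naive_synthetic(d))),
                                       c(rep(1L, 200), rep(0L, 200)),
                                       5L, 1000L, 1L, c(0L, 0L))
  expect_true(all(vapply(stump$trees, function(t) t$n_leaves, 1L) == 1))
  mem <- arfimpute:::cpp_route(stump$trees, X, c(0L, 0L))
  members <- arfimpute:::leaf_member_lists(stump$trees, mem)
  s <- arfimpute:::cpp_leafwise_synth(X, mem, members)
  expect_true(all(s[, 1] %in% X[, 1]) && all(s[, 2] %in% X[, 2]))

  # a trained (non-stump) forest mixes the two clusters less than naive
  fit <- arf(d, num_trees = 25, seed = 32)
  mem2 <- arfimpute:::cpp_route(fit$forest$trees, X, fit$ftype)
  members2 <- arfimpute:::leaf_member_lists(fit$forest$trees, mem2)
  mixed <- function(tab) mean(sign(tab[, 1]) == sign(tab[, 2]))
  set.seed(33)
  m_leaf <- mean(replicate(5, mixed(
    arfimpute:::cpp_leafwise_synth(X, mem2, members2))))
  m_naive <- mean(replicate(5, mixed(as.matrix(naive_synthetic(d)))))
  expect_lt(m_leaf, m_naive)
})

test_that("median OOB accuracy does not increase over the first two rounds", {
  accs <- t(sapply(1:20, function(s) {
    set.seed(40 + s)
    d <- as.data.frame(sim_copula_data(300, 4, "normal"))
    fit <- suppressWarnings(
      arf(d, num_trees = 20, delta = 0, max_iters = 2, seed = 140 + s))
    h <- fit$oob_history
    c(h[1], if (length(h) > 1) h[2] else h[1])
  }))
  expect_gte(median(accs[, 1]), median(accs[, 2]))
})
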