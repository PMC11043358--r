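sim_expr <- function(n, g, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * g), n, g,
         dimnames = list(sprintf("S%03d", 1:n), sprintf("G%04d", 1:g)))
}

test_that("exact duplicate genes collapse to one representative", {
  X <- sim_expr(30, 6)
  X[, 4] <- X[, 1]
  X[, 5] <- X[, 1]
  X[, 6] <- -X[, 1]  # anti-correlated duplicate collapses too
  res <- remove_multicollinearity(X)
  expect_true(sum(c("G0001", "G0004", "G0005", "G0006") %in% res$representatives) == 1)
  rep1 <- intersect(res$representatives, c("G0001", "G0004", "G0005", "G0006"))
  expect_setequal(res$cluster_map[[rep1]], c("G0001", "G0004", "G0005", "G0006"))
})

test_that("no retained pair violates the correlation threshold (post-hoc scan)", {
  set.seed(2)
  n <- 50
  base <- matrix(rnorm(n * 10), n, 10)
  # correlated blocks: each base gene spawns 4 noisy copies
  X <- base[, rep(1:10, each = 5)] + matrix(rnorm(n * 50, 0, 0.45), n, 50)
  colnames(X) <- sprintf("G%04d", 1:50)
  rownames(X) <- sprintf("S%03d", 1:n)
  res <- remove_multicollinearity(X, r_threshold = 0.6, p_threshold = 0.05)
  expect_lt(length(res$representatives), 50)
  C <- abs(cor(res$expression))
  diag(C) <- 0
  tq <- qt(1 - 0.05 / 2, n - 2)
  r_crit <- tq / sqrt(n - 2 + tq^2)
  expect_true(all(C < 0.6 | C < r_crit))
  # every input gene is accounted for exactly once in the cluster map
  expect_setequal(unlist(res$cluster_map), colnames(X))
})

test_that("independent genes are mostly retained and constants dropped", {
  kept <- vapply(1:10, function(seed) {
    X <- sim_expr(200, 100, seed = seed)
    length(remove_multicollinearity(X)$representatives) / 100
  }, 0)
  expect_true(all(kept >= 0.95))
  X <- sim_expr(30, 5)
  X[, 3] <- 7
  expect_warning(res <- remove_multicollinearity(X), "constant.*G0003")
  expect_false("G0003" %in% res$representatives)
})

test_that("retained set size is monotone in the correlation threshold", {
  set.seed(3)
  n <- 60
  base <- matrix(rnorm(n * 8), n, 8)
  X <- base[, rep(1:8, each = 4)] + matrix(rnorm(n * 32, 0, 0.8), n, 32)
  colnames(X) <- sprintf("G%04d", 1:32); rownames(X) <- sprintf("S%03d", 1:n)
  sizes <- vapply(c(0.9, 0.6, 0.3),
                  function(r) length(remove_multicollinearity(X, r)$representatives), 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("relevance scores rank a perfectly informative gene first", {
  X <- sim_expr(60, 20)
  y <- X[, 7]
  names(y) <- rownames(X)
  tab <- relevance_scores(X, y)
  expect_equal(tab$pearson[7], 1, tolerance = 1e-12)
  expect_equal(tab$spearman[7], 1, tolerance = 1e-12)
  expect_equal(tab$poly2_ssr[7], 0, tolerance = 1e-9)
  expect_equal(which.max(tab$pearson), 7L)
  expect_equal(which.max(tab$poly2_ssr), 7L)  # oriented: least residual wins
  expect_equal(which.max(tab$mutual_information), 7L)
  expect_equal(which.max(tab$linear_svm_coef), 7L)
})

test_that("null genes score near zero at large n", {
  set.seed(4)
  X <- sim_expr(500, 30, seed = 5)
  y <- rnorm(500); names(y) <- rownames(X)
  tab <- relevance_scores(X, y, scores = c("pearson", "mutual_information"))
  expect_true(all(tab$pearson <= 0.15))
  expect_lt(mean(tab$mutual_information), 0.05)
})

test_that("poly2 residual detects a quadratic signal that Pearson misses", {
  set.seed(6)
  X <- sim_expr(150, 15, seed = 6)
  x <- X[, 3]
  y <- (x - mean(x))^2
  names(y) <- rownames(X)
  tab <- relevance_scores(X, y, scores = c("pearson", "poly2_ssr"))
  expect_equal(which.max(tab$poly2_ssr), 3L)
  expect_lt(tab$pearson[3], 0.5)  # linear correlation largely blind to it
})

test_that("relevance_scores enforces its sample-size precondition", {
  X <- sim_expr(8, 5)
  y <- rnorm(8); names(y) <- rownames(X)
  expect_error(relevance_scores(X, y), ">= 10 samples")
})

test_that("threshold sweep recovers a planted gene signal", {
  set.seed(7)
  n <- 120; g <- 200; n_causal <- 10
  X <- sim_expr(n, g, seed = 7)
  causal <- sort(sample(g, n_causal))
  w <- runif(n_causal, 0.7, 1.3) * sample(c(-1, 1), n_causal, TRUE)
  y <- as.vector(X[, causal] %*% w) + rnorm(n, 0, 0.3)
  names(y) <- rownames(X)
  res <- threshold_sweep(X, y, score_names = "pearson", n_thresholds = 50,
                         n_folds = 5, seed = 1)
  recall <- mean(colnames(X)[causal] %in% res$selected_genes)
  expect_gte(recall, 0.8)
  expect_gte(res$cv_performance, 0.8)
})

test_that("a pure-noise response yields no illusory signal", {
  set.seed(8)
  X <- sim_expr(100, 150, seed = 8)
  y <- rnorm(100); names(y) <- rownames(X)
  res <- threshold_sweep(X, y, score_names = "pearson", n_thresholds = 50,
                         n_folds = 5, seed = 1)
  expect_lte(res$cv_performance, 0.2)
})

test_that("a single threshold at the score minimum selects every gene", {
  X <- sim_expr(40, 12)
  y <- X[, 1] + rnorm(40, 0, 0.5); names(y) <- rownames(X)
  res <- threshold_sweep(X, y, score_names = "pearson", n_thresholds = 1,
                         n_folds = 4, seed = 1)
  expect_setequal(res$selected_genes, colnames(X))
})

test_that("the sweep is invariant to gene column order", {
  set.seed(9)
  X <- sim_expr(60, 30, seed = 9)
  y <- as.vector(X[, c(2, 11)] %*% c(1, -1)) + rnorm(60, 0, 0.4)
  names(y) <- rownames(X)
  r1 <- threshold_sweep(X, y, score_names = "pearson", n_thresholds = 20,
                        n_folds = 4, seed = 3)
  perm <- sample(ncol(X))
  r2 <- threshold_sweep(X[, perm], y, score_names = "pearson", n_thresholds = 20,
                        n_folds = 4, seed = 3)
  expect_setequal(r1$selected_genes, r2$selected_genes)
  expect_equal(r1$cv_performance, r2$cv_performance, tolerance = 1e-10)
})

test_that("the fast ridge path agrees with a direct ridge fit", {
  set.seed(10)
  X <- sim_expr(50, 40, seed = 10)
  y <- as.vector(X[, 1:3] %*% c(1, 2, -1)) + rnorm(50, 0, 0.3)
  names(y) <- rownames(X)
  res <- threshold_sweep(X, y, score_names = "pearson", n_thresholds = 10,
                         n_folds = 5, seed = 2)
  # recompute with the generic per-fit path (same ridge, no Gram downdating)
  res2 <- threshold_sweep(X, y, score_names = "pearson", n_thresholds = 10,
                          n_folds = 5, seed = 2, fast = FALSE)
  expect_equal(res2$cv_performance, res$cv_performance, tolerance = 1e-8)
  expect_setequal(res2$selected_genes, res$selected_genes)
})
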