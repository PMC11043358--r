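mk_train <- function(v, samples, drugs) {
  dimnames(v) <- list(samples, drugs)
  response_matrix(v)
}

test_that("tanimoto matches |intersection| / |union|", {
  a <- c(1, 1, 1, 0, 0); b <- c(0, 1, 1, 1, 0)  # bits {1,2,3} vs {2,3,4}
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)
  # matrix form agrees with elementwise form
  set.seed(1)
  F1 <- matrix(rbinom(40, 1, 0.4), 4, 10, dimnames = list(letters[1:4], NULL))
  S <- tanimoto(F1, F1)
  for (i in 1:4) for (j in 1:4)
    expect_equal(S[i, j], tanimoto(F1[i, ], F1[j, ]))
})

test_that("mean baseline predicts the per-drug train mean", {
  train <- mk_train(matrix(c(2, 4, 1, 3), 2), c("S1", "S2"), c("dA", "dB"))
  p <- mean_baseline_fit_predict(train, c("S3", "S4"))
  expect_true(all(p$predictions[, "dA"] == 3))
  expect_true(all(p$predictions[, "dB"] == 2))
  # drug never observed in train: undefined, messaged
  v <- matrix(c(2, 4, NA, NA), 2)
  expect_message(
    p2 <- mean_baseline_fit_predict(mk_train(v, c("S1", "S2"), c("dA", "dB")),
                                    "S3"),
    "no training observations.*dB")
  expect_true(is.na(p2$predictions[, "dB"]))
})

test_that("mean baseline on z-scored data predicts near zero", {
  b <- tiny_bundle()
  z <- zscore_by_drug(b$response)
  p <- mean_baseline_fit_predict(z, rownames(z)[1:5])
  expect_lt(max(abs(p$predictions), na.rm = TRUE), 0.5)
  expect_lt(abs(mean(p$predictions, na.rm = TRUE)), 0.1)
})

test_that("bimodal kNN at k = 1 returns an identical train pair's response", {
  b <- tiny_bundle()
  v <- rm_values_test(b$response)
  cell <- which(!is.na(v), arr.ind = TRUE)[5, ]
  s <- rownames(v)[cell[1]]; d <- colnames(v)[cell[2]]
  p <- bimodal_knn_fit_predict(b$response, b$expression, b$fingerprints,
                               test_samples = s, k = 1, test_drugs = d)
  expect_equal(unname(p$predictions[s, d]), v[cell[1], cell[2]])
})

test_that("zero-filled omics makes kNN predictions constant across samples per drug", {
  b <- tiny_bundle()
  te <- rownames(b$response)[1:4]
  p <- bimodal_knn_fit_predict(b$response, b$expression, b$fingerprints,
                               test_samples = te, omics_mode = "zero_filled")
  expect_true(all(apply(p$predictions, 2, function(col) length(unique(col)) == 1)))
})

test_that("kNN neighbour ranking matches a brute-force scan on small instances", {
  set.seed(2)
  v <- matrix(rnorm(8), 4, 2)
  v[2, 1] <- NA  # 7 train pairs
  dimnames(v) <- list(sprintf("S%d", 1:4), c("dA", "dB"))
  train <- response_matrix(v)
  expr <- matrix(rnorm(5 * 6), 5, 6,
                 dimnames = list(sprintf("S%d", 1:5), sprintf("G%d", 1:6)))
  fp <- matrix(rbinom(2 * 16, 1, 0.5), 2, 16, dimnames = list(c("dA", "dB"), NULL))
  k <- 3; w <- 0.5
  p <- bimodal_knn_fit_predict(train, expr, fp, "S5", k = k, w = w)
  cells <- which(!is.na(v), arr.ind = TRUE)
  # brute force with the same normalizations
  ed <- as.matrix(dist(expr))[c("S5"), sprintf("S%d", 1:4)]
  ed_all <- as.matrix(dist(expr))["S5", unique(sprintf("S%d", cells[, 1]))]
  ed <- ed / max(ed_all)
  td <- 1 - c(dA = tanimoto(fp["dA", ], fp["dA", ]),
              dB = tanimoto(fp["dA", ], fp["dB", ]))
  tdB <- 1 - c(dA = tanimoto(fp["dB", ], fp["dA", ]),
               dB = tanimoto(fp["dB", ], fp["dB", ]))
  for (dd in c("dA", "dB")) {
    dvec <- if (dd == "dA") td else tdB
    dvec <- dvec / max(1 - tanimoto(fp, fp))
    comb <- w * dvec[colnames(v)[cells[, 2]]] + (1 - w) * ed[cells[, 1]]
    expect_equal(unname(p$predictions["S5", dd]),
                 mean(v[cells][order(comb)[1:k]]))
  }
})

test_that("kNN validates k and fingerprint availability", {
  b <- tiny_bundle()
  expect_error(bimodal_knn_fit_predict(b$response, b$expression, b$fingerprints,
                                       "S001", k = 1e6), "exceeds")
  fp <- b$fingerprints[-1, , drop = FALSE]
  expect_error(bimodal_knn_fit_predict(b$response, b$expression, fp, "S001"),
               "missing fingerprints.*D001")
})

test_that("single-drug ridge recovers a realizable linear hypothesis", {
  set.seed(3)
  expr <- matrix(rnorm(80 * 10), 80, 10,
                 dimnames = list(sprintf("S%d", 1:80), sprintf("G%d", 1:10)))
  y <- as.vector(expr[, 1:3] %*% c(2, -1, 0.5))
  names(y) <- rownames(expr)
  p <- single_drug_fit_predict(y[1:60], expr, "ridge", sprintf("G%d", 1:3),
                               new_samples = rownames(expr)[61:80], alpha = 1e-6)
  expect_gte(cor(p, y[61:80]), 0.999)
})

test_that("single-drug models see no signal in pure noise", {
  rs <- vapply(1:20, function(seed) {
    set.seed(seed)
    expr <- matrix(rnorm(60 * 15), 60, 15,
                   dimnames = list(sprintf("S%d", 1:60), sprintf("G%d", 1:15)))
    y <- rnorm(60); names(y) <- rownames(expr)
    p <- single_drug_fit_predict(y[1:40], expr, "ridge", colnames(expr),
                                 new_samples = rownames(expr)[41:60])
    cor(p, y[41:60])
  }, 0)
  expect_lte(abs(mean(rs)), 0.1)
})

test_that("every registry regressor runs behind the one contract", {
  set.seed(4)
  expr <- matrix(rnorm(50 * 8), 50, 8,
                 dimnames = list(sprintf("S%d", 1:50), sprintf("G%d", 1:8)))
  y <- as.vector(expr[, 1] * 2 + rnorm(50, 0, 0.3)); names(y) <- rownames(expr)
  for (nm in c("ridge", "knn", "svr_linear", "svr_rbf", "svr_poly",
               "decision_tree", "random_forest", "mlp")) {
    p <- single_drug_fit_predict(y[1:35], expr, nm, colnames(expr),
                                 new_samples = rownames(expr)[36:50])
    expect_length(p, 15)
    expect_true(all(is.finite(p)), info = nm)
  }
  expect_error(single_drug_fit_predict(y[1:35], expr, "no_such_model",
                                       colnames(expr), "S40"),
               "unknown regressor")
  expect_error(single_drug_fit_predict(y[1:35], expr, "ridge", character(0), "S40"),
               "non-empty")
})

test_that("feed-forward baseline is deterministic and learns a linear screen", {
  b <- tiny_bundle(seed = 31, noise_sd = 0.02)
  te <- rownames(b$response)[1:5]
  tr <- response_matrix(rm_values_test(b$response)[-(1:5), , drop = FALSE])
  p1 <- feedforward_fit_predict(tr, b$expression, b$fingerprints, te, seed = 7)
  p2 <- feedforward_fit_predict(tr, b$expression, b$fingerprints, te, seed = 7)
  expect_identical(p1$predictions, p2$predictions)
  obs <- response_matrix(rm_values_test(b$response)[te, , drop = FALSE])
  ev <- evaluate_predictions(obs, p1$predictions)
  expect_gte(ev$summary[["per_sample_pearson"]], 0.8)
  # zero-filling omics barely moves raw-measure performance on this
  # drug-dominated screen
  p0 <- feedforward_fit_predict(tr, b$expression, b$fingerprints, te,
                                omics_mode = "zero_filled", seed = 7)
  ev0 <- evaluate_predictions(obs, p0$predictions)
  expect_lt(abs(ev$summary[["per_sample_pearson"]] -
                ev0$summary[["per_sample_pearson"]]), 0.05)
})

test_that("mean baseline is bit-identical under the omics ablation", {
  b <- tiny_bundle()
  p_real <- mean_baseline_fit_predict(b$response, "S001")
  p_zero <- mean_baseline_fit_predict(b$response, "S001")
  expect_identical(p_real$predictions, p_zero$predictions)
})
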