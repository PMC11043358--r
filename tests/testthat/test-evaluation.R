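named_v <- function(v) stats::setNames(v, sprintf("d%02d", seq_along(v)))

test_that("precision_at_k handles perfect, disjoint and partial overlaps", {
  tv <- named_v(c(1, 2, 3, 4, 5, 6))
  expect_equal(precision_at_k(tv, tv, k = 3), 1)
  # predictions that invert the ranking: top-3 disjoint from true top-3
  expect_equal(precision_at_k(tv, named_v(rev(tv)), k = 3), 0)
  # 6 drugs, k = 3, exactly 2 overlapping
  pv <- named_v(c(1, 2, 10, 9, 3, 8))  # predicted top-3: d01, d02, d05
  expect_equal(precision_at_k(tv, pv, k = 3), 2 / 3)
  expect_warning(out <- precision_at_k(tv[1:2], named_v(c(1, 2)), k = 5), "undefined")
  expect_true(is.na(out))
})

test_that("ndcg_at_k matches the hand-enumerated discount sum", {
  # relevances (3,2,1,0) after mapping; predicted order swaps the top two
  tv <- named_v(c(0, 1, 2, 3))          # d01 most sensitive (rel 1, 2/3, 1/3, 0)
  pv <- named_v(c(2, 1, 3, 4))          # predicted order: d02, d01, d03, d04
  rel <- (3 - c(0, 1, 2, 3)) / 3
  dcg <- rel[2] / log2(2) + rel[1] / log2(3) + rel[3] / log2(4) + rel[4] / log2(5)
  idcg <- rel[1] / log2(2) + rel[2] / log2(3) + rel[3] / log2(4) + rel[4] / log2(5)
  expect_equal(ndcg_at_k(tv, pv, k = 4), dcg / idcg)
  expect_equal(ndcg_at_k(tv, tv, k = 4), 1)
  expect_lt(ndcg_at_k(tv, named_v(rev(tv)), k = 3), 1)
  expect_warning(out <- ndcg_at_k(named_v(rep(2, 5)), named_v(1:5), k = 3),
                 "constant")
  expect_true(is.na(out))
})

test_that("ranking metrics match brute-force references over random instances", {
  set.seed(10)
  for (i in 1:1000) {
    n <- sample(5:12, 1)
    k <- sample(2:(n - 1), 1)
    tv <- named_v(sample(seq_len(n)) + round(rnorm(n), 3))
    pv <- named_v(rnorm(n))
    expect_identical(precision_at_k(tv, pv, k), oracle_precision_at_k(tv, pv, k))
    expect_equal(ndcg_at_k(tv, pv, k), oracle_ndcg_at_k(tv, pv, k),
                 tolerance = 1e-12)
  }
})

test_that("cv folds partition the samples into near-equal, reproducible folds", {
  ids <- sprintf("S%02d", 1:10)
  f <- make_cv_folds(ids, 5, seed = 4)
  expect_setequal(names(f), ids)
  expect_true(all(table(f) == 2))
  expect_identical(f, make_cv_folds(ids, 5, seed = 4))
  expect_false(identical(f, make_cv_folds(ids, 5, seed = 5)))
  f2 <- make_cv_folds(sprintf("S%02d", 1:11), 3, seed = 1)
  expect_lte(diff(range(table(f2))), 1)
  expect_error(make_cv_folds(ids, 11), "exceeds")
})

test_that("per-drug Pearson of the mean baseline on its own train set is undefined", {
  b <- tiny_bundle()
  p <- mean_baseline_fit_predict(b$response, rownames(b$response))
  ev <- evaluate_predictions(b$response, p$predictions)
  # constant predictor per drug: correlation must be NA, never 0 or 1
  expect_true(all(is.na(ev$per_drug$pearson)))
})

test_that("the setting matrix enumerates model x measure x omics cells", {
  b <- tiny_bundle()
  rep_ <- run_setting_matrix(b, models = c("mean_baseline", "bimodal_knn"),
                             n_folds = 3, seed = 2)
  cells <- unique(rep_[c("model", "measure", "omics")])
  expect_equal(nrow(cells), 8L)
  agg <- aggregate_report(rep_)
  # fold means lie within the fold range
  for (i in seq_len(nrow(cells))) {
    sel <- rep_$model == cells$model[i] & rep_$measure == cells$measure[i] &
      rep_$omics == cells$omics[i] & rep_$metric == "per_sample_pearson" &
      rep_$status == "ok"
    vals <- rep_$value[sel]
    m <- agg$mean[agg$model == cells$model[i] & agg$measure == cells$measure[i] &
                  agg$omics == cells$omics[i] & agg$metric == "per_sample_pearson"]
    if (all(is.na(vals))) next
    expect_gte(m, min(vals, na.rm = TRUE))
    expect_lte(m, max(vals, na.rm = TRUE))
  }
  # ablation theorem: the mean baseline's cells are identical bit-for-bit
  preds <- attr(rep_, "predictions")
  expect_identical(preds[["mean_baseline|raw|real"]],
                   preds[["mean_baseline|raw|zero_filled"]])
  expect_identical(preds[["mean_baseline|zscored|real"]],
                   preds[["mean_baseline|zscored|zero_filled"]])
})

test_that("a failing model marks its cell failed without touching others", {
  b <- tiny_bundle()
  b$fingerprints <- b$fingerprints[-1, , drop = FALSE]  # breaks the kNN only
  rep_ <- run_setting_matrix(b, models = c("mean_baseline", "bimodal_knn"),
                             n_folds = 3, seed = 2)
  expect_true(any(grepl("failed", rep_$status[rep_$model == "bimodal_knn"])))
  expect_true(all(rep_$status[rep_$model == "mean_baseline"] == "ok"))
})

test_that("degenerate transfer on one bundle equals in-sample evaluation", {
  b <- tiny_bundle()
  tb <- zero_shot_transfer(b, b, models = "mean_baseline", measures = "raw",
                           omics_modes = "real")
  p <- mean_baseline_fit_predict(b$response, rownames(b$response))
  ev <- evaluate_predictions(b$response, p$predictions)
  got <- tb$value[tb$metric == "per_sample_pearson"]
  expect_equal(got, unname(ev$summary["per_sample_pearson"]), tolerance = 1e-12)
  expect_true(attr(tb, "transfer"))
})

test_that("transfer requires shared drugs", {
  b <- tiny_bundle()
  b2 <- b
  colnames(b2$response) <- paste0("X", colnames(b2$response))
  rownames(b2$fingerprints) <- paste0("X", rownames(b2$fingerprints))
  b2$response <- response_matrix(rm_values_test(b2$response))
  expect_error(zero_shot_transfer(b, b2), "no shared drugs")
})
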