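#' Precision at k of a predicted drug ranking
#'
#' Fraction of a sample's true top-k most-sensitive drugs recovered in the
#' predicted top-k. "Top" means smallest measure value (all shipped
#' measures are lower-is-more-sensitive). Ties at the k-boundary are broken
#' deterministically by drug id after the value sort.
#'
#' @param true_responses named numeric vector (names = drug ids) of one
#'   sample's observed responses.
#' @param predicted same shape, the predictions.
#' @param k size of the top list.
#' @return |top-k(pred) ∩ top-k(true)| / k, or `NA` with a warning when
#'   fewer than k drugs are observed.
#' @export
precision_at_k <- function(true_responses, predicted, k = 5) {
  obs <- names(true_responses)[!is.na(true_responses) & !is.na(predicted[names(true_responses)])]
  if (length(obs) < k) {
    warning("fewer than k = ", k, " observed drugs; precision undefined")
    return(NA_real_)
  }
  tv <- true_responses[obs]; pv <- predicted[obs]
  top_true <- obs[order(tv, obs)][seq_len(k)]
  top_pred <- obs[order(pv, obs)][seq_len(k)]
  length(intersect(top_true, top_pred)) / k
}

#' Normalized discounted cumulative gain at k
#'
#' Relevance of each drug is mapped to [0, 1] by
#' `(worst - value) / (worst - best)` over the sample's observed drugs, so
#' the most sensitive drug has relevance 1. The DCG of the predicted
#' ordering (log2 positional discount, positions 1..k) is divided by the
#' DCG of the ideal ordering; a perfect ranking scores 1.
#'
#' @inheritParams precision_at_k
#' @return NDCG in [0, 1], or `NA` with a warning when all relevances are
#'   zero (constant truth) or fewer than k drugs are observed.
#' @export
ndcg_at_k <- function(true_responses, predicted, k = 5) {
  obs <- names(true_responses)[!is.na(true_responses) & !is.na(predicted[names(true_responses)])]
  if (length(obs) < k) {
    warning("fewer than k = ", k, " observed drugs; NDCG undefined")
    return(NA_real_)
  }
  tv <- true_responses[obs]; pv <- predicted[obs]
  worst <- max(tv); best <- min(tv)
  if (worst == best) {
    warning("all relevances zero (constant truth); NDCG undefined")
    return(NA_real_)
  }
  rel <- (worst - tv) / (worst - best)
  disc <- 1 / log2(seq_len(k) + 1)
  dcg <- sum(rel[order(pv, obs)][seq_len(k)] * disc)
  idcg <- sum(sort(rel, decreasing = TRUE)[seq_len(k)] * disc)
  dcg / idcg
}

#' Sample-disjoint cross-validation folds
#'
#' Partitions the samples into `n_folds` folds of sizes differing by at
#' most one, reproducibly from `seed`. No sample appears in two folds, so
#' evaluation is always on unseen samples.
#'
#' @param sample_ids character vector of sample ids.
#' @param n_folds number of folds (<= number of samples).
#' @param seed RNG seed.
#' @return Named integer vector: sample id -> fold in 1..n_folds.
#' @export
make_cv_folds <- function(sample_ids, n_folds, seed = 1) {
  m <- length(sample_ids)
  if (n_folds > m) stop("n_folds = ", n_folds, " exceeds ", m, " samples")
  if (n_folds < 2) stop("need at least 2 folds")
  set.seed(seed)
  stats::setNames(rep_len(seq_len(n_folds), m)[sample.int(m)], sample_ids)
}

#' Score a prediction matrix against observed responses
#'
#' Computes, over the observed cells, the Pearson correlation and MSE
#' separately per sample (across that sample's drugs) and per drug (across
#' samples), plus Precision at k and NDCG at k per sample. Correlations
#' over constant vectors or fewer than 3 points are reported as `NA`
#' (undefined), never coerced to 0 or 1.
#'
#' @param observed a [response_matrix()] of the test samples.
#' @param predictions matrix aligned to (a superset of) `observed`.
#' @param k ranking cutoff for Precision/NDCG.
#' @return A list with `per_sample` and `per_drug` data.frames and
#'   `summary` (named means over the defined entries).
#' @export
evaluate_predictions <- function(observed, predictions, k = 5) {
  stopifnot(inherits(observed, "response_matrix"))
  v <- rm_values(observed)
  p <- predictions[rownames(v), colnames(v), drop = FALSE]
  safe_cor <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      return(NA_real_)
    stats::cor(a[ok], b[ok])
  }
  safe_mse <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(NA_real_)
    mean((a[ok] - b[ok])^2)
  }
  per_sample <- data.frame(
    sample_id = rownames(v),
    pearson = vapply(seq_len(nrow(v)), function(i) safe_cor(v[i, ], p[i, ]), 0),
    mse = vapply(seq_len(nrow(v)), function(i) safe_mse(v[i, ], p[i, ]), 0),
    precision_at_k = vapply(seq_len(nrow(v)), function(i)
      suppressWarnings(precision_at_k(v[i, ], p[i, ], k)), 0),
    ndcg_at_k = vapply(seq_len(nrow(v)), function(i)
      suppressWarnings(ndcg_at_k(v[i, ], p[i, ], k)), 0),
    stringsAsFactors = FALSE)
  per_drug <- data.frame(
    drug_id = colnames(v),
    pearson = vapply(seq_len(ncol(v)), function(j) safe_cor(v[, j], p[, j]), 0),
    mse = vapply(seq_len(ncol(v)), function(j) safe_mse(v[, j], p[, j]), 0),
    stringsAsFactors = FALSE)
  summary <- c(
    per_sample_pearson = mean(per_sample$pearson, na.rm = TRUE),
    per_sample_mse = mean(per_sample$mse, na.rm = TRUE),
    per_drug_pearson = mean(per_drug$pearson, na.rm = TRUE),
    per_drug_mse = mean(per_drug$mse, na.rm = TRUE),
    precision_at_k = mean(per_sample$precision_at_k, na.rm = TRUE),
    ndcg_at_k = mean(per_sample$ndcg_at_k, na.rm = TRUE))
  list(per_sample = per_sample, per_drug = per_drug, summary = summary)
}

# internal dispatcher from model name to a prediction matrix
run_model <- function(model, train_rm, expr, fingerprints, test_samples,
                      omics_mode, seed, nn_args = list()) {
  switch(model,
    mean_baseline = mean_baseline_fit_predict(train_rm, test_samples),
    bimodal_knn = bimodal_knn_fit_predict(train_rm, expr, fingerprints,
                                          test_samples,
                                          omics_mode = omics_mode),
    feedforward_nn = do.call(feedforward_fit_predict,
      c(list(train_rm, expr, fingerprints, test_samples,
             omics_mode = omics_mode, seed = seed), nn_args)),
    stop("unknown pan-screen model: ", model))
}

#' Run the four-setting experiment matrix
#'
#' Evaluates every (model x measure x omics mode) combination under
#' sample-disjoint cross-validation: raw and per-drug z-scored responses,
#' each with real and zero-filled omics. The z-score transform is applied
#' to the full response matrix before splitting (the transform is treated
#' as a dataset property, as screen-level z-scores are published). The mean
#' baseline ignores omics, so it is computed once per measure and reused in
#' both omics columns — its two cells are identical by construction.
#'
#' @param bundle list with `response` (a raw [response_matrix()]), `expression`
#'   (samples x genes), `fingerprints` (drugs x bits).
#' @param models character vector from `"mean_baseline"`, `"bimodal_knn"`,
#'   `"feedforward_nn"`.
#' @param measures subset of `c("raw", "zscored")`.
#' @param omics_modes subset of `c("real", "zero_filled")`.
#' @param n_folds cross-validation folds.
#' @param k ranking cutoff.
#' @param seed seed for folds and stochastic models.
#' @param nn_args list of extra arguments for [feedforward_fit_predict()].
#' @return An `evaluation_report` data.frame: one row per model x measure x
#'   omics x fold x metric, with a `status` column (`"ok"`/`"failed"`);
#'   attribute `predictions` holds the out-of-fold prediction matrices per
#'   (model, measure, omics).
#' @export
run_setting_matrix <- function(bundle, models = c("mean_baseline", "bimodal_knn"),
                               measures = c("raw", "zscored"),
                               omics_modes = c("real", "zero_filled"),
                               n_folds = 5, k = 5, seed = 1,
                               nn_args = list()) {
  measures <- match.arg(measures, c("raw", "zscored"), several.ok = TRUE)
  omics_modes <- match.arg(omics_modes, c("real", "zero_filled"), several.ok = TRUE)
  resp <- list()
  if ("raw" %in% measures) resp$raw <- bundle$response
  if ("zscored" %in% measures) resp$zscored <- zscore_by_drug(bundle$response)
  folds <- make_cv_folds(rownames(bundle$response), n_folds, seed = seed)

  rows <- list(); preds <- list()
  for (meas in names(resp)) {
    rm_full <- resp[[meas]]
    for (model in models) {
      for (om in omics_modes) {
        # the mean baseline is omics-blind: reuse the first omics mode's run
        reuse <- model == "mean_baseline" && om != omics_modes[1] &&
          !is.null(preds[[paste(model, meas, omics_modes[1], sep = "|")]])
        pred_full <- matrix(NA_real_, nrow(rm_full), ncol(rm_full),
                            dimnames = dimnames(rm_full))
        for (f in sort(unique(folds))) {
          te <- names(folds)[folds == f]
          tr <- setdiff(rownames(rm_full), te)
          train_rm <- as_response_matrix(rm_values(rm_full)[tr, , drop = FALSE],
                                         rm_full)
          fit <- if (reuse) NULL else tryCatch(
            run_model(model, train_rm, bundle$expression, bundle$fingerprints,
                      te, om, seed = seed + f, nn_args = nn_args),
            error = function(e) e)
          if (inherits(fit, "error")) {
            rows[[length(rows) + 1]] <- data.frame(
              model = model, measure = meas, omics = om, fold = f,
              metric = "per_sample_pearson", value = NA_real_,
              status = paste0("failed: ", conditionMessage(fit)),
              stringsAsFactors = FALSE)
            next
          }
          if (!reuse) pred_full[te, colnames(fit$predictions)] <-
            fit$predictions[te, , drop = FALSE]
          else pred_full[te, ] <-
            attr(preds[[paste(model, meas, omics_modes[1], sep = "|")]],
                 "matrix")[te, ]
          test_rm <- as_response_matrix(rm_values(rm_full)[te, , drop = FALSE],
                                        rm_full)
          ev <- evaluate_predictions(test_rm, pred_full, k = k)
          rows[[length(rows) + 1]] <- data.frame(
            model = model, measure = meas, omics = om, fold = f,
            metric = names(ev$summary), value = unname(ev$summary),
            status = "ok", stringsAsFactors = FALSE)
        }
        key <- paste(model, meas, om, sep = "|")
        preds[[key]] <- structure(list(), "matrix" = pred_full)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_report", "data.frame")
  attr(out, "predictions") <- lapply(preds, attr, "matrix")
  attr(out, "k") <- k
  out
}

#' Aggregate an evaluation report across folds
#'
#' @param report an `evaluation_report`.
#' @return data.frame with mean and sd across folds per (model, measure,
#'   omics, metric).
#' @export
aggregate_report <- function(report) {
  ok <- report[report$status == "ok", ]
  agg <- stats::aggregate(value ~ model + measure + omics + metric, data = ok,
                          FUN = function(z) c(mean = mean(z, na.rm = TRUE),
                                              sd = stats::sd(z)))
  out <- cbind(agg[, 1:4], mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  out[order(out$model, out$measure, out$omics, out$metric), ]
}

#' Zero-shot transfer evaluation between two screens
#'
#' Trains each model on the full training bundle and evaluates it on the
#' test bundle without any re-training, restricted to the drugs shared by
#' the two screens. Expression is harmonized by double z-scoring
#' ([harmonize_expression()]); z-scored responses are computed within each
#' dataset separately (each screen's own population is its reference). No
#' test information enters training.
#'
#' @param train_bundle,test_bundle lists with `response`, `expression`,
#'   `fingerprints` (sample ids must not clash across bundles).
#' @param models as in [run_setting_matrix()].
#' @param measures,omics_modes,k,seed,nn_args as in [run_setting_matrix()].
#' @return An `evaluation_report` (single pseudo-fold, `fold = NA`) with
#'   attribute `transfer = TRUE`.
#' @export
zero_shot_transfer <- function(train_bundle, test_bundle,
                               models = c("mean_baseline", "bimodal_knn"),
                               measures = c("raw", "zscored"),
                               omics_modes = c("real", "zero_filled"),
                               k = 5, seed = 1, nn_args = list()) {
  shared <- intersect(colnames(train_bundle$response),
                      colnames(test_bundle$response))
  if (length(shared) == 0) stop("no shared drugs between the two bundles")
  expr <- harmonize_expression(train_bundle$expression, test_bundle$expression)
  te_samples <- rownames(test_bundle$response)

  resp_tr <- list(); resp_te <- list()
  if ("raw" %in% measures) {
    resp_tr$raw <- train_bundle$response
    resp_te$raw <- test_bundle$response
  }
  if ("zscored" %in% measures) {
    resp_tr$zscored <- zscore_by_drug(train_bundle$response)
    resp_te$zscored <- zscore_by_drug(test_bundle$response)
  }
  rows <- list(); preds <- list()
  for (meas in names(resp_tr)) {
    tr_rm <- resp_tr[[meas]]
    sh <- intersect(shared, intersect(colnames(tr_rm), colnames(resp_te[[meas]])))
    te_rm <- as_response_matrix(
      rm_values(resp_te[[meas]])[, sh, drop = FALSE], resp_te[[meas]])
    for (model in models) {
      for (om in omics_modes) {
        fit <- tryCatch(
          run_model(model, tr_rm, expr, train_bundle$fingerprints,
                    te_samples, om, seed = seed, nn_args = nn_args),
          error = function(e) e)
        if (inherits(fit, "error")) {
          rows[[length(rows) + 1]] <- data.frame(
            model = model, measure = meas, omics = om, fold = NA_integer_,
            metric = "per_sample_pearson", value = NA_real_,
            status = paste0("failed: ", conditionMessage(fit)),
            stringsAsFactors = FALSE)
          next
        }
        ev <- evaluate_predictions(te_rm, fit$predictions, k = k)
        rows[[length(rows) + 1]] <- data.frame(
          model = model, measure = meas, omics = om, fold = NA_integer_,
          metric = names(ev$summary), value = unname(ev$summary),
          status = "ok", stringsAsFactors = FALSE)
        preds[[paste(model, meas, om, sep = "|")]] <- fit$predictions
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_report", "data.frame")
  attr(out, "predictions") <- preds
  attr(out, "transfer") <- TRUE
  attr(out, "shared_drugs") <- shared
  out
}
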