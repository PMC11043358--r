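#' Remove multicollinearity among genes by iterative clustering
#'
#' Iteratively performs agglomerative clustering of genes with complete
#' linkage on correlation distances (1 - |Pearson r|, so anti-correlated
#' duplicates also collapse), cuts at distance `1 - r_threshold`, keeps one
#' representative per cluster (highest variance, ties by gene id), and
#' repeats while any cluster holds more than one gene. Pairs whose
#' correlation is not significant at `p_threshold` are treated as
#' uncorrelated, so weakly-sampled coincidental correlations do not prune
#' genes. On return no retained pair has |r| >= `r_threshold` with
#' p < `p_threshold`.
#'
#' @param expr samples x genes matrix (>= 3 samples, >= 2 genes).
#' @param r_threshold absolute correlation above which two genes are
#'   considered collinear (default 0.6).
#' @param p_threshold significance level for the correlation test.
#' @return A list with `expression` (the reduced matrix), `representatives`
#'   (retained gene ids) and `cluster_map` (named list: representative ->
#'   character vector of all genes it stands for, itself included).
#' @export
remove_multicollinearity <- function(expr, r_threshold = 0.6, p_threshold = 0.05) {
  stopifnot(is.matrix(expr), nrow(expr) >= 3, ncol(expr) >= 2)
  vars <- apply(expr, 2, stats::var)
  if (any(vars == 0)) {
    warning("dropping constant genes: ",
            paste(colnames(expr)[vars == 0], collapse = ", "))
    expr <- expr[, vars > 0, drop = FALSE]
    vars <- vars[vars > 0]
  }
  n <- nrow(expr)
  # two-sided p-value of Pearson r at n samples
  r_crit <- if (n > 2) {
    tq <- stats::qt(1 - p_threshold / 2, n - 2)
    tq / sqrt(n - 2 + tq^2)
  } else 1
  members <- stats::setNames(as.list(colnames(expr)), colnames(expr))
  reps <- colnames(expr)
  repeat {
    if (length(reps) < 2) break
    C <- abs(stats::cor(expr[, reps, drop = FALSE]))
    C[C < r_crit] <- 0  # not significant at p_threshold: treat as uncorrelated
    d <- stats::as.dist(1 - C)
    cl <- stats::cutree(stats::hclust(d, method = "complete"),
                        h = 1 - r_threshold)
    if (max(cl) == length(reps)) break  # all singletons: converged
    new_reps <- character(0)
    for (g in split(reps, cl)) {
      if (length(g) == 1) { new_reps <- c(new_reps, g); next }
      rep_g <- g[order(-vars[g], g)][1]
      members[[rep_g]] <- unique(unlist(members[c(rep_g, setdiff(g, rep_g))]))
      members[setdiff(g, rep_g)] <- NULL
      new_reps <- c(new_reps, rep_g)
    }
    reps <- sort(new_reps)
  }
  reps <- sort(reps)
  list(expression = expr[, reps, drop = FALSE],
       representatives = reps,
       cluster_map = members[reps])
}

#' Relevance scores of genes for one drug's response
#'
#' Scores each gene's association with a per-sample response vector by five
#' statistics: Pearson and Spearman correlation, mutual information
#' (k-nearest-neighbour estimator for continuous pairs, `k = mi_k`), the sum
#' of squared residuals of a degree-2 polynomial least-squares fit, and the
#' per-gene coefficient of a linear support-vector regression on all genes.
#' Every column is oriented so that larger = more relevant: correlations and
#' SVM coefficients enter as absolute values, the polynomial residual is
#' negated (a small residual means the gene explains the response).
#'
#' @param expr samples x genes matrix.
#' @param response named numeric vector of one drug's responses; names are
#'   sample ids (must be rows of `expr`); `NA`s are dropped.
#' @param scores which score columns to compute.
#' @param mi_k neighbour count of the mutual-information estimator.
#' @return A data.frame with a `gene` column and one oriented column per
#'   requested score.
#' @export
relevance_scores <- function(expr, response,
                             scores = c("pearson", "spearman",
                                        "mutual_information", "poly2_ssr",
                                        "linear_svm_coef"),
                             mi_k = 3) {
  scores <- match.arg(scores, several.ok = TRUE)
  if (!is.null(names(response))) {
    keep <- intersect(rownames(expr), names(response)[!is.na(response)])
    y <- response[keep]; X <- expr[keep, , drop = FALSE]
  } else {
    stopifnot(length(response) == nrow(expr))
    keep <- !is.na(response)
    y <- response[keep]; X <- expr[keep, , drop = FALSE]
  }
  n <- length(y)
  if (n < 10) stop("need >= 10 samples with observed response, got ", n)
  out <- data.frame(gene = colnames(X), stringsAsFactors = FALSE)
  if ("pearson" %in% scores)
    out$pearson <- abs(as.vector(stats::cor(X, y)))
  if ("spearman" %in% scores)
    out$spearman <- abs(as.vector(stats::cor(X, y, method = "spearman")))
  if ("mutual_information" %in% scores)
    out$mutual_information <- apply(X, 2, ksg_mutual_information, y = y, k = mi_k)
  if ("poly2_ssr" %in% scores) {
    out$poly2_ssr <- if (n < 4) NA_real_ else -apply(X, 2, function(x) {
      r <- stats::lm.fit(cbind(1, x, x * x), y)$residuals
      sum(r * r)
    })
  }
  if ("linear_svm_coef" %in% scores) {
    sv <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                     scale = apply(X, 2, stats::sd) > 0)
    w <- crossprod(sv$coefs, sv$SV)
    out$linear_svm_coef <- abs(as.vector(w))
  }
  out
}

# Kraskov-Stoegbauer-Grassberger kNN mutual information estimator
# (variant 1, max-norm) for a continuous pair; >= 0 up to estimator noise.
ksg_mutual_information <- function(x, y, k = 3) {
  n <- length(x)
  stopifnot(length(y) == n, k < n)
  # tiny jitter-free rank-breaking: scale both margins to unit sd
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  x <- x / sx; y <- y / sy
  dx <- abs(outer(x, x, "-")); dy <- abs(outer(y, y, "-"))
  dz <- pmax(dx, dy)
  diag(dz) <- Inf
  eps <- apply(dz, 1, function(r) sort(r, partial = k)[k])
  nx <- rowSums(dx < eps) - 1L
  ny <- rowSums(dy < eps) - 1L
  digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
}

#' Cross-validated sweep over relevance-score thresholds
#'
#' For each relevance score, lays a grid of `n_thresholds` thresholds on the
#' score's empirical quantiles, fits the inner model (default: exact ridge
#' regression, `alpha = 10`) on the genes passing each threshold, and
#' evaluates every (score, threshold) candidate by the mean across
#' cross-validation folds of the Pearson correlation between observed and
#' predicted response. Returns the best combination, ties broken toward
#' fewer genes.
#'
#' Relevance scores are recomputed inside each training fold by default so
#' no test response leaks into gene selection; pass a precomputed `scores`
#' table to reproduce protocols that select on the full dataset.
#'
#' For the ridge model the threshold grid is swept with incrementally
#' downdated Gram matrices (gene sets along one score's grid are nested), so
#' the full 5-score x 100-threshold x k-fold sweep costs little more than
#' one pass over the data.
#'
#' @param expr samples x genes matrix.
#' @param response named per-sample response vector for one drug.
#' @param scores optional precomputed [relevance_scores()] table.
#' @param score_names which scores to sweep.
#' @param model inner model: `"ridge"` (fast path) or any name from
#'   [single_drug_model()].
#' @param fast use the incremental-Gram ridge path when `model = "ridge"`
#'   (identical results; set `FALSE` to force the generic per-fit path).
#' @param alpha ridge penalty.
#' @param n_thresholds thresholds per score (quantile-spaced).
#' @param n_folds cross-validation folds.
#' @param seed fold-assignment seed.
#' @param drug_id identifier carried into the result.
#' @return A list of class `gene_selection_result`: `drug_id`, `score_name`,
#'   `threshold` (full-data score scale), `selected_genes`,
#'   `cv_performance`, `n_genes`, and `sweep` (data.frame: score,
#'   threshold_index, n_genes, cv_performance).
#' @export
threshold_sweep <- function(expr, response, scores = NULL,
                            score_names = c("pearson", "spearman",
                                            "mutual_information", "poly2_ssr",
                                            "linear_svm_coef"),
                            model = "ridge", fast = TRUE, alpha = 10,
                            n_thresholds = 100, n_folds = 10, seed = 1,
                            drug_id = NA_character_) {
  score_names <- match.arg(score_names, several.ok = TRUE)
  if (is.null(names(response))) names(response) <- rownames(expr)
  keep <- intersect(rownames(expr), names(response)[!is.na(response)])
  X <- expr[keep, , drop = FALSE]; y <- response[keep]
  folds <- make_cv_folds(keep, n_folds, seed = seed)
  probs <- seq(0, 1, length.out = n_thresholds)
  genes <- colnames(X)

  # cv_perf[score, threshold_index, fold]
  cv_perf <- array(NA_real_, c(length(score_names), n_thresholds, n_folds),
                   dimnames = list(score_names, NULL, NULL))
  for (f in seq_len(n_folds)) {
    te <- names(folds)[folds == f]; tr <- setdiff(keep, te)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    ytr <- y[tr]; yte <- y[te]
    tab <- if (is.null(scores))
      relevance_scores(Xtr, ytr, scores = score_names) else scores
    for (sn in score_names) {
      s <- tab[[sn]][match(genes, tab$gene)]
      if (all(is.na(s))) next
      thr <- stats::quantile(s, probs, na.rm = TRUE, names = FALSE)
      counts <- vapply(thr, function(t) sum(s >= t, na.rm = TRUE), 0L)
      ord <- order(-s, genes)  # stable: score desc, then gene id
      if (model == "ridge" && fast) {
        cv_perf[sn, , f] <- sweep_ridge_path(Xtr, ytr, Xte, yte, ord, counts, alpha)
      } else {
        for (ti in seq_len(n_thresholds)) {
          if (counts[ti] == 0) next
          g <- genes[ord[seq_len(counts[ti])]]
          p <- tryCatch(
            single_drug_fit_predict(ytr, X, model, g, new_samples = te,
                                    alpha = alpha),
            error = function(e) NULL)
          if (!is.null(p) && stats::sd(p) > 0 && stats::sd(yte) > 0)
            cv_perf[sn, ti, f] <- stats::cor(yte, p)
        }
      }
    }
  }

  perf <- apply(cv_perf, c(1, 2), function(z) {
    if (sum(!is.na(z)) < max(1, n_folds / 2)) NA_real_ else mean(z, na.rm = TRUE)
  })
  # gene counts of each candidate on the full data (for tie-breaks and report)
  full_tab <- if (is.null(scores)) relevance_scores(X, y, scores = score_names)
              else scores
  n_genes_full <- matrix(NA_integer_, length(score_names), n_thresholds,
                         dimnames = list(score_names, NULL))
  for (sn in score_names) {
    s <- full_tab[[sn]][match(genes, full_tab$gene)]
    if (all(is.na(s))) next
    thr <- stats::quantile(s, probs, na.rm = TRUE, names = FALSE)
    n_genes_full[sn, ] <- vapply(thr, function(t) sum(s >= t, na.rm = TRUE), 0L)
  }
  sweep_tab <- data.frame(
    score = rep(score_names, n_thresholds),
    threshold_index = rep(seq_len(n_thresholds), each = length(score_names)),
    n_genes = as.vector(n_genes_full),
    cv_performance = as.vector(perf), stringsAsFactors = FALSE)
  ok <- !is.na(sweep_tab$cv_performance) & sweep_tab$n_genes > 0
  if (!any(ok)) stop("no (score, threshold) candidate produced a defined fit")
  cand <- sweep_tab[ok, ]
  best <- cand[order(-cand$cv_performance, cand$n_genes), ][1, ]

  s <- full_tab[[best$score]][match(genes, full_tab$gene)]
  thr_val <- stats::quantile(s, probs[best$threshold_index], na.rm = TRUE,
                             names = FALSE)
  sel <- genes[order(-s, genes)][seq_len(sum(s >= thr_val, na.rm = TRUE))]
  structure(list(drug_id = drug_id, score_name = best$score,
                 threshold = thr_val, selected_genes = sel,
                 cv_performance = best$cv_performance,
                 n_genes = length(sel), sweep = sweep_tab),
            class = "gene_selection_result")
}

# ridge over one score's nested threshold path with Gram downdating.
# ord: gene order (score desc); counts: genes kept per threshold (desc).
# Returns per-threshold held-out Pearson.
sweep_ridge_path <- function(Xtr, ytr, Xte, yte, ord, counts, alpha) {
  n <- nrow(Xtr); nt <- length(counts)
  res <- rep(NA_real_, nt)
  if (stats::sd(yte) == 0) return(res)
  cur <- counts[1]
  K <- tcrossprod(Xtr[, ord[seq_len(cur)], drop = FALSE])
  Kx <- tcrossprod(Xte[, ord[seq_len(cur)], drop = FALSE],
                   Xtr[, ord[seq_len(cur)], drop = FALSE])
  yc <- ytr - mean(ytr)
  for (ti in seq_len(nt)) {
    if (counts[ti] == 0) next
    if (counts[ti] < cur) {
      drop_idx <- ord[(counts[ti] + 1):cur]
      K <- K - tcrossprod(Xtr[, drop_idx, drop = FALSE])
      Kx <- Kx - tcrossprod(Xte[, drop_idx, drop = FALSE],
                            Xtr[, drop_idx, drop = FALSE])
      cur <- counts[ti]
    }
    rk <- rowMeans(K); mk <- mean(K)
    Kc <- K - outer(rk, rep(1, n)) - outer(rep(1, n), rk) + mk
    Kxc <- Kx - outer(rowMeans(Kx), rep(1, n)) -
      outer(rep(1, nrow(Kx)), rk) + mk
    a <- tryCatch(solve(Kc + diag(alpha, n), yc), error = function(e) NULL)
    if (is.null(a)) next
    pred <- as.vector(Kxc %*% a) + mean(ytr)
    if (stats::sd(pred) > 0) res[ti] <- stats::cor(yte, pred)
  }
  res
}

#' @export
print.gene_selection_result <- function(x, ...) {
  cat(sprintf("gene_selection_result: drug %s, score %s, %d genes, cv Pearson %.3f\n",
              x$drug_id, x$score_name, x$n_genes, x$cv_performance))
  invisible(x)
}
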