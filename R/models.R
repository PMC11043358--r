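#' Tanimoto similarity between binary fingerprints
#'
#' |intersection| / |union| of set bits. For two all-zero fingerprints the
#' similarity is defined as 0 (cheminformatics convention).
#'
#' @param a,b binary vectors (0/1) of equal length, or matrices of
#'   fingerprints in rows, in which case the full similarity matrix between
#'   the rows of `a` and of `b` is returned.
#' @return A similarity in [0, 1], or a matrix thereof.
#' @export
tanimoto <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- rbind(a); b <- rbind(b)
    stopifnot(ncol(a) == ncol(b))
    inter <- tcrossprod(a, b)
    na <- rowSums(a); nb <- rowSums(b)
    uni <- outer(na, nb, "+") - inter
    s <- ifelse(uni == 0, 0, inter / uni)
    dimnames(s) <- list(rownames(a), rownames(b))
    return(s)
  }
  stopifnot(length(a) == length(b))
  inter <- sum(a & b); uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

#' Per-drug mean baseline
#'
#' The simplest pan-screen predictor: for each drug, the mean of its
#' training responses is the prediction for every test sample. It consumes
#' no omics data at all, so its predictions are identical under the
#' zero-filled-omics ablation by construction — the reference point against
#' which "is the model using molecular features?" is judged.
#'
#' @param train a [response_matrix()] of training samples.
#' @param test_samples character vector of test sample ids.
#' @return A list of class `prediction_result`: `predictions` (test samples
#'   x drugs matrix), `model = "mean_baseline"`. Drugs absent from the
#'   train set get `NA` predictions with a message.
#' @export
mean_baseline_fit_predict <- function(train, test_samples) {
  stopifnot(inherits(train, "response_matrix"))
  mu <- colMeans(rm_values(train), na.rm = TRUE)
  missing <- !is.finite(mu)
  if (any(missing)) {
    message("drugs with no training observations, predictions undefined: ",
            paste(colnames(train)[missing], collapse = ", "))
    mu[missing] <- NA_real_
  }
  pred <- matrix(mu, nrow = length(test_samples), ncol = ncol(train),
                 byrow = TRUE, dimnames = list(test_samples, colnames(train)))
  structure(list(predictions = pred, model = "mean_baseline"),
            class = "prediction_result")
}

#' Bimodal k-nearest-neighbour pan-drug model
#'
#' Predicts the response of a test (sample, drug) pair as the mean response
#' of its k nearest training (sample, drug) pairs in a bimodal similarity
#' space: drug-drug distance is the inversed Tanimoto similarity of the
#' fingerprints, sample-sample distance the Euclidean distance between
#' expression profiles, each normalized to [0, 1] over the involved pairs
#' and combined with weight `w` on the drug modality. With
#' `omics_mode = "zero_filled"` the expression vectors are replaced by
#' zeros, so the expression term is constant and the ranking depends on the
#' drug modality alone — for a fixed drug every test sample then receives
#' the same prediction.
#'
#' @param train a [response_matrix()] of training samples.
#' @param expr samples x genes expression matrix covering train and test
#'   samples.
#' @param fingerprints drugs x bits 0/1 matrix covering all drugs of
#'   `train`.
#' @param test_samples test sample ids (rows of `expr`).
#' @param k neighbour count (default 5).
#' @param w drug-modality weight in [0, 1] (default 0.5).
#' @param omics_mode `"real"` or `"zero_filled"`.
#' @param test_drugs drugs to predict (default: all train drugs).
#' @return A `prediction_result` with a test samples x drugs matrix.
#' @export
bimodal_knn_fit_predict <- function(train, expr, fingerprints, test_samples,
                                    k = 5, w = 0.5,
                                    omics_mode = c("real", "zero_filled"),
                                    test_drugs = colnames(train)) {
  omics_mode <- match.arg(omics_mode)
  stopifnot(inherits(train, "response_matrix"), k >= 1)
  v <- rm_values(train)
  cells <- which(!is.na(v), arr.ind = TRUE)
  if (nrow(cells) == 0) stop("empty training set")
  if (k > nrow(cells))
    stop("k = ", k, " exceeds the ", nrow(cells), " training pairs")
  miss_fp <- setdiff(union(colnames(train), test_drugs), rownames(fingerprints))
  if (length(miss_fp))
    stop("missing fingerprints for drugs: ", paste(miss_fp, collapse = ", "))
  tr_samples <- rownames(v)[cells[, 1]]
  tr_drugs <- colnames(v)[cells[, 2]]
  y <- v[cells]

  drug_dist <- 1 - tanimoto(fingerprints[test_drugs, , drop = FALSE],
                            fingerprints[unique(tr_drugs), , drop = FALSE])
  if (omics_mode == "zero_filled") {
    expr_dist <- matrix(0, length(test_samples), length(unique(tr_samples)),
                        dimnames = list(test_samples, unique(tr_samples)))
  } else {
    A <- expr[test_samples, , drop = FALSE]
    B <- expr[unique(tr_samples), , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    expr_dist <- sqrt(pmax(d2, 0))
    dimnames(expr_dist) <- list(test_samples, unique(tr_samples))
    if (max(expr_dist) > 0) expr_dist <- expr_dist / max(expr_dist)
  }
  if (max(drug_dist) > 0) drug_dist <- drug_dist / max(drug_dist)

  pred <- matrix(NA_real_, length(test_samples), length(test_drugs),
                 dimnames = list(test_samples, test_drugs))
  dd_tr <- drug_dist[, tr_drugs, drop = FALSE]   # test drugs x train pairs
  for (s in test_samples) {
    ed_tr <- expr_dist[s, tr_samples]            # train pairs
    for (d in test_drugs) {
      comb <- w * dd_tr[d, ] + (1 - w) * ed_tr
      nn <- order(comb)[seq_len(k)]              # stable: ties by pair index
      pred[s, d] <- mean(y[nn])
    }
  }
  structure(list(predictions = pred, model = "bimodal_knn",
                 k = k, w = w, omics_mode = omics_mode),
            class = "prediction_result")
}

#' Registry of single-drug regressors
#'
#' One contract over eight standard regressors trained per drug on selected
#' genes: `"ridge"` (exact penalised least squares, default `alpha = 10`),
#' `"knn"`, `"svr_linear"`, `"svr_rbf"`, `"svr_poly"`, `"decision_tree"`,
#' `"random_forest"`, `"mlp"`. Each returns a fitted object with a
#' `predict` method taking a samples x genes matrix.
#'
#' @param name regressor name.
#' @param alpha ridge penalty.
#' @param k neighbour count for `"knn"`.
#' @param ntree trees for `"random_forest"`.
#' @param seed seed for the stochastic fits (forest, mlp).
#' @return A model factory: `function(x, y)` returning the fitted model.
#' @export
single_drug_model <- function(name, alpha = 10, k = 5, ntree = 200, seed = 1) {
  fit <- switch(name,
    ridge = function(x, y) ridge_fit(x, y, alpha),
    knn = function(x, y) structure(list(x = x, y = y, k = k), class = "knn_reg"),
    svr_linear = function(x, y) e1071::svm(x, y, type = "eps-regression",
                                           kernel = "linear"),
    svr_rbf = function(x, y) e1071::svm(x, y, type = "eps-regression",
                                        kernel = "radial"),
    svr_poly = function(x, y) e1071::svm(x, y, type = "eps-regression",
                                         kernel = "polynomial", degree = 2),
    decision_tree = function(x, y) {
      d <- data.frame(y = y, x, check.names = TRUE)
      fit <- rpart::rpart(y ~ ., data = d, method = "anova")
      structure(list(fit = fit), class = "rpart_reg")
    },
    random_forest = function(x, y) {
      set.seed(seed)
      randomForest::randomForest(x, y, ntree = ntree)
    },
    mlp = function(x, y) {
      set.seed(seed)
      sc <- max(abs(y), 1)  # nnet sigmoid-free linear output benefits from scaling
      m <- nnet::nnet(x, y / sc, size = 16, linout = TRUE, maxit = 300,
                      decay = 1e-3, trace = FALSE, MaxNWts = 1e5)
      structure(list(net = m, sc = sc), class = "scaled_nnet")
    },
    stop("unknown regressor: ", name))
  fit
}

#' @export
predict.knn_reg <- function(object, newdata, ...) {
  d2 <- outer(rowSums(newdata^2), rowSums(object$x^2), "+") -
    2 * tcrossprod(newdata, object$x)
  apply(d2, 1, function(r) mean(object$y[order(r)[seq_len(object$k)]]))
}

#' @export
predict.rpart_reg <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  names(nd) <- make.names(names(nd))
  unname(stats::predict(object$fit, nd))
}

#' @export
predict.scaled_nnet <- function(object, newdata, ...) {
  as.vector(stats::predict(object$net, newdata)) * object$sc
}

# exact ridge: centered least squares with penalty alpha on the slopes,
# dual form when p > n. Matches min ||y - b0 - Xw||^2 + alpha ||w||^2.
ridge_fit <- function(x, y, alpha) {
  xb <- colMeans(x); yb <- mean(y)
  Xc <- sweep(x, 2, xb); yc <- y - yb
  p <- ncol(x); n <- nrow(x)
  w <- if (p <= n) {
    solve(crossprod(Xc) + diag(alpha, p), crossprod(Xc, yc))
  } else {
    crossprod(Xc, solve(tcrossprod(Xc) + diag(alpha, n), yc))
  }
  structure(list(w = as.vector(w), b0 = yb - sum(xb * w), genes = colnames(x)),
            class = "ridge_reg")
}

#' @export
predict.ridge_reg <- function(object, newdata, ...) {
  as.vector(newdata[, object$genes, drop = FALSE] %*% object$w) + object$b0
}

#' Fit and predict a single-drug regressor
#'
#' Trains one regressor from the registry on the expression submatrix of
#' `selected_genes` for the samples with observed training response, and
#' predicts the requested samples. Single-drug models see omics only —
#' they are blind to all other drugs.
#'
#' @param train_response named numeric vector of one drug's training
#'   responses (names = sample ids; `NA`s dropped).
#' @param expr samples x genes matrix covering train and new samples.
#' @param regressor_name a [single_drug_model()] name.
#' @param selected_genes non-empty character vector of gene ids.
#' @param new_samples sample ids to predict.
#' @param ... passed to [single_drug_model()] (e.g. `alpha`, `seed`).
#' @return Named numeric vector of predictions for `new_samples`.
#' @export
single_drug_fit_predict <- function(train_response, expr, regressor_name,
                                    selected_genes, new_samples, ...) {
  if (length(selected_genes) == 0) stop("selected_genes must be non-empty")
  tr <- names(train_response)[!is.na(train_response)]
  tr <- intersect(tr, rownames(expr))
  if (length(tr) < 10) stop("need >= 10 training samples, got ", length(tr))
  bad <- setdiff(selected_genes, colnames(expr))
  if (length(bad)) stop("genes absent from expression: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  X <- expr[tr, selected_genes, drop = FALSE]
  fit <- single_drug_model(regressor_name, ...)(X, train_response[tr])
  p <- stats::predict(fit, expr[new_samples, selected_genes, drop = FALSE])
  stats::setNames(as.vector(p), new_samples)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: model %s, %d samples x %d drugs\n",
              x$model, nrow(x$predictions), ncol(x$predictions)))
  invisible(x)
}
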