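#' Feed-forward pan-drug baseline network
#'
#' A fully connected network with three hidden layers (ReLU) and a linear
#' output unit, trained by Adam on the mean squared error. The input of a
#' training pair is the concatenation of the drug's fingerprint and the
#' sample's expression vector; with `omics_mode = "zero_filled"` the
#' expression part is replaced by zeros at train and test time. Training is
#' full-batch with early stopping on a held-out validation split and is
#' deterministic given `seed`.
#'
#' Hidden widths default to (64, 32, 16), sized for screens of a few
#' thousand training pairs; pass `hidden` for other capacities.
#'
#' @param train a [response_matrix()] of training samples.
#' @param expr samples x genes matrix covering train and test samples.
#' @param fingerprints drugs x bits 0/1 matrix.
#' @param test_samples test sample ids.
#' @param omics_mode `"real"` or `"zero_filled"`.
#' @param hidden integer vector of three hidden-layer widths.
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param val_fraction fraction of training pairs held out for early
#'   stopping.
#' @param seed RNG seed (weights, validation split).
#' @param test_drugs drugs to predict (default: all train drugs).
#' @return A `prediction_result` with a test samples x drugs matrix.
#' @export
feedforward_fit_predict <- function(train, expr, fingerprints, test_samples,
                                    omics_mode = c("real", "zero_filled"),
                                    hidden = c(64, 32, 16), epochs = 150,
                                    lr = 1e-3, patience = 15,
                                    val_fraction = 0.15, seed = 1,
                                    test_drugs = colnames(train)) {
  omics_mode <- match.arg(omics_mode)
  stopifnot(inherits(train, "response_matrix"), length(hidden) == 3)
  v <- rm_values(train)
  cells <- which(!is.na(v), arr.ind = TRUE)
  if (nrow(cells) == 0) stop("empty training set")
  ex <- expr
  if (omics_mode == "zero_filled") ex[] <- 0
  X <- cbind(fingerprints[colnames(v)[cells[, 2]], , drop = FALSE],
             ex[rownames(v)[cells[, 1]], , drop = FALSE])
  y <- v[cells]
  # standardise response for stable optimisation; undone at predict time
  my <- mean(y); sy <- max(stats::sd(y), 1e-12)

  set.seed(seed)
  n <- nrow(X)
  val <- sample.int(n, max(1, round(val_fraction * n)))
  fit <- mlp_train(X[-val, , drop = FALSE], (y[-val] - my) / sy,
                   X[val, , drop = FALSE], (y[val] - my) / sy,
                   hidden, epochs, lr, patience)
  if (!is.finite(fit$best_val))
    stop("feed-forward training diverged (non-finite loss) at epoch ", fit$epoch)

  Xte <- cbind(
    fingerprints[rep(test_drugs, each = length(test_samples)), , drop = FALSE],
    ex[rep(test_samples, length(test_drugs)), , drop = FALSE])
  p <- mlp_forward(fit$weights, Xte)$out * sy + my
  pred <- matrix(p, length(test_samples), length(test_drugs),
                 dimnames = list(test_samples, test_drugs))
  structure(list(predictions = pred, model = "feedforward_nn",
                 omics_mode = omics_mode, epochs_run = fit$epoch),
            class = "prediction_result")
}

mlp_init <- function(dims) {
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    # He initialisation for ReLU layers
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], 0,
                                  sqrt(2 / dims[l])), dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(wts, X) {
  L <- length(wts$W)
  a <- list(X)
  for (l in seq_len(L)) {
    z <- sweep(a[[l]] %*% wts$W[[l]], 2, wts$b[[l]], "+")
    a[[l + 1]] <- if (l < L) pmax(z, 0) else z
  }
  list(out = as.vector(a[[L + 1]]), acts = a)
}

mlp_train <- function(Xtr, ytr, Xval, yval, hidden, epochs, lr, patience) {
  dims <- c(ncol(Xtr), hidden, 1)
  wts <- mlp_init(dims)
  L <- length(wts$W)
  mW <- vW <- lapply(wts$W, function(w) w * 0)
  mb <- vb <- lapply(wts$b, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(weights = wts, best_val = Inf, epoch = 0)
  bad <- 0
  n <- nrow(Xtr)
  for (ep in seq_len(epochs)) {
    fw <- mlp_forward(wts, Xtr)
    delta <- matrix(2 * (fw$out - ytr) / n, ncol = 1)  # dMSE/dout
    for (l in L:1) {
      gW <- crossprod(fw$acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(wts$W[[l]])) * (fw$acts[[l]] > 0)
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      c1 <- 1 - b1^ep; c2 <- 1 - b2^ep
      wts$W[[l]] <- wts$W[[l]] - lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
      wts$b[[l]] <- wts$b[[l]] - lr * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
    }
    vloss <- mean((mlp_forward(wts, Xval)$out - yval)^2)
    if (!is.finite(vloss)) return(list(weights = wts, best_val = vloss, epoch = ep))
    if (vloss < best$best_val - 1e-6) {
      best <- list(weights = wts, best_val = vloss, epoch = ep)
      bad <- 0
    } else {
      bad <- bad + 1
      if (bad >= patience) break
    }
  }
  best
}
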