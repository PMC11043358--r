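#' Per-drug z-score transformation of a response matrix
#'
#' Standardises each drug column across all samples it was tested on:
#' \deqn{Z_{i,j} = (x_{i,j} - \bar x_i) / \sigma_i}
#' where the mean and standard deviation of drug i are taken over the
#' observed cells only. This removes each drug's overall potency level, so
#' the transformed value measures how a sample responds *relative to the
#' average sample* for that drug. Missing cells stay missing.
#'
#' By default the population standard deviation (divide by N) is used,
#' matching the convention of published screen-level z-scores where the full
#' panel is the reference population; set `sd_type = "sample"` for the N-1
#' estimator.
#'
#' Drugs observed fewer than `min_obs` times, or with zero variance, are
#' dropped with a warning naming them — never silently zeroed.
#'
#' @param x a [response_matrix()].
#' @param min_obs minimum observed values a drug needs to be transformed.
#' @param sd_type `"population"` (divide by N, default) or `"sample"`.
#' @return A `response_matrix` with measure tag `ZSCORE(<base>)`.
#' @export
zscore_by_drug <- function(x, min_obs = 3, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(x, "response_matrix"))
  v <- rm_values(x)
  n_obs <- colSums(!is.na(v))
  mu <- colMeans(v, na.rm = TRUE)
  ss <- colSums(sweep(v, 2, mu, "-")^2, na.rm = TRUE)
  denom <- if (sd_type == "population") n_obs else pmax(n_obs - 1L, 1L)
  sig <- sqrt(ss / denom)

  few <- n_obs < min_obs
  flat <- !few & (sig == 0 | !is.finite(sig))
  if (any(few))
    warning("dropping drugs with < ", min_obs, " observed values: ",
            paste(colnames(v)[few], collapse = ", "))
  if (any(flat))
    warning("dropping constant drug columns (sd = 0): ",
            paste(colnames(v)[flat], collapse = ", "))
  keep <- !few & !flat
  if (!any(keep)) stop("no drug column is transformable")

  z <- sweep(sweep(v[, keep, drop = FALSE], 2, mu[keep], "-"), 2, sig[keep], "/")
  base <- attr(x, "measure")
  # z of z keeps a single-level tag
  tag <- if (grepl("^ZSCORE\\(", base)) base else sprintf("ZSCORE(%s)", base)
  response_matrix(z, measure = tag)
}

#' Harmonize two expression datasets by double z-scoring
#'
#' Restricts both matrices to shared genes, z-scores each dataset separately
#' per gene, stacks them, then z-scores the merged matrix per gene once
#' more. The first pass removes dataset-level location/scale shifts (e.g.
#' cell lines vs organoids processed with different RNA-seq pipelines); the
#' second puts the pooled values on a common standard scale.
#'
#' @param train_expr,test_expr numeric matrices, samples x genes, with
#'   sample ids as rownames and gene ids as colnames.
#' @return A merged samples x genes matrix on the shared genes, with an
#'   attribute `origin` (factor, `"train"`/`"test"`) recording each row's
#'   provenance.
#' @export
harmonize_expression <- function(train_expr, test_expr) {
  stopifnot(is.matrix(train_expr), is.matrix(test_expr))
  shared <- intersect(colnames(train_expr), colnames(test_expr))
  if (length(shared) == 0) stop("no shared genes between the two datasets")
  a <- train_expr[, shared, drop = FALSE]
  b <- test_expr[, shared, drop = FALSE]
  const <- apply(a, 2, stats::sd) == 0 | apply(b, 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping genes constant in one dataset: ",
            paste(shared[const], collapse = ", "))
    a <- a[, !const, drop = FALSE]
    b <- b[, !const, drop = FALSE]
    if (ncol(a) == 0) stop("no non-constant shared genes")
  }
  merged <- rbind(scale(a), scale(b))
  merged <- scale(merged)
  attr(merged, "scaled:center") <- NULL
  attr(merged, "scaled:scale") <- NULL
  attr(merged, "origin") <- factor(rep(c("train", "test"), c(nrow(a), nrow(b))),
                                   levels = c("train", "test"))
  rownames(merged) <- c(rownames(train_expr), rownames(test_expr))
  merged
}

#' Validate externally supplied per-drug z-scores against recomputation
#'
#' Checks that a matrix of precomputed z-scores (e.g. shipped with a public
#' screen) matches [zscore_by_drug()] applied to the raw measure across all
#' samples, to a relative tolerance.
#'
#' @param raw a `response_matrix` of the raw measure.
#' @param external a `response_matrix` (or plain matrix) of precomputed
#'   z-scores with matching dimnames.
#' @param tol relative tolerance.
#' @param ... passed to [zscore_by_drug()].
#' @return `TRUE` invisibly if validation passes, otherwise an error naming
#'   the worst cell.
#' @export
validate_external_zscores <- function(raw, external, tol = 1e-6, ...) {
  z <- zscore_by_drug(raw, ...)
  ext <- external[rownames(z), colnames(z), drop = FALSE]
  rel <- abs(rm_values(z) - ext) / pmax(abs(rm_values(z)), 1)
  worst <- which.max(rel)
  if (isTRUE(max(rel, na.rm = TRUE) > tol)) {
    ij <- arrayInd(worst, dim(rel))
    stop(sprintf("external z-scores disagree with recomputation: sample %s, drug %s, rel. error %.3g",
                 rownames(z)[ij[1]], colnames(z)[ij[2]], max(rel, na.rm = TRUE)))
  }
  invisible(TRUE)
}
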