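#' Pairwise correlation of drug-response profiles between samples
#'
#' For every unordered pair of samples (j, k), computes the Pearson and
#' Spearman correlation of their response profiles over the drugs observed
#' in *both* samples, with the profile means taken over those shared drugs:
#' \deqn{r_{j,k} = \frac{\sum_i (x_{i,j} - \bar x_j)(x_{i,k} - \bar x_k)}
#'   {\sqrt{\sum_i (x_{i,j} - \bar x_j)^2 \sum_i (x_{i,k} - \bar x_k)^2}}}
#' Spearman replaces values by average ranks within the shared set. High
#' pairwise correlations on absolute measures (ln-IC50, AUC) indicate that
#' the response is dominated by drug identity rather than sample identity —
#' the diagnostic this package exists for.
#'
#' Pairs with fewer than `min_shared` shared drugs, or with a zero-variance
#' profile over the shared drugs, are reported with `NA` correlations and a
#' `reason`, and excluded from summaries.
#'
#' @param x a [response_matrix()] with >= 2 samples.
#' @param min_shared minimum number of shared drugs for a pair to be
#'   evaluated (default 10).
#' @param subsample optionally, the maximum number of pairs to evaluate
#'   (uniformly subsampled, reproducibly via `seed`); `NULL` = all pairs.
#' @param seed RNG seed used only when `subsample` is set.
#' @return A data.frame of class `correlation_report` with columns
#'   `sample_j`, `sample_k` (j < k in sample order), `n_shared`, `pearson`,
#'   `spearman`, `reason`; attribute `summary` holds median and quartiles of
#'   the defined pairs per method.
#' @export
pairwise_profile_correlation <- function(x, min_shared = 10,
                                         subsample = NULL, seed = 1) {
  stopifnot(inherits(x, "response_matrix"))
  v <- rm_values(x)
  m <- nrow(v)
  if (m < 2) stop("need at least 2 samples")
  pairs <- utils::combn(m, 2)
  if (!is.null(subsample) && ncol(pairs) > subsample) {
    set.seed(seed)
    pairs <- pairs[, sort(sample.int(ncol(pairs), subsample)), drop = FALSE]
  }
  np <- ncol(pairs)
  n_shared <- integer(np); pe <- sp <- rep(NA_real_, np)
  reason <- rep(NA_character_, np)
  obs <- !is.na(v)
  for (p in seq_len(np)) {
    j <- pairs[1, p]; k <- pairs[2, p]
    shared <- obs[j, ] & obs[k, ]
    ns <- sum(shared)
    n_shared[p] <- ns
    if (ns < min_shared) { reason[p] <- "too_few_shared_drugs"; next }
    a <- v[j, shared]; b <- v[k, shared]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      reason[p] <- "zero_variance_profile"; next
    }
    pe[p] <- stats::cor(a, b)
    sp[p] <- stats::cor(rank(a), rank(b))
  }
  out <- data.frame(sample_j = rownames(v)[pairs[1, ]],
                    sample_k = rownames(v)[pairs[2, ]],
                    n_shared = n_shared, pearson = pe, spearman = sp,
                    reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("correlation_report", "data.frame")
  attr(out, "summary") <- correlation_summary(out)
  attr(out, "measure") <- attr(x, "measure")
  out
}

correlation_summary <- function(report) {
  qs <- function(z) {
    z <- z[!is.na(z)]
    if (!length(z)) return(c(q1 = NA_real_, median = NA_real_, q3 = NA_real_, n = 0))
    c(q1 = unname(stats::quantile(z, 0.25)), median = stats::median(z),
      q3 = unname(stats::quantile(z, 0.75)), n = length(z))
  }
  rbind(pearson = qs(report$pearson), spearman = qs(report$spearman))
}

#' @export
print.correlation_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("correlation_report: %d pairs (%d defined), measure = %s\n",
              nrow(x), sum(!is.na(x$pearson)), attr(x, "measure")))
  print(round(s, 4))
  invisible(x)
}

#' Stratify pairwise correlations by sample subtype
#'
#' Splits the pairs of a correlation report into within-subtype and
#' between-subtype groups (or the full subtype-pair grid) and summarises
#' each, to check that high profile correlations are not a between-subtype
#' artefact but hold locally within subtypes too.
#'
#' @param report a [pairwise_profile_correlation()] result.
#' @param annotation a data.frame with columns `sample_id`, `subtype`.
#' @param by `"within_vs_between"` (default) or `"subtype_pair"`.
#' @return A data.frame of per-stratum summaries (median/quartiles of
#'   Pearson and Spearman, pair count); attribute `pairs` maps each pair to
#'   its stratum.
#' @export
stratify_correlations <- function(report, annotation,
                                  by = c("within_vs_between", "subtype_pair")) {
  by <- match.arg(by)
  stopifnot(inherits(report, "correlation_report"))
  if (is.null(annotation) || nrow(annotation) == 0) stop("empty annotation")
  lab <- stats::setNames(annotation$subtype, annotation$sample_id)
  sj <- lab[report$sample_j]; sk <- lab[report$sample_k]
  known <- !is.na(sj) & !is.na(sk)
  if (!any(known)) stop("annotation covers none of the report's samples")
  if (length(unique(stats::na.omit(c(sj, sk)))) < 2)
    warning("all annotated samples share one subtype; within-subtype summaries only")
  stratum <- ifelse(sj == sk, "within", "between")
  if (by == "subtype_pair")
    stratum <- paste(pmin(sj, sk), pmax(sj, sk), sep = ":")
  stratum[!known] <- NA
  res <- do.call(rbind, lapply(sort(unique(stats::na.omit(stratum))), function(s) {
    sel <- !is.na(stratum) & stratum == s
    sm <- correlation_summary(report[sel, , drop = FALSE])
    data.frame(stratum = s, n_pairs = sum(sel),
               pearson_median = sm["pearson", "median"],
               pearson_q1 = sm["pearson", "q1"], pearson_q3 = sm["pearson", "q3"],
               spearman_median = sm["spearman", "median"],
               stringsAsFactors = FALSE)
  }))
  attr(res, "pairs") <- stratum
  res
}

#' Profile correlations restricted to one drug pathway
#'
#' Recomputes [pairwise_profile_correlation()] using only the drugs carrying
#' a given target-pathway label, to check the diagnostic is robust across
#' pharmacological classes.
#'
#' @param x a [response_matrix()].
#' @param annotation a data.frame with columns `drug_id`, `pathway`.
#' @param pathway pathway label to restrict to.
#' @param ... passed to [pairwise_profile_correlation()].
#' @return A `correlation_report` over the restricted drug set.
#' @export
pathway_restricted_correlation <- function(x, annotation, pathway, ...) {
  stopifnot(inherits(x, "response_matrix"))
  if (!pathway %in% annotation$pathway)
    stop("unknown pathway: ", pathway)
  drugs <- annotation$drug_id[annotation$pathway == pathway]
  drugs <- intersect(colnames(x), drugs)
  if (!length(drugs)) stop("no drug of pathway ", pathway, " is in the matrix")
  sub <- response_matrix(rm_values(x)[, drugs, drop = FALSE],
                         measure = attr(x, "measure"))
  pairwise_profile_correlation(sub, ...)
}
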