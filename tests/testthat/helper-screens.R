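# small screens shared across tests; cached per session so repeated
# test files do not refit curves
tiny_screen <- local({
  cache <- new.env()
  function(seed = 11, ...) {
    key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_screen(
        screen_config(n_samples = 20, n_drugs = 12, n_genes = 60, seed = seed, ...))
    cache[[key]]
  }
})

# a ready response matrix + bundle for model tests
tiny_bundle <- local({
  cache <- new.env()
  function(seed = 11, ...) {
    key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
    if (is.null(cache[[key]])) {
      sc <- tiny_screen(seed, ...)
      cache[[key]] <- list(response = curves_to_matrix(sc$dose_response),
                           expression = sc$expression,
                           fingerprints = sc$fingerprints,
                           screen = sc)
    }
    cache[[key]]
  }
})

# plain numeric matrix from a response_matrix
rm_values_test <- function(x) {
  y <- unclass(x)
  attr(y, "measure") <- NULL
  y
}

# brute-force textbook Pearson/Spearman over shared drugs (oracle)
oracle_pair_cor <- function(v, j, k) {
  shared <- !is.na(v[j, ]) & !is.na(v[k, ])
  a <- v[j, shared]; b <- v[k, shared]
  am <- a - mean(a); bm <- b - mean(b)
  pe <- sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  ra <- rank(a); rb <- rank(b)
  ram <- ra - mean(ra); rbm <- rb - mean(rb)
  sp <- sum(ram * rbm) / sqrt(sum(ram^2) * sum(rbm^2))
  c(pearson = pe, spearman = sp, n = sum(shared))
}

# brute-force ranking metric references (enumeration, no shortcuts)
oracle_precision_at_k <- function(tv, pv, k) {
  ids <- names(tv)
  tt <- ids[order(tv, ids)][1:k]
  tp <- ids[order(pv, ids)][1:k]
  sum(tp %in% tt) / k
}
oracle_ndcg_at_k <- function(tv, pv, k) {
  ids <- names(tv)
  rel <- (max(tv) - tv) / (max(tv) - min(tv))
  ord <- ids[order(pv, ids)]
  dcg <- 0; idcg <- 0
  srel <- sort(rel, decreasing = TRUE)
  for (i in 1:k) {
    dcg <- dcg + rel[ord[i]] / log2(i + 1)
    idcg <- idcg + srel[i] / log2(i + 1)
  }
  unname(dcg / idcg)
}
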