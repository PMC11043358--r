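#' Configuration of a synthetic pharmacogenomic screen
#'
#' Defines the generative model of [generate_screen()]. The planted
#' log-IC50 of drug i in sample j is
#' \deqn{\ln IC50_{j,i} = \mu_i + s_j + \sum_g w_{i,g}\, e_{j,g}}
#' where `mu_i` is the drug's mean log-potency (sd `drug_potency_sd`), `s_j`
#' a per-sample general-sensitivity factor (sd `sample_factor_sd`, capturing
#' multi-drug resistance / general sensitivity), and the last term a small
#' gene-driven effect of `causal_genes_per_drug` causal genes with weights of
#' magnitude ~`genetic_effect_sd`. On top of this, samples of one subtype
#' share a per-(subtype, drug) response shift (sd `subtype_shift_sd`) that
#' models common subtype biology and gives within-subtype pairs correlated
#' profiles even after per-drug z-scoring. Viability follows a two-parameter
#' log-logistic (Hill) curve around the planted IC50 plus Gaussian assay
#' noise, truncated to [0, 1.2]. Each sample is screened on only a random
#' subset of drugs (mean fraction `coverage_fraction`, spread `coverage_sd`),
#' so two samples share about `coverage_fraction^2` of drugs, mirroring the
#' partial drug overlap of public screens.
#'
#' @param n_samples,n_drugs,n_genes screen dimensions.
#' @param causal_genes_per_drug number of causal genes planted per drug.
#' @param drug_potency_sd sd of per-drug mean log-potency (log-concentration
#'   units); this between-drug spread drives the high raw profile
#'   correlations.
#' @param sample_factor_sd sd of the per-sample general-sensitivity factor.
#' @param genetic_effect_sd scale of per-gene causal effect sizes.
#' @param noise_sd residual assay noise sd on viability.
#' @param hill_slope Hill coefficient h > 0.
#' @param dose_grid ascending positive concentrations (uM) shared by all
#'   drugs, or `NULL` (default) for drug-adaptive grids of `n_doses` points
#'   spanning `dose_decades` decades either side of each drug's typical
#'   IC50, as real screens calibrate concentration ranges per compound.
#' @param dose_decades half-width of the adaptive dose window (decades).
#' @param n_doses points per adaptive dose grid.
#' @param coverage_fraction mean fraction of drugs measured per sample.
#' @param coverage_sd its spread across samples.
#' @param n_subtypes number of sample subtype labels (round-robin).
#' @param subtype_shift_sd sd of the shared per-(subtype, drug) response
#'   shift (makes within-subtype correlation structure).
#' @param n_pathways number of drug target-pathway labels (round-robin).
#' @param fingerprint_bits length of the synthetic binary fingerprints.
#' @param seed integer RNG seed.
#' @return A validated `screen_config` list.
#' @export
screen_config <- function(n_samples = 50, n_drugs = 30, n_genes = 500,
                          causal_genes_per_drug = 5,
                          drug_potency_sd = 2.0, sample_factor_sd = 0.5,
                          genetic_effect_sd = 0.2, noise_sd = 0.05,
                          hill_slope = 1, dose_grid = NULL,
                          dose_decades = 2, n_doses = 9,
                          coverage_fraction = 0.9, coverage_sd = 0.08,
                          n_subtypes = 5, subtype_shift_sd = 0.25,
                          n_pathways = 6, fingerprint_bits = 256,
                          seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_samples >= 1, n_drugs >= 1, n_genes >= 1,
              causal_genes_per_drug >= 0, causal_genes_per_drug <= n_genes,
              drug_potency_sd >= 0, sample_factor_sd >= 0,
              genetic_effect_sd >= 0, noise_sd >= 0, coverage_sd >= 0,
              subtype_shift_sd >= 0, hill_slope > 0,
              coverage_fraction > 0, coverage_fraction <= 1,
              n_subtypes >= 1, n_pathways >= 1, fingerprint_bits >= 8,
              dose_decades > 0, n_doses >= 3)
    if (!is.null(dose_grid)) {
      stopifnot(all(dose_grid > 0), !is.unsorted(dose_grid, strictly = TRUE),
                length(dose_grid) >= 3)
    }
  })
  structure(cfg, class = "screen_config")
}

# sample-specific coverage probabilities from a Beta matched by moments
coverage_probs <- function(n, mean, sd) {
  if (sd == 0 || mean >= 1) return(rep(mean, n))
  v <- min(sd^2, mean * (1 - mean) * 0.95)  # keep Beta parameters valid
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

#' Generate a synthetic pharmacogenomic screen
#'
#' Draws a full screen under the model described in [screen_config()]:
#' a standard-normal expression matrix, a long-format dose-response
#' viability table, per-drug binary fingerprints (drugs sharing a pathway
#' label share a bit-block), subtype/pathway annotations, and the planted
#' ground truth. Fully reproducible from `config$seed`.
#'
#' `drug_params` (the `truth` element of a previous screen) reuses that
#' screen's drug-side structure — mean potencies, causal genes and weights,
#' fingerprints, pathway labels — with fresh samples, which is how paired
#' train/transfer screens sharing drug potency structure are built.
#'
#' @param config a [screen_config()].
#' @param drug_params optional `truth` of a previous screen to reuse.
#' @return A list of class `synthetic_screen`: `expression` (samples x
#'   genes), `dose_response` (long-format data.frame: sample_id, drug_id,
#'   concentration_uM, viability), `fingerprints` (drugs x bits 0/1 matrix),
#'   `annotation` (list: `samples` data.frame sample_id/subtype, `drugs`
#'   data.frame drug_id/pathway), `truth` (mu_drug, sample_factor,
#'   causal_genes, causal_weights, true_log_ic50, fingerprints, pathways,
#'   dose_grids), and `config`.
#' @export
generate_screen <- function(config, drug_params = NULL) {
  stopifnot(inherits(config, "screen_config"))
  cf <- config
  set.seed(cf$seed)

  sample_ids <- sprintf("S%03d", seq_len(cf$n_samples))
  drug_ids <- sprintf("D%03d", seq_len(cf$n_drugs))
  gene_ids <- sprintf("G%04d", seq_len(cf$n_genes))

  expr <- matrix(stats::rnorm(cf$n_samples * cf$n_genes), cf$n_samples,
                 dimnames = list(sample_ids, gene_ids))

  subtype <- factor(sprintf("T%02d", (seq_len(cf$n_samples) - 1) %% cf$n_subtypes + 1))

  if (is.null(drug_params)) {
    mu_drug <- stats::rnorm(cf$n_drugs, 0, cf$drug_potency_sd)
    names(mu_drug) <- drug_ids
    pathway <- factor(sprintf("P%02d", (seq_len(cf$n_drugs) - 1) %% cf$n_pathways + 1))
    causal_genes <- lapply(drug_ids, function(d)
      sort(sample(gene_ids, cf$causal_genes_per_drug)))
    names(causal_genes) <- drug_ids
    causal_weights <- lapply(drug_ids, function(d) {
      w <- cf$genetic_effect_sd * stats::runif(cf$causal_genes_per_drug, 0.85, 1.15) *
        sample(c(-1, 1), cf$causal_genes_per_drug, replace = TRUE)
      names(w) <- causal_genes[[d]]
      w
    })
    names(causal_weights) <- drug_ids
    fp <- synthetic_fingerprints(drug_ids, pathway, cf$fingerprint_bits)
  } else {
    mu_drug <- drug_params$mu_drug
    drug_ids <- names(mu_drug)
    if (length(drug_ids) != cf$n_drugs)
      stop("drug_params carry ", length(drug_ids), " drugs but config asks for ", cf$n_drugs)
    pathway <- drug_params$pathways
    causal_genes <- drug_params$causal_genes
    causal_weights <- drug_params$causal_weights
    fp <- drug_params$fingerprints
    if (!all(unlist(causal_genes) %in% gene_ids))
      stop("drug_params causal genes are not covered by config n_genes")
  }

  sample_factor <- stats::rnorm(cf$n_samples, 0, cf$sample_factor_sd)
  names(sample_factor) <- sample_ids
  # shared subtype biology: a per-(subtype, drug) response shift, so samples
  # of one subtype correlate over drugs even after per-drug z-scoring
  # (a per-sample constant could not do this: profile correlation is
  # invariant to it)
  subtype_profile <- matrix(stats::rnorm(cf$n_subtypes * cf$n_drugs, 0,
                                         cf$subtype_shift_sd),
                            cf$n_subtypes, cf$n_drugs,
                            dimnames = list(levels(subtype), drug_ids))
  subtype_effect <- subtype_profile[as.integer(subtype), , drop = FALSE]
  rownames(subtype_effect) <- sample_ids

  genetic <- matrix(0, cf$n_samples, cf$n_drugs, dimnames = list(sample_ids, drug_ids))
  for (d in drug_ids) {
    if (length(causal_weights[[d]]))
      genetic[, d] <- expr[, names(causal_weights[[d]]), drop = FALSE] %*%
        causal_weights[[d]]
  }
  true_log_ic50 <- outer(sample_factor, mu_drug, "+") + subtype_effect + genetic

  # per-drug dose grids: adaptive around exp(mu_i) unless a shared grid given
  dose_grids <- if (is.null(cf$dose_grid)) {
    lapply(drug_ids, function(d)
      exp(mu_drug[[d]]) * 10^seq(-cf$dose_decades, cf$dose_decades,
                                 length.out = cf$n_doses))
  } else {
    rep(list(cf$dose_grid), cf$n_drugs)
  }
  names(dose_grids) <- drug_ids
  if (!is.null(cf$dose_grid) &&
      (any(true_log_ic50 < log(min(cf$dose_grid))) ||
       any(true_log_ic50 > log(max(cf$dose_grid)))))
    warning("some planted IC50 values fall outside the shared dose grid; ",
            "their fits will be extrapolated")

  p_cov <- coverage_probs(cf$n_samples, cf$coverage_fraction, cf$coverage_sd)
  observed <- matrix(stats::runif(cf$n_samples * cf$n_drugs) < p_cov,
                     cf$n_samples, cf$n_drugs, dimnames = list(sample_ids, drug_ids))
  # every sample keeps at least one drug so it stays in the screen
  none <- rowSums(observed) == 0
  observed[cbind(which(none), sample.int(cf$n_drugs, sum(none), replace = TRUE))] <- TRUE

  cells <- which(observed, arr.ind = TRUE)
  n_dose <- lengths(dose_grids)[1]
  long <- data.frame(
    sample_id = rep(sample_ids[cells[, 1]], each = n_dose),
    drug_id = rep(drug_ids[cells[, 2]], each = n_dose),
    concentration_uM = unlist(dose_grids[cells[, 2]], use.names = FALSE),
    stringsAsFactors = FALSE)
  lnic <- rep(true_log_ic50[cells], each = n_dose)
  viab <- 1 / (1 + exp(cf$hill_slope * (log(long$concentration_uM) - lnic)))
  if (cf$noise_sd > 0) viab <- viab + stats::rnorm(length(viab), 0, cf$noise_sd)
  long$viability <- pmin(pmax(viab, 0), 1.2)

  structure(list(
    expression = expr,
    dose_response = long,
    fingerprints = fp,
    annotation = list(
      samples = data.frame(sample_id = sample_ids, subtype = as.character(subtype),
                           stringsAsFactors = FALSE),
      drugs = data.frame(drug_id = drug_ids, pathway = as.character(pathway),
                         stringsAsFactors = FALSE)),
    truth = list(mu_drug = mu_drug, sample_factor = sample_factor,
                 subtype_effect = subtype_effect,
                 causal_genes = causal_genes, causal_weights = causal_weights,
                 true_log_ic50 = true_log_ic50, fingerprints = fp,
                 pathways = pathway, dose_grids = dose_grids),
    config = cf), class = "synthetic_screen")
}

#' Study configuration with a strong planted gene signal
#'
#' The screen configuration used to study drug-specific gene selection: 200
#' samples, 1000 genes of which 20 are causal per drug, and a per-gene
#' effect size (0.7 log-units) chosen so the total gene-driven IC50 spread
#' (sd ~3.1 natural-log units) stays within the 6-decade adaptive dose
#' window — effects any larger would push IC50s outside the measurable
#' range and censor the very cells that carry the signal.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [screen_config()].
#' @return A `screen_config`.
#' @export
planted_signal_config <- function(seed = 1, ...) {
  screen_config(n_samples = 200, n_drugs = 3, n_genes = 1000,
                causal_genes_per_drug = 20, genetic_effect_sd = 0.7,
                coverage_fraction = 1, dose_decades = 3, seed = seed, ...)
}

# drugs sharing a pathway share a dedicated bit-block; the rest is sparse
# per-drug structure. Returns a drugs x bits 0/1 integer matrix.
synthetic_fingerprints <- function(drug_ids, pathway, n_bits) {
  n <- length(drug_ids)
  levs <- levels(pathway)
  block <- max(8L, n_bits %/% (2L * length(levs)))
  fp <- matrix(0L, n, n_bits, dimnames = list(drug_ids, NULL))
  for (p in seq_along(levs)) {
    lo <- (p - 1L) * block + 1L
    idx <- lo:min(lo + block - 1L, n_bits)
    bits <- idx[stats::runif(length(idx)) < 0.6]
    fp[pathway == levs[p], bits] <- 1L
  }
  free <- (length(levs) * block + 1L):n_bits
  for (i in seq_len(n)) {
    fp[i, free[stats::runif(length(free)) < 0.25]] <- 1L
    if (sum(fp[i, ]) == 0) fp[i, sample(n_bits, 4)] <- 1L
  }
  # guarantee distinct fingerprints per drug (flip a private bit on clash)
  repeat {
    i <- anyDuplicated(apply(fp, 1, paste, collapse = ""))
    if (i == 0L) break
    j <- sample(free, 1)
    fp[i, j] <- 1L - fp[i, j]
  }
  fp
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat(sprintf("synthetic_screen: %d samples x %d drugs, %d genes, %d viability rows\n",
              nrow(x$expression), nrow(x$fingerprints), ncol(x$expression),
              nrow(x$dose_response)))
  invisible(x)
}
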