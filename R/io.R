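#' Read / write a response matrix CSV
#'
#' The on-disk dialect is a wide CSV: first column `sample_id`, remaining
#' columns drug ids, empty cell = missing. Numbers are written with R's
#' shortest round-trippable representation, so write -> read -> write is
#' byte-identical.
#'
#' @param path file path.
#' @param measure measure tag attached on read.
#' @return [read_response_matrix()]: a [response_matrix()].
#' @export
read_response_matrix <- function(path, measure = "LN_IC50") {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "sample_id") stop("first column must be sample_id")
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample id: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  if (anyDuplicated(names(d)[-1]))
    stop("duplicate drug id: ",
         paste(unique(names(d)[-1][duplicated(names(d)[-1])]), collapse = ", "))
  vals <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!is.na(vals) & is.na(suppressWarnings(
      matrix(as.numeric(vals), nrow(vals)))), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at sample %s, drug %s",
                 d$sample_id[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  rownames(vals) <- d$sample_id
  response_matrix(vals, measure = measure)
}

# shortest decimal representation of each double that parses back exactly
format_dbl <- function(x) {
  out <- sprintf("%.15g", x)
  for (dg in c("%.16g", "%.17g")) {
    miss <- as.numeric(out) != x
    if (!any(miss)) break
    out[miss] <- sprintf(dg, x[miss])
  }
  out
}

#' @rdname read_response_matrix
#' @param x a [response_matrix()].
#' @export
write_response_matrix <- function(x, path) {
  stopifnot(inherits(x, "response_matrix"))
  v <- rm_values(x)
  ch <- matrix("", nrow(v), ncol(v))
  ch[!is.na(v)] <- format_dbl(v[!is.na(v)])
  d <- data.frame(sample_id = rownames(v), ch, stringsAsFactors = FALSE,
                  check.names = FALSE)
  names(d) <- c("sample_id", colnames(v))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an expression TSV
#'
#' Wide TSV: first column `sample_id`, remaining columns gene ids.
#' @param path file path.
#' @return A samples x genes numeric matrix.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "sample_id") stop("first column must be sample_id")
  if (anyDuplicated(d$sample_id)) stop("duplicate sample ids in expression file")
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- d$sample_id
  m
}

#' @rdname read_expression
#' @param expr samples x genes matrix.
#' @export
write_expression <- function(expr, path) {
  ch <- matrix(format_dbl(expr), nrow(expr), dimnames = dimnames(expr))
  d <- data.frame(sample_id = rownames(expr), ch, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write fingerprint TSVs
#'
#' Two-column TSV `drug_id`, `bits` where `bits` is a 0/1 string; all
#' bitstrings must have equal length and contain only 0/1.
#' @param path file path.
#' @return drugs x bits 0/1 integer matrix.
#' @export
read_fingerprints <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  if (!all(c("drug_id", "bits") %in% names(d)))
    stop("fingerprint TSV needs columns drug_id, bits")
  if (anyDuplicated(d$drug_id)) stop("duplicate drug ids in fingerprint file")
  if (length(unique(nchar(d$bits))) > 1)
    stop("fingerprint length mismatch: lengths ",
         paste(sort(unique(nchar(d$bits))), collapse = ", "))
  if (any(grepl("[^01]", d$bits)))
    stop("fingerprint bitstrings may contain only 0 and 1")
  m <- t(vapply(strsplit(d$bits, ""), function(b) as.integer(b),
                integer(nchar(d$bits[1]))))
  rownames(m) <- d$drug_id
  m
}

#' @rdname read_fingerprints
#' @param fp drugs x bits matrix.
#' @export
write_fingerprints <- function(fp, path) {
  d <- data.frame(drug_id = rownames(fp),
                  bits = apply(fp, 1, paste, collapse = ""),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SMILES TSV
#'
#' Two-column TSV `drug_id`, `smiles`.
#' @param path file path.
#' @return data.frame with columns `drug_id`, `smiles`.
#' @export
read_smiles <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  if (!all(c("drug_id", "smiles") %in% names(d)))
    stop("SMILES TSV needs columns drug_id, smiles")
  if (anyDuplicated(d$drug_id)) stop("duplicate drug ids in SMILES file")
  d
}

#' Read an annotation TSV against a set of known ids
#'
#' Two-column TSV (id column first, label second). Rows whose id is not in
#' `known_ids` are skipped with a warning.
#' @param path file path.
#' @param known_ids valid ids; `NULL` skips validation.
#' @return data.frame with the file's two columns.
#' @export
read_annotations <- function(path, known_ids = NULL) {
  d <- utils::read.delim(path, colClasses = "character")
  if (ncol(d) < 2) stop("annotation TSV needs an id and a label column")
  if (!is.null(known_ids)) {
    unknown <- !(d[[1]] %in% known_ids)
    if (any(unknown)) {
      warning("skipping annotation rows with unknown ids: ",
              paste(d[[1]][unknown], collapse = ", "))
      d <- d[!unknown, , drop = FALSE]
    }
  }
  d
}

#' Read the long-format dose-response TSV
#'
#' Columns `sample_id`, `drug_id`, `concentration_uM`, `viability`.
#' @param path file path.
#' @return data.frame in long format.
#' @export
read_dose_response <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "drug_id", "concentration_uM", "viability")
  if (!all(need %in% names(d)))
    stop("dose-response TSV needs columns: ", paste(need, collapse = ", "))
  d
}

#' @rdname read_dose_response
#' @param d long-format dose-response data.frame.
#' @export
write_dose_response <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic screen to a directory
#'
#' Emits the screen's on-disk artefacts: `dose_response.tsv`,
#' `expression.tsv`, `fingerprints.tsv`, `samples.tsv`, `drugs.tsv` and the
#' planted ground truth as `truth.json`.
#' @param screen a [generate_screen()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(screen, dir) {
  stopifnot(inherits(screen, "synthetic_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dose_response(screen$dose_response, file.path(dir, "dose_response.tsv"))
  write_expression(screen$expression, file.path(dir, "expression.tsv"))
  write_fingerprints(screen$fingerprints, file.path(dir, "fingerprints.tsv"))
  utils::write.table(screen$annotation$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(screen$annotation$drugs, file.path(dir, "drugs.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- screen$truth
  truth$true_log_ic50 <- as.data.frame(truth$true_log_ic50)
  truth$fingerprints <- NULL
  truth$dose_grids <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Run the analysis pipeline end to end
#'
#' Executes, on a synthetic screen: simulate -> derive measures -> profile
#' correlations (raw and z-scored) -> the model setting matrix -> reports.
#' Any subset of stages can be selected; later stages re-derive what they
#' need. All outputs land under `out_dir`, a provenance JSON records the
#' configuration and seeds, and inputs on disk are never mutated.
#'
#' @param config list with elements `screen` (a [screen_config()]),
#'   `stages` (subset of `c("simulate", "measures", "correlate", "models")`),
#'   `measure` (curve summary for the response matrix, default
#'   `"LN_IC50"`), `models`, `n_folds`, `k`, `min_shared`, `seed`.
#' @param out_dir output directory.
#' @return Invisible list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stages <- config$stages %||% c("simulate", "measures", "correlate", "models")
  measure <- config$measure %||% "LN_IC50"
  seed <- config$seed %||% 1
  if (is.null(config$screen)) stop("config$screen (a screen_config) is required")
  if (!is.null(config$inputs)) {
    absent <- unlist(config$inputs)[!file.exists(unlist(config$inputs))]
    if (length(absent))
      stop("input path(s) do not exist: ", paste(absent, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  res <- list()
  screen <- generate_screen(config$screen)
  if ("simulate" %in% stages) write_screen(screen, file.path(out_dir, "screen"))
  res$screen <- screen

  rm_raw <- curves_to_matrix(screen$dose_response, measure = measure)
  res$response <- rm_raw
  if ("measures" %in% stages) {
    write_response_matrix(rm_raw, file.path(out_dir, "response_raw.csv"))
    res$response_z <- zscore_by_drug(rm_raw)
    write_response_matrix(res$response_z, file.path(out_dir, "response_zscored.csv"))
  }
  if ("correlate" %in% stages) {
    min_shared <- config$min_shared %||% 10
    rep_raw <- pairwise_profile_correlation(rm_raw, min_shared = min_shared)
    rep_z <- pairwise_profile_correlation(zscore_by_drug(rm_raw),
                                          min_shared = min_shared)
    utils::write.table(rep_raw, file.path(out_dir, "correlations_raw.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(rep_z, file.path(out_dir, "correlations_zscored.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(raw = as.data.frame(attr(rep_raw, "summary")),
           zscored = as.data.frame(attr(rep_z, "summary"))),
      file.path(out_dir, "correlation_summary.json"), digits = NA)
    res$correlations <- list(raw = rep_raw, zscored = rep_z)
  }
  if ("models" %in% stages) {
    bundle <- list(response = rm_raw, expression = screen$expression,
                   fingerprints = screen$fingerprints)
    report <- run_setting_matrix(bundle,
                                 models = config$models %||% c("mean_baseline", "bimodal_knn"),
                                 n_folds = config$n_folds %||% 5,
                                 k = config$k %||% 5, seed = seed)
    utils::write.table(report, file.path(out_dir, "evaluation_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(aggregate_report(report),
                       file.path(out_dir, "evaluation_aggregate.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    res$report <- report
  }
  prov <- list(
    package_version = as.character(utils::packageVersion("pharmsense")),
    r_version = R.version.string,
    seed = seed, screen_seed = config$screen$seed,
    measure = measure, stages = stages,
    screen_config = unclass(config$screen),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
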