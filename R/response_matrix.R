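#' Response matrix container
#'
#' A samples x drugs matrix of one drug-response measure with an explicit
#' missing-value convention (`NA` = not screened). Rows are samples (cell
#' lines, organoids), columns are drugs. The measure tag records which
#' summary the values are (`"LN_IC50"`, `"AUC"`, `"AUC_NORM"`, `"DRS"` or a
#' per-drug z-score thereof, `"ZSCORE(<base>)"`). All shipped measures share
#' the same orientation: lower value = more sensitive sample.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   drugs in columns (colnames = drug ids); `NA` marks missing cells.
#' @param measure character measure tag.
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(values, measure = "LN_IC50") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (length(values) && (is.null(rownames(values)) || is.null(colnames(values))))
    stop("`values` must have sample ids as rownames and drug ids as colnames")
  if (is.null(dimnames(values)) && all(dim(values) == 0))
    dimnames(values) <- list(character(0), character(0))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate drug ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  structure(values, measure = measure, class = c("response_matrix", "matrix", "array"))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d samples x %d drugs, measure = %s, %d/%d cells observed\n",
              nrow(x), ncol(x), attr(x, "measure"), sum(!is.na(x)), length(x)))
  invisible(x)
}

#' Measure tag of a response matrix
#' @param x a `response_matrix`.
#' @return The measure tag string.
#' @export
measure_of <- function(x) attr(x, "measure")

#' Is the measure oriented lower-is-more-sensitive?
#'
#' True for every measure the package ships (ln-IC50, AUC, normalized AUC,
#' drug relevance score, and their per-drug z-scores): a smaller value always
#' means the drug was more effective in that sample.
#' @param measure measure tag string.
#' @return logical.
#' @export
lower_is_more_sensitive <- function(measure) {
  TRUE
}

# strip the class but keep dimnames; internal
rm_values <- function(x) {
  y <- unclass(x)
  attr(y, "measure") <- NULL
  y
}

as_response_matrix <- function(values, like) {
  response_matrix(values, measure = attr(like, "measure"))
}
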