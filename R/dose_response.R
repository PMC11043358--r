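#' Dose-response curve for one (sample, drug) pair
#'
#' Viability fractions over an ascending concentration grid; the raw unit
#' of screening data. Viability is expected in roughly [0, 1.2] (screens
#' routinely report mild over-growth above 100%).
#'
#' @param sample_id,drug_id identifiers.
#' @param concentrations strictly increasing positive concentrations (uM).
#' @param viability viability fractions, same length.
#' @return An object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(sample_id, drug_id, concentrations, viability) {
  if (length(concentrations) != length(viability))
    stop("concentrations and viability must have the same length")
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop("concentrations must be positive and finite")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  structure(list(sample_id = sample_id, drug_id = drug_id,
                 concentrations = as.numeric(concentrations),
                 viability = as.numeric(viability)),
            class = "dose_response_curve")
}

# two-parameter log-logistic (Hill) viability: upper asymptote 1, lower 0
# par = c(b = ln IC50, lh = log hill slope); lc = ln concentration
hill_viability <- function(lc, b, h) 1 / (1 + exp(h * (lc - b)))

hill_rss <- function(par, lc, v) {
  r <- v - hill_viability(lc, par[1], exp(par[2]))
  sum(r * r)
}

hill_grad <- function(par, lc, v) {
  h <- exp(par[2])
  e <- exp(h * (lc - par[1]))
  f <- 1 / (1 + e)
  r <- v - f
  dfdb <- e * f^2 * h
  dfdlh <- -e * f^2 * (lc - par[1]) * h
  c(-2 * sum(r * dfdb), -2 * sum(r * dfdlh))
}

#' Fit ln-IC50 by a two-parameter log-logistic least-squares fit
#'
#' Fits viability = 1 / (1 + (c / IC50)^h) (upper asymptote 1, lower 0) to a
#' dose-response curve by least squares and returns the natural log of the
#' concentration at 50% viability. Optimisation uses a heuristic start from
#' a logit-linear regression plus a multi-start grid of five initial ln-IC50
#' values spanning the tested range, each refined by BFGS with an analytic
#' gradient; the best final fit wins.
#'
#' Viability is clipped to [0, 1.2] before fitting. When the fitted IC50
#' lies outside the tested concentration range (e.g. a flat, fully resistant
#' curve) the result carries `extrapolated = TRUE` rather than an `NA`.
#'
#' @param curve a [dose_response_curve()], or a numeric vector of
#'   concentrations when `viability` is supplied separately.
#' @param viability optional viability vector (vector interface).
#' @return A list with `ln_ic50` (log uM), `hill` (slope h > 0), `rss`
#'   (residual sum of squares) and `extrapolated` (logical).
#' @export
fit_ic50 <- function(curve, viability = NULL) {
  if (inherits(curve, "dose_response_curve")) {
    conc <- curve$concentrations; v <- curve$viability
  } else {
    conc <- as.numeric(curve); v <- as.numeric(viability)
  }
  if (length(conc) < 3) stop("at least 3 doses are required to fit an IC50")
  if (length(conc) != length(v)) stop("concentration/viability length mismatch")
  if (any(!is.finite(v))) stop("non-finite viability values")
  if (any(conc <= 0) || is.unsorted(conc, strictly = TRUE))
    stop("concentrations must be positive and strictly increasing")
  v <- pmin(pmax(v, 0), 1.2)
  lc <- log(conc)

  # heuristic start: logit-linear regression on clipped viability
  v2 <- pmin(pmax(v, 0.005), 0.995)
  cf <- stats::lm.fit(cbind(1, lc), log(v2 / (1 - v2)))$coefficients
  h0 <- max(-cf[2], 0.05)
  starts <- rbind(c(cf[1] / h0, log(h0)),
                  cbind(seq(min(lc), max(lc), length.out = 5), 0))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      stats::optim(starts[i, ], hill_rss, hill_grad, lc = lc, v = v,
                   method = "BFGS", control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("IC50 fit failed to converge from any start")
  b <- unname(best$par[1])
  list(ln_ic50 = b,
       hill = unname(exp(best$par[2])),
       rss = best$value,
       extrapolated = b < min(lc) || b > max(lc))
}

#' Area under the dose-response curve
#'
#' Trapezoidal integral of viability over log10(concentration), and the
#' normalized AUC: the integral divided by the maximum possible area for the
#' tested concentration range (log10 span x full viability 1). Full survival
#' gives normalized AUC 1, full kill gives 0; lower = more sensitive.
#'
#' @inheritParams fit_ic50
#' @return A list with `auc` (log10-concentration units) and `auc_norm`
#'   (unitless, in [0, ~1.2]).
#' @export
compute_auc <- function(curve, viability = NULL) {
  if (inherits(curve, "dose_response_curve")) {
    conc <- curve$concentrations; v <- curve$viability
  } else {
    conc <- as.numeric(curve); v <- as.numeric(viability)
  }
  if (length(conc) < 2) stop("at least 2 doses are required for an AUC")
  if (length(conc) != length(v)) stop("concentration/viability length mismatch")
  if (any(!is.finite(v))) stop("non-finite viability values")
  x <- log10(conc)
  auc <- sum(diff(x) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  span <- x[length(x)] - x[1]
  list(auc = auc, auc_norm = auc / span)
}

#' Drug relevance score
#'
#' Ratio of a drug's IC50 to its maximum (therapeutic or tested)
#' concentration: IC50 / c_max. Values below 1 mean the drug reaches its
#' half-inhibitory concentration within the usable range; the score is
#' monotone in IC50, so lower = more sensitive.
#'
#' @param ln_ic50 natural-log IC50 (log uM).
#' @param max_concentration maximum concentration (uM), > 0.
#' @return Numeric DRS (unitless).
#' @export
drug_relevance_score <- function(ln_ic50, max_concentration) {
  if (any(!is.finite(max_concentration)) || any(max_concentration <= 0))
    stop("max_concentration must be positive")
  exp(ln_ic50) / max_concentration
}

#' Summarise a table of dose-response curves into a response matrix
#'
#' Derives the chosen measure for every (sample, drug) curve and assembles a
#' samples x drugs [response_matrix()], with `NA` where no curve exists.
#'
#' @param curves either a long-format data.frame with columns `sample_id`,
#'   `drug_id`, `concentration_uM`, `viability`, or a list of
#'   [dose_response_curve()] objects.
#' @param measure one of `"LN_IC50"`, `"AUC"`, `"AUC_NORM"`, `"DRS"`. For
#'   `"DRS"` each curve's own maximum tested concentration is the
#'   denominator.
#' @param cap_extrapolation extrapolated ln-IC50 fits are truncated to the
#'   tested concentration window widened by this many natural-log units on
#'   each side (screens conventionally report out-of-range IC50s as capped
#'   values, since a flat curve constrains the IC50 only one-sidedly and
#'   the unconstrained least-squares estimate is arbitrary far outside the
#'   window). `NULL` disables capping.
#' @return A `response_matrix`; attribute `extrapolated` is a logical matrix
#'   flagging cells whose fitted IC50 fell outside the tested range
#'   (`LN_IC50`/`DRS` only).
#' @export
curves_to_matrix <- function(curves,
                             measure = c("LN_IC50", "AUC", "AUC_NORM", "DRS"),
                             cap_extrapolation = 2) {
  measure <- match.arg(measure)
  if (is.data.frame(curves)) {
    need <- c("sample_id", "drug_id", "concentration_uM", "viability")
    if (!all(need %in% names(curves)))
      stop("long-format curves need columns: ", paste(need, collapse = ", "))
    dup <- duplicated(curves[c("sample_id", "drug_id", "concentration_uM")])
    if (any(dup))
      stop("duplicate (sample, drug) curves: ",
           paste(unique(paste(curves$sample_id[dup], curves$drug_id[dup],
                              sep = " / ")), collapse = "; "))
    sp <- split(curves, list(curves$sample_id, curves$drug_id), drop = TRUE)
    curves <- lapply(sp, function(d) {
      d <- d[order(d$concentration_uM), ]
      dose_response_curve(d$sample_id[1], d$drug_id[1],
                          d$concentration_uM, d$viability)
    })
  }
  samples <- unique(vapply(curves, `[[`, "", "sample_id"))
  drugs <- unique(vapply(curves, `[[`, "", "drug_id"))
  if (length(curves) == 0) {
    m <- matrix(numeric(0), 0, 0, dimnames = list(character(0), character(0)))
    return(response_matrix(m, measure = measure))
  }
  key <- paste(vapply(curves, `[[`, "", "sample_id"),
               vapply(curves, `[[`, "", "drug_id"), sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample, drug) curves: ",
         paste(gsub("\r", " / ", unique(key[duplicated(key)])), collapse = "; "))
  m <- matrix(NA_real_, length(samples), length(drugs),
              dimnames = list(samples, drugs))
  ex <- matrix(FALSE, length(samples), length(drugs),
               dimnames = list(samples, drugs))
  for (cv in curves) {
    val <- switch(measure,
      LN_IC50 = , DRS = {
        f <- fit_ic50(cv)
        ex[cv$sample_id, cv$drug_id] <- f$extrapolated
        b <- f$ln_ic50
        if (f$extrapolated && !is.null(cap_extrapolation))
          b <- min(max(b, log(min(cv$concentrations)) - cap_extrapolation),
                   log(max(cv$concentrations)) + cap_extrapolation)
        if (measure == "DRS")
          drug_relevance_score(b, max(cv$concentrations))
        else b
      },
      AUC = compute_auc(cv)$auc,
      AUC_NORM = compute_auc(cv)$auc_norm)
    m[cv$sample_id, cv$drug_id] <- val
  }
  out <- response_matrix(m, measure = measure)
  attr(out, "extrapolated") <- ex
  out
}
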