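#' Two-colour restriction ratio and classification
#'
#' The restriction assay compares the infection rate (percent EGFP+) among
#' restriction-factor-positive (EYFP+) cells with that among
#' factor-negative (EYFP-) cells. Per replicate, ratio = p_pos / p_neg;
#' replicate ratios are averaged (mean +/- sd across independent
#' experiments) and the mean classified by the step rule: ratio < 0.3 is
#' restricted, ratio > 0.7 is not restricted, anything else (including the
#' boundary values exactly) is intermediate.
#'
#' @param pct_pos Percent infected among factor-positive cells, per
#'   replicate (values in \[0, 100\]).
#' @param pct_neg Percent infected among factor-negative cells, per
#'   replicate (must be > 0 for a defined ratio).
#' @return An object of class `restriction_result`: per-replicate
#'   `ratios`, `mean`, `sd` and `class` (one of `"restricted"`,
#'   `"intermediate"`, `"not_restricted"`).
#' @examples
#' restriction_ratio(2.0, 25.0) # ratio 0.08: restricted
#' @export
restriction_ratio <- function(pct_pos, pct_neg) {
  stopifnot(length(pct_pos) == length(pct_neg), length(pct_pos) >= 1,
            all(pct_pos >= 0), all(pct_pos <= 100),
            all(pct_neg >= 0), all(pct_neg <= 100))
  if (any(pct_neg == 0))
    stop("zero factor-negative infection rate: ratio undefined")
  ratios <- pct_pos / pct_neg
  m <- mean(ratios)
  structure(list(ratios = ratios, mean = m,
                 sd = if (length(ratios) > 1) sd(ratios) else NA_real_,
                 class = classify_restriction(m)),
            class = "restriction_result")
}

#' Classify a restriction ratio
#'
#' @param ratio Ratio of infection rates in factor-positive over
#'   factor-negative cells.
#' @return `"restricted"` (< 0.3), `"not_restricted"` (> 0.7) or
#'   `"intermediate"` (otherwise; boundary values are intermediate since
#'   only the strict inequalities are defined).
#' @export
classify_restriction <- function(ratio) {
  stopifnot(is.finite(ratio), ratio >= 0)
  if (ratio < 0.3) "restricted"
  else if (ratio > 0.7) "not_restricted"
  else "intermediate"
}

#' @export
print.restriction_result <- function(x, ...) {
  cat(sprintf("restriction_result: ratio %.2f%s (%s, n = %d)\n", x$mean,
              if (is.na(x$sd)) "" else sprintf(" +/- %.2f", x$sd),
              x$class, length(x$ratios)))
  invisible(x)
}

#' Wild-type-normalized infectious titres
#'
#' Within each independent experiment the wild-type titre is set to 100%
#' and the other samples expressed relative to it; percentages are then
#' aggregated as mean +/- sd across experiments. Normalization is
#' scale-invariant within an experiment.
#'
#' @param titres A numeric matrix (experiments x samples) or a list of
#'   per-experiment numeric vectors of equal length.
#' @param wt_index Column/position of the wild-type sample.
#' @param sample_names Optional sample names.
#' @return A data.frame with one row per sample: `mean_pct`, `sd_pct`,
#'   `n`.
#' @export
normalize_titres <- function(titres, wt_index = 1, sample_names = NULL) {
  if (is.list(titres) && !is.matrix(titres))
    titres <- do.call(rbind, titres)
  if (is.vector(titres)) titres <- matrix(titres, nrow = 1)
  stopifnot(wt_index >= 1, wt_index <= ncol(titres))
  if (any(titres[, wt_index] <= 0))
    stop("wild-type titre must be > 0 in every experiment")
  pct <- sweep(titres, 1, titres[, wt_index], "/") * 100
  if (is.null(sample_names))
    sample_names <- colnames(titres) %||% paste0("sample", seq_len(ncol(titres)))
  data.frame(sample = sample_names,
             mean_pct = colMeans(pct),
             sd_pct = if (nrow(pct) > 1) apply(pct, 2, sd) else NA_real_,
             n = nrow(pct), row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
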