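# Fold-change-binned feature association: AREP series, the fixed-constant
# PCC statistic, and Student-t significance.

#' Bin a feature over positive log2 fold changes
#'
#' Genes with log2FC strictly greater than 0 are placed in half-open bins
#' `[k*window, (k+1)*window)`; each retained (non-empty) bin carries its
#' midpoint and the arithmetic mean of the feature over its genes (AREP).
#'
#' @param lfc Numeric vector of log2 fold changes.
#' @param values Numeric feature values, same length.
#' @param window Bin width (default 0.1).
#' @return List of class `bin_series`: `bin_mid`, `arep`, `n_genes`,
#'   `window`.
#' @export
bin_by_lfc <- function(lfc, values, window = 0.1) {
  stopifnot(length(lfc) == length(values))
  keep <- !is.na(lfc) & lfc > 0 & !is.na(values)
  if (!any(keep)) stop("no genes with positive log2 fold change")
  lfc <- lfc[keep]
  values <- values[keep]
  k <- floor(lfc / window)
  arep <- tapply(values, k, mean)
  n <- tapply(values, k, length)
  ks <- as.numeric(names(arep))
  structure(list(bin_mid = (ks + 0.5) * window,
                 arep = as.numeric(arep),
                 n_genes = as.integer(n),
                 window = window),
            class = "bin_series")
}

#' Fixed-constant Pearson-style association over a bin series
#'
#' `PCC(f) = 1/(n-1) * sum_i ((LFC_i - m0)/sd0) * ((AREP_i - M_f)/SD_f)`
#' where `LFC_i` is the bin midpoint, standardised with the fixed constants
#' `m0`, `sd0`, while `M_f`, `SD_f` are the sample mean and (n-1) standard
#' deviation of the AREP series. With `empirical_moments = TRUE` the fixed
#' constants are replaced by the empirical moments of the bin midpoints, in
#' which case the statistic equals the textbook Pearson correlation.
#'
#' @param bins A `bin_series` from [bin_by_lfc()].
#' @param m0,sd0 Fixed standardisation constants for the fold-change axis.
#' @param empirical_moments Replace `m0`, `sd0` by the empirical moments.
#' @return Numeric scalar (unclipped). A constant AREP series yields `NaN`
#'   with attribute `zero_variance = TRUE`.
#' @export
pcc_eq1 <- function(bins, m0 = 6.4, sd0 = 3.7, empirical_moments = FALSE) {
  stopifnot(inherits(bins, "bin_series"))
  n <- length(bins$bin_mid)
  if (n < 3L) stop("need at least 3 bins")
  if (empirical_moments) {
    m0 <- mean(bins$bin_mid)
    sd0 <- stats::sd(bins$bin_mid)
  }
  sf <- stats::sd(bins$arep)
  if (!is.finite(sf) || sf == 0)
    return(structure(NaN, zero_variance = TRUE))
  mf <- mean(bins$arep)
  sum(((bins$bin_mid - m0) / sd0) * ((bins$arep - mf) / sf)) / (n - 1)
}

#' Student-t significance of a correlation over n bins
#'
#' `t = pcc * sqrt((n-2)/(1-pcc^2))`, two-sided p with `n - 2` degrees of
#' freedom; `|pcc| >= 1` yields p = 0.
#'
#' @param pcc Correlation value.
#' @param n_bins Number of bins.
#' @return List `t_stat`, `p`.
#' @export
pcc_pvalue <- function(pcc, n_bins) {
  stopifnot(n_bins > 2)
  if (!is.finite(pcc)) return(list(t_stat = NA_real_, p = NA_real_))
  if (abs(pcc) >= 1)
    return(list(t_stat = sign(pcc) * Inf, p = 0))
  t <- pcc * sqrt((n_bins - 2) / (1 - pcc^2))
  list(t_stat = t, p = 2 * stats::pt(abs(t), df = n_bins - 2,
                                     lower.tail = FALSE))
}

#' Association of every feature with interferon-triggered upregulation
#'
#' Features are normalised (5th/95th percentile clamp-and-scale) before
#' binning by default; pattern co-occurrence count features (columns
#' starting `cooc_`) are excluded by default.
#'
#' @param feature_table Numeric matrix or data frame, genes x features.
#' @param lfc Log2 fold changes aligned to rows.
#' @param window Bin width.
#' @param m0,sd0 Fixed standardisation constants (see [pcc_eq1()]).
#' @param normalize_first Apply the percentile normalisation first.
#' @param empirical_moments Passed to [pcc_eq1()].
#' @param include_cooc Keep `cooc_*` columns.
#' @return Data frame `feature, pcc, t_stat, p, n_bins`.
#' @export
associate_all <- function(feature_table, lfc, window = 0.1,
                          m0 = 6.4, sd0 = 3.7, normalize_first = TRUE,
                          empirical_moments = FALSE, include_cooc = FALSE) {
  X <- as.matrix(feature_table)
  stopifnot(nrow(X) == length(lfc))
  if (!include_cooc)
    X <- X[, !grepl("^cooc_", colnames(X)), drop = FALSE]
  if (normalize_first)
    X <- apply_normalizer(X, fit_normalizer(X))
  rows <- lapply(colnames(X), function(f) {
    res <- tryCatch({
      bins <- bin_by_lfc(lfc, X[, f], window = window)
      p <- pcc_eq1(bins, m0 = m0, sd0 = sd0,
                   empirical_moments = empirical_moments)
      n <- length(bins$bin_mid)
      if (!is.finite(p))
        list(pcc = NA_real_, t_stat = NA_real_, pv = NA_real_, n = n)
      else {
        tt <- pcc_pvalue(as.numeric(p), n)
        list(pcc = as.numeric(p), t_stat = tt$t_stat, pv = tt$p, n = n)
      }
    }, error = function(e)
      list(pcc = NA_real_, t_stat = NA_real_, pv = NA_real_, n = 0L))
    data.frame(feature = f, pcc = res$pcc, t_stat = res$t_stat, p = res$pv,
               n_bins = res$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
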