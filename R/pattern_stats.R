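# Class-enrichment statistics for short linear patterns.

#' Pearson chi-squared test on a 2x2 presence/absence table
#'
#' Without continuity correction; `a`/`b` are the positive-class counts with
#' and without the pattern, `c`/`d` the negative-class counts. A zero margin
#' leaves the statistic undefined.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return List `statistic`, `p`, `undefined`.
#' @export
chi2_presence <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    return(list(statistic = NA_real_, p = NA_real_, undefined = TRUE))
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       undefined = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

.rank_flagged <- function(df) {
  df[order(df$p_adj, -(df$freq_pos - df$freq_neg), df$pattern), ,
     drop = FALSE]
}

.finish_flagging <- function(df, n_pos, n_neg, alpha, adjusted) {
  n_family <- nrow(df)
  if (!nrow(df)) {
    df$chi2 <- df$p <- df$p_adj <- numeric(0)
    attr(df, "n_family") <- 0L
    return(df)
  }
  tests <- mapply(function(a, c)
    chi2_presence(a, n_pos - a, c, n_neg - c)[c("statistic", "p")],
    df$a, df$c, SIMPLIFY = FALSE)
  df$chi2 <- vapply(tests, function(t) t$statistic, numeric(1))
  df$p <- vapply(tests, function(t) t$p, numeric(1))
  df$p_adj <- bh_adjust(df$p)
  keep <- if (adjusted) df$p_adj < alpha else df$p < alpha
  keep[is.na(keep)] <- FALSE
  df <- df[keep, , drop = FALSE]
  df <- .rank_flagged(df)
  rownames(df) <- NULL
  attr(df, "n_family") <- n_family # size of the BH family (frequency-passing)
  df
}

# 4^L x n logical matrix: which exact k-mers occur in which sequence
.kmer_presence <- function(seqs, L) {
  K <- 4L^L
  out <- matrix(FALSE, nrow = K, ncol = length(seqs))
  for (j in seq_along(seqs)) {
    ci <- match(strsplit(toupper(seqs[[j]]), "", fixed = TRUE)[[1L]],
                .BASES) - 1L
    n <- length(ci)
    if (n < L) next
    idx <- integer(n - L + 1L)
    for (k in seq_len(L)) idx <- idx * 4L + ci[k:(n - L + k)]
    idx <- unique(idx[!is.na(idx)]) # NA: window contained an N
    out[idx + 1L, j] <- TRUE
  }
  out
}

#' Flag class-enriched degenerate nucleotide patterns (SLNPs)
#'
#' Streams the full 3-5-mer pattern space (708,540 patterns) against both
#' sequence classes using per-sequence exact-k-mer presence bitsets; only
#' patterns whose presence frequency is higher in the positive class by more
#' than `min_freq_diff` are materialised. These frequency-passing patterns
#' form the Benjamini-Hochberg family; patterns with adjusted p below
#' `alpha_adj` are returned, ranked by adjusted p (ties: larger frequency
#' difference, then pattern text).
#'
#' @param pos_seqs,neg_seqs Character vectors of coding sequences.
#' @param lengths Pattern lengths to scan (subset of 3:5).
#' @param min_freq_diff Positive frequency-difference cutoff.
#' @param alpha_adj Threshold on the BH-adjusted p-value.
#' @return Data frame `pattern, length, freq_pos, freq_neg, a, b, c, d,
#'   chi2, p, p_adj`.
#' @export
flag_slnps <- function(pos_seqs, neg_seqs, lengths = 3:5,
                       min_freq_diff = 0.05, alpha_adj = 0.01) {
  if (!length(pos_seqs) || !length(neg_seqs)) stop("empty sequence class")
  stopifnot(all(lengths %in% 3:5))
  n_pos <- length(pos_seqs)
  n_neg <- length(neg_seqs)
  parts <- lapply(lengths, function(L) {
    hits <- slnp_scan_cpp(.kmer_presence(pos_seqs, L),
                          .kmer_presence(neg_seqs, L), L, min_freq_diff)
    n_hit <- length(hits$a)
    if (!n_hit)
      return(data.frame(pattern = character(0), length = integer(0),
                        a = integer(0), c = integer(0)))
    pat <- apply(hits$masks, 1L, slnp_format)
    data.frame(pattern = pat, length = L, a = hits$a, c = hits$c,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  df$freq_pos <- df$a / n_pos
  df$freq_neg <- df$c / n_neg
  df$b <- n_pos - df$a
  df$d <- n_neg - df$c
  df <- df[, c("pattern", "length", "freq_pos", "freq_neg",
               "a", "b", "c", "d")]
  .finish_flagging(df, n_pos, n_neg, alpha_adj, adjusted = TRUE)
}

# present SLAAPs per protein (unique canonical pattern strings)
.slaap_presence_sets <- function(proteins) {
  gap_combos3 <- expand.grid(g1 = c(FALSE, TRUE), g2 = c(FALSE, TRUE))
  gap_combos4 <- expand.grid(g1 = c(FALSE, TRUE), g2 = c(FALSE, TRUE),
                             g3 = c(FALSE, TRUE))
  lapply(proteins, function(p) {
    ch <- strsplit(toupper(p), "", fixed = TRUE)[[1L]]
    std <- ch %in% .AA20
    n <- length(ch)
    out <- character(0)
    for (m in c(3L, 4L)) {
      combos <- if (m == 3L) gap_combos3 else gap_combos4
      for (g in seq_len(nrow(combos))) {
        gaps <- as.logical(combos[g, ])
        offs <- cumsum(c(1L, ifelse(gaps, 2L, 1L)))
        w <- offs[m]
        if (n < w) next
        ns <- n - w + 1L
        ok <- rep(TRUE, ns)
        for (pos in seq_len(w)) ok <- ok & std[pos:(ns + pos - 1L)]
        if (!any(ok)) next
        pieces <- vector("list", 2L * m - 1L)
        for (j in seq_len(m)) pieces[[2L * j - 1L]] <-
          ch[(offs[j]):(ns + offs[j] - 1L)]
        for (j in seq_len(m - 1L)) pieces[[2L * j]] <-
          if (gaps[j]) "x" else ""
        pats <- do.call(paste0, pieces)[ok]
        out <- c(out, pats)
      }
    }
    unique(out)
  })
}

#' Flag class-enriched gapped amino-acid patterns (SLAAPs)
#'
#' Scans every pattern occurring in either class (the remainder of the
#' 1,312,000-pattern space is absent from both classes and can never be
#' enriched). Patterns more frequent in the positive class (by more than
#' `min_freq_diff`) form the family; selection is on the raw chi-squared
#' p-value by default (`p_mode = "raw"`), with BH-adjusted values reported
#' either way.
#'
#' @param pos_seqs,neg_seqs Character vectors of protein sequences.
#' @param alpha Significance threshold.
#' @param min_freq_diff Required frequency excess in the positive class.
#' @param p_mode `"raw"` or `"adjusted"`: which p-value `alpha` applies to.
#' @return Data frame as in [flag_slnps()] (without `length`).
#' @export
flag_slaaps <- function(pos_seqs, neg_seqs, alpha = 0.05,
                        min_freq_diff = 0, p_mode = c("raw", "adjusted")) {
  if (!length(pos_seqs) || !length(neg_seqs)) stop("empty sequence class")
  p_mode <- match.arg(p_mode)
  n_pos <- length(pos_seqs)
  n_neg <- length(neg_seqs)
  pos_sets <- .slaap_presence_sets(pos_seqs)
  neg_sets <- .slaap_presence_sets(neg_seqs)
  pos_tab <- table(unlist(pos_sets, use.names = FALSE))
  neg_tab <- table(unlist(neg_sets, use.names = FALSE))
  pats <- union(names(pos_tab), names(neg_tab))
  a <- as.integer(pos_tab[pats]); a[is.na(a)] <- 0L
  c_ <- as.integer(neg_tab[pats]); c_[is.na(c_)] <- 0L
  df <- data.frame(pattern = pats, freq_pos = a / n_pos, freq_neg = c_ / n_neg,
                   a = a, b = n_pos - a, c = c_, d = n_neg - c_,
                   stringsAsFactors = FALSE)
  df <- df[df$freq_pos - df$freq_neg > min_freq_diff, , drop = FALSE]
  .finish_flagging(df, n_pos, n_neg, alpha, adjusted = p_mode == "adjusted")
}

#' Keep the top-k flagged patterns
#' @param flagged Ranked data frame from [flag_slnps()] / [flag_slaaps()].
#' @param k Number of patterns to keep.
#' @return The first `min(k, nrow)` rows.
#' @export
top_k <- function(flagged, k = 100L) {
  stopifnot(k >= 0)
  utils::head(flagged, k)
}

#' Conditional frequency of a pattern inside intrinsically disordered regions
#'
#' IDRs are maximal runs of residues with disorder score >= `threshold`. Only
#' proteins containing the pattern contribute; the result is the pooled
#' fraction of matches whose full span lies inside a single IDR.
#'
#' @param pattern SLAAP pattern string.
#' @param proteins Named character vector of protein sequences.
#' @param disorder_scores Named list of per-residue score vectors aligned to
#'   `proteins`.
#' @param threshold Disorder score defining an IDR residue.
#' @param min_run Minimum IDR run length in residues.
#' @return Fraction in \[0, 1\] (NaN when no protein contains the pattern).
#' @export
idr_conditional_frequency <- function(pattern, proteins, disorder_scores,
                                      threshold = 0.5, min_run = 1L) {
  inside <- 0L
  total <- 0L
  for (id in names(proteins)) {
    sc <- disorder_scores[[id]]
    if (is.null(sc)) stop("no disorder scores for protein ", id)
    if (length(sc) != nchar(proteins[[id]]))
      stop("score/sequence length mismatch for protein ", id)
    hit <- pattern_present(pattern, proteins[[id]], spans = TRUE)
    if (!hit$present) next
    is_idr <- sc >= threshold
    r <- rle(is_idr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts, ends)[r$values & r$lengths >= min_run, ,
                                drop = FALSE]
    for (i in seq_len(nrow(hit$spans))) {
      s <- hit$spans[i, "start"] + 1L # back to 1-based inclusive
      e <- hit$spans[i, "end"]
      total <- total + 1L
      if (nrow(runs) && any(runs[, 1L] <= s & runs[, 2L] >= e))
        inside <- inside + 1L
    }
  }
  inside / total
}
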