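# Nucleotide-level discrete features from a coding sequence.
#
# Ambiguity policy: positions/windows containing N are excluded from both
# numerator and denominator, so every composition stays a fraction of the
# unambiguous content.

.seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1L]]

# integer base codes 0..3 (A,C,G,T), NA for N
.base_codes <- function(x) {
  ch <- .seq_chars(x)
  bad <- !ch %in% c(.BASES, "N")
  if (any(bad))
    stop("non-nucleotide characters: ",
         paste(unique(ch[bad]), collapse = ","))
  match(ch, .BASES) - 1L
}

# counts of overlapping k-mer windows (N-containing windows dropped)
.kmer_counts <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(integer(4L^k))
  idx <- integer(n - k + 1L)
  for (j in seq_len(k)) idx <- idx * 4L + codes[j:(n - k + j)]
  tabulate(idx[!is.na(idx)] + 1L, nbins = 4L^k)
}

# ACGT-lexicographic, which matches the integer k-mer index order
.kmer_names <- function(k)
  sort(do.call(paste0, expand.grid(rep(list(.BASES), k),
                                   KEEP.OUT.ATTRS = FALSE,
                                   stringsAsFactors = FALSE)))

#' Single-base composition of a CDS
#'
#' Fractions of A, C, G and T over the unambiguous positions of the sequence.
#'
#' @param cds Nucleotide string (A/C/G/T/N).
#' @return Named numeric vector `c(A=, C=, G=, T=)` summing to 1.
#' @export
mono_composition <- function(cds) {
  codes <- .base_codes(cds)
  codes <- codes[!is.na(codes)]
  if (!length(codes)) stop("all positions ambiguous")
  stats::setNames(tabulate(codes + 1L, 4L) / length(codes), .BASES)
}

#' Paired-base content of a CDS
#'
#' Content of two distinct bases, e.g. GC content = (G + C) / unambiguous
#' length. The six pairs are AC, AG, AT, GC, CT and GT.
#'
#' @param cds Nucleotide string.
#' @param pair One of `"AC","AG","AT","GC","CT","GT"` (order-insensitive).
#' @return Fraction in \[0, 1\].
#' @export
paired_content <- function(cds, pair) {
  pair <- toupper(pair)
  b <- strsplit(pair, "", fixed = TRUE)[[1L]]
  b_sorted <- paste(sort(b), collapse = "")
  allowed <- vapply(.PAIRS, function(p)
    paste(sort(strsplit(p, "")[[1L]]), collapse = ""), character(1))
  if (!b_sorted %in% allowed) stop("unknown base pair: ", pair)
  m <- mono_composition(cds)
  unname(m[b[1L]] + m[b[2L]])
}

#' All six paired-base contents
#' @param cds Nucleotide string.
#' @return Named numeric vector `content_AC` ... `content_GT`.
#' @export
paired_contents <- function(cds) {
  m <- mono_composition(cds)
  out <- vapply(.PAIRS, function(p) {
    b <- strsplit(p, "")[[1L]]
    unname(m[b[1L]] + m[b[2L]])
  }, numeric(1))
  stats::setNames(out, paste0("content_", .PAIRS))
}

#' Overlapping dinucleotide (XpY) composition
#'
#' Fractions of the 16 5'->3' dinucleotides over overlapping width-2 windows;
#' windows containing N are dropped from numerator and denominator.
#'
#' @param cds Nucleotide string of length >= 2.
#' @return Named numeric vector of 16 fractions (`dinuc_ApA`, ...,
#'   `dinuc_TpT`) summing to 1.
#' @export
dinuc_composition <- function(cds) {
  counts <- .kmer_counts(.base_codes(cds), 2L)
  if (sum(counts) < 2L) stop("fewer than 2 unambiguous dinucleotide windows")
  lv <- .kmer_names(2L)
  nm <- paste0("dinuc_", substr(lv, 1, 1), "p", substr(lv, 2, 2))
  stats::setNames(counts / sum(counts), nm)
}

#' Overlapping 4-mer composition
#'
#' Fractions of the 256 nucleotide 4-mers over overlapping width-4 windows;
#' N-containing windows are dropped.
#'
#' @param cds Nucleotide string of length >= 4.
#' @return Named numeric vector of 256 fractions (`k4_AAAA`, ...).
#' @export
fourmer_composition <- function(cds) {
  counts <- .kmer_counts(.base_codes(cds), 4L)
  if (sum(counts) < 1L) stop("no unambiguous 4-mer window")
  stats::setNames(counts / sum(counts), paste0("k4_", .kmer_names(4L)))
}

#' Relative synonymous codon usage
#'
#' Codons are read in frame from position 1. Each codon's usage is its count
#' divided by the count of all codons of its synonymous family (standard
#' genetic code; the three stop codons TAA/TAG/TGA form one family). Families
#' absent from the CDS yield zeros for all members. Codons containing N are
#' skipped.
#'
#' @param cds Nucleotide string, `nchar(cds) %% 3 == 0`.
#' @param strict Error on a frame violation instead of truncating.
#' @return Named numeric vector of 64 usages (`codon_AAA`, ...).
#' @export
codon_usage <- function(cds, strict = FALSE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    if (strict) stop("CDS length not a multiple of 3")
    n <- n - n %% 3L
  }
  code <- .genetic_code()
  codes <- .base_codes(cds)[seq_len(n)]
  n_cod <- n %/% 3L
  idx <- codes[seq(1L, by = 3L, length.out = n_cod)] * 16L +
    codes[seq(2L, by = 3L, length.out = n_cod)] * 4L +
    codes[seq(3L, by = 3L, length.out = n_cod)]
  counts <- tabulate(idx[!is.na(idx)] + 1L, 64L)
  lv <- .kmer_names(3L)
  fam <- ifelse(code[lv] == "*", "*", code[lv]) # codon -> family key
  fam_tot <- tapply(counts, fam, sum)
  denom <- as.numeric(fam_tot[fam])
  usage <- ifelse(denom > 0, counts / denom, 0)
  stats::setNames(usage, paste0("codon_", lv))
}

#' Encode all nucleotide-level features for a set of coding sequences
#'
#' One row per sequence: 4 single-base fractions, 6 paired-base contents,
#' 16 dinucleotide fractions, 256 4-mer fractions and 64 codon usages
#' (346 columns).
#'
#' @param seqs Named character vector of CDSs.
#' @return Numeric matrix, rownames = sequence ids.
#' @export
encode_nucleotide_features <- function(seqs) {
  rows <- lapply(seqs, function(s) {
    c(stats::setNames(mono_composition(s), paste0("mono_", .BASES)),
      paired_contents(s),
      dinuc_composition(s),
      fourmer_composition(s),
      codon_usage(s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(seqs)
  out
}
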