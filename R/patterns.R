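# Degenerate short linear patterns.
#
# SLNP: 3-5 positions, each a nonempty subset of {A,C,G,T}; the first and
# last positions must be proper subsets (an unrestricted end could always be
# written as a shorter pattern). Canonical text: singleton subsets as the
# base, larger proper subsets bracketed ("[AG]"), the full set as "x"
# (interior only).
#
# SLAAP: 3-4 fixed standard residues; between consecutive fixed residues an
# optional gap of exactly one wildcard residue, written "x".

# subset masks, bit values A=1, C=2, G=4, T=8; canonical order: by size then
# alphabetically
.SLNP_MASKS <- c(1L, 2L, 4L, 8L,
                 3L, 5L, 9L, 6L, 10L, 12L,
                 7L, 11L, 13L, 14L,
                 15L)

.mask_to_text <- function(mask) {
  if (mask == 15L) return("x")
  b <- .BASES[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L]
  if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
}

.SLNP_TEXT <- vapply(.SLNP_MASKS, .mask_to_text, character(1))

#' Parse an SLNP from its bracket notation
#' @param text Pattern such as `"T[AT]AAA"` or `"ATA[AG][TG]"`; `"x"` denotes
#'   an unrestricted interior position.
#' @return Integer vector of per-position base-subset masks
#'   (A=1, C=2, G=4, T=8).
#' @export
slnp_parse <- function(text) {
  toks <- regmatches(text, gregexpr("\\[[ACGT]+\\]|[ACGTx]", text))[[1L]]
  if (paste(toks, collapse = "") != text)
    stop("cannot parse SLNP: ", text)
  masks <- vapply(toks, function(t) {
    if (t == "x") return(15L)
    b <- strsplit(gsub("\\[|\\]", "", t), "")[[1L]]
    sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[b])
  }, integer(1), USE.NAMES = FALSE)
  L <- length(masks)
  if (L < 3L || L > 5L) stop("SLNP length must be 3-5, got ", L)
  if (masks[1L] == 15L || masks[L] == 15L)
    stop("SLNP ends must be proper base subsets")
  masks
}

#' Format an SLNP mask vector in canonical bracket notation
#' @param masks Integer masks as returned by [slnp_parse()].
#' @return Pattern string.
#' @export
slnp_format <- function(masks)
  paste(vapply(as.integer(masks), .mask_to_text, character(1)), collapse = "")

#' Enumerate the degenerate nucleotide pattern space
#'
#' All patterns of the given length where every position is one of the 15
#' nonempty base subsets and the two end positions are proper subsets
#' (14 choices), i.e. `14 * 15^(L-2) * 14` patterns.
#'
#' @param length Pattern length, 3, 4 or 5.
#' @return Character vector of canonical pattern strings, each exactly once.
#' @export
enumerate_slnps <- function(length) {
  if (!length %in% 3:5) stop("SLNP length must be 3, 4 or 5")
  end_idx <- seq_len(14L)          # proper subsets
  mid_idx <- seq_len(15L)
  idx <- c(list(end_idx), rep(list(mid_idx), length - 2L), list(end_idx))
  grid <- do.call(expand.grid, c(idx, KEEP.OUT.ATTRS = FALSE))
  cols <- lapply(grid, function(i) .SLNP_TEXT[i])
  do.call(paste0, cols)
}

#' Parse an SLAAP from its text notation
#' @param text Pattern such as `"SxNxE"` or `"KEN"`; `"x"` is a
#'   single-residue wildcard between two fixed residues.
#' @return List with `fixed` (character vector of residues) and `gaps`
#'   (logical vector, length `length(fixed) - 1`).
#' @export
slaap_parse <- function(text) {
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% c(.AA20, "x"))) stop("cannot parse SLAAP: ", text)
  if (ch[1L] == "x" || ch[length(ch)] == "x" ||
      any(ch == "x" & c("", ch[-length(ch)]) == "x"))
    stop("SLAAP wildcards must be single and between fixed residues: ", text)
  fixed <- ch[ch != "x"]
  if (length(fixed) < 3L || length(fixed) > 4L)
    stop("SLAAP must have 3-4 fixed residues")
  pos_fixed <- which(ch != "x")
  gaps <- diff(pos_fixed) == 2L
  list(fixed = fixed, gaps = gaps)
}

#' Format an SLAAP in canonical notation
#' @param slaap List as returned by [slaap_parse()].
#' @return Pattern string.
#' @export
slaap_format <- function(slaap) {
  out <- slaap$fixed[1L]
  for (i in seq_along(slaap$gaps))
    out <- paste0(out, if (slaap$gaps[i]) "x" else "", slaap$fixed[i + 1L])
  out
}

#' Enumerate the gapped amino-acid pattern space
#'
#' All patterns with 3 fixed residues (`20^3 * 2^2` gap combinations) and 4
#' fixed residues (`20^4 * 2^3`), 1,312,000 in total.
#'
#' @param n_fixed Restrict to 3- or 4-fixed patterns; default both.
#' @return Character vector of canonical pattern strings, each exactly once.
#' @export
enumerate_slaaps <- function(n_fixed = c(3L, 4L)) {
  one <- function(m) {
    res <- expand.grid(rep(list(.AA20), m), KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    gaps <- expand.grid(rep(list(c("", "x")), m - 1L),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out <- character(0)
    for (g in seq_len(nrow(gaps))) {
      pieces <- vector("list", 2L * m - 1L)
      for (j in seq_len(m)) pieces[[2L * j - 1L]] <- res[[j]]
      for (j in seq_len(m - 1L)) pieces[[2L * j]] <- gaps[g, j]
      out <- c(out, do.call(paste0, pieces))
    }
    out
  }
  unlist(lapply(sort(unique(as.integer(n_fixed))), one), use.names = FALSE)
}

.encode_nt <- function(sequence) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- !ch %in% c("A", "C", "G", "T", "N")
  if (any(bad)) stop("alphabet mismatch: not a nucleotide sequence")
  m <- c(A = 1L, C = 2L, G = 4L, T = 8L)[ch]
  m[is.na(m)] <- 0L # N never matches
  m
}

.slnp_match_starts <- function(masks, seqmask) {
  L <- length(masks)
  n <- length(seqmask)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L))
    ok <- ok & bitwAnd(seqmask[j:(n - L + j)], masks[j]) > 0L
  which(ok)
}

.slaap_match_starts <- function(slaap, chars) {
  offs <- cumsum(c(1L, ifelse(slaap$gaps, 2L, 1L))) # 1-based offsets in window
  w <- offs[length(offs)]
  n <- length(chars)
  if (n < w) return(integer(0))
  std <- chars %in% .AA20
  ok <- rep(TRUE, n - w + 1L)
  for (j in seq_along(offs)) {
    pos <- offs[j]:(n - w + offs[j])
    ok <- ok & chars[pos] == slaap$fixed[j] & std[pos]
  }
  # wildcard positions must hold a standard residue
  wild <- setdiff(seq_len(w), offs)
  for (p in wild) ok <- ok & std[p:(n - w + p)]
  which(ok)
}

#' Test whether a pattern occurs in a sequence
#'
#' The pattern type is taken from the sequence alphabet: nucleotide sequences
#' (A/C/G/T/N) are scanned with SLNP semantics, anything else with SLAAP
#' semantics. Overlapping matches are allowed; `N` never matches an SLNP
#' position and SLAAP wildcards match the 20 standard residues only.
#'
#' @param pattern Pattern string (SLNP bracket notation or SLAAP notation).
#' @param sequence Nucleotide or protein string.
#' @param spans Also return the match spans as 0-based half-open intervals.
#' @return Logical scalar, or (with `spans = TRUE`) a list
#'   `list(present =, spans = <matrix start,end>)`.
#' @export
pattern_present <- function(pattern, sequence, spans = FALSE) {
  is_nt <- grepl("^[ACGTNacgtn]+$", sequence)
  if (is_nt) {
    masks <- slnp_parse(pattern)
    starts <- .slnp_match_starts(masks, .encode_nt(sequence))
    w <- length(masks)
  } else {
    sl <- slaap_parse(pattern)
    ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
    starts <- .slaap_match_starts(sl, ch)
    w <- cumsum(c(1L, ifelse(sl$gaps, 2L, 1L)))[length(sl$fixed)]
  }
  if (!spans) return(length(starts) > 0L)
  list(present = length(starts) > 0L,
       spans = cbind(start = starts - 1L, end = starts - 1L + w))
}

#' Number of flagged patterns present in a sequence
#'
#' @param patterns Character vector of patterns (one alphabet).
#' @param sequence Sequence string.
#' @return Integer count (<= `length(patterns)`).
#' @export
co_occurrence_count <- function(patterns, sequence) {
  if (!length(patterns)) return(0L)
  sum(vapply(patterns, pattern_present, logical(1), sequence = sequence))
}
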