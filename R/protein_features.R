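# Amino-acid level features: translation, 20 residue compositions and the
# 17 physicochemical / geometric group compositions.

#' Translate a CDS with the standard genetic code
#'
#' Reads codons in frame from position 1 and drops the terminal stop. In
#' non-strict mode an internal stop truncates the protein with a warning;
#' in strict mode it is an error. Codons containing N translate to `X`.
#'
#' @param cds Nucleotide string with `nchar %% 3 == 0`.
#' @param strict Error on internal stops / frame violations.
#' @return Protein string.
#' @export
translate_cds <- function(cds, strict = FALSE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    if (strict) stop("CDS length not a multiple of 3")
    n <- n - n %% 3L
  }
  code <- .genetic_code()
  n_cod <- n %/% 3L
  codons <- substring(cds, seq(1L, by = 3L, length.out = n_cod),
                      seq(3L, by = 3L, length.out = n_cod))
  aa <- code[codons]
  aa[is.na(aa)] <- "X"
  if (n_cod > 0L && aa[n_cod] == "*") aa <- aa[-n_cod]
  internal <- which(aa == "*")
  if (length(internal)) {
    if (strict) stop("internal stop codon at codon ", internal[1L])
    warning("internal stop codon; truncating translation")
    aa <- aa[seq_len(internal[1L] - 1L)]
  }
  paste(aa, collapse = "")
}

#' The 17 physicochemical / geometric residue groups
#'
#' Group memberships follow the source figure legend verbatim: seven
#' side-chain chemistry groups (aliphatic, aromatic/huge, sulphur, hydroxyl,
#' acidic, amide, positively charged) that partition the 20 residues; a
#' hydrophobicity partition (hydrophobic / neutral / hydrophilic); a
#' geometric-volume partition (tiny / small / medium / large, with
#' aromatic/huge completing it); charge (uncharged completes positive +
#' acidic); and polarity (polar / nonpolar).
#'
#' @return Named list of 17 character vectors of one-letter residue codes.
#' @export
aa_groups <- function() {
  list(
    aliphatic        = c("A", "G", "I", "L", "P", "V"),
    aromatic_huge    = c("F", "W", "Y"),
    sulphur          = c("C", "M"),
    hydroxyl         = c("S", "T"),
    acidic_negative  = c("D", "E"),
    amide            = c("N", "Q"),
    positive_charged = c("R", "H", "K"),
    hydrophobic      = c("A", "C", "I", "L", "M", "F", "V", "W"),
    neutral          = c("G", "H", "P", "S", "T", "Y"),
    hydrophilic      = c("R", "N", "D", "Q", "E", "K"),
    tiny             = c("G", "A", "S"),
    small            = c("N", "D", "C", "P", "T"),
    medium           = c("Q", "E", "H", "V"),
    large            = c("R", "I", "L", "K", "M"),
    uncharged        = setdiff(.AA20, c("R", "H", "K", "D", "E")),
    polar            = c("R", "H", "K", "D", "E", "N", "Q", "S", "T", "Y"),
    nonpolar         = setdiff(.AA20, c("R", "H", "K", "D", "E", "N", "Q",
                                        "S", "T", "Y"))
  )
}

#' Amino-acid composition
#'
#' Fractions of the 20 standard residues over the non-ambiguous positions
#' (U/B/Z/X are excluded from numerator and denominator).
#'
#' @param protein Protein string.
#' @return Named numeric vector of 20 fractions (`aa_A`, `aa_R`, ...)
#'   summing to 1.
#' @export
aa_composition <- function(protein) {
  ch <- strsplit(toupper(protein), "", fixed = TRUE)[[1L]]
  ch <- ch[ch %in% .AA20]
  if (!length(ch)) stop("no standard residues in protein")
  tab <- table(factor(ch, levels = .AA20))
  stats::setNames(as.numeric(tab) / length(ch), paste0("aa_", .AA20))
}

#' Physicochemical group composition
#'
#' Each group fraction is the sum of its member residue fractions.
#'
#' @param protein Protein string.
#' @param scheme Named list of residue groups, default [aa_groups()].
#' @return Named numeric vector (`grp_aliphatic`, ..., `grp_nonpolar`).
#' @export
group_composition <- function(protein, scheme = aa_groups()) {
  comp <- aa_composition(protein)
  names(comp) <- sub("^aa_", "", names(comp))
  out <- vapply(scheme, function(g) sum(comp[g]), numeric(1))
  stats::setNames(out, paste0("grp_", names(scheme)))
}

#' Encode all protein-level features (20 + 17 columns)
#' @param proteins Named character vector of protein sequences.
#' @return Numeric matrix, rownames = ids.
#' @export
encode_protein_features <- function(proteins) {
  scheme <- aa_groups()
  rows <- lapply(proteins, function(p)
    c(aa_composition(p), group_composition(p, scheme)))
  out <- do.call(rbind, rows)
  rownames(out) <- names(proteins)
  out
}
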