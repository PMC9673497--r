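#' Read a FASTA file
#'
#' Light wrapper around [Biostrings::readBStringSet()] with a line-level
#' pre-scan so that malformed records are reported with their line number.
#' Sequence ids are the first whitespace-delimited token of the header and
#' sequences are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-cased sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(stats::setNames(character(0), character(0)))
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">"))
    stop("malformed FASTA: line ", first, " precedes any header")
  hdr <- which(startsWith(lines, ">"))
  empty_hdr <- hdr[!nzchar(trimws(sub("^>", "", lines[hdr])))]
  if (length(empty_hdr))
    stop("malformed FASTA: empty header at line ", empty_hdr[1L])
  bad <- setdiff(nonblank, hdr)
  bad <- bad[grepl(">", lines[bad], fixed = TRUE)]
  if (length(bad))
    stop("malformed FASTA: '>' inside sequence at line ", bad[1L])
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Validate a coding sequence
#'
#' Checks the structural contract of a CDS: length a multiple of three,
#' leading ATG, terminal stop codon, no in-frame internal stop, and flags
#' ambiguous (N) bases. Characters other than A/C/G/T/N are an error.
#'
#' @param cds Nucleotide string.
#' @return List with logical flags `bad_length`, `bad_start`, `bad_stop`,
#'   `internal_stop`, `ambiguous_bases` and `valid` (all flags clear).
#' @export
validate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L, nzchar(cds))
  cds <- toupper(cds)
  ch <- strsplit(cds, "", fixed = TRUE)[[1L]]
  if (any(!ch %in% c("A", "C", "G", "T", "N")))
    stop("non-nucleotide characters in CDS: ",
         paste(unique(ch[!ch %in% c("A", "C", "G", "T", "N")]), collapse = ","))
  n <- nchar(cds)
  bad_length <- (n %% 3L) != 0L
  bad_start <- substr(cds, 1L, 3L) != "ATG"
  n_cod <- n %/% 3L
  codons <- if (n_cod > 0L)
    substring(cds, seq(1L, by = 3L, length.out = n_cod),
              seq(3L, by = 3L, length.out = n_cod)) else character(0)
  bad_stop <- bad_length || n_cod == 0L || !(codons[n_cod] %in% .STOPS)
  # a premature stop inside an otherwise stop-terminated frame; a missing
  # terminal stop is reported through bad_stop alone
  internal_stop <- !bad_stop && n_cod > 1L && any(codons[-n_cod] %in% .STOPS)
  list(bad_length = bad_length, bad_start = bad_start, bad_stop = bad_stop,
       internal_stop = internal_stop, ambiguous_bases = any(ch == "N"),
       valid = !(bad_length || bad_start || bad_stop || internal_stop ||
                   any(ch == "N")))
}

#' Refine primary ISG / non-ISG labels with independent fold-change evidence
#'
#' ISG-labelled genes keep the high-confidence label (`ISG_high`) only when at
#' least one type-I interferon observation shows strong upregulation
#' (log2FC > `up_thresh`) and none shows obvious downregulation
#' (log2FC < `down_thresh`); otherwise they become `ISG_low`. Non-ISGs showing
#' any type-I upregulation (log2FC > `nonisg_thresh`) are `excluded`,
#' otherwise `nonISG_high`. ELG labels pass through. Comparisons are strict.
#'
#' @param records Data frame with columns `gene_id`, `label`
#'   (ISG / nonISG / ELG).
#' @param observations Data frame with columns `gene_id`, `ifn_type`
#'   (I / II / III), `log2fc`.
#' @param up_thresh,down_thresh,nonisg_thresh Strict thresholds.
#' @return Data frame `gene_id`, `refined_label`.
#' @export
refine_labels <- function(records, observations,
                          up_thresh = 1.0, down_thresh = -1.0,
                          nonisg_thresh = 0.0) {
  stopifnot(all(c("gene_id", "label") %in% names(records)))
  stopifnot(all(c("gene_id", "ifn_type", "log2fc") %in% names(observations)))
  if (!all(records$label %in% c("ISG", "nonISG", "ELG")))
    stop("unknown primary label")
  orphan <- setdiff(unique(observations$gene_id), records$gene_id)
  if (length(orphan))
    stop("observations for gene(s) without a primary label: ",
         paste(utils::head(orphan, 3), collapse = ","))
  obs <- observations[observations$ifn_type == "I", , drop = FALSE]
  up <- tapply(obs$log2fc > up_thresh, obs$gene_id, any)
  down <- tapply(obs$log2fc < down_thresh, obs$gene_id, any)
  pos <- tapply(obs$log2fc > nonisg_thresh, obs$gene_id, any)
  g <- records$gene_id
  has <- function(tab, id) !is.na(tab[id]) & tab[id]
  refined <- character(length(g))
  is_isg <- records$label == "ISG"
  refined[is_isg] <- ifelse(has(up, g[is_isg]) & !has(down, g[is_isg]),
                            "ISG_high", "ISG_low")
  is_non <- records$label == "nonISG"
  refined[is_non] <- ifelse(has(pos, g[is_non]), "excluded", "nonISG_high")
  refined[records$label == "ELG"] <- "ELG"
  data.frame(gene_id = g, refined_label = refined, stringsAsFactors = FALSE)
}

#' Flag interferon-repressed genes (IRGs)
#'
#' An IRG is a non-ISG whose primary-experiment log2 fold change falls below
#' `irg_thresh` (strict). The default threshold is configurable; -0.871 is
#' the dashed cut-off printed on the source experiment's binned plots.
#'
#' @param records Data frame with columns `label` and `log2fc`.
#' @param irg_thresh Strict threshold on log2 fold change.
#' @return Logical vector, one element per record.
#' @export
tag_irg <- function(records, irg_thresh = -0.871) {
  out <- records$label == "nonISG" & !is.na(records$log2fc) &
    records$log2fc < irg_thresh
  out[is.na(out)] <- FALSE
  out
}

#' Read a tab-separated table with required columns
#' @param path Path to a TSV file with a header row.
#' @param required Character vector of required column names.
#' @return A `data.frame`.
#' @export
read_tsv_checked <- function(path, required = character(0)) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ","))
  dt
}

#' Read a gene annotation table
#'
#' Expected columns: `gene_id`, `label`, and optionally `log2fc`, `fdr`,
#' `n_transcripts`, `n_orfs`, `n_coding_exons`, `n_paralogues`, `dn`, `ds`,
#' `dnds`.
#' @param path TSV path.
#' @return A `data.frame`.
#' @export
read_annotation <- function(path)
  read_tsv_checked(path, c("gene_id", "label"))

#' Read a fold-change observation table (`gene_id`, `ifn_type`, `log2fc`)
#' @param path TSV path.
#' @return A `data.frame`.
#' @export
read_fold_changes <- function(path)
  read_tsv_checked(path, c("gene_id", "ifn_type", "log2fc"))

#' Write refined labels (and IRG flags) as TSV
#' @param refined Data frame from [refine_labels()].
#' @param irg_flag Logical vector from [tag_irg()] (optional).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refined_labels <- function(refined, path, irg_flag = NULL) {
  if (!is.null(irg_flag)) refined$irg_flag <- irg_flag
  utils::write.table(refined, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
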