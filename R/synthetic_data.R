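# Seeded synthetic benchmark with the statistical structure the analyses
# assume: two CDS classes with a planted GC gap, planted nucleotide and
# amino-acid motifs at class-specific prevalences, feature-linked positive
# log2 fold changes, a preferential-attachment interactome and smooth
# disorder scores. Every coding sequence is valid by construction (ATG
# start, single terminal stop, no internal stop) and motif planting edits
# synonymous codons only, so nucleotide planting never disturbs proteins.

.sense_codons <- function() {
  code <- .genetic_code()
  names(code)[code != "*"]
}

.codon_gc <- function(codons)
  vapply(strsplit(codons, ""), function(ch) sum(ch %in% c("G", "C")),
         numeric(1))

# exponential tilt on codon GC so interior codons hit the target class GC
.gc_codon_weights <- function(target_gc, mean_interior) {
  sense <- .sense_codons()
  gcc <- .codon_gc(sense)
  m <- mean_interior
  # account for the fixed ATG (1 GC) and a uniform stop (2/3 GC on average)
  target_interior <- (target_gc * 3 * (m + 2) - 1 - 2 / 3) / (3 * m)
  f <- function(w) {
    p <- exp(w * gcc)
    p <- p / sum(p)
    sum(p * gcc) / 3 - target_interior
  }
  w <- stats::uniroot(f, c(-5, 5))$root
  p <- exp(w * gcc)
  stats::setNames(p / sum(p), sense)
}

#' Default benchmark configuration
#'
#' Defaults mirror the contrasts the analyses are built around: a GC gap of
#' 52% vs 55% between the upregulated and background class, the SxNxE /
#' KEN amino-acid motifs at their published per-class prevalences, one
#' planted exact nucleotide 5-mer, and log2 fold changes generated as an
#' affine function of named features plus Gaussian noise, clipped to
#' (0, 12.6].
#'
#' @param n_pos,n_neg,n_elg Class sizes.
#' @param length_range Interior codon count range (start/stop excluded).
#' @param gc_pos,gc_neg Target class GC fractions.
#' @param planted_slnps Data frame `pattern`, `prev_pos`, `prev_neg`.
#' @param planted_slaaps Data frame `pattern`, `prev_pos`, `prev_neg`.
#' @param lfc_intercept,lfc_weights,lfc_noise_sd,max_lfc Fold-change model.
#' @param irg_fraction,irg_thresh Downregulated tail of the negative class.
#' @param graph Preferential-attachment settings: `n_nodes`,
#'   `edges_per_new_node`, `conf_range`.
#' @param unmapped_fraction Fraction of genes with no protein in the graph.
#' @param n_noise_features Pure-noise feature columns for recovery tests.
#' @param seed Master seed; all outputs are reproducible from it.
#' @return Named list of class `benchmark_config`.
#' @export
benchmark_config <- function(
    n_pos = 500L, n_neg = 500L, n_elg = 50L,
    length_range = c(150L, 600L),
    gc_pos = 0.52, gc_neg = 0.55,
    planted_slnps = data.frame(pattern = "TACGT",
                               prev_pos = 0.80, prev_neg = 0.68),
    planted_slaaps = data.frame(pattern = c("SxNxE", "KEN"),
                                prev_pos = c(0.152, 0.160),
                                prev_neg = c(0.088, 0.106)),
    lfc_intercept = 2.2,
    lfc_weights = c(content_GC = -1.2, slnp_TACGT = 0.8,
                    slaap_SxNxE = 0.8),
    lfc_noise_sd = 0.8, max_lfc = 12.6,
    irg_fraction = 0.12, irg_thresh = -0.871,
    graph = list(n_nodes = 600L, edges_per_new_node = 3L,
                 conf_range = c(0.3, 1.0)),
    unmapped_fraction = 0.15,
    n_noise_features = 20L,
    seed = 1L) {
  stopifnot(gc_pos > 0.2, gc_pos < 0.8, gc_neg > 0.2, gc_neg < 0.8,
            all(planted_slnps$prev_pos <= 1), all(planted_slnps$prev_pos >= 0),
            length_range[1L] >= 10L, length_range[2L] >= length_range[1L])
  structure(as.list(environment()), class = "benchmark_config")
}

# ---- codon-level sequence construction ------------------------------------

.sample_codon_lists <- function(n, length_range, weights) {
  lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
  interior <- sample(names(weights), sum(lens), replace = TRUE,
                     prob = weights)
  stops <- sample(.STOPS, n, replace = TRUE)
  split_idx <- rep.int(seq_len(n), lens)
  interior_split <- split(interior, split_idx)
  lapply(seq_len(n), function(i)
    c("ATG", interior_split[[i]], stops[i]))
}

.codons_to_cds <- function(codons) paste(codons, collapse = "")

.codon_families <- function() {
  code <- .genetic_code()
  split(names(code), ifelse(code == "*", "*", code))
}

# plant an amino-acid motif by rewriting codons at a random position
.plant_slaap <- function(codons, slaap, weights, families) {
  offs <- cumsum(c(1L, ifelse(slaap$gaps, 2L, 1L)))
  w <- offs[length(offs)]
  nres <- length(codons) - 1L  # residues (stop excluded); residue i = codon i
  if (nres < w + 1L) return(NULL)
  s <- sample(2:(nres - w + 1L), 1L)
  for (j in seq_along(slaap$fixed)) {
    fam <- families[[slaap$fixed[j]]]
    wts <- weights[fam]
    wts[is.na(wts)] <- min(weights) / 10
    codons[s + offs[j] - 1L] <- sample(fam, 1L, prob = wts)
  }
  codons
}

# realise a concrete SLNP instance via synonymous codon replacement; all
# placements are scanned in random order, so planting only fails when no
# codon-compatible placement exists for any tried instance
.plant_slnp <- function(codons, masks, families, weights,
                        n_instances = 8L) {
  code <- .genetic_code()
  L <- length(masks)
  n_nt <- 3L * length(codons)
  for (try in seq_len(n_instances)) {
    inst <- vapply(masks, function(m) {
      b <- .BASES[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
      if (length(b) == 1L) b else sample(b, 1L)
    }, character(1))
    for (q in sample.int(n_nt - L + 1L)) {
      c_first <- (q - 1L) %/% 3L + 1L
      c_last <- (q + L - 2L) %/% 3L + 1L
      repl <- vector("list", c_last - c_first + 1L)
      ok <- TRUE
      for (ci in c_first:c_last) {
        cur <- codons[ci]
        fam <- families[[ifelse(code[cur] == "*", "*", code[cur])]]
        # bases this codon must carry under the instance
        need <- rep(NA_character_, 3L)
        for (pos in 1:3) {
          k <- 3L * (ci - 1L) + pos - q + 1L  # position within the instance
          if (k >= 1L && k <= L) need[pos] <- inst[k]
        }
        cand <- fam[vapply(strsplit(fam, ""), function(ch)
          all(is.na(need) | ch == need), logical(1))]
        if (!length(cand)) { ok <- FALSE; break }
        wts <- weights[cand]
        wts[is.na(wts)] <- min(weights, na.rm = TRUE) / 10
        repl[[ci - c_first + 1L]] <- sample(cand, 1L, prob = wts)
      }
      if (ok) {
        codons[c_first:c_last] <- unlist(repl)
        return(codons)
      }
    }
  }
  NULL
}

#' Generate valid coding sequences with a planted GC gap and planted motifs
#'
#' Interior codons are drawn from the 61 sense codons with an exponential
#' tilt on codon GC calibrated so each class hits its target GC. Motifs are
#' planted to reach the configured per-class prevalence exactly: after
#' measuring natural occurrences, absent sequences are edited until the
#' target count is met (amino-acid motifs by rewriting codons, nucleotide
#' motifs by synonymous codon replacement only). Infeasible plantings after
#' bounded retries are reported via the `planting_failures` attribute.
#'
#' @param config A [benchmark_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return List `cds`, `protein` (named character vectors), `label`
#'   (character: ISG / nonISG / ELG), with attribute `planting_failures`.
#' @export
generate_cds <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "benchmark_config"))
  .with_seed(seed, {
    families <- .codon_families()
    classes <- list(
      pos = list(n = config$n_pos, gc = config$gc_pos, plant = TRUE),
      neg = list(n = config$n_neg, gc = config$gc_neg, plant = TRUE),
      elg = list(n = config$n_elg, gc = config$gc_neg, plant = FALSE))
    mean_len <- mean(config$length_range)
    failures <- 0L
    out_cds <- character(0)
    out_lab <- character(0)
    for (cl in names(classes)) {
      info <- classes[[cl]]
      if (info$n == 0L) next
      weights <- .gc_codon_weights(info$gc, mean_len)
      lists <- .sample_codon_lists(info$n, config$length_range, weights)
      if (info$plant) {
        prev_col <- if (cl == "pos") "prev_pos" else "prev_neg"
        for (r in seq_len(nrow(config$planted_slaaps))) {
          pat <- config$planted_slaaps$pattern[r]
          sl <- slaap_parse(pat)
          target <- round(config$planted_slaaps[[prev_col]][r] * info$n)
          prots <- vapply(lists, function(cd)
            paste(.genetic_code()[cd[-length(cd)]], collapse = ""),
            character(1))
          present <- vapply(prots, pattern_present, logical(1),
                            pattern = pat)
          deficit <- target - sum(present)
          if (deficit > 0) {
            cand <- sample(which(!present), deficit)
            for (i in cand) {
              upd <- .plant_slaap(lists[[i]], sl, weights, families)
              if (is.null(upd)) failures <- failures + 1L
              else lists[[i]] <- upd
            }
          }
        }
        for (r in seq_len(nrow(config$planted_slnps))) {
          pat <- config$planted_slnps$pattern[r]
          masks <- slnp_parse(pat)
          target <- round(config$planted_slnps[[prev_col]][r] * info$n)
          seqs <- vapply(lists, .codons_to_cds, character(1))
          present <- vapply(seqs, pattern_present, logical(1),
                            pattern = pat)
          deficit <- target - sum(present)
          if (deficit > 0) {
            cand <- sample(which(!present), deficit)
            for (i in cand) {
              upd <- .plant_slnp(lists[[i]], masks, families, weights)
              if (is.null(upd)) failures <- failures + 1L
              else lists[[i]] <- upd
            }
          }
        }
      }
      cds <- vapply(lists, .codons_to_cds, character(1))
      out_cds <- c(out_cds, cds)
      out_lab <- c(out_lab,
                   rep(switch(cl, pos = "ISG", neg = "nonISG", elg = "ELG"),
                       info$n))
    }
    ids <- sprintf("g%04d", seq_along(out_cds))
    names(out_cds) <- ids
    proteins <- vapply(out_cds, translate_cds, character(1))
    names(proteins) <- ids
    structure(list(cds = out_cds, protein = proteins, label = out_lab),
              planting_failures = failures)
  })
}

# feature values used by the fold-change model
.lfc_feature_matrix <- function(cds, proteins, feature_names) {
  cols <- lapply(feature_names, function(f) {
    if (grepl("^content_", f)) {
      pair <- sub("^content_", "", f)
      vapply(cds, paired_content, numeric(1), pair = pair)
    } else if (grepl("^mono_", f)) {
      base <- sub("^mono_", "", f)
      vapply(cds, function(s) mono_composition(s)[[base]], numeric(1))
    } else if (grepl("^slnp_", f)) {
      pat <- sub("^slnp_", "", f)
      as.numeric(vapply(cds, pattern_present, logical(1), pattern = pat))
    } else if (grepl("^slaap_", f)) {
      pat <- sub("^slaap_", "", f)
      as.numeric(vapply(proteins, pattern_present, logical(1),
                        pattern = pat))
    } else stop("unsupported fold-change model feature: ", f)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- feature_names
  out
}

#' Generate feature-linked log2 fold changes
#'
#' Positive-class values are an affine combination of the (z-scored) named
#' features plus Gaussian noise, clipped to (0, `max_lfc`]; negative-class
#' values are mildly centred below zero with a configured fraction forming
#' an interferon-repressed tail strictly below `irg_thresh`.
#'
#' @param features Numeric matrix for the positive-class genes (columns must
#'   cover `names(weights)`).
#' @param n_neg Number of negative-class values.
#' @param weights Named numeric weights.
#' @param intercept,noise_sd,max_lfc Model parameters.
#' @param irg_fraction,irg_thresh Downregulated tail.
#' @param seed Seed.
#' @return List `pos`, `neg` (numeric vectors).
#' @export
generate_lfc <- function(features, n_neg, weights, intercept = 2.2,
                         noise_sd = 0.8, max_lfc = 12.6,
                         irg_fraction = 0.12, irg_thresh = -0.871,
                         seed = 1L) {
  features <- as.matrix(features)
  stopifnot(all(names(weights) %in% colnames(features)))
  .with_seed(seed, {
    Z <- scale(features[, names(weights), drop = FALSE])
    Z[, attr(Z, "scaled:scale") == 0] <- 0
    lfc <- as.numeric(intercept + Z %*% weights +
                        stats::rnorm(nrow(features), 0, noise_sd))
    pos <- pmin(pmax(lfc, 0.01), max_lfc)
    n_irg <- round(irg_fraction * n_neg)
    irg <- irg_thresh - 0.05 - abs(stats::rnorm(n_irg, 0, 0.5))
    rest <- stats::rnorm(n_neg - n_irg, -0.1, 0.3)
    list(pos = pos, neg = sample(c(irg, rest)))
  })
}

#' Generate a scale-free interaction network and gene-protein map
#'
#' Preferential attachment (Barabasi-Albert) with edge confidences drawn
#' uniformly from `conf_range`, so a known fraction fails the 0.63 filter;
#' a configured fraction of genes is left unmapped to exercise the all-zero
#' metrics rule.
#'
#' @param gene_ids Character vector of genes to map.
#' @param n_nodes,edges_per_new_node,conf_range Graph settings.
#' @param unmapped_fraction Fraction of genes left unmapped.
#' @param seed Seed.
#' @return List `edges` (data frame `id_a`, `id_b`, `confidence`) and
#'   `map` (data frame `gene_id`, `protein_id`).
#' @export
generate_ppi <- function(gene_ids, n_nodes = 600L, edges_per_new_node = 3L,
                         conf_range = c(0.3, 1.0), unmapped_fraction = 0.15,
                         seed = 1L) {
  stopifnot(n_nodes >= edges_per_new_node + 1L)
  .with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = edges_per_new_node,
                           directed = FALSE)
    el <- igraph::as_edgelist(g)
    prot <- sprintf("P%04d", seq_len(n_nodes))
    edges <- data.frame(id_a = prot[el[, 1L]], id_b = prot[el[, 2L]],
                        confidence = stats::runif(nrow(el), conf_range[1L],
                                                  conf_range[2L]),
                        stringsAsFactors = FALSE)
    n_map <- round((1 - unmapped_fraction) * length(gene_ids))
    mapped <- sort(sample(seq_along(gene_ids), n_map))
    map <- data.frame(gene_id = gene_ids[mapped],
                      protein_id = sample(prot, n_map, replace = TRUE),
                      stringsAsFactors = FALSE)
    list(edges = edges, map = map)
  })
}

#' Generate smooth per-residue disorder scores in \[0, 1\]
#'
#' A moving average of uniform noise, rescaled per protein, so maximal runs
#' of scores >= 0.5 (the IDR rule) have varied lengths.
#'
#' @param proteins Named character vector of protein sequences.
#' @param window Smoothing window (residues).
#' @param seed Seed.
#' @return Named list of numeric score vectors.
#' @export
generate_disorder <- function(proteins, window = 15L, seed = 1L) {
  .with_seed(seed, {
    out <- lapply(proteins, function(p) {
      n <- nchar(p)
      x <- stats::runif(n + window - 1L)
      s <- as.numeric(stats::filter(x, rep(1 / window, window),
                                    sides = 1L))[window:(n + window - 1L)]
      rng <- range(s)
      if (diff(rng) == 0) return(rep(0.5, n))
      (s - rng[1L]) / diff(rng)
    })
    names(out) <- names(proteins)
    out
  })
}

#' Write a complete synthetic benchmark to a directory
#'
#' Produces every input the pipeline consumes (CDS and protein FASTA,
#' annotation and fold-change observation TSVs, PPI edge list and
#' gene-protein map, per-residue disorder scores, pure-noise feature
#' columns) plus a JSON manifest recording the ground truth (planted
#' patterns and prevalences, fold-change weights, signal features,
#' planting failures).
#'
#' @param dir Output directory (created if needed).
#' @param config A [benchmark_config()].
#' @return Invisibly, a list with the manifest and file paths.
#' @export
make_benchmark <- function(dir, config = benchmark_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_cds(config, seed = config$seed)
  ids <- names(gen$cds)
  is_pos <- gen$label == "ISG"
  is_neg <- gen$label == "nonISG"

  lfc_feats <- .lfc_feature_matrix(gen$cds[is_pos], gen$protein[is_pos],
                                   names(config$lfc_weights))
  lfc <- generate_lfc(lfc_feats, sum(is_neg), config$lfc_weights,
                      intercept = config$lfc_intercept,
                      noise_sd = config$lfc_noise_sd,
                      max_lfc = config$max_lfc,
                      irg_fraction = config$irg_fraction,
                      irg_thresh = config$irg_thresh,
                      seed = config$seed + 1000L)
  log2fc <- rep(NA_real_, length(ids))
  log2fc[is_pos] <- lfc$pos
  log2fc[is_neg] <- lfc$neg

  obs <- .with_seed(config$seed + 2000L, {
    rows <- list()
    pos_ids <- ids[is_pos]
    contradict <- stats::runif(length(pos_ids)) < 0.08
    for (i in seq_along(pos_ids)) {
      n_obs <- 1L + stats::rpois(1L, 1L)
      v <- lfc$pos[i] + stats::rnorm(n_obs, 0, 0.4)
      if (all(v <= 1) && !contradict[i]) v[1L] <- max(lfc$pos[i], 1.2) + 0.2
      if (contradict[i]) v <- c(v, -1.5)
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = pos_ids[i], ifn_type = "I", log2fc = v)
    }
    neg_ids <- ids[is_neg]
    leaky <- stats::runif(length(neg_ids)) < 0.10
    for (i in seq_along(neg_ids)) {
      v <- stats::rnorm(1L + stats::rpois(1L, 0.5), -0.2, 0.25)
      v <- pmin(v, 0)
      if (leaky[i]) v <- c(v, 0.5)
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = neg_ids[i], ifn_type = "I", log2fc = v)
    }
    # some type-II observations that the refinement must ignore
    extra <- sample(ids[is_pos | is_neg], round(0.1 * sum(is_pos | is_neg)))
    rows[[length(rows) + 1L]] <-
      data.frame(gene_id = extra, ifn_type = "II",
                 log2fc = stats::rnorm(length(extra), 0, 2))
    do.call(rbind, rows)
  })

  ann <- .with_seed(config$seed + 3000L, {
    n <- length(ids)
    dn <- stats::rgamma(n, shape = 1.2, rate = 8)
    ds <- stats::rgamma(n, shape = 2, rate = 2) + 0.01
    data.frame(
      gene_id = ids, label = gen$label, log2fc = log2fc,
      fdr = ifelse(is_pos, stats::runif(n, 0, 0.01),
                   stats::runif(n, 0.1, 1)),
      n_transcripts = 1L + stats::rpois(n, 3),
      n_orfs = 1L + stats::rpois(n, 1),
      n_coding_exons = 1L + stats::rnbinom(n, size = 3, mu = 8),
      n_paralogues = stats::rnbinom(n, size = 1, mu = 3),
      dn = dn, ds = ds, dnds = dn / ds, stringsAsFactors = FALSE)
  })

  ppi <- generate_ppi(ids, n_nodes = config$graph$n_nodes,
                      edges_per_new_node = config$graph$edges_per_new_node,
                      conf_range = config$graph$conf_range,
                      unmapped_fraction = config$unmapped_fraction,
                      seed = config$seed + 4000L)
  disorder <- generate_disorder(gen$protein, seed = config$seed + 5000L)
  noise <- .with_seed(config$seed + 6000L, {
    m <- matrix(stats::rnorm(length(ids) * config$n_noise_features),
                nrow = length(ids))
    colnames(m) <- sprintf("noise_%02d", seq_len(config$n_noise_features))
    m
  })

  paths <- list(
    cds = file.path(dir, "cds.fasta"),
    protein = file.path(dir, "protein.fasta"),
    annotation = file.path(dir, "annotation.tsv"),
    fold_changes = file.path(dir, "fold_changes.tsv"),
    ppi_edges = file.path(dir, "ppi_edges.tsv"),
    gene2protein = file.path(dir, "gene2protein.tsv"),
    disorder = file.path(dir, "disorder.tsv"),
    noise = file.path(dir, "noise_features.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_fasta(gen$cds, paths$cds)
  write_fasta(gen$protein, paths$protein)
  data.table::fwrite(ann, paths$annotation, sep = "\t")
  data.table::fwrite(obs, paths$fold_changes, sep = "\t")
  data.table::fwrite(ppi$edges, paths$ppi_edges, sep = "\t")
  data.table::fwrite(ppi$map, paths$gene2protein, sep = "\t")
  dis_df <- data.frame(
    protein_id = rep(names(disorder), lengths(disorder)),
    position = unlist(lapply(disorder, seq_along), use.names = FALSE),
    score = round(unlist(disorder, use.names = FALSE), 4))
  data.table::fwrite(dis_df, paths$disorder, sep = "\t")
  data.table::fwrite(data.frame(gene_id = ids, noise,
                                stringsAsFactors = FALSE),
                     paths$noise, sep = "\t")

  manifest <- list(
    config = unclass(config)[setdiff(names(config),
                                     c("planted_slnps", "planted_slaaps"))],
    planted_slnps = config$planted_slnps,
    planted_slaaps = config$planted_slaaps,
    lfc_weights = as.list(config$lfc_weights),
    signal_features = unique(c(
      "content_GC",
      paste0("slnp_", config$planted_slnps$pattern),
      paste0("slaap_", config$planted_slaaps$pattern))),
    planting_failures = attr(gen, "planting_failures"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, paths = paths))
}
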