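# End-to-end orchestration: read a benchmark (or user) directory, refine
# labels, mine patterns on the training split only, encode the full feature
# table, and train/evaluate the classifier with feature selection.

#' Encode pattern presence and co-occurrence features
#'
#' One binary column per flagged pattern (`slnp_*` / `slaap_*`) plus the two
#' co-occurrence count columns (`cooc_slnp`, `cooc_slaap`).
#'
#' @param cds Named character vector of coding sequences.
#' @param proteins Named character vector of proteins (same order).
#' @param slnp_patterns,slaap_patterns Character vectors of patterns.
#' @return Numeric matrix.
#' @export
encode_pattern_features <- function(cds, proteins, slnp_patterns,
                                    slaap_patterns) {
  nt_codes <- lapply(cds, .encode_nt)       # encode each sequence once
  aa_chars <- lapply(proteins, function(s)
    strsplit(toupper(s), "", fixed = TRUE)[[1L]])
  slnp_cols <- vapply(slnp_patterns, function(p) {
    masks <- slnp_parse(p)
    vapply(nt_codes, function(m)
      as.numeric(length(.slnp_match_starts(masks, m)) > 0L), numeric(1))
  }, numeric(length(cds)))
  slaap_cols <- vapply(slaap_patterns, function(p) {
    sl <- slaap_parse(p)
    vapply(aa_chars, function(ch)
      as.numeric(length(.slaap_match_starts(sl, ch)) > 0L), numeric(1))
  }, numeric(length(proteins)))
  if (length(cds) == 1L) {
    slnp_cols <- matrix(slnp_cols, nrow = 1L)
    slaap_cols <- matrix(slaap_cols, nrow = 1L)
  }
  out <- cbind(slnp_cols, slaap_cols,
               cooc_slnp = if (length(slnp_patterns))
                 rowSums(as.matrix(slnp_cols)) else rep(0, length(cds)),
               cooc_slaap = if (length(slaap_patterns))
                 rowSums(as.matrix(slaap_cols)) else rep(0, length(cds)))
  cn <- c(if (length(slnp_patterns)) paste0("slnp_", slnp_patterns),
          if (length(slaap_patterns)) paste0("slaap_", slaap_patterns),
          "cooc_slnp", "cooc_slaap")
  colnames(out) <- cn
  rownames(out) <- names(cds)
  out
}

#' Assemble the full feature table for a set of genes
#'
#' Joins nucleotide, protein, evolutionary (annotation scalars), network and
#' pattern features into one genes-by-features matrix.
#'
#' @param cds,proteins Named character vectors (same ids).
#' @param annotation Data frame with `gene_id` and the evolutionary columns.
#' @param graph An [igraph::graph] (or NULL to skip network features).
#' @param gene_map Gene-to-protein map data frame (for network features).
#' @param slnp_patterns,slaap_patterns Flagged patterns to encode.
#' @return Numeric matrix, rownames = gene ids.
#' @export
build_feature_table <- function(cds, proteins, annotation = NULL,
                                graph = NULL, gene_map = NULL,
                                slnp_patterns = character(0),
                                slaap_patterns = character(0)) {
  ids <- names(cds)
  X <- cbind(encode_nucleotide_features(cds),
             encode_protein_features(proteins))
  evo_cols <- c("n_transcripts", "n_orfs", "n_coding_exons",
                "n_paralogues", "dn", "ds", "dnds")
  if (!is.null(annotation)) {
    keep <- intersect(evo_cols, names(annotation))
    evo <- as.matrix(annotation[match(ids, annotation$gene_id), keep,
                                drop = FALSE])
    evo[is.na(evo)] <- 0
    colnames(evo) <- keep
    X <- cbind(X, evo)
  }
  if (!is.null(graph) && !is.null(gene_map)) {
    net <- as.matrix(metrics_for_genes(graph, gene_map, ids))
    colnames(net) <- paste0("net_", colnames(net))
    X <- cbind(X, net)
  }
  if (length(slnp_patterns) || length(slaap_patterns))
    X <- cbind(X, encode_pattern_features(cds, proteins, slnp_patterns,
                                          slaap_patterns))
  rownames(X) <- ids
  X
}

#' Run the full analysis and modelling pipeline on a benchmark directory
#'
#' Reads the files written by [make_benchmark()] (or equivalently formatted
#' user data), refines labels with the type-I observations, splits
#' train/test (stratified), mines enriched patterns on the training split
#' only, encodes all features, balances the training set, screens features
#' by single-feature AUC, optionally runs ASI, trains the SVM and evaluates
#' on the held-out genes.
#'
#' @param dir Benchmark directory.
#' @param seed Seed controlling the split, undersampling, CV folds and
#'   training.
#' @param test_fraction Held-out fraction.
#' @param screen_top Features kept by the univariate screen before
#'   selection.
#' @param slnp_top Top SLNPs kept (by adjusted p).
#' @param slaap_top Top SLAAPs kept (same ranking).
#' @param select `"asi"`, `"ffs"` or `"none"`.
#' @param spec Classifier description.
#' @param asi_max_iter Iteration bound for ASI.
#' @param k_folds Cross-validation folds.
#' @return List: `model` (bundle), `eval` (held-out metrics), `selected`,
#'   `trajectory`, `flagged_slnps`, `flagged_slaaps`, `refined`, `split`,
#'   `features` (the full feature matrix).
#' @export
run_isg_pipeline <- function(dir, seed = 1L, test_fraction = 0.25,
                             screen_top = 30L, slnp_top = 100L,
                             slaap_top = 20L,
                             select = c("asi", "ffs", "none"),
                             spec = classifier_spec("svm_rbf"),
                             asi_max_iter = 15L, k_folds = 5L) {
  select <- match.arg(select)
  cds <- read_fasta(file.path(dir, "cds.fasta"))
  proteins <- read_fasta(file.path(dir, "protein.fasta"))
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  obs <- read_fold_changes(file.path(dir, "fold_changes.tsv"))
  refined <- refine_labels(ann, obs)
  usable <- refined$refined_label %in% c("ISG_high", "nonISG_high")
  ids <- refined$gene_id[usable]
  y <- refined$refined_label[usable] == "ISG_high"

  split <- .with_seed(seed, {
    te <- logical(length(ids))
    for (cl in c(TRUE, FALSE)) {
      idx <- which(y == cl)
      te[sample(idx, round(test_fraction * length(idx)))] <- TRUE
    }
    te
  })
  train_ids <- ids[!split]
  test_ids <- ids[split]
  y_train <- y[!split]
  y_test <- y[split]

  flag_n_all <- flag_slnps(cds[train_ids[y_train]], cds[train_ids[!y_train]])
  flag_n <- top_k(flag_n_all, slnp_top)
  flag_a_all <- flag_slaaps(proteins[train_ids[y_train]],
                            proteins[train_ids[!y_train]])
  flag_a <- top_k(flag_a_all, slaap_top)

  graph <- build_graph(read_tsv_checked(file.path(dir, "ppi_edges.tsv"),
                                        c("id_a", "id_b", "confidence")))
  gene_map <- read_tsv_checked(file.path(dir, "gene2protein.tsv"),
                               c("gene_id", "protein_id"))
  X <- build_feature_table(cds[ids], proteins[ids], ann, graph, gene_map,
                           flag_n$pattern, flag_a$pattern)

  bal <- undersample(y_train, seed = seed + 1L)
  Xb <- X[train_ids[bal], , drop = FALSE]
  yb <- y_train[bal]
  plan <- make_cv_plan(yb, k_folds, seed + 2L)
  screened <- screen_features(Xb, yb, n_keep = screen_top)
  sel <- switch(select,
    asi = asi_select(Xb[, screened, drop = FALSE], yb, plan, spec,
                     max_iter = asi_max_iter),
    ffs = ffs_select(Xb[, screened, drop = FALSE], yb, plan, spec),
    none = list(selected = screened, trajectory = NULL))
  model <- train_isg_model(Xb, yb, spec, k_folds = k_folds,
                           seed = seed + 3L, features = sel$selected)
  scores_test <- stats::predict(model, X[test_ids, , drop = FALSE])
  eval <- evaluate_predictions(scores_test, y_test, model$threshold,
                               sn_n_n = sum(y_test))
  list(model = model, eval = eval, selected = sel$selected,
       trajectory = sel$trajectory,
       flagged_slnps = flag_n_all, flagged_slaaps = flag_a_all,
       slnp_used = flag_n$pattern, slaap_used = flag_a$pattern,
       refined = refined,
       split = data.frame(gene_id = ids, test = split, label = y),
       features = X)
}
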