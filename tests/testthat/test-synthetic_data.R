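# Cheap generator checks run on a reduced configuration; the full default
# benchmark is exercised by the acceptance suite.

small_config <- function(seed = 5L)
  benchmark_config(n_pos = 60L, n_neg = 60L, n_elg = 10L,
                   length_range = c(60L, 120L),
                   graph = list(n_nodes = 150L, edges_per_new_node = 2L,
                                conf_range = c(0.3, 1)),
                   n_noise_features = 5L, seed = seed)

test_that("every generated CDS is valid by construction", {
  gen <- generate_cds(small_config())
  flags <- vapply(gen$cds, function(s) validate_cds(s)$valid, logical(1))
  expect_true(all(flags))
  expect_identical(unname(gen$protein),
                   unname(vapply(gen$cds, translate_cds, character(1))))
})

test_that("generation is deterministic in the seed", {
  g1 <- generate_cds(small_config(9L))
  g2 <- generate_cds(small_config(9L))
  expect_identical(g1, g2)
  g3 <- generate_cds(small_config(10L))
  expect_false(identical(g1$cds, g3$cds))
})

test_that("class GC means land near their targets", {
  cfg <- benchmark_config(n_pos = 150L, n_neg = 150L, n_elg = 0L,
                          length_range = c(100L, 200L), seed = 3L)
  gen <- generate_cds(cfg)
  gc <- vapply(gen$cds, paired_content, numeric(1), pair = "GC")
  expect_lt(abs(mean(gc[gen$label == "ISG"]) - cfg$gc_pos), 0.01)
  expect_lt(abs(mean(gc[gen$label == "nonISG"]) - cfg$gc_neg), 0.01)
})

test_that("planted motif prevalences hit their per-class targets", {
  cfg <- benchmark_config(n_pos = 150L, n_neg = 150L, n_elg = 0L,
                          length_range = c(100L, 200L), seed = 4L)
  gen <- generate_cds(cfg)
  pos <- gen$label == "ISG"
  neg <- gen$label == "nonISG"
  for (r in seq_len(nrow(cfg$planted_slaaps))) {
    pat <- cfg$planted_slaaps$pattern[r]
    pp <- mean(vapply(gen$protein[pos], pattern_present, logical(1),
                      pattern = pat))
    pn <- mean(vapply(gen$protein[neg], pattern_present, logical(1),
                      pattern = pat))
    expect_lt(abs(pp - cfg$planted_slaaps$prev_pos[r]), 0.03)
    expect_lt(abs(pn - cfg$planted_slaaps$prev_neg[r]), 0.03)
  }
  for (r in seq_len(nrow(cfg$planted_slnps))) {
    pat <- cfg$planted_slnps$pattern[r]
    pp <- mean(vapply(gen$cds[pos], pattern_present, logical(1),
                      pattern = pat))
    pn <- mean(vapply(gen$cds[neg], pattern_present, logical(1),
                      pattern = pat))
    expect_lt(abs(pp - cfg$planted_slnps$prev_pos[r]), 0.03)
    expect_lt(abs(pn - cfg$planted_slnps$prev_neg[r]), 0.03)
  }
})

test_that("fold-change generation follows the affine model and clipping", {
  X <- cbind(f = rnorm(100))
  # zero weights, zero noise: constant at the intercept
  r0 <- generate_lfc(X, 50, c(f = 0), intercept = 2, noise_sd = 0,
                     seed = 1)
  expect_true(all(r0$pos == 2))
  # clipping
  r1 <- generate_lfc(X, 50, c(f = 50), intercept = 0, noise_sd = 0,
                     max_lfc = 12.6, seed = 1)
  expect_lte(max(r1$pos), 12.6)
  expect_gt(min(r1$pos), 0)
  # a pure feature-driven LFC maximises the binned association
  set.seed(2)
  Xf <- cbind(f = runif(400))
  r2 <- generate_lfc(Xf, 10, c(f = 2), intercept = 3, noise_sd = 0,
                     seed = 3)
  b <- bin_by_lfc(r2$pos, Xf[, "f"])
  expect_gt(pcc_eq1(b, empirical_moments = TRUE), 0.99)
  # IRG tail strictly below the threshold
  r3 <- generate_lfc(X, 200, c(f = 0), irg_fraction = 0.2, seed = 4)
  expect_gte(sum(r3$neg < -0.871), round(0.2 * 200))
})

test_that("the interactome generator produces a heavy-tailed graph", {
  ppi <- generate_ppi(sprintf("g%03d", 1:100), n_nodes = 2000L,
                      edges_per_new_node = 3L, seed = 6L)
  g <- build_graph(ppi$edges, min_confidence = 0)
  deg <- igraph::degree(g)
  expect_gte(max(deg), 3 * stats::median(deg))
  # a known fraction of confidences fails the default 0.63 filter
  frac_low <- mean(ppi$edges$confidence <= 0.63)
  expect_gt(frac_low, 0.2)
  g63 <- build_graph(ppi$edges)
  expect_lt(igraph::ecount(g63), nrow(ppi$edges))
  # all confidences 0.5 -> empty graph -> all-zero metrics
  e5 <- ppi$edges
  e5$confidence <- 0.5
  g0 <- build_graph(e5)
  out <- metrics_for_genes(g0, ppi$map)
  expect_true(all(out == 0))
})

test_that("disorder scores are smooth, seeded and in [0, 1]", {
  prots <- c(a = random_protein(120), b = random_protein(80))
  d1 <- generate_disorder(prots, seed = 7)
  d2 <- generate_disorder(prots, seed = 7)
  expect_identical(d1, d2)
  expect_true(all(unlist(d1) >= 0 & unlist(d1) <= 1))
  expect_identical(lengths(d1), c(a = 120L, b = 80L))
  # runs of >= 0.5 exist and are not the whole protein
  r <- rle(d1$a >= 0.5)
  expect_gt(length(r$lengths), 1)
})

test_that("make_benchmark writes a complete, reproducible directory", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  out1 <- make_benchmark(dir1, small_config(8L))
  out2 <- make_benchmark(dir2, small_config(8L))
  for (f in c("cds.fasta", "protein.fasta", "annotation.tsv",
              "fold_changes.tsv", "ppi_edges.tsv", "gene2protein.tsv",
              "disorder.tsv", "noise_features.tsv", "manifest.json")) {
    expect_true(file.exists(file.path(dir1, f)))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  m <- jsonlite::read_json(file.path(dir1, "manifest.json"),
                           simplifyVector = TRUE)
  expect_true(all(c("signal_features", "planted_slaaps", "lfc_weights")
                  %in% names(m)))
  # the annotation supports label refinement end to end
  ann <- read_annotation(file.path(dir1, "annotation.tsv"))
  obs <- read_fold_changes(file.path(dir1, "fold_changes.tsv"))
  ref <- refine_labels(ann, obs)
  expect_gt(sum(ref$refined_label == "ISG_high"), 0)
  expect_gt(sum(ref$refined_label == "nonISG_high"), 0)
})
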