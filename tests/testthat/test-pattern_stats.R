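test_that("chi-squared matches the closed form and the library oracle", {
  r <- chi2_presence(8, 2, 2, 8)
  expect_equal(r$statistic, 7.2)
  or <- suppressWarnings(
    stats::chisq.test(matrix(c(8, 2, 2, 8), 2), correct = FALSE))
  expect_equal(r$statistic, unname(or$statistic))
  expect_equal(r$p, or$p.value)

  expect_equal(chi2_presence(5, 5, 5, 5)$statistic, 0)
  expect_equal(chi2_presence(5, 5, 5, 5)$p, 1)
  expect_equal(chi2_presence(10, 0, 0, 10)$statistic, 20)
  z <- chi2_presence(0, 0, 5, 5)
  expect_true(z$undefined)
})

test_that("BH adjustment equals the independent step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(9)
  p <- runif(50)
  # independent step-up: p * m / rank, cumulative min from the largest rank
  o <- order(p)
  m <- length(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  oracle <- numeric(m)
  oracle[o] <- pmin(adj_sorted, 1)
  expect_equal(bh_adjust(p), oracle)
  # order invariance (up to permutation)
  perm <- sample(m)
  expect_equal(bh_adjust(p[perm]), oracle[perm])
  expect_true(all(bh_adjust(p) >= p))
})

test_that("flag_slnps flags a planted pattern and applies both cutoffs", {
  set.seed(21)
  base <- replicate(40, paste(sample(c("A", "C", "G", "T"), 60, TRUE,
                                     prob = c(.3, .2, .2, .3)),
                              collapse = ""))
  pos <- base[1:20]
  neg <- base[21:40]
  pos[1:16] <- paste0(substr(pos[1:16], 1, 20), "TTCGA",
                      substr(pos[1:16], 26, 60))
  got <- flag_slnps(pos, neg, lengths = 3:5, min_freq_diff = 0.05,
                    alpha_adj = 0.05)
  expect_true("TTCGA" %in% got$pattern)
  expect_true(all(got$freq_pos - got$freq_neg > 0.05))
  expect_true(all(got$p_adj < 0.05))
  expect_true(all(got$a + got$b == 20L) && all(got$c + got$d == 20L))
  # ranking: ascending adjusted p
  expect_true(!is.unsorted(got$p_adj))
  # identical classes flag nothing
  expect_identical(nrow(flag_slnps(base, base)), 0L)
  expect_error(flag_slnps(character(0), base), "empty")
})

test_that("flagging is anti-monotone in alpha", {
  set.seed(22)
  pos <- replicate(30, random_protein(50))
  neg <- replicate(30, random_protein(50))
  pos[1:12] <- paste0(substr(pos[1:12], 1, 20), "KEN",
                      substr(pos[1:12], 24, 50))
  f1 <- flag_slaaps(pos, neg, alpha = 0.01)
  f2 <- flag_slaaps(pos, neg, alpha = 0.10)
  expect_true(all(f1$pattern %in% f2$pattern))
  expect_true("KEN" %in% f2$pattern)
  # direction requirement: swapping the classes removes the planted motif
  f_swap <- flag_slaaps(neg, pos, alpha = 0.10)
  expect_false("KEN" %in% f_swap$pattern)
})

test_that("top_k truncates a ranked list", {
  df <- data.frame(pattern = letters[1:3], p_adj = c(.1, .2, .3))
  expect_identical(nrow(top_k(df, 100)), 3L)
  expect_identical(nrow(top_k(df, 2)), 2L)
  expect_identical(nrow(top_k(df, 0)), 0L)
})

test_that("IDR conditional frequency obeys the full-span rule", {
  prots <- c(p1 = "SKNTE")
  expect_equal(idr_conditional_frequency("SxNxE", prots,
                                         list(p1 = rep(1, 5))), 1)
  expect_equal(idr_conditional_frequency("SxNxE", prots,
                                         list(p1 = rep(0, 5))), 0)
  # span exits the IDR by one residue
  expect_equal(idr_conditional_frequency(
    "SxNxE", prots, list(p1 = c(.9, .9, .9, .9, .4))), 0)
  # threshold is >=
  expect_equal(idr_conditional_frequency(
    "SxNxE", prots, list(p1 = rep(0.5, 5))), 1)
  # pooled across proteins: one match inside, one outside
  prots2 <- c(p1 = "SKNTE", p2 = "ASKNTEA")
  sc <- list(p1 = rep(1, 5), p2 = rep(0, 7))
  expect_equal(idr_conditional_frequency("SxNxE", prots2, sc), 0.5)
  expect_error(idr_conditional_frequency("SxNxE", prots,
                                         list(p1 = rep(1, 3))),
               "length mismatch")
})
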