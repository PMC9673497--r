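test_that("SLNP enumeration matches the closed form and has no duplicates", {
  s3 <- enumerate_slnps(3)
  expect_length(s3, 14 * 15 * 14)
  expect_identical(anyDuplicated(s3), 0L)
  expect_length(enumerate_slnps(4), 14 * 15^2 * 14)
  expect_error(enumerate_slnps(6), "3, 4 or 5")
  # sampled uniqueness + invariants for length 5
  s5 <- enumerate_slnps(5)
  expect_length(s5, 14 * 15^3 * 14)
  set.seed(2)
  sub <- sample(s5, 2000)
  expect_identical(anyDuplicated(sub), 0L)
  for (p in sample(sub, 50)) {
    m <- slnp_parse(p)
    expect_identical(slnp_format(m), p)
    expect_true(m[1] != 15L && m[length(m)] != 15L)
  }
})

test_that("SLAAP enumeration matches the closed form", {
  s3 <- enumerate_slaaps(3)
  expect_length(s3, 20^3 * 4)
  expect_identical(anyDuplicated(s3), 0L)
  expect_true("KEN" %in% s3)
  expect_identical(sum(s3 == "KEN"), 1L)
  # 4-fixed subtotal by the closed form; full space asserted in acceptance
  expect_length(enumerate_slaaps(4), 20^4 * 8)
})

test_that("pattern parsing and canonical formatting round-trip", {
  m <- slnp_parse("ATA[AG][TG]")
  expect_identical(m, c(1L, 8L, 1L, 5L, 12L))
  # canonical form writes bracketed bases alphabetically
  expect_identical(slnp_format(m), "ATA[AG][GT]")
  expect_identical(slnp_parse("ATA[AG][GT]"), m)
  expect_identical(slnp_format(slnp_parse("TxAAA")), "TxAAA")
  expect_error(slnp_parse("xTAA"), "proper")
  expect_error(slnp_parse("TA"), "length")

  sl <- slaap_parse("SxNxE")
  expect_identical(sl$fixed, c("S", "N", "E"))
  expect_identical(sl$gaps, c(TRUE, TRUE))
  expect_identical(slaap_format(sl), "SxNxE")
  expect_error(slaap_parse("xKEN"), "wildcard")
  expect_error(slaap_parse("KxxEN"), "wildcard")
})

test_that("pattern_present matches the worked examples", {
  r <- pattern_present("T[AT]AAA", "GGTTAAAG", spans = TRUE)
  expect_true(r$present)
  expect_equal(r$spans, cbind(start = 2L, end = 7L))
  r <- pattern_present("SxNxE", "MSKNAEG", spans = TRUE)
  expect_true(r$present)
  expect_equal(r$spans, cbind(start = 1L, end = 6L))
  expect_false(pattern_present("KEN", "KEQ"))
  # overlapping matches are all reported
  r <- pattern_present("AAA", "AAAAA", spans = TRUE)
  expect_identical(nrow(r$spans), 3L)
  # N never matches; X does not satisfy an SLAAP wildcard
  expect_false(pattern_present("TAA", "TNA"))
  expect_false(pattern_present("SxNxE", "SXNTE"))
})

test_that("matcher agrees with the regex-translation oracle", {
  set.seed(31)
  masks_pool <- c(1L, 2L, 4L, 8L, 3L, 5L, 9L, 6L, 10L, 12L, 7L, 11L,
                  13L, 14L, 15L)
  for (i in 1:400) {
    L <- sample(3:5, 1)
    m <- c(sample(masks_pool[1:14], 1),
           sample(masks_pool, L - 2, replace = TRUE),
           sample(masks_pool[1:14], 1))
    pat <- slnp_format(m)
    seq <- paste(sample(c("A", "C", "G", "T"), sample(5:40, 1), TRUE),
                 collapse = "")
    expect_identical(pattern_present(pat, seq),
                     grepl(slnp_regex(pat), seq),
                     info = paste(pat, seq))
  }
  slaaps <- enumerate_slaaps(3)
  for (i in 1:400) {
    pat <- sample(slaaps, 1)
    seq <- random_protein(sample(4:30, 1))
    expect_identical(pattern_present(pat, seq),
                     grepl(slaap_regex(pat), seq),
                     info = paste(pat, seq))
  }
})

test_that("co-occurrence counting is bounded and exact", {
  seqs <- "GGTTAAAGCGCG"
  pats <- c("T[AT]AAA", "CGCG", "AAAAA")
  expect_identical(co_occurrence_count(pats, seqs), 2L)
  expect_identical(co_occurrence_count(character(0), seqs), 0L)
  expect_lte(co_occurrence_count(pats, seqs), length(pats))
})
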