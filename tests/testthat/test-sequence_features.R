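test_that("mono composition and paired contents match the definitions", {
  expect_equal(unname(mono_composition("ATGC")), rep(0.25, 4))
  expect_equal(unname(mono_composition("AAAA")), c(1, 0, 0, 0))
  expect_equal(unname(mono_composition("ATNGC")), rep(0.25, 4)) # N excluded
  expect_error(mono_composition("NNN"), "ambiguous")

  expect_equal(paired_content("ATGCGC", "GC"), 4 / 6)
  expect_equal(paired_content("ATGCGC", "AT"), 2 / 6)
  s <- random_cds(30)
  expect_equal(paired_content(s, "GC") + paired_content(s, "AT"), 1)
  expect_error(paired_content(s, "AA"), "unknown")
})

test_that("dinucleotide and 4-mer compositions use overlapping windows", {
  d <- dinuc_composition("CGCG")
  expect_equal(unname(d["dinuc_CpG"]), 2 / 3)
  expect_equal(unname(d["dinuc_GpC"]), 1 / 3)
  expect_equal(unname(dinuc_composition("TATA")["dinuc_TpA"]), 2 / 3)

  f <- fourmer_composition("CGCGCG")
  expect_equal(unname(f["k4_CGCG"]), 2 / 3)
  expect_equal(unname(fourmer_composition("AAAAA")["k4_AAAA"]), 1)
  expect_error(dinuc_composition("AN"), "fewer than 2")
})

test_that("codon usage is relative within synonymous families", {
  u <- codon_usage("ATGAGAAGACGTTAA")
  expect_equal(unname(u["codon_AGA"]), 2 / 3) # 2 of 3 Arg codons
  expect_equal(unname(u["codon_CGT"]), 1 / 3)
  expect_equal(unname(u["codon_TAA"]), 1)     # only stop used
  expect_equal(unname(u["codon_CTG"]), 0)     # Leu family absent
  expect_error(codon_usage("ATGAA", strict = TRUE), "multiple of 3")
})

test_that("normalisation invariants hold on random valid CDSs", {
  set.seed(101)
  code <- Biostrings::GENETIC_CODE
  fam <- split(names(code), as.character(code))
  for (i in 1:200) {
    s <- random_cds(sample(10:60, 1))
    expect_equal(sum(mono_composition(s)), 1)
    expect_equal(sum(dinuc_composition(s)), 1)
    expect_equal(sum(fourmer_composition(s)), 1)
    u <- codon_usage(s)
    names(u) <- sub("^codon_", "", names(u))
    for (f in fam) {
      tot <- sum(u[f])
      expect_true(abs(tot - 1) < 1e-9 || tot == 0)
    }
    expect_true(all(u >= 0 & u <= 1))
  }
})

test_that("compositions equal a naive substring-scan oracle", {
  set.seed(77)
  for (len in c(50, 500, 5000)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    d <- dinuc_composition(s)
    f <- fourmer_composition(s)
    # oracle: count fixed substrings with a sliding regex scan
    count_sub <- function(seq, pat) {
      hits <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1L]]
      if (hits[1L] == -1L) 0L else length(hits)
    }
    for (pat in c("CG", "TA", "AA", "GT"))
      expect_equal(unname(d[paste0("dinuc_", substr(pat, 1, 1), "p",
                                   substr(pat, 2, 2))]),
                   count_sub(s, pat) / (len - 1))
    for (pat in c("CGCG", "AAAA", "ATGC", "TTAA"))
      expect_equal(unname(f[paste0("k4_", pat)]),
                   count_sub(s, pat) / (len - 3))
  }
})

test_that("compositions are case-invariant", {
  s <- random_cds(25)
  expect_equal(mono_composition(s), mono_composition(tolower(s)))
  expect_equal(dinuc_composition(s), dinuc_composition(tolower(s)))
  expect_equal(fourmer_composition(s), fourmer_composition(tolower(s)))
})

test_that("encode_nucleotide_features assembles the full manifest", {
  seqs <- c(a = random_cds(20), b = random_cds(30))
  X <- encode_nucleotide_features(seqs)
  expect_identical(dim(X), c(2L, 4L + 6L + 16L + 256L + 64L))
  expect_identical(rownames(X), c("a", "b"))
  expect_true(all(X >= 0 & X <= 1))
})
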