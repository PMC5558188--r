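test_that("BLOSUM62 lookups match the canonical matrix and are symmetric", {
  expect_identical(blosum62_element("W", "W"), 11L)
  expect_identical(blosum62_element("A", "A"), 4L)
  expect_identical(blosum62_element("D", "E"), 2L)
  expect_identical(blosum62_element("E", "D"), 2L)
  expect_error(blosum62_element("A", "X"), "non-standard")

  # independent cross-check of all 400 pairs against the Biostrings copy
  bio <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  aa <- amino_acids()
  pairs <- expand.grid(a = aa, b = aa, stringsAsFactors = FALSE)
  ours <- blosum62_element(pairs$a, pairs$b)
  theirs <- bio[cbind(pairs$a, pairs$b)]
  expect_identical(unname(ours), as.integer(theirs))
  expect_identical(blosum62_element(pairs$a, pairs$b),
                   blosum62_element(pairs$b, pairs$a))
  expect_true(all(ours >= -4 & ours <= 11))
})

test_that("Shannon entropy matches closed forms and is permutation-invariant", {
  expect_equal(shannon_entropy(strsplit("AAAA", "")[[1]]), 0)
  expect_equal(shannon_entropy(strsplit("AAVV", "")[[1]]), log(2))
  expect_equal(shannon_entropy(amino_acids()), log(20))
  expect_equal(shannon_entropy(strsplit("AAVV", "")[[1]], base = 2), 1)
  expect_error(shannon_entropy(character(0)), "empty")
  # gaps are excluded from the composition
  expect_equal(shannon_entropy(strsplit("AA--", "")[[1]]), 0)

  set.seed(42)
  for (i in 1:20) {
    col <- sample(amino_acids(), 30, replace = TRUE)
    expect_equal(shannon_entropy(col), shannon_entropy(sample(col)))
    expect_lte(shannon_entropy(col), log(20) + 1e-12)
  }
})

test_that("pssm_nat matches hand-computed log-ratios", {
  # identical frequencies -> 0
  cc <- c(A = 2, V = 2)
  mc <- c(A = 10, V = 10)
  expect_equal(pssm_nat("A", cc, mc, pseudocount = 0), 0)
  # f_col 1.0 vs f_msa 0.5 -> log 2
  expect_equal(pssm_nat("A", c(A = 4), c(A = 10, V = 10), pseudocount = 0),
               log(2))
  # native absent from the column, pseudocount 0.5, hand recount:
  # column (V=2, L=2): f_col = 0.5 / (4 + 10); alignment (A=3 of 20):
  # f_msa = 3.5 / (20 + 10); ratio = 15/49
  expect_equal(pssm_nat("A", c(V = 2, L = 2), c(A = 3, V = 9, L = 8),
                        pseudocount = 0.5),
               log(15 / 49))
  expect_error(pssm_nat("A", c(V = 2), c(A = 0, V = 2), pseudocount = 0),
               "not finite")
  # smoothed value converges to the plain ratio when all counts positive
  cc <- c(A = 5, V = 3); mc <- c(A = 50, V = 70)
  plain <- pssm_nat("A", cc, mc, pseudocount = 0)
  expect_equal(pssm_nat("A", cc, mc, pseudocount = 1e-9), plain,
               tolerance = 1e-6)
})

test_that("annotate_features fills the triple from a toy alignment", {
  # human ACDEF + two homologs; variant C2W
  m <- toy_msa("ACDEF", "ACDEF", "AVDEF")
  rec <- variant_table("PTOY", "C", 2L, "W", label = "pathogenic")
  out <- annotate_features(rec, list(PTOY = m))
  expect_equal(out$blosum62, blosum62_element("C", "W"))
  # column 2 is C,C,V -> entropy of (2,1)
  expect_equal(out$entropy, -(2 / 3 * log(2 / 3) + 1 / 3 * log(1 / 3)))
  # pssm_nat: C count 2 of 3 in column, 2 of 15 overall, pseudocount 0.5
  expect_equal(out$pssm_nat,
               log(((2 + 0.5) / (3 + 10)) / ((2 + 0.5) / (15 + 10))))
  expect_identical(nrow(attr(out, "feature_errors")), 0L)
})

test_that("a fully conserved column gives entropy 0 and non-negative pssm_nat", {
  m <- toy_msa("ACDEF", "AWDEF", "AYDEF")
  rec <- variant_table("PTOY", "A", 1L, "V", label = "neutral")
  out <- annotate_features(rec, list(PTOY = m))
  expect_equal(out$entropy, 0)
  expect_gte(out$pssm_nat, 0)
})

test_that("precomputed features are kept unless recompute is requested", {
  m <- toy_msa("ACDEF", "ACDEF")
  rec <- variant_table("PTOY", "C", 2L, "W", label = "neutral",
                       blosum62 = -99, pssm_nat = -99, entropy = -99)
  kept <- annotate_features(rec, list(PTOY = m))
  expect_equal(kept$blosum62, -99)
  redone <- annotate_features(rec, list(PTOY = m), recompute = TRUE)
  expect_equal(redone$blosum62, blosum62_element("C", "W"))
})

test_that("unmappable rows are reported, not fatal", {
  m <- toy_msa("ACDEF", "ACDEF")
  rec <- variant_table("PTOY", c("C", "C"), c(2L, 99L), c("W", "W"),
                       label = "neutral")
  out <- annotate_features(rec, list(PTOY = m))
  errs <- attr(out, "feature_errors")
  expect_identical(errs$row, 2L)
  expect_match(errs$reason, "beyond")
  expect_true(is.na(out$entropy[2]) && !is.na(out$entropy[1]))
  # missing alignment is collected the same way
  out2 <- annotate_features(rec[1, ], list())
  expect_identical(nrow(attr(out2, "feature_errors")), 1L)
})
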