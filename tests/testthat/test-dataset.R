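test_that("the per-protein count filter keeps >= thres and drops < thres", {
  rec <- rbind(
    variant_table("PBIG", "A", 1:31, "V", label = "pathogenic"),
    variant_table("PSMALL", "A", 1:2, "V", label = "pathogenic"),
    variant_table("PSMALL", "A", 3:12, "V", label = "neutral"))
  out <- filter_by_protein_count(rec, thres = 30)
  expect_identical(sum(out$protein_id == "PBIG"), 31L)
  expect_identical(sum(out$protein_id == "PSMALL" &
                         out$label == "pathogenic"), 0L)
  # neutral records of a below-threshold protein are not what the filter
  # removes
  expect_identical(sum(out$protein_id == "PSMALL" & out$label == "neutral"),
                   10L)
  expect_identical(filter_by_protein_count(rec, thres = 0), rec)
  expect_error(filter_by_protein_count(rec, thres = -1), "non-negative")
})

test_that("raising thres never increases the retained pathogenic count", {
  set.seed(7)
  rec <- variant_table(
    protein_id = sample(paste0("P", 1:8), 300, replace = TRUE),
    native_aa = "A", position = 1:300, variant_aa = "V",
    label = sample(c("pathogenic", "neutral"), 300, replace = TRUE))
  counts <- vapply(c(0, 5, 10, 30, 50), function(th) {
    sum(filter_by_protein_count(rec, th)$label == "pathogenic")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pairwise identity uses mutually gap-free columns", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 1)
  expect_equal(pairwise_identity("ACDE", "ACDF"), 0.75)
  expect_equal(pairwise_identity("AC--", "ACDE"), 1)
  expect_error(pairwise_identity("--", "AA"), "gap-free")
  expect_error(pairwise_identity("ACD", "AC"), "lengths differ")
})

test_that("neutral harvesting follows the close-homolog rule", {
  # 100-column human; homolog differs only at position 42 (A -> V)
  human <- paste(rep("A", 100), collapse = "")
  hom <- paste(c(rep("A", 41), "V", rep("A", 58)), collapse = "")
  m <- toy_msa(human, hom)
  out <- harvest_neutral_variants(m, protein_id = "PTOY")
  expect_identical(nrow(out), 1L)
  expect_identical(out$native_aa, "A")
  expect_identical(out$position, 42L)
  expect_identical(out$variant_aa, "V")
  expect_identical(out$label, "neutral")

  # identical homolog contributes nothing
  expect_identical(nrow(harvest_neutral_variants(toy_msa(human, human))), 0L)

  # 80% identity homolog (20 differences) is below the 0.95 cutoff
  far <- paste(c(rep("V", 20), rep("A", 80)), collapse = "")
  expect_identical(nrow(harvest_neutral_variants(toy_msa(human, far))), 0L)

  # duplicates across homologs collapse to one record
  m2 <- toy_msa(human, hom, hom)
  expect_identical(nrow(harvest_neutral_variants(m2)), 1L)
})

test_that("harvested positions map to gap-free human columns", {
  # human has a gap; positions are ungapped human coordinates
  m <- toy_msa("AC-DEF", "ACWDEV")
  out <- harvest_neutral_variants(
    m, dataset_build_config(identity_min_neutral = 0.75))
  expect_identical(out$position, 5L)  # F at ungapped position 5
  expect_identical(out$native_aa, "F")
  expect_identical(out$variant_aa, "V")
  expect_true(all(out$native_aa != out$variant_aa))
})

test_that("raising the neutral identity cutoff never adds variants", {
  set.seed(3)
  human <- paste(sample(amino_acids(), 60, replace = TRUE), collapse = "")
  homs <- vapply(1:6, function(i) {
    h <- strsplit(human, "")[[1]]
    k <- sample(0:8, 1)
    if (k > 0) {
      at <- sample(60, k)
      h[at] <- vapply(at, function(j) sample(setdiff(amino_acids(), h[j]), 1),
                      character(1))
    }
    paste(h, collapse = "")
  }, character(1))
  m <- do.call(toy_msa, as.list(c(human, homs)))
  ns <- vapply(c(0.80, 0.90, 0.95, 0.99), function(idn) {
    cfg <- dataset_build_config(identity_min_neutral = idn)
    nrow(harvest_neutral_variants(m, cfg))
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("single-nucleotide reachability matches a brute-force codon scan", {
  # independent oracle: all codon pairs at Hamming distance 1
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  reach <- matrix(FALSE, 20, 20,
                  dimnames = list(amino_acids(), amino_acids()))
  split <- strsplit(codons, "")
  for (i in seq_along(codons)) {
    for (j in seq_along(codons)) {
      if (sum(split[[i]] != split[[j]]) == 1) {
        a1 <- code[[i]]; a2 <- code[[j]]
        if (a1 != a2 && a1 != "*" && a2 != "*") reach[a1, a2] <- TRUE
      }
    }
  }
  expect_true(reach["M", "V"])
  expect_false(reach["M", "P"])

  pairs <- expand.grid(a = amino_acids(), b = amino_acids(),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  rec <- variant_table("PTOY", pairs$a, seq_len(nrow(pairs)), pairs$b,
                       label = "neutral")
  kept <- filter_snv_reachable(rec)
  expect_identical(
    sort(paste(kept$native_aa, kept$variant_aa)),
    sort(paste(pairs$a, pairs$b)[reach[cbind(pairs$a, pairs$b)]]))
})

test_that("assemble_dataset unions filtered pathogenic and harvested neutral", {
  human <- paste(rep("A", 50), collapse = "")
  h <- strsplit(human, "")[[1]]
  h[c(3, 9, 17, 25, 33)] <- c("V", "L", "I", "T", "S")
  hom <- paste(h, collapse = "")  # 5 differences, identity 0.9 -> use 45/50
  patho <- variant_table("PTOY", "A", 1:30, "V", label = "pathogenic")
  cfg <- dataset_build_config(identity_min_neutral = 0.88)
  out <- assemble_dataset(patho, list(PTOY = toy_msa(human, hom)), cfg,
                          dataset_tag = "VSTOY")
  expect_identical(nrow(out), 35L)
  expect_identical(sum(out$label == "neutral"), 5L)
  expect_true(all(out$dataset_tag == "VSTOY"))

  # thres larger than any protein's count -> empty
  cfg2 <- dataset_build_config(thres = 99, identity_min_neutral = 0.88)
  expect_identical(nrow(assemble_dataset(patho,
                                         list(PTOY = toy_msa(human, hom)),
                                         cfg2)), 0L)

  # protein without an alignment lands in the skip report
  out3 <- assemble_dataset(patho, list(), cfg)
  expect_identical(attr(out3, "skip_report"), "PTOY")
  expect_identical(nrow(out3), 30L)

  # snv_only removes exactly the non-reachable substitutions
  cfg3 <- dataset_build_config(identity_min_neutral = 0.88, snv_only = TRUE)
  out4 <- assemble_dataset(patho, list(PTOY = toy_msa(human, hom)), cfg3)
  manual <- filter_snv_reachable(out)
  expect_setequal(variant_ids(out4), variant_ids(manual))
})
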