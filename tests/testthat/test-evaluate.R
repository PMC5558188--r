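test_that("the six measures match their defining formulas", {
  m <- compute_metrics(5, 5, 0, 0)
  expect_equal(m$mcc, 1)
  expect_equal(m$accuracy, 1)
  expect_identical(m$undefined, character(0))

  m2 <- compute_metrics(3, 4, 1, 2)
  expect_equal(m2$accuracy, 0.7)
  expect_equal(m2$mcc, 10 / sqrt(600))  # (3*4 - 1*2)/sqrt(5*5*4*6)
  expect_equal(m2$sensitivity, 3 / 5)
  expect_equal(m2$specificity, 4 / 5)
  expect_equal(m2$ppv, 3 / 4)
  expect_equal(m2$npv, 4 / 6)

  # all-pathogenic caller on balanced data
  m3 <- compute_metrics(10, 0, 10, 0)
  expect_equal(m3$sensitivity, 1)
  expect_equal(m3$specificity, 0)
  expect_true(is.na(m3$mcc))
  expect_true(all(c("mcc", "npv") %in% m3$undefined))
  expect_error(compute_metrics(0, 0, 0, 0), "empty")
  expect_error(compute_metrics(-1, 2, 3, 4), ">= 0")
})

test_that("compute_metrics agrees with a brute-force per-variant tally", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(4:60, 1)
    truth <- sample(c("pathogenic", "neutral"), n, replace = TRUE)
    call <- ifelse(runif(n) < 0.3, sample(c("pathogenic", "neutral"), n,
                                          replace = TRUE), truth)
    o <- oracle_metrics(truth, call)
    m <- compute_metrics(o$tp, o$tn, o$fp, o$fn)
    for (f in c("sensitivity", "specificity", "accuracy", "ppv", "npv",
                "mcc")) {
      expect_equal(m[[f]], o[[f]], info = f)
    }
  }
})

test_that("MCC is invariant under a simultaneous class swap", {
  set.seed(17)
  for (i in 1:50) {
    cnt <- sample(0:30, 4, replace = TRUE)
    if (sum(cnt) == 0) cnt[1] <- 1
    a <- compute_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    b <- compute_metrics(cnt[2], cnt[1], cnt[4], cnt[3])
    expect_equal(a$mcc, b$mcc)
  }
})

test_that("cross-validation partitions the data and pools test counts", {
  panel <- small_panel(seed = 21, n_proteins = 5, vpp = 60)
  part <- apply_coincidence_rule(panel$variants, c("SIFT", "PolyPhen2"))
  prdis <- panel$variants[part$prdis, ]
  plan <- cv_plan(n_replicas = 3, seeds = 0:2)
  cv <- cross_validate(prdis, c("SIFT", "PolyPhen2"),
                       training_config(epochs = 100), plan, keep_oof = TRUE)
  # pooled confusion counts cover every variant exactly once per replica
  for (r in seq_len(3)) {
    m <- cv$replicas[[r]]
    expect_equal(m$tp + m$tn + m$fp + m$fn, nrow(prdis))
    expect_identical(nrow(cv$oof[[r]]), nrow(prdis))
  }
  # the averaged MCC lies within the replica range
  expect_gte(cv$mean$mcc, min(cv$mcc))
  expect_lte(cv$mean$mcc, max(cv$mcc))
  # input table is untouched by the whole procedure
  expect_error(cross_validate(prdis[prdis$label == "pathogenic", ],
                              c("SIFT", "PolyPhen2"),
                              training_config(epochs = 10), plan),
               "both classes")
})

test_that("cross-validation never leaks SMOTE rows into test folds", {
  # test-fold class counts must match the raw data regardless of the
  # training-fold rebalancing; with pooled counts this is the identity
  # tp + fn = #pathogenic and tn + fp = #neutral
  panel <- small_panel(seed = 22)
  part <- apply_coincidence_rule(panel$variants, c("SIFT", "CADD"))
  prdis <- panel$variants[part$prdis, ]
  before <- prdis
  cv <- cross_validate(prdis, c("SIFT", "CADD"),
                       training_config(epochs = 60),
                       cv_plan(n_replicas = 2, seeds = 5:6))
  for (m in cv$replicas) {
    expect_equal(m$tp + m$fn, sum(prdis$label == "pathogenic"))
    expect_equal(m$tn + m$fp, sum(prdis$label == "neutral"))
  }
  expect_identical(prdis, before)
})

test_that("the coincidence rule is scored on the agreement set only", {
  # hand-built 8-variant fixture: 4 agree (3 right, 1 wrong),
  # 2 disagree, 2 without output
  rec <- toy_records(
    p1 = c(0.9, 0.9, 0.1, 0.9, 0.9, 0.1, NA, 0.6),
    p2 = c(0.8, 0.7, 0.2, 0.8, 0.2, 0.9, 0.5, NA),
    label = c("pathogenic", "pathogenic", "neutral", "neutral",
              "pathogenic", "pathogenic", "neutral", "neutral"))
  part <- apply_coincidence_rule(rec, c("P1", "P2"), toy_specs())
  m <- evaluate_coincidence_rule(part, rec)
  expect_identical(c(m$tp, m$tn, m$fp, m$fn), c(2, 1, 1, 0))
  expect_equal(m$coverage, 0.5)

  # both predictors always right -> MCC 1
  rec2 <- toy_records(p1 = c(0.9, 0.1, 0.9, 0.1),
                      p2 = c(0.8, 0.2, 0.7, 0.3),
                      label = c("pathogenic", "neutral", "pathogenic",
                                "neutral"))
  part2 <- apply_coincidence_rule(rec2, c("P1", "P2"), toy_specs())
  expect_equal(evaluate_coincidence_rule(part2, rec2)$mcc, 1)

  # empty agreement set -> undefined metrics, flagged
  rec3 <- toy_records(p1 = c(0.9, 0.1), p2 = c(0.1, 0.9),
                      label = c("pathogenic", "neutral"))
  part3 <- apply_coincidence_rule(rec3, c("P1", "P2"), toy_specs())
  m3 <- evaluate_coincidence_rule(part3, rec3)
  expect_true(is.na(m3$mcc))
  expect_equal(m3$coverage, 0)
})

test_that("reference predictors are scored over their covered variants", {
  rec <- toy_records(p1 = c(0.9, 0.1, 0.9, NA, 0.2),
                     p2 = runif(5),
                     label = c("pathogenic", "neutral", "neutral",
                               "pathogenic", "pathogenic"))
  m <- evaluate_reference_predictor(rec, toy_specs()$P1)
  # covered: rows 1,2,3,5 -> tp 1, tn 1, fp 1, fn 1
  expect_identical(c(m$tp, m$tn, m$fp, m$fn), c(1, 1, 1, 1))
  expect_equal(m$coverage, 0.8)
  expect_equal(m$accuracy, 0.5)

  rec$P1 <- NA_character_
  m2 <- evaluate_reference_predictor(rec, toy_specs()$P1)
  expect_equal(m2$coverage, 0)
  expect_true(is.na(m2$mcc))
})

test_that("hybrid confusion counts are the sum of the two parts", {
  rec <- toy_records(
    p1 = c(0.9, 0.9, 0.1, 0.9, 0.1, 0.9, NA),
    p2 = c(0.8, 0.7, 0.2, 0.1, 0.9, 0.2, 0.5),
    label = c("pathogenic", "neutral", "neutral",
              "pathogenic", "neutral", "pathogenic", "neutral"))
  part <- apply_coincidence_rule(rec, c("P1", "P2"), toy_specs())
  calls <- setNames(c("pathogenic", "pathogenic", "neutral"),
                    variant_ids(rec)[part$prdis])
  m <- evaluate_hybrid(part, rec, prdis_calls = calls)
  expect_equal(m$tp, m$agree_counts$tp + m$prdis_counts$tp)
  expect_equal(m$tn, m$agree_counts$tn + m$prdis_counts$tn)
  expect_equal(m$fp, m$agree_counts$fp + m$prdis_counts$fp)
  expect_equal(m$fn, m$agree_counts$fn + m$prdis_counts$fn)
  expect_equal(m$coverage, (length(part$agree) + length(part$prdis)) / 7)
  # agree part: rows 1,2,3 -> tp 1, fp 1, tn 1; prdis rows 4,5,6 with
  # the supplied calls -> tp 1, fp 1, fn 1
  expect_identical(c(m$tp, m$tn, m$fp, m$fn), c(2, 1, 2, 1))
  # pooled MCC equals a direct computation on the pooled table
  direct <- compute_metrics(2, 1, 2, 1)
  expect_equal(m$mcc, direct$mcc)
})

test_that("hybrid scoring with a model requires a matching combination", {
  panel <- small_panel(seed = 23)
  part <- apply_coincidence_rule(panel$variants, c("SIFT", "PolyPhen2"))
  prdis <- panel$variants[part$prdis, ]
  fm <- build_feature_matrix(prdis, c("SIFT", "PolyPhen2"), "scores_only")
  bal <- smote_oversample(fm$x, fm$y, seed = 1)
  model <- train_specific_model(bal$x, bal$y, training_config(epochs = 60),
                                combination = c("SIFT", "PolyPhen2"))
  m <- evaluate_hybrid(part, panel$variants, model = model)
  expect_equal(m$tp + m$tn + m$fp + m$fn,
               length(part$agree) + length(part$prdis))
  wrong <- model
  wrong$combination <- c("SIFT", "CADD")
  expect_error(evaluate_hybrid(part, panel$variants, model = wrong),
               "does not match")
  expect_error(evaluate_hybrid(part, panel$variants), "exactly one")
})
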