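test_that("feature matrices have the documented column layout", {
  panel <- small_panel()
  part <- apply_coincidence_rule(panel$variants, c("SIFT", "PONP2"))
  prdis <- panel$variants[part$prdis, ]
  fm <- build_feature_matrix(prdis, c("SIFT", "PONP2"), "scores_only")
  expect_identical(colnames(fm$x), c("SIFT", "PONP2"))
  expect_identical(nrow(fm$x), nrow(prdis))
  expect_true(all(fm$y %in% c(0, 1)))
  # categorical predictor encoded as the 0/1 binarised call
  expect_true(all(fm$x[, "PONP2"] %in% c(0, 1)))

  part3 <- apply_coincidence_rule(panel$variants,
                                  c("SIFT", "PolyPhen2", "CADD"))
  fm3 <- build_feature_matrix(panel$variants[part3$prdis, ],
                              c("SIFT", "PolyPhen2", "CADD"),
                              "scores_plus_bio")
  expect_identical(colnames(fm3$x),
                   c("SIFT", "PolyPhen2", "CADD",
                     "blosum62", "entropy", "pssm_nat"))

  fm0 <- build_feature_matrix(panel$variants[0, ], c("SIFT", "PolyPhen2"),
                              "scores_only")
  expect_identical(nrow(fm0$x), 0L)

  # missing output in a would-be PRDIS row is an invariant violation
  bad <- toy_records(p1 = c(0.2, NA), p2 = c(0.9, 0.3),
                     label = c("pathogenic", "neutral"))
  expect_error(build_feature_matrix(bad, c("P1", "P2"), "scores_only",
                                    toy_specs()),
               "missing P1")
})

test_that("SMOTE reaches exact parity without touching original rows", {
  set.seed(5)
  x <- rbind(matrix(rnorm(20), ncol = 2),            # 10 majority
             matrix(rnorm(10, mean = 4), ncol = 2))  # 5 minority
  y <- c(rep(0, 10), rep(1, 5))
  out <- smote_oversample(x, y, k = 3, seed = 9)
  expect_identical(sum(out$y == 0), sum(out$y == 1))
  expect_identical(sum(out$y == 0), 10L)
  expect_identical(out$x[1:15, ], x)  # originals byte-identical
  expect_identical(attr(out, "n_synthetic"), 5L)
})

test_that("every synthetic SMOTE row lies on a minority-minority segment", {
  set.seed(6)
  x <- rbind(matrix(rnorm(60), ncol = 2),
             matrix(rnorm(16, mean = 3), ncol = 2))
  y <- c(rep(0, 30), rep(1, 8))
  out <- smote_oversample(x, y, k = 5, seed = 2)
  minority <- x[y == 1, , drop = FALSE]
  synth <- out$x[-seq_len(nrow(x)), , drop = FALSE]
  on_segment <- function(s) {
    for (i in seq_len(nrow(minority))) {
      for (j in seq_len(nrow(minority))) {
        if (i == j) next
        a <- minority[i, ]; b <- minority[j, ]
        d <- b - a
        if (sum(d^2) == 0) next
        u <- sum((s - a) * d) / sum(d^2)
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            sqrt(sum((s - (a + u * d))^2)) < 1e-8) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, on_segment)))
})

test_that("degenerate SMOTE geometry and k clamping behave as documented", {
  x <- rbind(matrix(rnorm(20), ncol = 2),
             matrix(rep(c(5, 5), each = 3), ncol = 2))  # identical minority
  y <- c(rep(0, 10), rep(1, 3))
  expect_warning(out <- smote_oversample(x, y, k = 5, seed = 1), "clamped")
  synth <- out$x[-seq_len(13), , drop = FALSE]
  expect_true(all(synth[, 1] == 5 & synth[, 2] == 5))
  expect_error(smote_oversample(x, rep(0, 13)), "two classes")
})

test_that("the no-hidden network separates linearly separable data", {
  set.seed(8)
  n <- 60
  # classes separated by a margin of 2 along the first axis
  x <- cbind(a = c(runif(n, -3, -1), runif(n, 1, 3)), b = rnorm(2 * n))
  y <- rep(c(0, 1), each = n)
  model <- train_specific_model(x, y, training_config(epochs = 200))
  scores <- predict(model, x)
  expect_true(all(scores >= 0 & scores <= 1))
  acc <- mean((scores >= 0.5) == (y == 1))
  expect_equal(acc, 1)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(10)
  x <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0, 1), 50)
  cfg <- training_config(architecture = "hidden_2", epochs = 50, seed = 3)
  m1 <- train_specific_model(x, y, cfg)
  m2 <- train_specific_model(x, y, cfg)
  expect_identical(m1$weights, m2$weights)
  cfg2 <- cfg; cfg2$seed <- 4L
  m3 <- train_specific_model(x, y, cfg2)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("prediction applies the decision threshold with ties pathogenic", {
  set.seed(11)
  x <- matrix(rnorm(100), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0, 1), 25)
  model <- train_specific_model(x, y, training_config(epochs = 20))
  out <- predict(model, x, type = "both")
  expect_identical(out$call, ifelse(out$score >= 0.5, "pathogenic", "neutral"))
  # prediction is pure: repeated application gives identical scores
  expect_identical(predict(model, x), predict(model, x))
  expect_error(train_specific_model(cbind(x, c = NA), y),
               "non-finite")
})

test_that("models survive a JSON round trip", {
  panel <- small_panel()
  part <- apply_coincidence_rule(panel$variants, c("SIFT", "PolyPhen2"))
  prdis <- panel$variants[part$prdis, ]
  fm <- build_feature_matrix(prdis, c("SIFT", "PolyPhen2"), "scores_plus_bio")
  bal <- smote_oversample(fm$x, fm$y, seed = 0)
  model <- train_specific_model(
    bal$x, bal$y,
    training_config(architecture = "hidden_2",
                    feature_set = "scores_plus_bio", epochs = 100),
    combination = c("SIFT", "PolyPhen2"))
  path <- withr::local_tempfile(fileext = ".json")
  write_specific_model(model, path)
  back <- read_specific_model(path)
  expect_equal(predict(back, prdis), predict(model, prdis), tolerance = 1e-12)
})
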