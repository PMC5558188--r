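# Performance assessment: the six standard measures, replicated
# stratified cross-validation, scoring of the coincidence rule and of
# the reference predictors, and the hybrid rule-plus-model predictor.

#' Compute the six performance measures from a confusion table
#'
#' TP and FN count correctly and incorrectly identified pathogenic
#' variants; TN and FP count correctly and incorrectly identified
#' neutral variants.  Measures: sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), accuracy (TP+TN)/total, PPV TP/(TP+FP), NPV TN/(TN+FN),
#' and the Matthews correlation coefficient
#' (TP·TN − FP·FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)).
#' A measure with a zero denominator is reported as `NA` and listed in
#' the report's `undefined` field — never silently coerced to 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts (total > 0).
#' @param coverage Optional fraction of the initial variant set that
#'   received a prediction.
#' @return A `metrics_report` object.
#' @export
compute_metrics <- function(tp, tn, fp, fn, coverage = NA_real_) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || anyNA(counts)) stop("confusion counts must be >= 0")
  total <- sum(counts)
  if (total == 0) stop("empty confusion table")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  mcc_den <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  rep <- list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    accuracy = (tp + tn) / total,
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(mcc_den),
    coverage = coverage)
  rep$undefined <- names(which(vapply(
    rep[c("sensitivity", "specificity", "ppv", "npv", "mcc")],
    is.na, logical(1))))
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d\n", x$tp, x$tn, x$fp, x$fn))
  m <- unlist(x[c("sensitivity", "specificity", "accuracy", "ppv", "npv",
                  "mcc", "coverage")])
  print(round(m, digits))
  if (length(x$undefined)) {
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

# confusion counts from truth/call character vectors
confusion_counts <- function(truth, call) {
  keep <- !is.na(truth) & !is.na(call) & truth != "unlabeled"
  truth <- truth[keep]; call <- call[keep]
  list(tp = sum(truth == "pathogenic" & call == "pathogenic"),
       tn = sum(truth == "neutral" & call == "neutral"),
       fp = sum(truth == "neutral" & call == "pathogenic"),
       fn = sum(truth == "pathogenic" & call == "neutral"))
}

metrics_from_calls <- function(truth, call, coverage = NA_real_) {
  cc <- confusion_counts(truth, call)
  compute_metrics(cc$tp, cc$tn, cc$fp, cc$fn, coverage = coverage)
}

#' Cross-validation plan
#'
#' @param n_folds Number of folds (default 5).
#' @param n_replicas Number of repetitions of the whole procedure
#'   (default 10; results are averaged to smooth out fluctuations).
#' @param stratified Stratify folds by class label?
#' @param seeds One RNG seed per replica.
#' @return A `cv_plan` object.
#' @export
cv_plan <- function(n_folds = 5L, n_replicas = 10L, stratified = TRUE,
                    seeds = seq_len(n_replicas) - 1L) {
  stopifnot(n_folds >= 2, n_replicas >= 1, length(seeds) == n_replicas)
  structure(list(n_folds = as.integer(n_folds),
                 n_replicas = as.integer(n_replicas),
                 stratified = isTRUE(stratified),
                 seeds = as.integer(seeds)),
            class = "cv_plan")
}

# fold assignment; stratification guarantees both classes per fold
# whenever each class has >= n_folds members
.make_folds <- function(y, n_folds, stratified) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < n_folds) {
        stop("class ", cls, " has fewer members (", length(idx),
             ") than folds (", n_folds, "): stratification impossible")
      }
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds),
                                                    length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
  }
  fold
}

#' Replicated stratified cross-validation of a specific predictor
#'
#' For each replica: draw a stratified k-fold split; for each fold,
#' rebalance the k−1 training folds with SMOTE (test folds are never
#' touched), train the network, and score the held-out fold.  Replica
#' metrics are computed from the pooled test-fold confusion counts
#' (micro-averaging); the final report is the mean over replicas, with
#' undefined replica values excluded and counted.
#'
#' @param records Labelled variant table (typically the PRDIS rows of
#'   one combination); both classes must be present.
#' @param combination Predictor names whose scores feed the model.
#' @param config A [training_config()].
#' @param plan A [cv_plan()].
#' @param specs Binarisation registry.
#' @param keep_oof Keep per-variant out-of-fold predictions?
#' @return A `cv_result`: `mean` (averaged measures), `replicas`
#'   (per-replica `metrics_report`s), `mcc` (per-replica MCC vector),
#'   `n`, and optionally `oof`.
#' @export
cross_validate <- function(records, combination, config = training_config(),
                           plan = cv_plan(), specs = default_predictor_specs(),
                           keep_oof = FALSE) {
  fm <- build_feature_matrix(records, combination, config$feature_set, specs)
  y <- fm$y
  if (anyNA(y)) stop("cross-validation needs labelled records")
  if (length(unique(y)) < 2) stop("both classes must be present")

  replicas <- vector("list", plan$n_replicas)
  oof <- if (keep_oof) vector("list", plan$n_replicas)
  ids <- variant_ids(records)
  for (r in seq_len(plan$n_replicas)) {
    rs <- plan$seeds[r]
    set.seed(rs)
    fold <- .make_folds(y, plan$n_folds, plan$stratified)
    counts <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    calls <- character(length(y))
    scores <- numeric(length(y))
    for (f in seq_len(plan$n_folds)) {
      test <- fold == f
      sub_seed <- (rs * 131L + f) %% .Machine$integer.max
      bal <- smote_oversample(fm$x[!test, , drop = FALSE], y[!test],
                              k = config$smote_k, seed = sub_seed)
      cfg <- config
      cfg$seed <- sub_seed
      model <- train_specific_model(bal$x, bal$y, cfg,
                                    combination = combination,
                                    feature_set = config$feature_set,
                                    specs = specs)
      pred <- predict(model, fm$x[test, , drop = FALSE], type = "both")
      scores[test] <- pred$score
      calls[test] <- pred$call
      truth <- ifelse(y[test] == 1, "pathogenic", "neutral")
      cc <- confusion_counts(truth, pred$call)
      counts <- counts + unlist(cc)
    }
    replicas[[r]] <- compute_metrics(counts["tp"], counts["tn"],
                                     counts["fp"], counts["fn"],
                                     coverage = 1)
    if (keep_oof) {
      oof[[r]] <- data.frame(variant_id = ids, truth = ifelse(y == 1,
                                                              "pathogenic",
                                                              "neutral"),
                             score = scores, call = calls,
                             stringsAsFactors = FALSE)
    }
  }

  measures <- c("sensitivity", "specificity", "accuracy", "ppv", "npv", "mcc")
  mean_rep <- list(tp = mean(vapply(replicas, `[[`, numeric(1), "tp")),
                   tn = mean(vapply(replicas, `[[`, numeric(1), "tn")),
                   fp = mean(vapply(replicas, `[[`, numeric(1), "fp")),
                   fn = mean(vapply(replicas, `[[`, numeric(1), "fn")))
  n_undef <- integer(0)
  for (m in measures) {
    vals <- vapply(replicas, `[[`, numeric(1), m)
    mean_rep[[m]] <- mean(vals, na.rm = TRUE)
    n_undef[m] <- sum(is.na(vals))
  }
  mean_rep$coverage <- 1
  mean_rep$undefined_replicas <- n_undef[n_undef > 0]
  out <- list(mean = mean_rep, replicas = replicas,
              mcc = vapply(replicas, `[[`, numeric(1), "mcc"),
              n = nrow(fm$x), combination = combination,
              feature_set = config$feature_set,
              architecture = config$architecture, plan = plan)
  if (keep_oof) out$oof <- oof
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-replica %d-fold CV [%s | %s | %s], n = %d\n",
              x$plan$n_replicas, x$plan$n_folds,
              paste(x$combination, collapse = "+"), x$feature_set,
              x$architecture, x$n))
  cat(sprintf("  mean MCC %.3f (replica sd %.3f), mean accuracy %.3f\n",
              x$mean$mcc, stats::sd(x$mcc), x$mean$accuracy))
  invisible(x)
}

#' Score the coincidence rule itself
#'
#' Confusion counts are computed on the agreement set only, using the
#' agreed call as the prediction; coverage is the agreement fraction
#' of the initial variant set.
#'
#' @param partition A [apply_coincidence_rule()] result.
#' @param records The variant table the partition was built from
#'   (labels are taken from it).
#' @return A `metrics_report`.
#' @export
evaluate_coincidence_rule <- function(partition, records) {
  stopifnot(inherits(partition, "partition_result"))
  if (length(partition$agree) == 0) {
    rep <- list(tp = 0, tn = 0, fp = 0, fn = 0,
                sensitivity = NA_real_, specificity = NA_real_,
                accuracy = NA_real_, ppv = NA_real_, npv = NA_real_,
                mcc = NA_real_, coverage = 0,
                undefined = c("sensitivity", "specificity", "accuracy",
                              "ppv", "npv", "mcc"))
    class(rep) <- "metrics_report"
    return(rep)
  }
  truth <- records$label[partition$agree]
  metrics_from_calls(truth, partition$agree_call,
                     coverage = length(partition$agree) / partition$n_total)
}

#' Score one reference predictor on its own
#'
#' Metrics are computed over every labelled variant for which the
#' predictor gives output; coverage is reported against the full set.
#'
#' @param records Labelled variant table.
#' @param spec A [predictor_spec()] for the predictor to score.
#' @return A `metrics_report`.
#' @export
evaluate_reference_predictor <- function(records, spec) {
  validate_variant_table(records)
  calls <- binarize(records[[spec$name]], spec)
  covered <- sum(!is.na(calls))
  if (covered == 0) {
    rep <- list(tp = 0, tn = 0, fp = 0, fn = 0,
                sensitivity = NA_real_, specificity = NA_real_,
                accuracy = NA_real_, ppv = NA_real_, npv = NA_real_,
                mcc = NA_real_, coverage = 0,
                undefined = c("sensitivity", "specificity", "accuracy",
                              "ppv", "npv", "mcc"))
    class(rep) <- "metrics_report"
    return(rep)
  }
  metrics_from_calls(records$label, calls,
                     coverage = covered / nrow(records))
}

#' Score the hybrid rule-plus-model predictor
#'
#' Agreement-set variants take the agreed call; disagreement-set
#' (PRDIS) variants take the specific model's call (or externally
#' supplied calls, e.g. out-of-fold predictions from
#' [cross_validate()]).  Confusion counts are pooled over both parts;
#' no-output variants are excluded from the metrics but reduce
#' coverage, which equals (|agree| + |prdis|) / initial.
#'
#' @param partition A [apply_coincidence_rule()] result.
#' @param records The variant table the partition was built from.
#' @param model A `specific_model` trained for the same combination
#'   (on variants disjoint from those scored, or via CV).
#' @param prdis_calls Alternative to `model`: named character vector of
#'   calls keyed by variant id, covering the PRDIS members.
#' @return A `metrics_report` with the additional fields
#'   `agree_counts` and `prdis_counts` (per-part confusion lists).
#' @export
evaluate_hybrid <- function(partition, records, model = NULL,
                            prdis_calls = NULL) {
  stopifnot(inherits(partition, "partition_result"))
  if (is.null(model) == is.null(prdis_calls)) {
    stop("supply exactly one of 'model' or 'prdis_calls'")
  }
  prdis_rows <- records[partition$prdis, , drop = FALSE]
  if (!is.null(model)) {
    if (!setequal(model$combination, partition$combination)) {
      stop("model combination (", paste(model$combination, collapse = "+"),
           ") does not match partition (",
           paste(partition$combination, collapse = "+"), ")")
    }
    p_calls <- if (nrow(prdis_rows) > 0) {
      predict(model, prdis_rows, type = "call")
    } else {
      character(0)
    }
  } else {
    ids <- partition$ids[partition$prdis]
    if (!all(ids %in% names(prdis_calls))) {
      stop("prdis_calls does not cover every PRDIS variant")
    }
    p_calls <- unname(prdis_calls[ids])
  }
  agree_cc <- confusion_counts(records$label[partition$agree],
                               partition$agree_call)
  prdis_cc <- confusion_counts(prdis_rows$label, p_calls)
  rep <- compute_metrics(agree_cc$tp + prdis_cc$tp, agree_cc$tn + prdis_cc$tn,
                         agree_cc$fp + prdis_cc$fp, agree_cc$fn + prdis_cc$fn,
                         coverage = (length(partition$agree) +
                                       length(partition$prdis)) /
                           partition$n_total)
  rep$agree_counts <- agree_cc
  rep$prdis_counts <- prdis_cc
  rep
}
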