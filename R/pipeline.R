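# End-to-end orchestration: for each predictor combination, partition
# the variant set, cross-validate the specific predictors (two feature
# sets x two architectures), score the coincidence rule, and score the
# hybrid rule-plus-model predictor from out-of-fold predictions.

#' Run the full specific-predictor workflow
#'
#' For every requested combination: apply the coincidence rule; score
#' the rule on the agreement set; for each feature set and
#' architecture, run replicated stratified cross-validation on the
#' PRDIS set; and score the hybrid predictor by pooling the agreement
#' calls with the model's out-of-fold PRDIS predictions (averaged over
#' replicas).  A failing combination is recorded and the sweep
#' continues.
#'
#' @param records Labelled, feature-annotated variant table.
#' @param combinations List of predictor-name vectors; `NULL` sweeps
#'   all combinations of the registered reference predictors present
#'   in `records`.
#' @param feature_sets,architectures Model variants to train.
#' @param plan A [cv_plan()]; its seeds derive from `seed` when `NULL`.
#' @param specs Binarisation registry.
#' @param config Base [training_config()]; architecture/feature set
#'   are overridden per model variant.
#' @param seed Top-level seed from which all stage seeds derive.
#' @param min_prdis Skip model training for PRDIS sets smaller than
#'   this (the rule is still scored).
#' @param out_dir Optional directory for `results.csv`,
#'   `partitions.csv` and `run_log.json`.
#' @param verbose Emit progress messages?
#' @return A `pipeline_result`: `results` (one row per combination x
#'   feature set x architecture), `partitions` (per-combination
#'   report), `rule` and `hybrid` metric tables, and `failures`.
#' @export
run_full_pipeline <- function(records, combinations = NULL,
                              feature_sets = c("scores_only",
                                               "scores_plus_bio"),
                              architectures = c("no_hidden", "hidden_2"),
                              plan = NULL, specs = default_predictor_specs(),
                              config = training_config(), seed = 0L,
                              min_prdis = 40L, out_dir = NULL,
                              verbose = FALSE) {
  validate_variant_table(records)
  if (is.null(combinations)) {
    avail <- predictor_columns(records, names(specs))
    combinations <- enumerate_combinations(intersect(reference_predictors(),
                                                     avail))
  }
  if (is.null(plan)) {
    plan <- cv_plan(seeds = seed * 100L + seq_len(10L) - 1L)
  }

  results <- list(); rule_rows <- list(); hybrid_rows <- list()
  part_rows <- list(); failures <- list()
  say <- function(...) if (verbose) message(sprintf(...))

  metric_cols <- function(m) {
    data.frame(tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
               sensitivity = m$sensitivity, specificity = m$specificity,
               accuracy = m$accuracy, ppv = m$ppv, npv = m$npv,
               mcc = m$mcc, coverage = m$coverage, stringsAsFactors = FALSE)
  }

  for (comb in combinations) {
    key <- paste(comb, collapse = "+")
    res <- tryCatch({
      part <- apply_coincidence_rule(records, comb, specs)
      part_rows[[key]] <- partition_report(part)
      rule <- evaluate_coincidence_rule(part, records)
      rule_rows[[key]] <- cbind(combination = key, metric_cols(rule))
      prdis_rows <- records[part$prdis, , drop = FALSE]
      n_prdis <- nrow(prdis_rows)
      both <- length(unique(prdis_rows$label[prdis_rows$label !=
                                               "unlabeled"])) == 2
      say("[%s] agree %d, prdis %d, no_output %d", key,
          length(part$agree), n_prdis, length(part$no_output))
      if (n_prdis < min_prdis || !both) {
        failures[[key]] <- paste0("PRDIS too small or single-class (n = ",
                                  n_prdis, "); models skipped")
      } else {
      for (fs in feature_sets) {
        for (arch in architectures) {
          cfg <- config
          cfg$feature_set <- fs
          cfg$architecture <- arch
          cfg$hidden_nodes <- if (arch == "hidden_2") 2L else 0L
          cv <- cross_validate(prdis_rows, comb, cfg, plan, specs,
                               keep_oof = TRUE)
          results[[paste(key, fs, arch)]] <- cbind(
            data.frame(combination = key, feature_set = fs,
                       architecture = arch, n_prdis = n_prdis,
                       mcc_sd = stats::sd(cv$mcc),
                       stringsAsFactors = FALSE),
            metric_cols(cv$mean))
          # hybrid: agreement calls + out-of-fold PRDIS calls, averaged
          # over replicas
          hyb <- lapply(cv$oof, function(oof) {
            calls <- setNames(oof$call, oof$variant_id)
            evaluate_hybrid(part, records, prdis_calls = calls)
          })
          hyb_mean <- colMeans(do.call(rbind, lapply(hyb, function(h) {
            unlist(h[c("tp", "tn", "fp", "fn", "sensitivity", "specificity",
                       "accuracy", "ppv", "npv", "mcc", "coverage")])
          })), na.rm = TRUE)
          hybrid_rows[[paste(key, fs, arch)]] <- cbind(
            data.frame(combination = key, feature_set = fs,
                       architecture = arch, stringsAsFactors = FALSE),
            as.data.frame(as.list(hyb_mean)))
          say("  %s/%s: cv mcc %.3f, hybrid mcc %.3f", fs, arch,
              cv$mean$mcc, hyb_mean[["mcc"]])
        }
      }
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) failures[[key]] <- res
  }

  bind <- function(rows) {
    if (length(rows) == 0) return(data.frame())
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  out <- list(results = bind(results), partitions = bind(part_rows),
              rule = bind(rule_rows), hybrid = bind(hybrid_rows),
              failures = failures, seed = seed, plan = plan)
  class(out) <- "pipeline_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(out$partitions, file.path(out_dir, "partitions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed,
           plan = unclass(plan),
           r_version = as.character(getRversion()),
           failures = failures),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Specific-predictor pipeline sweep:",
      nrow(x$partitions), "combination(s),",
      nrow(x$results), "model variant(s)\n")
  if (nrow(x$results) > 0) {
    best <- x$results[which.max(x$results$mcc), ]
    cat(sprintf("  best CV MCC %.3f [%s | %s | %s]\n", best$mcc,
                best$combination, best$feature_set, best$architecture))
  }
  if (length(x$failures)) {
    cat("  skipped/failed:", paste(names(x$failures), collapse = ", "), "\n")
  }
  invisible(x)
}
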