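# Binarisation of heterogeneous predictor outputs and the
# coincidence-rule tri-partition (AGREE / PRDIS / NO-OUTPUT).
#
# The clinical coincidence rule counts computational evidence only when
# every applied predictor agrees; disagreement discards it.  Here the
# rule is turned into a partition of a variant set for any predictor
# combination: variants with unanimous calls (AGREE), variants with at
# least two differing calls and full output (PRDIS), and variants where
# at least one predictor gave no output (NO-OUTPUT).

#' Describe how one predictor's raw output is binarised
#'
#' Two modes: `score_threshold` compares a numeric score against a
#' cutoff (ties resolved as pathogenic), `categorical_map` translates
#' categorical calls through an explicit map.  A score-mode spec may
#' also carry a `category_map` as a fallback for tables that report
#' categorical calls instead of scores.
#'
#' @param name Predictor name.
#' @param mode `"score_threshold"` or `"categorical_map"`.
#' @param threshold Numeric cutoff (score mode).
#' @param direction `"higher_is_pathogenic"` or `"lower_is_pathogenic"`.
#' @param category_map Named character vector mapping raw calls to
#'   `"pathogenic"`, `"neutral"` or `"missing"`.
#' @return A `predictor_spec` object.
#' @export
predictor_spec <- function(name,
                           mode = c("score_threshold", "categorical_map"),
                           threshold = NA_real_,
                           direction = c("higher_is_pathogenic",
                                         "lower_is_pathogenic"),
                           category_map = NULL) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (mode == "score_threshold" && !is.finite(threshold)) {
    stop("score_threshold mode needs a finite threshold")
  }
  if (mode == "categorical_map" &&
      (is.null(category_map) || is.null(names(category_map)))) {
    stop("categorical_map mode needs a named category_map")
  }
  if (!is.null(category_map)) {
    bad <- !category_map %in% c("pathogenic", "neutral", "missing")
    if (any(bad)) {
      stop("category_map values must be pathogenic/neutral/missing, got: ",
           paste(unique(category_map[bad]), collapse = ", "))
    }
  }
  structure(list(name = name, mode = mode, threshold = threshold,
                 direction = direction, category_map = category_map),
            class = "predictor_spec")
}

#' Default binarisation registry for the five reference predictors
#'
#' SIFT: score, pathogenic at or below 0.05.  PolyPhen-2 (HDIV): score,
#' pathogenic at or above 0.5.  CADD (phred): score, pathogenic at or
#' above 15.  PON-P2 and MutationTaster2: categorical maps (PON-P2's
#' `"unknown"` class is treated as no output).  Score-mode specs carry
#' categorical fallbacks so that tables reporting calls instead of
#' scores binarise without extra configuration.  All entries are
#' overridable; these are conventional cutoffs, not fitted ones.
#'
#' @return Named list of [predictor_spec()] objects.
#' @export
default_predictor_specs <- function() {
  generic_map <- c(pathogenic = "pathogenic", deleterious = "pathogenic",
                   damaging = "pathogenic", neutral = "neutral",
                   tolerated = "neutral", benign = "neutral")
  list(
    SIFT = predictor_spec("SIFT", "score_threshold", threshold = 0.05,
                          direction = "lower_is_pathogenic",
                          category_map = generic_map),
    PolyPhen2 = predictor_spec("PolyPhen2", "score_threshold", threshold = 0.5,
                               direction = "higher_is_pathogenic",
                               category_map = c(generic_map,
                                                probably_damaging = "pathogenic",
                                                possibly_damaging = "pathogenic")),
    PONP2 = predictor_spec("PONP2", "categorical_map",
                           category_map = c(generic_map, unknown = "missing")),
    CADD = predictor_spec("CADD", "score_threshold", threshold = 15,
                          direction = "higher_is_pathogenic",
                          category_map = generic_map),
    MutationTaster2 = predictor_spec(
      "MutationTaster2", "categorical_map",
      category_map = c(generic_map,
                       disease_causing = "pathogenic",
                       disease_causing_automatic = "pathogenic",
                       polymorphism = "neutral",
                       polymorphism_automatic = "neutral")))
}

#' Read a binarisation registry from YAML
#'
#' Each top-level key names a predictor; fields mirror the arguments of
#' [predictor_spec()].  Predictors absent from the file keep their
#' [default_predictor_specs()] entry.
#'
#' @param path YAML file.
#' @return Named list of [predictor_spec()] objects.
#' @export
read_predictor_specs <- function(path) {
  cfg <- yaml::read_yaml(path)
  specs <- default_predictor_specs()
  for (nm in names(cfg)) {
    e <- cfg[[nm]]
    specs[[nm]] <- predictor_spec(
      name = nm,
      mode = e$mode %||% "score_threshold",
      threshold = e$threshold %||% NA_real_,
      direction = e$direction %||% "higher_is_pathogenic",
      category_map = if (!is.null(e$category_map)) unlist(e$category_map))
  }
  specs
}

#' Binarise raw predictor output
#'
#' Missing values propagate.  In score mode the output is pathogenic
#' when the score reaches the threshold from the pathogenic side, with
#' ties resolved as pathogenic; values that do not parse as numbers
#' fall back to the spec's `category_map`.  A raw call absent from the
#' map is an error (never silently missing).
#'
#' @param x Character (or numeric) vector of raw outputs; `NA` =
#'   missing.
#' @param spec A [predictor_spec()].
#' @return Character vector with values `"pathogenic"`, `"neutral"` or
#'   `NA` (missing).
#' @export
binarize <- function(x, spec) {
  stopifnot(inherits(spec, "predictor_spec"))
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  have <- !is.na(x)
  if (!any(have)) return(out)

  map_categories <- function(vals) {
    mapped <- spec$category_map[vals]
    unknown <- is.na(mapped)
    if (any(unknown)) {
      stop("predictor '", spec$name, "': call(s) not in category map: ",
           paste(unique(vals[unknown]), collapse = ", "))
    }
    ifelse(mapped == "missing", NA_character_, unname(mapped))
  }

  if (spec$mode == "score_threshold") {
    num <- suppressWarnings(as.numeric(x[have]))
    is_num <- !is.na(num)
    res <- rep(NA_character_, sum(have))
    if (any(is_num)) {
      patho <- if (spec$direction == "higher_is_pathogenic") {
        num[is_num] >= spec$threshold
      } else {
        num[is_num] <= spec$threshold
      }
      res[is_num] <- ifelse(patho, "pathogenic", "neutral")
    }
    if (any(!is_num)) {
      if (is.null(spec$category_map)) {
        stop("predictor '", spec$name, "': non-numeric output(s) ",
             paste(unique(x[have][!is_num]), collapse = ", "),
             " and no category map")
      }
      res[!is_num] <- map_categories(x[have][!is_num])
    }
    out[have] <- res
  } else {
    out[have] <- map_categories(x[have])
  }
  out
}

# n x k matrix of binary calls for a combination
.call_matrix <- function(records, combination, specs) {
  absent <- setdiff(combination, names(specs))
  if (length(absent) > 0) {
    stop("no predictor spec registered for: ", paste(absent, collapse = ", "))
  }
  absent <- setdiff(combination, names(records))
  if (length(absent) > 0) {
    stop("variant table lacks predictor column(s): ",
         paste(absent, collapse = ", "))
  }
  calls <- vapply(combination,
                  function(p) binarize(records[[p]], specs[[p]]),
                  character(nrow(records)))
  matrix(calls, nrow = nrow(records), ncol = length(combination),
         dimnames = list(NULL, combination))
}

#' Partition a variant set with the coincidence rule
#'
#' For a combination of at least two predictors, every variant falls in
#' exactly one of three sets: `agree` (all predictors gave output and
#' the binary calls are unanimous; the agreed call is recorded),
#' `prdis` (full output, calls differ) or `no_output` (at least one
#' predictor gave no output).
#'
#' @param records A variant table.
#' @param combination Character vector of at least two predictor names.
#' @param specs Binarisation registry, see [default_predictor_specs()].
#' @return A `partition_result`: list with the `combination`, integer
#'   row indices `agree`, `prdis`, `no_output`, the `agree_call`
#'   vector (parallel to `agree`), per-variant ids, and `n_total`.
#' @export
apply_coincidence_rule <- function(records, combination,
                                   specs = default_predictor_specs()) {
  if (length(combination) < 2) {
    stop("the coincidence rule needs at least two predictors")
  }
  validate_variant_table(records)
  ids <- variant_ids(records)
  if (nrow(records) == 0) {
    res <- list(combination = combination, agree = integer(0),
                prdis = integer(0), no_output = integer(0),
                agree_call = character(0), ids = ids, n_total = 0L)
    class(res) <- "partition_result"
    return(res)
  }
  calls <- .call_matrix(records, combination, specs)
  any_missing <- rowSums(is.na(calls)) > 0
  unanimous <- !any_missing &
    rowSums(calls == calls[, 1]) == ncol(calls)
  no_output <- which(any_missing)
  agree <- which(unanimous)
  prdis <- which(!any_missing & !unanimous)
  res <- list(combination = combination,
              agree = agree, prdis = prdis, no_output = no_output,
              agree_call = calls[agree, 1],
              ids = ids, n_total = nrow(records))
  class(res) <- "partition_result"
  res
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Coincidence-rule partition [", paste(x$combination, collapse = " + "),
      "]\n", sep = "")
  cat(sprintf("  total %d: agree %d, prdis %d, no_output %d\n",
              x$n_total, length(x$agree), length(x$prdis),
              length(x$no_output)))
  invisible(x)
}

#' Enumerate predictor combinations
#'
#' All subsets of the predictor set with at least `min_size` members,
#' ordered by size and then lexicographically.  For the five reference
#' predictors this yields the 26 combinations studied.
#'
#' @param predictors Predictor names.
#' @param min_size Smallest subset size (>= 2; the coincidence rule is
#'   undefined for a single predictor).
#' @return List of character vectors.
#' @export
enumerate_combinations <- function(predictors = reference_predictors(),
                                   min_size = 2L) {
  if (min_size < 2L) stop("min_size must be >= 2")
  if (length(predictors) < min_size) return(list())
  out <- list()
  for (k in seq(min_size, length(predictors))) {
    subsets <- combn(sort(predictors), k, simplify = FALSE)
    keys <- vapply(subsets, paste, character(1), collapse = "\r")
    out <- c(out, subsets[order(keys)])
  }
  out
}

#' Summarise a partition
#'
#' Counts and percentages of the variants that entered the study
#' (agree + prdis), agreed, disagreed, and lacked output, relative to
#' the initial variant count.
#'
#' @param result A [apply_coincidence_rule()] partition.
#' @param total Initial variant count (defaults to the partition's).
#' @return A one-row data.frame of counts and percentages.
#' @export
partition_report <- function(result, total = result$n_total) {
  stopifnot(inherits(result, "partition_result"))
  if (total < result$n_total) stop("total smaller than partitioned set")
  n_agree <- length(result$agree)
  n_prdis <- length(result$prdis)
  n_miss <- length(result$no_output)
  pct <- function(k) if (total == 0) 0 else 100 * k / total
  data.frame(combination = paste(result$combination, collapse = "+"),
             total = total, entered = n_agree + n_prdis,
             agree = n_agree, prdis = n_prdis, no_output = n_miss,
             entered_pct = pct(n_agree + n_prdis), agree_pct = pct(n_agree),
             prdis_pct = pct(n_prdis), no_output_pct = pct(n_miss),
             stringsAsFactors = FALSE)
}
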