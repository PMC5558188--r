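# The central data container: a variant table.
#
# One row per amino-acid substitution.  Fixed columns first, then one
# character column per registered predictor holding the tool's raw
# output verbatim ("0.02", "disease_causing", ...) with NA for missing
# output.  Binarisation into pathogenic/neutral calls happens in the
# partition layer, never at read time.

#' Names of the five reference predictors
#'
#' The reference tools whose outputs the pipeline consumes.  `PolyPhen2`
#' refers to the HumDiv-trained (HDIV) version throughout; the HVAR
#' output may be carried as an extra column but is not part of this set.
#'
#' @return Character vector of predictor names.
#' @export
reference_predictors <- function() {
  c("SIFT", "PolyPhen2", "PONP2", "CADD", "MutationTaster2")
}

.fixed_columns <- function() {
  c("protein_id", "native_aa", "position", "variant_aa", "label",
    "blosum62", "pssm_nat", "entropy", "dataset_tag")
}

#' Construct an empty variant table
#'
#' @param predictors Predictor column names to include.
#' @return A zero-row data.frame with the canonical column layout.
#' @export
empty_variant_table <- function(predictors = reference_predictors()) {
  df <- data.frame(
    protein_id = character(0), native_aa = character(0),
    position = integer(0), variant_aa = character(0),
    label = character(0), blosum62 = numeric(0), pssm_nat = numeric(0),
    entropy = numeric(0), dataset_tag = character(0),
    stringsAsFactors = FALSE)
  for (p in predictors) df[[p]] <- character(0)
  df
}

#' Build a variant table from vectors
#'
#' Convenience constructor that recycles scalar arguments, fills
#' unspecified feature columns with `NA` and validates the result.
#'
#' @param protein_id,native_aa,position,variant_aa Core substitution fields.
#' @param label One of `"pathogenic"`, `"neutral"`, `"unlabeled"`.
#' @param dataset_tag Free-form dataset label (e.g. `"VS228"`).
#' @param blosum62,pssm_nat,entropy Optional precomputed features.
#' @param predictor_outputs Named list of character vectors, one per
#'   predictor column; `NA` marks missing output.
#' @param predictors Registry of predictor columns to materialise.
#' @return A validated variant table (data.frame).
#' @export
variant_table <- function(protein_id, native_aa, position, variant_aa,
                          label = "unlabeled", dataset_tag = "other",
                          blosum62 = NA_real_, pssm_nat = NA_real_,
                          entropy = NA_real_, predictor_outputs = list(),
                          predictors = reference_predictors()) {
  n <- max(length(protein_id), length(position))
  df <- data.frame(
    protein_id = rep_len(as.character(protein_id), n),
    native_aa = rep_len(toupper(as.character(native_aa)), n),
    position = rep_len(as.integer(position), n),
    variant_aa = rep_len(toupper(as.character(variant_aa)), n),
    label = rep_len(as.character(label), n),
    blosum62 = rep_len(as.numeric(blosum62), n),
    pssm_nat = rep_len(as.numeric(pssm_nat), n),
    entropy = rep_len(as.numeric(entropy), n),
    dataset_tag = rep_len(as.character(dataset_tag), n),
    stringsAsFactors = FALSE)
  for (p in union(predictors, names(predictor_outputs))) {
    v <- predictor_outputs[[p]]
    df[[p]] <- if (is.null(v)) NA_character_ else rep_len(as.character(v), n)
  }
  validate_variant_table(df)
}

#' Validate a variant table
#'
#' Checks the structural invariants: required columns present, positions
#' >= 1, native and variant residues distinct, labels drawn from the
#' allowed set.
#'
#' @param records A variant table.
#' @return The table, invisibly unchanged, or an error.
#' @export
validate_variant_table <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.fixed_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0) return(records)
  if (any(records$position < 1L, na.rm = TRUE)) {
    stop("variant positions must be >= 1")
  }
  same <- records$native_aa == records$variant_aa
  if (any(same, na.rm = TRUE)) {
    stop("native and variant residue identical in row(s): ",
         paste(utils::head(which(same), 5), collapse = ", "))
  }
  bad_label <- !records$label %in% c("pathogenic", "neutral", "unlabeled")
  if (any(bad_label)) {
    stop("unknown label(s): ", paste(unique(records$label[bad_label]), collapse = ", "))
  }
  records
}

#' Stable per-variant identifiers
#'
#' @param records A variant table.
#' @return Character vector `"<protein>:<native><position><variant>"`.
#' @export
variant_ids <- function(records) {
  paste0(records$protein_id, ":", records$native_aa,
         records$position, records$variant_aa)
}

# predictor columns actually present in a table
predictor_columns <- function(records, predictors = reference_predictors()) {
  intersect(predictors, names(records))
}
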