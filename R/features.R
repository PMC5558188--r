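# MSA-derived biological features: Shannon entropy of the variant
# column, the native-residue PSSM log-ratio, and the BLOSUM62 element
# of the replacement (the latter lives in substitution.R).
#
# Conventions (documented in the methods vignette): gaps and
# non-standard residues are excluded from all counts; logarithms are
# natural by default with base 2 available as a switch; a Jeffreys-type
# pseudocount of 0.5 keeps the PSSM ratio finite on sparse alignments
# and 0 reproduces the plain frequency ratio.

.residue_counts <- function(chars) {
  chars <- chars[chars %in% amino_acids()]
  counts <- table(factor(chars, levels = amino_acids()))
  v <- as.vector(counts)
  names(v) <- amino_acids()
  v
}

#' Residue counts of one alignment column
#'
#' @param m An [msa()] object.
#' @param position 1-based position in the ungapped human reference
#'   sequence.
#' @return Named integer vector of counts over the 20 amino acids
#'   (gaps and non-standard residues excluded).
#' @export
msa_column_counts <- function(m, position) {
  cols <- human_column_map(m)
  if (position < 1L || position > length(cols)) {
    stop("position ", position, " outside the human sequence (length ",
         length(cols), ")")
  }
  mat <- msa_matrix(m)
  .residue_counts(mat[, cols[position]])
}

#' Residue counts over a whole alignment
#'
#' @param m An [msa()] object.
#' @return Named integer vector of counts over the 20 amino acids.
#' @export
msa_residue_counts <- function(m) {
  .residue_counts(unlist(strsplit(m$seqs, "", fixed = TRUE), use.names = FALSE))
}

#' Shannon entropy of a residue composition
#'
#' Computes \eqn{-\sum_i p_i \log p_i} over the amino acids present in a
#' column, where \eqn{p_i} are the relative frequencies.  A fully
#' conserved column has entropy 0; the uniform composition over the 20
#' amino acids attains the maximum, \eqn{\log 20}.
#'
#' @param column_counts Either a named count vector (as returned by
#'   [msa_column_counts()]) or a character vector of residues.
#' @param base Logarithm base; `exp(1)` (nats, default) or 2 (bits).
#' @return Non-negative entropy value.
#' @export
shannon_entropy <- function(column_counts, base = exp(1)) {
  if (is.character(column_counts)) {
    column_counts <- .residue_counts(column_counts)
  }
  total <- sum(column_counts)
  if (total == 0) stop("empty column: entropy undefined")
  p <- column_counts[column_counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Native-residue PSSM log-ratio
#'
#' The position-specific scoring matrix element for the native amino
#' acid: \eqn{\log(f_{nat,i} / f_{nat,MSA})}, where \eqn{f_{nat,i}} is
#' the native residue's frequency in the variant's alignment column and
#' \eqn{f_{nat,MSA}} its frequency over the whole alignment.  With
#' `pseudocount > 0` both frequencies are smoothed as
#' \eqn{(n + c) / (N + 20c)}.
#'
#' @param native_aa 1-letter code of the native residue.
#' @param column_counts Named residue counts of the variant column.
#' @param alignment_counts Named residue counts of the whole alignment.
#' @param pseudocount Non-negative smoothing constant `c`; with 0 the
#'   plain frequency ratio is used and a zero frequency is an error.
#' @param base Logarithm base (natural by default).
#' @return The log-ratio (dimensionless).
#' @export
pssm_nat <- function(native_aa, column_counts, alignment_counts,
                     pseudocount = 0.5, base = exp(1)) {
  native_aa <- toupper(native_aa)
  if (!native_aa %in% amino_acids()) {
    stop("non-standard native residue: ", native_aa)
  }
  smooth <- function(counts) {
    n_nat <- if (native_aa %in% names(counts)) counts[[native_aa]] else 0
    (n_nat + pseudocount) / (sum(counts) + 20 * pseudocount)
  }
  f_col <- smooth(column_counts)
  f_msa <- smooth(alignment_counts)
  if (f_col == 0 || f_msa == 0) {
    stop("native residue absent and pseudocount 0: pssm_nat not finite")
  }
  log(f_col / f_msa, base = base)
}

#' Annotate variants with the three biological features
#'
#' Fills the `blosum62`, `entropy` and `pssm_nat` columns of a variant
#' table from each protein's alignment.  Rows that already carry all
#' three values are left untouched unless `recompute = TRUE`.  Rows
#' whose protein has no alignment, whose position falls outside the
#' human sequence, or whose human residue disagrees with the table's
#' native residue are left `NA` and collected in the
#' `"feature_errors"` attribute of the result.
#'
#' @param records A variant table.
#' @param msas Named list of [msa()] objects, keyed by protein id.
#' @param recompute Recompute features that are already present?
#' @param pseudocount,base Passed to [pssm_nat()] / [shannon_entropy()].
#' @return The annotated variant table; skipped rows are described in
#'   `attr(, "feature_errors")`.
#' @export
annotate_features <- function(records, msas, recompute = FALSE,
                              pseudocount = 0.5, base = exp(1)) {
  validate_variant_table(records)
  todo <- if (recompute) {
    rep(TRUE, nrow(records))
  } else {
    is.na(records$blosum62) | is.na(records$pssm_nat) | is.na(records$entropy)
  }
  errors <- data.frame(row = integer(0), protein_id = character(0),
                       reason = character(0), stringsAsFactors = FALSE)
  fail <- function(i, reason) {
    errors[nrow(errors) + 1L, ] <<- list(i, records$protein_id[i], reason)
  }

  for (pid in unique(records$protein_id[todo])) {
    rows <- which(todo & records$protein_id == pid)
    m <- msas[[pid]]
    if (is.null(m)) {
      for (i in rows) fail(i, "no alignment for protein")
      next
    }
    msa_counts <- msa_residue_counts(m)
    hseq <- strsplit(human_sequence(m), "", fixed = TRUE)[[1]]
    mat <- msa_matrix(m)
    cols <- human_column_map(m)
    for (i in rows) {
      pos <- records$position[i]
      if (pos > length(hseq)) {
        fail(i, "position beyond human sequence")
        next
      }
      if (hseq[pos] != records$native_aa[i]) {
        fail(i, "native residue does not match human sequence")
        next
      }
      counts <- .residue_counts(mat[, cols[pos]])
      if (sum(counts) == 0) {
        fail(i, "empty alignment column")
        next
      }
      records$blosum62[i] <- blosum62_element(records$native_aa[i],
                                              records$variant_aa[i])
      records$entropy[i] <- shannon_entropy(counts, base = base)
      records$pssm_nat[i] <- pssm_nat(records$native_aa[i], counts, msa_counts,
                                      pseudocount = pseudocount, base = base)
    }
  }
  attr(records, "feature_errors") <- errors
  records
}
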