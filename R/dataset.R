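# Dataset assembly: the per-protein variant-count filter, the
# homology-based neutral-variant model, and the optional restriction to
# substitutions reachable by a single nucleotide change.

#' Configuration for dataset assembly
#'
#' @param thres Minimum number of pathogenic variants a protein must
#'   contribute for its variants to be retained (default 30).
#' @param identity_min_neutral Minimum pairwise identity to the human
#'   sequence for a homolog to contribute neutral variants (default
#'   0.95).
#' @param identity_min_keep Homologs below this identity are dropped
#'   from the alignment before harvesting (default 0.40); a no-op when
#'   the supplied alignment was already pruned.
#' @param snv_only Restrict to substitutions reachable by a single
#'   nucleotide change?
#' @param count_label Which variants count towards `thres`:
#'   `"pathogenic"` (default; the filter exists to limit the
#'   neutral-to-pathogenic imbalance) or `"all"`.
#' @return A `dataset_build_config` list.
#' @export
dataset_build_config <- function(thres = 30L, identity_min_neutral = 0.95,
                                 identity_min_keep = 0.40, snv_only = FALSE,
                                 count_label = c("pathogenic", "all")) {
  count_label <- match.arg(count_label)
  thres <- as.integer(thres)
  if (is.na(thres) || thres < 0L) stop("thres must be a non-negative integer")
  if (!(identity_min_keep >= 0 && identity_min_keep <= identity_min_neutral &&
        identity_min_neutral <= 1)) {
    stop("need 0 <= identity_min_keep <= identity_min_neutral <= 1")
  }
  structure(list(thres = thres,
                 identity_min_neutral = identity_min_neutral,
                 identity_min_keep = identity_min_keep,
                 snv_only = isTRUE(snv_only),
                 count_label = count_label),
            class = "dataset_build_config")
}

#' Drop variants of sparsely represented proteins
#'
#' Removes the pathogenic variants of every protein contributing fewer
#' than `thres` counted variants.  Proteins at or above the threshold
#' keep all their records.
#'
#' @param records A variant table.
#' @param thres Minimum variant count per protein.
#' @param count_label Count only `"pathogenic"` variants (default) or
#'   `"all"` variants towards the threshold.
#' @return The filtered variant table.
#' @export
filter_by_protein_count <- function(records, thres = 30L,
                                    count_label = c("pathogenic", "all")) {
  count_label <- match.arg(count_label)
  thres <- as.integer(thres)
  if (is.na(thres) || thres < 0L) stop("thres must be a non-negative integer")
  if (nrow(records) == 0 || thres == 0L) return(records)
  counted <- if (count_label == "pathogenic") {
    records$label == "pathogenic"
  } else {
    rep(TRUE, nrow(records))
  }
  counts <- table(records$protein_id[counted])
  below <- names(counts)[counts < thres]
  below <- union(below, setdiff(records$protein_id, names(counts)))
  drop <- records$label == "pathogenic" & records$protein_id %in% below
  records[!drop, , drop = FALSE]
}

#' Pairwise sequence identity between two aligned sequences
#'
#' Identity is the fraction of identical residues over the columns
#' where neither sequence has a gap.
#'
#' @param seq_a,seq_b Aligned residue strings of equal length.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("aligned lengths differ")
  ok <- a != "-" & b != "-"
  if (!any(ok)) stop("no mutually gap-free columns: identity undefined")
  sum(a[ok] == b[ok]) / sum(ok)
}

#' Harvest neutral variants from close homologs
#'
#' Implements the homology-based neutral model: every deviation from
#' the human sequence observed in a homolog at or above
#' `identity_min_neutral` pairwise identity yields one neutral variant
#' (native = human residue, variant = homolog residue, position in
#' ungapped human coordinates).  Only mutually gap-free columns with
#' standard residues are considered, and identical substitutions seen
#' in several homologs are collapsed to one record.
#'
#' @param m An [msa()] object containing the human reference.
#' @param config A [dataset_build_config()].
#' @param protein_id Protein identifier for the emitted records.
#' @param dataset_tag Dataset tag for the emitted records.
#' @return A variant table of neutral variants.
#' @export
harvest_neutral_variants <- function(m, config = dataset_build_config(),
                                     protein_id = m$ids[m$human_index],
                                     dataset_tag = "other") {
  stopifnot(inherits(m, "msa"))
  hrow <- m$human_index
  hum <- strsplit(m$seqs[hrow], "", fixed = TRUE)[[1]]
  hpos <- cumsum(hum != "-")  # ungapped human position per column
  out <- list()
  for (j in seq_along(m$seqs)) {
    if (j == hrow) next
    idn <- pairwise_identity(m$seqs[hrow], m$seqs[j])
    if (idn < config$identity_min_keep) next
    if (idn < config$identity_min_neutral) next
    hom <- strsplit(m$seqs[j], "", fixed = TRUE)[[1]]
    diff <- which(hum != "-" & hom != "-" & hum != hom &
                    hum %in% amino_acids() & hom %in% amino_acids())
    if (length(diff) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      native_aa = hum[diff], position = hpos[diff], variant_aa = hom[diff],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty_variant_table())
  dev <- unique(do.call(rbind, out))
  variant_table(protein_id = protein_id, native_aa = dev$native_aa,
                position = dev$position, variant_aa = dev$variant_aa,
                label = "neutral", dataset_tag = dataset_tag)
}

#' Keep substitutions reachable by a single nucleotide change
#'
#' A substitution is kept when at least one codon of the native amino
#' acid can be converted into a codon of the variant amino acid by a
#' single nucleotide replacement (standard genetic code; protein-level
#' data carry no codon context, so all native codons are considered).
#'
#' @param records A variant table.
#' @return The filtered variant table.
#' @export
filter_snv_reachable <- function(records) {
  validate_variant_table(records)
  if (nrow(records) == 0) return(records)
  bad <- !(records$native_aa %in% amino_acids()) |
    !(records$variant_aa %in% amino_acids())
  if (any(bad)) {
    stop("non-standard residue in row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  reach <- snv_reachability()
  keep <- reach[cbind(records$native_aa, records$variant_aa)]
  records[keep, , drop = FALSE]
}

#' Assemble a pathogenic + neutral variant dataset
#'
#' Applies the per-protein count filter to the pathogenic records, then
#' harvests neutral variants from each retained protein's alignment,
#' and optionally restricts the union to single-nucleotide-reachable
#' substitutions.  Proteins with pathogenic variants but no alignment
#' are skipped (reported in the `"skip_report"` attribute, not fatal).
#'
#' @param pathogenic Variant table of pathogenic records.
#' @param msas Named list of [msa()] objects keyed by protein id.
#' @param config A [dataset_build_config()].
#' @param dataset_tag Tag stored on every emitted record.
#' @param verbose Print per-protein class counts to stderr?
#' @return A variant table; `attr(, "skip_report")` lists proteins
#'   without alignments, `attr(, "build_log")` the per-protein counts.
#' @export
assemble_dataset <- function(pathogenic, msas, config = dataset_build_config(),
                             dataset_tag = "VS228", verbose = FALSE) {
  validate_variant_table(pathogenic)
  kept <- filter_by_protein_count(pathogenic, config$thres, config$count_label)
  proteins <- unique(kept$protein_id)
  skip <- character(0)
  pieces <- list(kept)
  for (pid in proteins) {
    m <- msas[[pid]]
    if (is.null(m)) {
      skip <- c(skip, pid)
      next
    }
    pieces[[length(pieces) + 1L]] <-
      harvest_neutral_variants(m, config, protein_id = pid,
                               dataset_tag = dataset_tag)
  }
  pieces <- pieces[vapply(pieces, nrow, integer(1)) > 0]
  out <- if (length(pieces) == 0) empty_variant_table() else {
    cols <- Reduce(union, lapply(pieces, names))
    pieces <- lapply(pieces, function(p) {
      for (cl in setdiff(cols, names(p))) p[[cl]] <- NA_character_
      p[, cols, drop = FALSE]
    })
    do.call(rbind, pieces)
  }
  if (nrow(out) > 0) out$dataset_tag <- dataset_tag
  if (config$snv_only && nrow(out) > 0) out <- filter_snv_reachable(out)
  rownames(out) <- NULL
  log <- if (nrow(out) > 0) {
    as.data.frame(table(protein_id = out$protein_id, label = out$label),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(protein_id = character(0), label = character(0),
               Freq = integer(0), stringsAsFactors = FALSE)
  }
  if (verbose) {
    message(sprintf("assembled %d variants (%d pathogenic, %d neutral) over %d proteins; %d protein(s) skipped",
                    nrow(out), sum(out$label == "pathogenic"),
                    sum(out$label == "neutral"),
                    length(unique(out$protein_id)), length(skip)))
  }
  attr(out, "skip_report") <- skip
  attr(out, "build_log") <- log
  out
}
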