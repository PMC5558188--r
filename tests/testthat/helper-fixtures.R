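# Shared fixtures: tiny in-code variant tables, toy predictor
# registries and an independent metrics oracle.

# two generic score predictors (threshold 0.5, higher = pathogenic)
toy_specs <- function() {
  list(
    P1 = predictor_spec("P1", "score_threshold", threshold = 0.5,
                        direction = "higher_is_pathogenic"),
    P2 = predictor_spec("P2", "score_threshold", threshold = 0.5,
                        direction = "higher_is_pathogenic"))
}

# variant table with two toy predictor columns; NA = missing output
toy_records <- function(p1, p2, label, protein = "PTOY") {
  n <- length(label)
  variant_table(protein_id = protein, native_aa = "A",
                position = seq_len(n), variant_aa = "V", label = label,
                predictor_outputs = list(P1 = as.character(p1),
                                         P2 = as.character(p2)),
                predictors = c("P1", "P2"))
}

# small alignment: human plus explicit homolog strings
toy_msa <- function(human, ..., ids = NULL) {
  seqs <- c(human, ...)
  if (is.null(ids)) ids <- c("HUMAN", paste0("HOM", seq_along(seqs[-1])))
  msa(ids = ids[seq_along(seqs)], seqs = seqs, human_index = 1L)
}

# independent metrics oracle: per-variant brute-force tally and the
# defining ratios, written without reference to compute_metrics()
oracle_metrics <- function(truth, call) {
  tp <- sum(truth == "pathogenic" & call == "pathogenic")
  tn <- sum(truth == "neutral" & call == "neutral")
  fp <- sum(truth == "neutral" & call == "pathogenic")
  fn <- sum(truth == "pathogenic" & call == "neutral")
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  den <- as.numeric(tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
       accuracy = (tp + tn) / length(truth),
       ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
       mcc = if (den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(den))
}

# small informative synthetic panel shared by several test files
small_panel <- function(seed = 11, n_proteins = 4, vpp = 50) {
  generate_panel(synthetic_panel_spec(n_proteins = n_proteins,
                                      variants_per_protein = vpp,
                                      seed = seed))
}
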