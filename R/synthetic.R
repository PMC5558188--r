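# Synthetic variant panels with the statistical structure the pipeline
# assumes: binary labels, per-predictor scores correlated with the
# label at controllable strength, controllable missingness, and MSAs
# whose column conservation is informative about pathogenicity.
#
# Generative model per variant: a latent signal z_j = s_j * label +
# N(0, sigma_j) for predictor j, squashed monotonically onto the
# tool's native scale with the midpoint s_j/2 mapped onto the
# binarisation cutoff.  The implied binary call is therefore
# pathogenic iff z_j >= s_j/2, so both per-class error rates equal
# Phi(-s_j / (2 sigma_j)) and closed-form partition expectations are
# available (expected_partition_fractions).  No claim is made that
# this matches real predictor score distributions.

#' Generative model for one synthetic predictor
#'
#' @param name Predictor name (must have a binarisation spec).
#' @param signal Latent class separation `s` (0 = uninformative).
#' @param noise_sd Latent noise standard deviation.
#' @param missing_rate Probability of missing output, in \[0, 1).
#' @param kind `"score"` emits a numeric score on the tool's native
#'   scale; `"categorical"` emits a categorical call.
#' @param squash For score kind: function mapping the centred latent
#'   value (z − s/2) onto the native scale.  The default depends on
#'   the predictor name (SIFT-like inverted \[0,1\] scale, CADD-like
#'   phred scale, plain \[0,1\] otherwise).
#' @param categories For categorical kind: the (pathogenic, neutral)
#'   raw call strings.
#' @return A `synthetic_predictor_model`.
#' @export
synthetic_predictor_model <- function(name, signal = 1.7, noise_sd = 1,
                                      missing_rate = 0,
                                      kind = c("score", "categorical"),
                                      squash = NULL,
                                      categories = c("pathogenic", "neutral")) {
  kind <- match.arg(kind)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (kind == "score" && is.null(squash)) {
    squash <- switch(name,
      SIFT = function(d) 0.1 * plogis(-d),       # [0, 0.1], low = pathogenic
      CADD = function(d) 30 * plogis(d),         # phred-like [0, 30]
      function(d) plogis(d))                     # [0, 1]
  }
  structure(list(name = name, signal = signal, noise_sd = noise_sd,
                 missing_rate = missing_rate, kind = kind, squash = squash,
                 categories = categories),
            class = "synthetic_predictor_model")
}

#' Default synthetic models for the five reference predictors
#'
#' Signal strengths give individual accuracies in the realistic
#' 80–90% band, strongest for PON-P2; missing rates emulate the very
#' different coverages of the tools (near-complete for SIFT and
#' PolyPhen-2, roughly half for MutationTaster2 and PON-P2).
#' PON-P2 and MutationTaster2 emit categorical calls, the other three
#' numeric scores, matching the default binarisation registry.
#'
#' @param signal Common multiplier on the per-predictor signal
#'   strengths (1 = default panel; 0 = uninformative scores).
#' @return Named list of [synthetic_predictor_model()]s.
#' @export
default_synthetic_models <- function(signal = 1) {
  list(
    SIFT = synthetic_predictor_model("SIFT", signal * 1.7, 1, 0.03, "score"),
    PolyPhen2 = synthetic_predictor_model("PolyPhen2", signal * 1.8, 1, 0.01,
                                          "score"),
    PONP2 = synthetic_predictor_model("PONP2", signal * 2.4, 1, 0.45,
                                      "categorical",
                                      categories = c("pathogenic", "neutral")),
    CADD = synthetic_predictor_model("CADD", signal * 1.6, 1, 0.15, "score"),
    MutationTaster2 = synthetic_predictor_model(
      "MutationTaster2", signal * 1.5, 1, 0.45, "categorical",
      categories = c("disease_causing", "polymorphism")))
}

#' Parameters of a synthetic variant panel
#'
#' Defaults emulate the study conditions of the training set the
#' pipeline targets: a pathogenic prevalence near 0.26 (15,723 of
#' 59,442), tens of variants per protein, and alignments deep enough
#' for stable column statistics.
#'
#' @param n_proteins Number of proteins.
#' @param variants_per_protein Variants per protein.
#' @param prevalence Fraction of pathogenic variants.
#' @param models Named list of [synthetic_predictor_model()]s.
#' @param msa_depth Sequences per alignment (beyond the human
#'   reference).
#' @param n_close_homologs How many of those are close homologs
#'   (≥ 95% identity, usable for neutral harvesting).
#' @param conserved_fraction Fraction of alignment columns that are
#'   conserved (low entropy).
#' @param conserved_bias Probability that a pathogenic variant sits in
#'   a conserved column (0.5 = no preference).
#' @param seed RNG seed; the whole panel is reproducible from it.
#' @return A `synthetic_panel_spec`.
#' @export
synthetic_panel_spec <- function(n_proteins = 10L, variants_per_protein = 60L,
                                 prevalence = 0.26,
                                 models = default_synthetic_models(),
                                 msa_depth = 40L, n_close_homologs = 5L,
                                 conserved_fraction = 0.5,
                                 conserved_bias = 0.8, seed = 0L) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  stopifnot(n_proteins >= 1, variants_per_protein >= 1,
            msa_depth >= n_close_homologs,
            conserved_fraction >= 0, conserved_fraction <= 1,
            conserved_bias >= 0, conserved_bias <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 variants_per_protein = as.integer(variants_per_protein),
                 prevalence = prevalence, models = models,
                 msa_depth = as.integer(msa_depth),
                 n_close_homologs = as.integer(n_close_homologs),
                 conserved_fraction = conserved_fraction,
                 conserved_bias = conserved_bias, seed = as.integer(seed)),
            class = "synthetic_panel_spec")
}

# one synthetic protein family: human sequence + homologs with
# column-dependent substitution rates
.generate_msa <- function(pid, length, conserved, spec) {
  aa <- amino_acids()
  human <- sample(aa, length, replace = TRUE)
  sub_rate <- ifelse(conserved, 0.01, 0.35)
  # column-specific alternative residues keep variable-column entropy
  # moderate rather than uniform over 20 residues
  alts <- replicate(length, sample(aa, 3), simplify = FALSE)
  n_hom <- spec$msa_depth
  seqs <- character(n_hom + 1L)
  seqs[1] <- paste(human, collapse = "")
  for (i in seq_len(n_hom)) {
    close <- i <= spec$n_close_homologs
    rate <- if (close) pmin(sub_rate, 0.02) else sub_rate
    mut <- runif(length) < rate
    s <- human
    if (any(mut)) {
      s[mut] <- vapply(which(mut), function(j) {
        pick <- setdiff(alts[[j]], human[j])
        if (length(pick) == 0) sample(setdiff(aa, human[j]), 1) else sample(pick, 1)
      }, character(1))
    }
    seqs[i + 1L] <- paste(s, collapse = "")
  }
  msa(ids = c(pid, paste0(pid, "_hom", seq_len(n_hom))), seqs = seqs,
      human_index = 1L)
}

#' Generate a synthetic variant panel
#'
#' Draws labels, per-predictor outputs and per-protein alignments from
#' a [synthetic_panel_spec()], then annotates the three biological
#' features from the generated alignments.  Pathogenic variants are
#' placed preferentially in conserved (low-entropy) columns and biased
#' towards non-conservative replacements (negative BLOSUM62), so the
#' biological features carry signal; predictor scores carry signal
#' through the latent model.  Fully reproducible under the spec seed.
#'
#' @param spec A [synthetic_panel_spec()].
#' @return `list(variants = variant table, msas = named list of msa)`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_panel_spec"))
  set.seed(spec$seed)
  aa <- amino_acids()
  all_rows <- list()
  msas <- list()
  for (pi in seq_len(spec$n_proteins)) {
    pid <- sprintf("SYNP%03d", pi)
    L <- spec$variants_per_protein + 20L
    conserved <- runif(L) < spec$conserved_fraction
    if (!any(conserved)) conserved[sample.int(L, 1)] <- TRUE
    if (all(conserved)) conserved[sample.int(L, 1)] <- FALSE
    m <- .generate_msa(pid, L, conserved, spec)
    msas[[pid]] <- m
    human <- strsplit(m$seqs[1], "", fixed = TRUE)[[1]]

    n_v <- spec$variants_per_protein
    label <- rbinom(n_v, 1, spec$prevalence)
    # position choice: pathogenic biased to conserved columns
    pos <- integer(n_v)
    pool_c <- which(conserved)
    pool_v <- which(!conserved)
    avail <- rep(TRUE, L)
    for (i in order(label, decreasing = TRUE)) {
      want_c <- if (label[i] == 1) {
        runif(1) < spec$conserved_bias
      } else {
        runif(1) < 1 - spec$conserved_bias
      }
      cand <- if (want_c) pool_c[avail[pool_c]] else pool_v[avail[pool_v]]
      if (length(cand) == 0) cand <- which(avail)
      pos[i] <- if (length(cand) == 1) cand else sample(cand, 1)
      avail[pos[i]] <- FALSE
    }
    native <- human[pos]
    # replacement residue: pathogenic biased to non-conservative swaps
    pick_variant <- function(nat, patho) {
      scores <- .blosum62[nat, setdiff(aa, nat)]
      harsh <- names(scores)[scores <= 0]
      mild <- names(scores)[scores > 0]
      prefer <- if (patho) harsh else mild
      other <- if (patho) mild else harsh
      pool <- if (length(prefer) > 0 && runif(1) < 0.7) prefer
              else if (length(other) > 0) other else prefer
      if (length(pool) == 1) pool else sample(pool, 1)
    }
    varaa <- vapply(seq_len(n_v),
                    function(i) pick_variant(native[i], label[i] == 1),
                    character(1))

    outputs <- list()
    for (mod in spec$models) {
      z <- mod$signal * label + rnorm(n_v, 0, mod$noise_sd)
      d <- z - mod$signal / 2
      raw <- if (mod$kind == "score") {
        formatC(mod$squash(d), digits = 6, format = "g")
      } else {
        ifelse(d >= 0, mod$categories[1], mod$categories[2])
      }
      raw[runif(n_v) < mod$missing_rate] <- NA_character_
      outputs[[mod$name]] <- raw
    }

    all_rows[[pi]] <- variant_table(
      protein_id = pid, native_aa = native, position = pos,
      variant_aa = varaa,
      label = ifelse(label == 1, "pathogenic", "neutral"),
      dataset_tag = "synthetic", predictor_outputs = outputs,
      predictors = names(spec$models))
  }
  variants <- do.call(rbind, all_rows)
  rownames(variants) <- NULL
  variants <- annotate_features(variants, msas)
  list(variants = variants, msas = msas)
}

#' Closed-form partition expectations for a synthetic panel
#'
#' Under the latent generative model the binary call of predictor `j`
#' is wrong with probability `e_j = pnorm(-s_j / (2 sigma_j))` in both
#' classes, independently across predictors, and output is missing
#' with probability `m_j`.  Hence, for a combination C:
#' no-output fraction `1 − prod(1 − m_j)`; agreement fraction
#' `prod(1 − m_j) · (prod(1 − e_j) + prod(e_j))`; disagreement is the
#' remainder.  Used as the independent oracle for partition tests.
#'
#' @param spec A [synthetic_panel_spec()].
#' @param combination Predictor names (subset of the spec's models).
#' @return Named numeric vector `c(agree, prdis, no_output)`.
#' @export
expected_partition_fractions <- function(spec, combination) {
  mods <- spec$models[combination]
  if (any(vapply(mods, is.null, logical(1)))) {
    stop("combination names absent from spec$models")
  }
  e <- vapply(mods, function(m) {
    if (m$noise_sd == 0) 0 else pnorm(-m$signal / (2 * m$noise_sd))
  }, numeric(1))
  miss <- vapply(mods, `[[`, numeric(1), "missing_rate")
  p_out <- prod(1 - miss)
  p_agree <- p_out * (prod(1 - e) + prod(e))
  c(agree = p_agree, prdis = p_out - p_agree, no_output = 1 - p_out)
}
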