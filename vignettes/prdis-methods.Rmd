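---
title: "Specific predictors for variants with discordant pathogenicity predictions: models and methods"
author: "prdis authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specific predictors for variants with discordant pathogenicity predictions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prdis)
```

## The problem

Clinical guidelines for sequence-variant interpretation (ACMG/AMP) admit in
silico pathogenicity predictions as supporting evidence only under a
*coincidence rule*: when several computational tools are applied, their
verdicts count only if they all agree.  Disagreement discards the evidence.
Because reference tools disagree on a sizeable fraction of missense variants
— typically 10–45% of those with full output — this rule throws away
information exactly where annotation is hardest.

`prdis` implements a pipeline for recovering that information.  For any
combination of reference predictors (SIFT, PolyPhen-2 HDIV, PON-P2, CADD,
MutationTaster2), it partitions a labelled variant set into three disjoint
parts:

* **agree** — all predictors give output and their binarised calls coincide;
* **PRDIS** — all predictors give output but the calls differ;
* **no-output** — at least one predictor gives no output.

It then trains *specific* classifiers on the PRDIS part alone, and combines
rule and model into a *hybrid* predictor: agreed calls where the rule
applies, the specific model's call on PRDIS, nothing on no-output.

## Dataset construction

The pathogenic class is taken from curated disease annotations; proteins
contributing fewer than `thres = 30` pathogenic variants are excluded
(`filter_by_protein_count()`), which bounds the neutral-to-pathogenic
imbalance near 2.8:1.  We count *pathogenic* variants towards the threshold
(configurable to all variants): the filter exists to limit the class
imbalance caused by proteins with few disease variants but many neutral
ones.

The neutral class uses the homology model: every deviation from the human
sequence observed in a homolog at ≥ 95% pairwise identity is taken as
neutral (`harvest_neutral_variants()`).  Identity is computed over mutually
gap-free alignment columns — the convention most robust to alignment
padding; sources differ here and the cutoffs make the choice nearly
inconsequential at 95%.  Duplicate substitutions seen in several homologs
collapse to one record.  Homologs below 40% identity are pruned first; when
the supplied alignment was already pruned upstream this is a no-op.

An optional filter keeps only substitutions reachable by a single
nucleotide change (`filter_snv_reachable()`).  Protein-level records carry
no codon context, so reachability considers every codon of the native
residue — the most permissive consistent reading.

## Variant features

Three biological features supplement the raw predictor scores:

* `blosum62` — the BLOSUM62 log-odds element of the replacement (canonical
  NCBI 20×20 integer matrix, embedded);
* `entropy` — Shannon entropy $-\sum_i p_i \log p_i$ of the variant's
  alignment column, over amino acids only;
* `pssm_nat` — $\log(f_{nat,i} / f_{nat,MSA})$, the log-ratio of the native
  residue's frequency at the variant column versus the whole alignment.

Conventions: logarithms are natural (base 2 available as a switch; only a
monotone scaling for downstream learners), gaps and non-standard residues
are excluded from all counts, and sequences are unweighted.  A
Jeffreys-style pseudocount of 0.5 — $(n + 0.5)/(N + 10)$ on both
frequencies — keeps `pssm_nat` finite on sparse alignments; a pseudocount
of 0 reproduces the plain ratio and recovers the smoothed value in the
limit when all counts are positive.

## Binarisation

The reference tools emit heterogeneous output (probabilities, phred-like
scores, categorical calls).  The shipped registry
(`default_predictor_specs()`) uses the tools' conventional cutoffs: SIFT
≤ 0.05 pathogenic, PolyPhen-2 ≥ 0.5 pathogenic, CADD phred ≥ 15 pathogenic,
categorical maps for PON-P2 and MutationTaster2.  These are conventional,
not fitted, and every entry is overridable (YAML via
`read_predictor_specs()`).  Ties at a score threshold resolve to
pathogenic.  PON-P2's "unknown" class is treated as no output rather than
as a discordant call — it is an abstention, not a verdict.  A categorical
call absent from its map is a loud error, never silently missing.

## The specific classifiers

Two architectures (`training_config()`): a single sigmoid output unit
(`no_hidden`) and one hidden layer with two sigmoid nodes (`hidden_2`).
Training is per-instance stochastic gradient descent on squared error with
momentum — learning rate 0.3, momentum 0.2, 500 epochs, no validation split
— with inputs affinely normalised to $[-1, 1]$ per feature.  The
presentation order is shuffled once from the seed and then fixed across
epochs, so training is deterministic given the seed.  These semantics
emulate the classic WEKA-style perceptron setup; they are not claimed to be
bit-identical to any other implementation, and all headline results are
cross-validated averages rather than single fits.

Inputs are either the combination's scores alone (`scores_only`) or scores
plus the three biological features (`scores_plus_bio`).  Categorical
predictors contribute their binarised call as a 0/1 column — the only
numeric summary available for them.

Class imbalance in each *training* split is corrected with SMOTE
(`smote_oversample()`): synthetic minority rows $x + u\,(x_{nn} - x)$,
$u \sim U[0,1]$, with $x_{nn}$ one of the $k = 5$ nearest minority
neighbours (Euclidean), added to exact parity.  Majority rows and test
folds are never modified.  The amount (parity) and $k$ follow the original
SMOTE formulation since neither is prescribed elsewhere.

## Performance assessment

Six measures from the confusion table (pathogenic = positive):
sensitivity, specificity, accuracy, PPV, NPV and the Matthews correlation
coefficient.  A zero denominator makes a measure *undefined* — reported as
`NA` and flagged, never coerced to 0, so averages stay honest; replicas
with undefined values are excluded from means with a count.

Cross-validation (`cross_validate()`) is 10 replicas of stratified 5-fold:
SMOTE is applied only to the four training folds, replica metrics come from
the pooled test-fold confusion counts (micro-averaging — whether published
averages pooled or macro-averaged fold counts is unstated; pooling is the
variance-minimising choice and is documented rather than asserted), and the
final report averages replicas.  Stratification requires at least five
members per class; replica seeds default to 0–9 and derive from the
top-level seed in the pipeline.

The coincidence rule itself is scored on the agree part only, with coverage
|agree|/total (`evaluate_coincidence_rule()`); reference tools are scored
on all variants where they give output (`evaluate_reference_predictor()`);
the hybrid pools agree-part and PRDIS-part confusion counts with coverage
(|agree|+|PRDIS|)/total (`evaluate_hybrid()`), taking PRDIS calls either
from a model trained on disjoint data or from out-of-fold CV predictions.

## The synthetic panel generator

Real inputs (curated variant tables, alignment libraries) cannot ship with
the package, so every stage is exercised on synthetic panels
(`generate_panel()`) with the statistical structure the pipeline assumes:

* labels drawn at prevalence 0.26, matching the 15,723/59,442 composition
  of the training conditions the pipeline targets;
* per-predictor latent scores $z_j = s_j\,\mathrm{label} +
  \mathcal N(0, \sigma_j)$, squashed monotonically onto each tool's native
  scale with the class midpoint mapped onto the binarisation cutoff — so
  both per-class error rates equal $\Phi(-s_j/2\sigma_j)$ and the
  agree/PRDIS/no-output fractions have the closed forms in
  `expected_partition_fractions()`, which serve as independent test
  oracles;
* default signals give individual accuracies in the 80–90% band (strongest
  for PON-P2) and missing rates mirror the tools' very different coverages
  (SIFT 3%, PolyPhen-2 1%, MutationTaster2 45% as printed; PON-P2 45% and
  CADD 15% chosen as realistic);
* per-protein alignments with a controllable fraction of conserved
  columns; pathogenic variants fall in conserved columns with probability
  0.8 and favour non-conservative (BLOSUM62 ≤ 0) replacements, so the
  biological features carry signal of realistic sign.

What the generator does **not** emulate: real predictor score
distributions and their correlations (tools share training data and
features; here errors are independent, which flatters agreement-based
rules), realistic protein families, position-dependent mutability, or
annotation noise in the labels.  Passing tests therefore demonstrate
correctness of the machinery and qualitative behaviour — specific models
beat random on informative PRDIS sets, biological features help, null
panels give MCC ≈ 0 — not clinical-grade performance on real variants.

Problem sizes: unit tests use panels of 150–600 variants; the acceptance
checks use 25 proteins × 80 variants = 2,000, with 10×5-fold CV, which
keeps the whole suite near a minute.

## Numerical and degenerate-input choices

* Ties: score at the binarisation threshold → pathogenic; model score at
  the decision threshold (0.5) → pathogenic.
* `pairwise_identity()` with no mutually gap-free columns, empty alignment
  columns, and empty confusion tables are errors, not silent zeros.
* A lone minority point in SMOTE has no neighbours and is duplicated;
  $k$ is clamped (with a warning) to minority size − 1.
* Constant feature columns normalise to 0 rather than dividing by zero.
* MCC uses double arithmetic throughout (integer overflow is possible at
  dataset scale otherwise).
* Missing predictor output (`'?'`) is `NA` end to end and never compares
  equal to any numeric score.

## Limitations

The five reference tools are consumed, never recomputed; binarisation
cutoffs are conventional defaults, not the (unpublished) ones behind any
specific published table; the network emulation reproduces training
semantics, not bit-exact weights; and consensus meta-methods (Condel,
CAROL) are supported only as extra score columns for comparison, not
reimplemented.

## A worked example

```{r example, eval = FALSE}
panel <- generate_panel(synthetic_panel_spec(n_proteins = 25,
                                             variants_per_protein = 80,
                                             seed = 1))
part <- apply_coincidence_rule(panel$variants, c("PolyPhen2", "SIFT"))
partition_report(part)

prdis <- panel$variants[part$prdis, ]
cv <- cross_validate(prdis, c("PolyPhen2", "SIFT"),
                     training_config(feature_set = "scores_plus_bio"),
                     keep_oof = TRUE)
cv

rule <- evaluate_coincidence_rule(part, panel$variants)
hybrid <- evaluate_hybrid(part, panel$variants,
                          prdis_calls = setNames(cv$oof[[1]]$call,
                                                 cv$oof[[1]]$variant_id))
```

The same workflow, end to end over all 26 combinations, is
`run_full_pipeline()`; `scripts/acceptance.R` in the source repository
recomputes the headline quantities from scratch.
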