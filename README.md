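# prdis

Specific pathogenicity predictors for protein sequence variants on which
reference in silico tools disagree.

## The problem

Clinical variant-interpretation guidelines (ACMG/AMP) accept computational
pathogenicity predictions as supporting evidence only when every applied
tool agrees — the *coincidence rule*.  When tools disagree, the evidence is
discarded, and tools disagree on a large fraction (often 10–45%) of the
missense variants for which they all produce output.  `prdis` targets
exactly those variants.

For any combination *C* of reference predictors (SIFT, PolyPhen-2 HDIV,
PON-P2, CADD, MutationTaster2) it splits a variant set into three disjoint
parts — **agree** (unanimous calls), **PRDIS** (full output, discordant
calls) and **no-output** — then trains classifiers *specifically* on the
PRDIS part and evaluates a **hybrid** predictor: the agreed call where the
rule applies, the specific model's call on PRDIS.

The specific classifiers are small feed-forward networks (no hidden layer,
or one hidden layer with two sigmoid nodes) trained by per-instance SGD
with momentum (L = 0.3, M = 0.2, 500 epochs) on SMOTE-balanced training
folds.  Inputs are the combination's scores, optionally extended with three
biological features computed from each protein family's multiple sequence
alignment: the BLOSUM62 element of the replacement, the Shannon entropy
−Σᵢ pᵢ log pᵢ of the variant column, and pssm_nat = log(f_nat,i / f_nat,MSA),
the log-ratio of the native residue's column frequency to its
whole-alignment frequency.  Performance is reported as sensitivity,
specificity, accuracy, PPV, NPV and the Matthews correlation coefficient

    MCC = (TP·TN − FP·FN) / √((TP+FN)(TN+FP)(TP+FP)(TN+FN))

averaged over 10 replicas of stratified 5-fold cross-validation (SMOTE is
applied to training folds only; test folds are never touched).

See `vignettes/prdis-methods.Rmd` for the full account of the models,
conventions and design choices.

## A worked example

```r
library(prdis)

panel <- generate_panel(synthetic_panel_spec(n_proteins = 25,
                                             variants_per_protein = 80,
                                             seed = 1))
part <- apply_coincidence_rule(panel$variants, c("PolyPhen2", "SIFT"))
part
#> Coincidence-rule partition [PolyPhen2 + SIFT]
#>   total 2000: agree 1329, prdis 590, no_output 81
```

29.5% of the variants with full output land in PRDIS — the coincidence
rule would discard them.  Cross-validate a specific predictor on exactly
those variants:

```r
prdis_set <- panel$variants[part$prdis, ]
cv <- cross_validate(prdis_set, c("PolyPhen2", "SIFT"),
                     training_config(feature_set = "scores_plus_bio"),
                     keep_oof = TRUE)
cv
#> 10-replica 5-fold CV [PolyPhen2+SIFT | scores_plus_bio | no_hidden], n = 590
#>   mean MCC 0.634 (replica sd 0.014), mean accuracy 0.846
```

Held-out MCC 0.63 on variants where the two tools contradict each other —
far from random, though below the rule's own success on concordant
variants.  Combining both gives the hybrid predictor:

```r
rule <- evaluate_coincidence_rule(part, panel$variants)
c(rule_mcc = rule$mcc, rule_coverage = rule$coverage)
#> rule_mcc 0.858, rule_coverage 0.664

hybrid <- evaluate_hybrid(part, panel$variants,
                          prdis_calls = setNames(cv$oof[[1]]$call,
                                                 cv$oof[[1]]$variant_id))
c(hybrid_mcc = hybrid$mcc, hybrid_coverage = hybrid$coverage)
#> hybrid_mcc 0.787, hybrid_coverage 0.96
```

The hybrid trades a little of the rule's MCC (0.86 → 0.79) for much larger
coverage (66% → 96% of all variants).  `run_full_pipeline()` repeats this
for all 26 predictor combinations, two feature sets and two architectures;
a thin command-line wrapper is installed at
`system.file("cli", "prdis", package = "prdis")`.

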