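# lumahet

Quantifying intratumor subtype heterogeneity in Luminal A breast cancer
from paired bulk transcriptomes and histology images.

## The problem

PAM50 expression profiling assigns each breast tumor one intrinsic subtype
(LumA, LumB, HER2, Basal), yet single tumors often harbor territories whose
expression program — and morphology — belong to a different, usually more
aggressive, subtype. `lumahet` implements a pipeline that measures this
admixture and maps it spatially:

1. **Transcriptomic admixture (ssNMF).** Bulk expression `V` (genes × cases)
   is factorized as `V ≈ W H` with nonnegative subtype metagenes `W`
   (genes × 4) and coefficients `H` (4 × cases), by multiplicative updates
   with component identity pinned by anchor cases. Each case's profile
   (pLumA, pLumB, pHER2, pBasal) is its coefficient column normalized to
   sum to one.
2. **Purity ranking and splits.** Cases are ranked by adherence to their
   assigned subtype; the purest LumA/non-LumA cases are partitioned into
   train/validation/initial-test groups, and all remaining LumA cases form
   the final test set.
3. **Weakly supervised patch classifier.** Annotated tumor regions are tiled
   into nonoverlapping 512-px patches that inherit their slide's label
   (LumA vs non-LumA). Training minimizes the generalized cross-entropy
   `L_q(p) = (1 − p^q)/q` (noise-robust for `q` near 1; cross-entropy as
   `q → 0`) with sample-specific pruning of the lowest-confidence patches
   after a warm-up — absorbing the label noise that weak slide-level
   labelling creates in admixed tumors.
4. **Calibration-based selection and iLumA%.** Per slide, iLumA% is the
   percentage of patches classified LumA; the selected checkpoint maximizes
   the Pearson correlation of validation iLumA% with genomic pLumA. A case
   is *pure* iff iLumA% > 50, else *admixed*. Smoothed probability heatmaps
   (Gaussian SD 2.5 in patch-grid units) map the heterogeneity spatially.
5. **Association battery.** iLumA% quartile contrasts (χ²/t), ordinal trend
   tests, ER gene-group score, MATH score, Kaplan–Meier/log-rank, and Cox
   hazard ratios with a 36-month time split (0–3 years; beyond 3 years as a
   landmark analysis).

Everything runs on a bundled synthetic cohort generator (expression
mixtures with known Dirichlet admixture, Voronoi-textured slides whose
territory areas match each case's admixture, clinical/survival tables with
planted effects), so every stage has ground truth and the whole pipeline is
testable on a desk.

## Worked example

```r
library(lumahet)

study <- run_study()   # default 200-case synthetic cohort, a few minutes
print(study)
```

```
LumA heterogeneity study (synthetic cohort)
  cases: 200; final test slides scored: 130
  selected checkpoint: epoch 1 (val r = 0.982)
  iLumA% vs true pLumA: Pearson r = 0.736, Spearman rho = 0.730
  pure calls: 71 / 130
```

The selected checkpoint's slide-level iLumA% correlates with the
generator's true LumA proportion at r ≈ 0.74 across the 130 held-out
slides; 71 of them are called pure (majority of patches LumA). The
survival table for the same study:

```r
study$survival
```

```
  stratum hazard_ratio ci_low ci_high logrank_p   n n_events
1  entire         1.76  0.921    3.38    0.0829 130       37
2    0-3y         3.49  1.112   10.98    0.0224 130       15
3     >3y         1.16  0.503    2.70    0.7211 115       22
```

The generator plants a hazard ratio of 2 for admixed cases; the pipeline's
pure-vs-admixed Cox models recover an elevated overall hazard (1.76) at
this cohort size, with wide stratum-level intervals — 37 events among 130
cases leave the time-split estimates imprecise, as expected. Individual stages
are available directly: `generate_cohort()`, `fit_ssnmf()` /
`admixture_proportions()`, `purity_rank()` / `make_splits()`,
`extract_patches()` / `label_patches()`, `train_classifier()` /
`select_model()`, `classify_patches()` / `slide_iluma()` /
`build_heatmap()`, and the `clinstats` functions (`assign_quartiles()`,
`q1_vs_q4_test()`, `trend_test()`, `er_gene_score()`, `math_score()`,
`km_logrank()`, `cox_hr()`). A thin command-line front end lives at
`inst/cli/lumahet.R` (`simulate`, `admix`, `patch`, `study` subcommands).

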