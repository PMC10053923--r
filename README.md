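# fusemet

Mid-level data fusion of LC-MS and NMR blocks for untargeted plant
metabolomics, built for seasonal-harvest studies: which specialized
metabolites change with harvest season, and can the two platforms say so
jointly with more confidence than either alone?

The package takes (a) per-sample 1D projections of 2D J-resolved ^1H NMR
spectra and (b) an aligned LC-MS feature table as exported after
MZmine-style preprocessing, and runs the complete analysis:

1. **Binning** — 0.04 ppm buckets over 0.0–9.0 ppm (225 bins), mean
   intensity per bucket.
2. **Curation** — solvent-blank feature removal; external-standard QC
   (reserpine, 11.38 ± 0.2 min, m/z 609.2794 [M+H]+, 3 ppm).
3. **Fusion** — each block scaled by the sum of its per-variable standard
   deviations, so both blocks contribute comparable variance:

   x̂ = x / Σ σ_block

4. **Modelling** — Pareto scaling, then natively implemented NIPALS PLS-DA
   and OPLS-DA (one-vs-rest contrast), inner-relation statistics, biplot
   coordinates, 7-fold venetian-blind Q², and permutation validation
   (n = 100; valid when the R² intercept exceeds the Q² intercept and the
   Q² intercept is negative).
5. **Selection** — variable importance in projection,
   VIP_j = √( p · Σ_a (w_ja/‖w_a‖)² SSY_a / Σ_a SSY_a ),
   intersected with an FDR gate on per-feature one-way ANOVA p-values.
   Features with p ≤ 0.05 are ranked and each assigned the
   Benjamini–Hochberg critical value FDR = (i/m) × Q at Q = 5% (the
   reported FDR column); the retention decision defaults to the standard
   BH step-up over all tested variables (`fdr_method = "bh"`), with the
   verbatim rank rule available as `fdr_method = "rank"`.
6. **Dereplication** — accurate-mass matching of selected MS features
   against a compound library under the polarity's default adduct
   ([M+H]+ / [M−H]−, proton-mass arithmetic), 3 ppm, Level 3 annotations.
7. **Group summaries** — per-season mean ± SD, box-plot statistics,
   one-way ANOVA and Tukey's HSD.

Because studies of this kind rarely deposit raw data, `generate_study()`
simulates the full design (4 seasons × 3 harvests × 3 replicates) with
planted ground truth: triterpene-like signals rising spring → winter and
C-glycosyl-flavone-like signals rising winter → spring, in both blocks.
Every pipeline stage is therefore testable end to end — recovery of
planted discriminants, false-positive control on null studies, and
permutation validation are measured properties.

## Worked example

```r
library(fusemet)

study  <- generate_study(study_design(seed = 2023))   # 36 samples, 225 + 90 variables
bundle <- run_pipeline(pipeline_config(study = study, n_permutations = 100, seed = 2023))
writeLines(write_report(bundle))
```

```
== MS-NMR fusion analysis report ==
mode = fused | seed = 2023 | ncomp = 2 | folds = 7 | k = 15 | Q = 0.05 | fdr = bh

QC external standard: PASS (1 match(es))
PLS-DA: R2X(cum) = 0.3464, R2Y = 0.5872, Q2 = 0.4397
Inner relation: slope = 1.0000, intercept = 0.0000, R2 = 0.9761
OPLS-DA (SPR vs rest): R2X(pred) = 0.1853, R2X(ortho) = 0.1564, R2Y = 0.9118
Permutation (n = 100): R2 intercept = 0.2660, Q2 intercept = -0.2139 -> valid

Discriminant features retained: 10
  7.32-7.36      NMR  VIP=4.86  p=0.00000  FDR=0.001
  0.56-0.60      NMR  VIP=5.77  p=0.00000  FDR=0.006
  N0001          MS   VIP=5.60  p=0.00000  FDR=0.010
  P0004          MS   VIP=3.11  p=0.00000  FDR=0.013
  P0005          MS   VIP=3.42  p=0.00000  FDR=0.015
  1.32-1.36      NMR  VIP=4.90  p=0.00000  FDR=0.020
  1.12-1.16      NMR  VIP=4.27  p=0.00000  FDR=0.020
  6.76-6.80      NMR  VIP=4.90  p=0.00000  FDR=0.024
  N0055          MS   VIP=2.24  p=0.00901  FDR=0.042
  N0025          MS   VIP=3.01  p=0.00975  FDR=0.043

Annotations (accurate-mass, Level 3):
  N0001      m/z  455.3531 [M-H]- -> ursolic acid (+0.07 ppm)
  P0004      m/z  433.1128 [M+H]+ -> isovitexin (-0.28 ppm)
  P0005      m/z  565.1548 [M+H]+ -> schaftoside (-0.68 ppm)

Ground-truth recall: 8/10 planted discriminants recovered (80%)
```

Reading the report: the model explains 58.7% of the class structure (R2Y)
with cross-validated predictability Q² = 0.44; the inner relation (u1 on
t1, R² = 0.976) shows the dominant latent direction of the fused matrix
tracking the season order; OPLS-DA splits explained X-variation into an
18.5% between-group and a 15.6% within-group share; the negative Q²
permutation intercept certifies the fit is not overfitting. Ten variables
pass both the top-15 VIP and FDR ≤ 0.05 gates — aliphatic buckets
(0.56–0.60, 1.12–1.36 ppm, triterpene-like, maximal in winter), aromatic
buckets (6.76–6.80, 7.32–7.36 ppm, flavone-like, maximal in spring), and
MS features annotated by accurate mass as a triterpene acid and two
C-glycosyl flavones. Eight of the ten planted discriminants are recovered.

Single-platform analyses are one flag away (`mode = "nmr"` or
`mode = "ms"`), and `tidy()`, `glance()`, `autoplot()`, `plot_biplot()`,
`plot_inner_relation()` and `plot_group_boxes()` expose every figure's
underlying coordinates as data.

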