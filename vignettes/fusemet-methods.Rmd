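---
title: "Methods: concatenated MS-NMR metabolomics with fusemet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concatenated MS-NMR metabolomics with fusemet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusemet)
```

## The problem

Seasonal studies of medicinal plants ask whether harvest time changes the
concentration of the specialized metabolites that carry the plant's activity.
Two complementary platforms are the workhorses: 1D projections of 2D
J-resolved ^1^H NMR (quantitative, highly reproducible) and untargeted
LC-ESI-HRMS (sensitive, with accurate mass for annotation).  fusemet
implements a mid-level fusion workflow for exactly this design: each
platform's sample-by-variable table is built separately, the two blocks are
put on a comparable variance scale, concatenated, and modelled jointly with
supervised latent-variable methods; discriminant variables are then selected
by variable importance and a rank-based false-discovery-rate rule, and the
selected MS features are dereplicated against a compound library by accurate
mass.

Because studies of this kind rarely deposit raw data, the package also ships
a first-class synthetic seasonal-study generator with planted ground truth,
so the entire pipeline is testable end to end: recovery of planted
discriminants, false-positive control on null studies, and permutation
validation of the models are all measurable properties, not hopes.

## Spectral binning (bucketing)

`bin_spectrum()` divides the 0.0--9.0 ppm window into 0.04 ppm buckets (225
bins by default) and summarises each bucket by the **arithmetic mean** of the
intensity points falling in it.  Buckets are half-open on the right, with the
final bucket closed so the breakpoints partition the window without double
counting; empty buckets emit 0 so downstream matrix algebra always sees a
complete matrix.  The mean (rather than the sum) makes bucket values
comparable across instruments with different digital resolution; a
`agg = "sum"` switch is provided for workflows that prefer summed bucket
intensities.  With a uniform ppm grid the point-weighted mean of the bucket
values equals the grand mean intensity exactly, a conservation property the
test suite checks to 1e-12.

## Feature-table curation and accurate-mass arithmetic

The LC-MS side consumes an aligned feature table as exported after
MZmine-style preprocessing (id with `P`/`N` polarity prefix, m/z, retention
time, per-sample peak areas).  Curation follows standard practice: every
feature detected in a solvent blank (area above a configurable threshold,
default any signal) is deleted, and the run is checked against the external
standard -- reserpine at 11.38 +/- 0.2 min, m/z 609.2794 `[M+H]+`, 3 ppm --
before modelling.  The printed reference m/z for the standard is treated as a
configured constant, not recomputed from its formula.

Mass arithmetic uses monoisotopic atomic masses to at least seven decimals
and **proton-mass adduct arithmetic**: `[M+H]+` adds 1.00727646688 Da and
`[M-H]-` subtracts it, with the electron mass neglected elsewhere.  This
convention reproduces published positive-mode values to four decimals (e.g.
C~28~H~24~O~14~ + H^+^ = 585.1239).  Molecular-formula prediction enumerates
CHNOS formulas inside elemental bounds and keeps candidates within the ppm
tolerance that also pass standard plausibility heuristics: H/C in [0.2, 3.1],
O/C at most 1.2, and integral non-negative ring-and-double-bond equivalents
(as required for even-electron protonated/deprotonated ions of neutral
molecules).  The heuristic set is deliberately small, explicit and
configurable; it is a documented subset of the many published rules, not an
attempt to replicate any specific tool's filter stack.  Dereplication
computes each library compound's theoretical m/z under the feature's
polarity's default adduct and reports all matches within tolerance as
**Level 3** annotations -- putative, class-level identifications, which is
all that accurate mass alone can support.

## Block-wise scaling and fusion

The two blocks differ wildly in dimensionality and intensity scale, so naive
concatenation would let one block dominate the model.  Each block is scaled
by the sum of its per-variable sample standard deviations:

$$\hat{x} = \frac{x}{\sum_{j \in \mathrm{block}} \sigma_j}$$

after which the per-variable standard deviations of each block sum to 1 and
the blocks contribute comparable total variance.  Two readings of this
formula are possible because the published notation overloads the symbol
*n*; the reading in which values are *multiplied* by the dataset size would
only rescale each block by a constant and could not balance the blocks, so
it is rejected in favour of the variance-balancing reading (the stated
purpose of the scaling -- each block "considered as a unit").  Sample
standard deviations (denominator n-1) are used; population-vs-sample is not
specified in the source material and the choice is recorded here.  Zero
variance variables are retained (they scale like the rest) and flagged.

Block scaling happens at fusion time; Pareto scaling (centering and division
by the square root of the standard deviation) is applied afterwards, inside
the modelling step, to the fused matrix.  Whether the original workflow
applied Pareto before or after block scaling is not stated; the adopted
order means Pareto sees the between-block balance, and it is exposed rather
than hidden so users can reorder by calling the stages themselves.

## PLS-DA, OPLS-DA, VIP

The latent-variable machinery is implemented natively (NIPALS), which keeps
every numerical convention inspectable:

* **PLS-DA** is NIPALS PLS2 against the centered dummy class matrix.  Per
  component the alternation `w = X'u / ||X'u||`, `t = Xw`, `c = Y't / t't`,
  `u = Yc / c'c` runs until the relative change of `t` drops below 1e-10
  (at most 500 iterations), followed by rank-one deflation of X and Y.  The
  first weight vector of each component is the dominant eigenvector of
  X'YY'X for the deflated matrices; the test suite checks this equivalence
  against a dense eigendecomposition at 1e-8.
* **Convergence in near-tied subspaces.**  Under permuted class labels the
  two leading eigenvalues of X'YY'X are frequently almost tied, and the
  power iteration's linear convergence plateaus orders of magnitude above
  the 1e-10 target even though any unit vector of the tied subspace is an
  equally good component.  A stagnated small score change (below 1e-2 and
  not halved over the last 100 iterations, or below 1e-3 at the iteration
  cap) is therefore accepted; only genuine non-convergence errors.  Without
  this rule, permutation validation would abort on realistic data.
* **Sign convention**: each weight vector is oriented so its
  largest-magnitude entry is positive, making scores and loadings
  reproducible across runs and platforms.
* **OPLS-DA** extracts `n_ortho` components orthogonal to the response from
  the PLS weight structure, deflates, then fits one predictive component on
  the filtered matrix.  Explained X-variation splits into a predictive
  (between-group) share and an orthogonal (within-group) share whose sum
  cannot exceed 1.  Multiclass designs are handled the way seasonal studies
  use the method operationally: the most distinct class (spring by default)
  is contrasted one-vs-rest; pairwise contrasts are available through
  `positive_class`.
* **VIP** uses the standard definition
  $\mathrm{VIP}_j = \sqrt{p \sum_a (w_{ja}/\|w_a\|)^2 \, SSY_a / \sum_a SSY_a}$,
  so the mean of squared VIPs is exactly 1 on every fit (checked to 1e-9).

## Validation: Q^2 and permutations

Q^2 uses 7-fold cross-validation with a deterministic venetian-blind fold
assignment (offset derived from the seed).  Seven folds is the long-standing
default of the commercial software this class of analyses is usually run in;
the fold count is configurable because the original analyses do not state
it.  Q^2 = 1 - PRESS/SS over the dummy class matrix, with centering
re-estimated inside each training fold.

`permutation_test()` refits the model under `n = 100` label permutations by
default, computes each refit's R^2 and Q^2, and regresses both against the
absolute correlation between permuted and original dummy matrices, the
original model entering at correlation 1.  The model is declared valid when
the R^2 intercept exceeds the Q^2 intercept *and* the Q^2 intercept is
negative -- scrambled labels must show no residual predictive ability.

## Discriminant selection and the FDR rule

Selection intersects two gates: the top-`k` variables by VIP (default 15,
the shortlist a loadings plot highlights) and a false-discovery-rate rule on
per-variable one-way ANOVA p-values across the four seasons (the published
tables do not state which test produced their p-values; fixed-effects ANOVA
is the method named for the group comparisons, and only the FDR transform of
given p-values is asserted against the printed tables).

The reporting rule ranks features with p <= 0.05 ascending and assigns each
the Benjamini-Hochberg critical value FDR = (i/m) x Q with Q = 0.05.
`fdr_rank()` implements this verbatim and reproduces the printed FDR columns
of both published discriminant tables exactly.  One property of the verbatim
rule deserves emphasis: since (i/m) x Q <= Q for every rank, *every* feature
with p <= 0.05 is retained -- the critical value is a reporting quantity,
not a step-up decision, and the rule reduces to an unadjusted p <= 0.05
filter.  Under a null study with ~315 variables that filter would flag about
15 variables by chance and the VIP shortlist would intersect them nearly
always, so study-wise false discoveries would be the norm rather than the
exception.  The pipeline therefore defaults to the standard BH step-up over
*all* tested variables for the retention decision (`fdr_method = "bh"`),
which restores study-wise FDR control, while still computing and reporting
the rank-FDR column; `fdr_method = "rank"` switches to the verbatim
behaviour.  This is the package's one deliberate departure from the
published procedure, taken because the generator's null studies make the
consequence measurable: with BH the fraction of null studies reporting any
discovery is ~2-5%, with the verbatim rule it approaches 100%.

Group summaries for the selected features use means +/- SD per season,
box-plot five-number summaries, one-way ANOVA, and Tukey's HSD for all
season pairs (via `stats::TukeyHSD`).

## The synthetic generator

`generate_study()` emulates the study design the analysis assumes: 4 seasons
(SPR/SUM/AUT/WIN) x 3 harvests x 3 replicates = 36 samples by default, a
90-feature MS block, and NMR projections over 0--9 ppm synthesised as sums
of Lorentzian lines (the natural NMR line shape) on a 2700-point grid.
Planted discriminants follow the seasonal biology the workflow is meant to
detect: triterpene-like signals (aliphatic shifts 0.5--3.1 ppm, late-eluting
triterpene-mass MS features) rise monotonically from spring to winter, and
C-glycosyl-flavone-like signals (aromatic shifts 6.5--8.0 ppm, flavone-mass
MS features) rise from winter to spring.  The seasonal effect enters as a
geometric ramp of the mean, `effect_size^(s/3)` across the season order, so
`effect_size` is exactly the fold change between the extreme seasons.

Intensity noise is multiplicative log-normal with unit mean and configurable
coefficient of variation (default 0.2) -- the standard positive-valued model
for peak areas; within-season biological variance is not stated by seasonal
studies of this kind, so it is exposed as `noise_cv` rather than guessed.
One non-discriminant MS slot carries the reserpine external standard so the
QC stage exercises its real path.  Planted MS features take accurate masses
of real triterpene/flavone formulas (with sub-ppm simulated mass error), so
dereplication against the built-in library annotates them.  A single RNG
stream seeded from `design$seed` makes the whole study bit-reproducible.

What the generator does **not** emulate: chromatographic peak shapes,
isotope patterns, 2D J-res artefacts (tilt, T1 noise), peak-position drift
between samples, and correlated metabolite co-regulation beyond the planted
monotone trends.  Passing recovery tests therefore demonstrates that the
statistical machinery works under the stated noise model, not that any
specific real dataset would yield the same discriminants.

## Problem sizes and numerical choices

The test suite and the acceptance script run the generator at the study's
stated size (36 samples, 225 + 90 fused variables).  Recovery is measured
over 20 seeded studies (mean recall of planted discriminants >= 80% is the
design target; observed ~0.95), null control over 50 seeded flat studies
(<= 15% of studies with any discovery is the target; observed ~0-4%), and
permutation validity over 20 seeded runs of 100 permutations (>= 90% valid
is the target).  Exact desk-scale identities -- 225 buckets, mean
conservation, 4-decimal adduct masses, the printed FDR columns -- are
asserted at 1e-12/printed precision.  Degenerate inputs (constant blocks,
single samples, one-class designs, empty libraries, folds that orphan a
class) raise classed errors (`fusemet_config_error`, `fusemet_data_error`,
`fusemet_model_error`) rather than propagating NaNs.

## Known limitations

* Two blocks only; no multiblock weighting beyond the sum-of-SDs scaling.
* OPLS-DA supports binary/one-vs-rest contrasts, not multiclass O2PLS.
* Dereplication is accurate-mass only (Level 3); no MS/MS matching.
* The formula predictor covers C, H, N, O, S; halogens and phosphorus are
  out of scope for the targeted compound classes.
* q-value estimation, multi-factor ANOVA and mixed models are out of scope.
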