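---
title: "Nucleosome profiling of cfDNA: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome profiling of cfDNA: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(griffin)
```

## The problem

Cell-free DNA circulates as nucleosome-protected fragments. At
accessible regulatory sites — actively bound transcription factor
binding sites (TFBS), open chromatin — nucleosomes are phased around a
protein-occupied, nuclease-exposed center, so sequencing coverage of
cfDNA shows a characteristic dip at the site with flanking peaks at
roughly 190 bp spacing. Averaged over the thousands of binding sites
of one factor, this signal reports the factor's aggregate activity in
the cells that shed the DNA, even at ultra-low-pass coverage (0.1x)
where any single locus is unreadable. Because a fraction of cfDNA in
cancer patients is tumor-derived, site lists differential between
tumor and blood turn these composite profiles into features for cancer
detection and subtype classification.

The obstacle is GC bias: library preparation and sequencing make
expected coverage a sample-specific function of fragment GC content,
and the bias differs between fragment lengths within one sample. Site
centers are systematically GC-elevated relative to their flanks, so GC
bias masquerades as (or hides) accessibility. The package's core is a
fragment-length-stratified GC correction wrapped around composite
midpoint-coverage profiling.

## The GC bias model

For each sample, the fragment length position model is estimated as
follows:

1. **Genome GC frequencies** (`compute_genome_gc_frequencies()`): for
   every fragment length $L$ in the modeled range, count the GC
   content of every $L$-mer fully contained in a valid region. Valid
   regions (`build_valid_regions()`) are positions at mappability 1
   (configurable threshold) minus exclusion-list intervals. An
   $L$-mer containing an ambiguous base is skipped; fragments are
   treated identically, so numerator and denominator share one
   admissibility convention (full containment in a single valid
   interval).
2. **Sample GC counts** (`count_sample_gc()`): the reference-sequence
   GC of every accepted proper-pair fragment (mapping quality >= 20,
   not duplicate/QC-fail, length in range, span contained in a valid
   interval), stratified by length. GC is computed from the reference
   over the fragment span rather than from read sequences, which makes
   it robust to sequencing errors; the read-sequence alternative is
   not implemented.
3. **Raw bias** (`compute_raw_gc_bias()`): counts over frequencies,
   rescaled to mean 1 over the observed combinations at each length.
   Combinations absent from the genome are missing, not zero.
4. **Smoothing** (`smooth_gc_bias()`): for each length, all raw values
   for lengths within ±10 bp are pooled, sorted by GC *fraction*
   (comparable across lengths — the pooled sort key is a deliberate
   choice, since absolute GC count is not commensurate between a
   130 bp and a 150 bp fragment), and each value is replaced by the
   median of its $k$ nearest neighbours in that order,
   $k = \max(50, 0.05\,n)$. Each length then receives its own curve,
   renormalized to mean 1.

Fragments are weighted $1/\text{bias}(L, g)$ in all downstream
coverage. Two guard rails apply: combinations missing from the model
give weight 0 (the fragment is excluded and counted, rather than
silently kept at weight 1), and smoothed bias below 0.05 is treated
the same way. The floor exists because the per-length mean-1
normalization runs over *all* observed combinations including sparse
tails, where the median smoother legitimately collapses toward zero;
without a floor such fragments would enter profiles with unbounded
weights. Both exclusions affect a negligible fragment fraction at
realistic depths but bound the variance contributed by any single
fragment.

A single-fragment-length comparison variant
(`single_length_gc_bias()`) treats every read as a 165 bp fragment
from its start position and maps arbitrary fragments to the closest
165 bp GC content.

## Composite profiling

`nucleosome_profile()` runs the chain per site list:

* fetch proper pairs within ±5 kb of each site, keep fragment lengths
  100–200 bp (alternative ranges are a config switch);
* weight each fragment by its inverse GC bias (optionally times an
  inverse mappability bias), take the fragment midpoint
  $\lfloor (start + end - 1)/2 \rfloor$, and sum weights in 15 bp
  bins. The grid is frozen: 666 bins, bin $i$ spanning
  $[-5000 + 15i, -4985 + 15i)$, offset 0 in bin 333. A fragment is
  admitted iff its midpoint lies on the grid, so each fragment
  contributes to exactly one bin;
* mask bins not fully contained in a valid region (equivalently: bins
  intersecting an exclusion or containing any sub-threshold
  mappability position) and bins above mean + 10 SD of the weighted
  coverage, the statistic pooled over all bins of all sites in the
  list (the pooling scope is a frozen choice, as is everything in this
  paragraph);
* average bins across sites, ignoring masked bins; a bin masked
  everywhere stays missing;
* smooth with a Savitzky–Golay filter (165 bp window = 11 bins,
  polynomial order 3 — exact on cubics, so it flattens noise without
  biasing smooth structure), normalize to mean 1 over the unmasked
  ±5 kb window, and trim to bins whose *centers* lie within ±1 kb
  (133 bins; the center rule is phase-unambiguous). Masked bins are
  linearly interpolated for filtering only and restored to missing.
  Smoothing is applied to the composite, not per site, following the
  processing order of the procedure this package implements; per-site
  smoothing would change little but is not offered.

Optional corrections, both off by default because they did not earn
their keep in our assessments: a mappability bias model
(`estimate_mappability_bias()`: per-5 Mb segments, every 100th
position, per-mappability-value mean read counts, locally weighted
regression with span 2/3, weights normalized to the value at
mappability 1) and a local copy-number correction
(`cna_local_correct()`: divide each bin by the running mean over
±50 kb at bin resolution, before compositing).

## Features

From a trimmed profile (`profile_features()`):

* **central coverage** — mean over bins with centers within ±30 bp
  (4 bins); lower = more accessible;
* **mean coverage** — mean over the ±1 kb window;
* **amplitude** — modulus of term 10 (0-indexed) of the unnormalized
  forward DFT of the 128 bins whose start offsets lie in
  [−960, +960). Term 10 of a 128-point transform corresponds to a
  192 bp period, matching the ~190 bp nucleosome spacing at active
  sites; the convention (unnormalized, 0-indexed) is frozen because
  the amplitude scales with it. A flat profile gives 0; a cosine of
  amplitude $A$ over the window gives $128A/2$.

`assemble_feature_matrix()` builds the samples × (site list × feature)
matrix with deterministic column order; samples missing any profile
are dropped with a message.

## Cohort statistics

`correlate_vs_tumor_fraction()` fits ordinary least squares of a
feature on tumor fraction and reports Pearson r (two-sided p via the t
transform), the fit, and the RMSE of the fit (denominator $n$).
`bh_adjust()` is the Benjamini–Hochberg step-up, applied per feature
type across site lists. `paired_wilcoxon()` drops zero differences
and uses the exact signed-rank null up to n = 25 (no ties), else the
continuity- and tie-corrected normal approximation; the statistic is
the smaller rank sum. `mad_mean()` is the *mean* absolute deviation,
mean-centered — the centering statistic is not dictated by the name,
so it is an explicit argument. `ancova()` fits
feature ~ group + covariate and tests the group term with a Type II
F-test (full vs covariate-only), no interaction;
`compare_correction_modes()` chains these into the before/after
correction assessment.

## Classifier

`bootstrap_train_eval()` implements bootstrap training/evaluation of
ridge-penalized logistic regression: draw n samples (or patients —
with patient-level resampling every sample of a drawn patient enters
training with the patient's multiplicity and no patient ever straddles
the split) with replacement; standardize to mean 0, population SD 1 on
the training multiset; optionally reduce to the leading principal
components explaining a target variance fraction (fit on the training
set, test projected with the training basis); select the inverse
regularization strength C by 10-fold cross-validation on the training
set (metric AUC; the grid $\{10^{-3},\dots,10^2\}$ is a package
default, configurable, since no canonical grid exists; ties break
toward stronger regularization); fit with class-balanced weights; and
score the out-of-bag samples. The ridge fit is glmnet with
$\lambda = 1/(nC)$, which makes C the inverse of the total penalty
strength in the usual convention. Metrics can be restricted to each
patient's first timepoint. Per-sample out-of-bag probabilities are
aggregated by their median. One master seed drives deterministic
per-iteration substreams, so any iteration is reproducible in
isolation. `finalize_and_apply()` trains a final model on all
training data at the modal bootstrap C and bootstraps the validation
metrics for confidence intervals.

## The synthetic cohort simulator

Real cfDNA cohorts at this scale are controlled-access, so every stage
is exercised on simulated data with known ground truth. The simulator
emulates, deliberately at desk scale:

* **Site-anchored midpoint density.** Within ±5 kb of a site the
  fragment-midpoint density is
  $d(x) = 1 - a\,e^{-x^2/2\sigma^2} + b\cos(2\pi x/T)\,e^{-|x|/\tau}$
  (dip depth $a$, phasing amplitude $b$, period $T$ = 190 bp, decay
  $\tau$ = 500 bp, dip width $\sigma$ = 60 bp); elsewhere uniform.
  A sample mixes a tumor spec and a background spec by tumor fraction.
  Specs that would clip more than 1% of density mass are refused.
* **Fragment lengths** from a mixture peaked at the mononucleosome
  mode (167 ± 10 bp, 85%) with minor short (~90 bp) and dinucleosome
  (~330 bp) components, truncated to 35–500 bp.
* **GC bias** by acceptance–rejection against an injected curve
  $w^*(L, g)$, so the induced bias is exactly $w^*$ up to per-length
  normalization.
* **Genome composition**: background GC 0.41 by default, optionally
  isochore-like blocky heterogeneity (per-block GC uniform in a
  range) and GC-enriched islands at site centers. Both matter: the
  enrichment recreates the center-vs-flank GC contrast through which
  GC bias distorts profiles, and the heterogeneity keeps high-GC
  fragments abundant *away* from sites. On a small genome with a
  homogeneous background, high-GC fragments would exist only at the
  enriched, dipped site centers, and the bias model would absorb the
  accessibility signal itself — an artifact real genomes do not have,
  because site centers are a negligible mass fraction of 3 Gb.
* **Alignments** as coordinate-sorted indexed BAMs of proper pairs,
  mapping quality 60, 100 bp reads; mates overlap for fragments under
  200 bp, on purpose.

`expected_composite()` is the analytic oracle: the same density,
pushed through the same binning, smoothing, normalization and trimming
conventions as the pipeline, plus the features of the result.

What the simulator does *not* model: sequencing error, base
qualities, mapping ambiguity, duplicate structure, chimeric fragments,
inter-site heterogeneity of accessibility, batch effects. Passing
tests therefore demonstrate correctness of the estimators and the
direction/magnitude structure of the signal under the stated model,
not performance on real plasma libraries.

## Simulation study conditions

The end-to-end properties are checked under fixed study conditions
(`inst/scenarios/scenarios.R`); all sizes below were set by the design
analyses described here, not tuned against outcomes.

* **GC-bias recovery**: 200k fragments on a 15 kb single-chromosome
  calibration genome, homogeneous GC 0.41, no sites, modeled lengths
  130–170, fragment lengths normal(150, 30) truncated — a calibration
  distribution spanning the modeled range, because under the cfDNA
  default mixture the lengths far from the 167 bp mode receive tens of
  fragments out of 200k and no estimator could recover their curves.
  The genome size follows from a signal-to-noise requirement: the
  recovery tolerance applies at combinations with at least 500 genome
  occurrences, and those combinations must carry several expected
  fragments each for the k-nearest-neighbour median to be unbiased;
  at 200k fragments that caps the genome near tens of kilobases. The
  valid region sits strictly inside the simulator's sampling frame so
  frequencies and sample share one sampling universe. Estimated and
  true curves are compared as shapes, renormalized over the
  comparison set (the model's own per-length normalization includes
  sparse tail combinations that profiles never see).
* **Profiling cohorts** (correction efficacy, RMSE reduction,
  tumor-fraction sweep) share one genome: 8 × 3.1 Mb chromosomes,
  2000 sites at ≥ 12 kb spacing, blocky background GC 0.44 ± 0.20
  (800 bp blocks), site centers ±75 bp at GC 0.60. Correction
  efficacy uses two samples of 2.5 M fragments with opposite bias
  curves $e^{\pm 1.5(gf - 0.45)}$ and identical accessibility
  (tumor dip 0.6, amplitude 0.15, tf 0.5). The RMSE study uses 40
  samples of 100k fragments, tumor fractions uniform in 0.1–0.5 and
  per-sample bias exponents uniform in ±2, over 20 site lists of 100
  sites. The sweep uses six unbiased samples of 500k fragments at
  tumor fractions 0 to 0.5. Fragment counts were sized so counting
  noise sits well below the effects being measured (per-bin weighted
  counts of order 10³ for profile comparisons; central-coverage noise
  of order 1% for the sweep).
* **Classifier sanity**: 60 samples, 6 features, two informative
  (±2.5 SD), 100 bootstrap iterations; a permuted-label null; 200
  patient-resampling draws checked exhaustively for patient
  integrity.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; conversion
  happens only at file I/O (SAM/BED/bedGraph).
* GTRD-style tables are deduplicated on (chromosome, position)
  keeping the maximum score; ranking ties break by (chromosome,
  position), so repeated runs and row permutations give identical
  lists.
* "Within 500 bp / ±250 bp" overlap rules are inclusive.
* Strand is ignored throughout; profiles are not strand-flipped
  (meta-cluster site lists carry no usable strand).
* Zero-variance feature columns standardize to 0 with a flag; a
  bootstrap training set with a single class is redrawn and counted;
  an all-masked profile, a site list with no usable sites, and a
  before/after table with no nonzero differences are errors, not
  silent results.
* `bh_adjust` is the standard step-up; note it is not idempotent (no
  step-up adjustment is), which is easy to verify on
  (0.01, 0.04, 0.03).

## Known limitations

* The mappability and copy-number corrections are implemented and
  tested at the unit level but are not exercised by the end-to-end
  simulation studies (they are off by default for the same reason
  they exist: they did not improve the assessments).
* The simulator's uniform off-site background means copy-number
  structure is absent unless injected by hand.
* Classification studies here are feature-level; no attempt is made
  to emulate cohort-scale batch effects, which in real data prevent
  transferring a trained model across cohorts.
* Runtime scales linearly in fragments and sites; the study sizes
  above run the whole acceptance suite in roughly ten minutes on one
  core. Larger simulations only tighten the same comparisons.
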