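---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenomark)
```

`xenomark` implements a systematic characterization workflow for tumor
xenograft lines: quantify immunohistochemistry (IHC) marker images and PET
uptake volumes into scalar parameters and global first-order texture
features, decompose every parameter into within- versus between-line
variance, and compare Random Forest tumor-line classifiers under a paired,
shared-split repeated cross-validation design. This vignette documents the
models, the tunable parameters, the synthetic-data generators that make the
pipeline testable, and the design decisions taken where the underlying
methodology left choices open.

## Image and volume quantification

**IHC parameters.** A marker image is a 12-bit grayscale scan (pixel size
2.59 µm by default) with a per-image segmentation threshold set above
background staining. A pixel is *positive* iff its grey value is `>=` the
threshold — the inclusive convention makes behaviour at the boundary
deterministic — and lies in the viable tumor area; necrosis (delineated on a
consecutive HE section and supplied as a mask) is excluded from every
computation. From the binary image we derive

* **staining fraction** — positive area / viable area, for area stains
  (PIMO, CA9, GLUT1, MCT4, EGFR, pAKT);
* **labeling index (LI)** — positive nuclei / all nuclei in the viable area
  (BrdU). Nuclei enter as a point set; nucleus segmentation from raw pixels
  is out of scope;
* **vascular density (VD)** — number of 8-connected vessel-mask components
  per mm² of viable tissue. 8-connectivity is the 2-D microscopy
  convention; when vessel staining fragments one vessel, each fragment
  counts (the merging rule is deliberately literal);
* **perfused fraction (PF)** — fraction of vascular components sharing at
  least one pixel with the Hoechst perfusion mask. One shared pixel
  suffices; any stricter overlap criterion would need a justification the
  data do not supply.

**PET parameters.** SUV is activity concentration divided by injected
activity per gram of body weight (decay-corrected to scan start, tissue
density 1 g/mL). The tumor VOI is auto-delineated at a fixed 40% of SUVmax:
voxels at or above the threshold are labelled with 26-connectivity and only
the component(s) containing the maximum voxel(s) are kept — hot but
disconnected structures (bladder, heart) are excluded, matching standard
small-animal practice. Ties at the maximum all seed the VOI. SUVmax is the
maximum within the search region; the muscle VOI is always supplied
manually. VOIs are nested in the threshold fraction by construction, and on
noiseless phantoms recovery of (SUVmax, SUVmean, VOI) is exact.

## Global texture features

Features are first-order (histogram) statistics: **mean** (IHC only),
**skewness** and **Shannon entropy** of the intensity distribution within
the positively stained area (IHC) or the tumor VOI (PET).

* IHC intensities are first linearly rescaled by the image's own
  segmentation threshold, `v * REF / threshold` with `REF = 1000`, so the
  threshold maps to the same reference level in every image and intensities
  are comparable across acquisitions of one marker. Entropy and skewness
  are invariant to `REF` (after bin-width scaling); only the mean feature
  depends on it, so `REF` is a recorded configuration value.
* Discretization uses fixed bin widths — 0.5 SUV for PET, 25 grey units for
  IHC — with half-open bins `[i*w, (i+1)*w)` anchored at zero. Anchoring at
  zero (rather than the sample minimum) keeps the binning identical across
  samples, which is the point of fixed-width discretization. `N_l` counts
  occupied bins only.
* Entropy is \(-\sum_{i=1}^{N_l} P(i)\log_2 P(i)\) in bits, with
  \(0\log 0 = 0\); it is bounded by \(\log_2 N_l\) and invariant under
  joint rescaling of values and bin width.
* Skewness is the population moment estimator \(m_3 / m_2^{3/2}\)
  (estimator choice was open; the uncorrected form is the common radiomics
  convention). Zero-variance or short samples yield an undefined flag that
  propagates as a missing value.

The feature block is exactly 3 features × 7 area markers + 2 PET features =
23 columns; VD and PF have no intensity distribution and contribute none.

## Variance decomposition

For each column the one-way random-intercept model
\(y_{ij} = \mu + b_i + e_{ij}\), \(b_i \sim N(0,\sigma^2_b)\),
\(e_{ij} \sim N(0,\sigma^2_w)\) is fit by REML, implemented as a 1-D profile
optimization over \(\lambda = \sigma^2_b/\sigma^2_w\): given \(\lambda\),
the GLS mean and profiled \(\sigma^2_w\) are closed-form, and the profiled
criterion is optimized over the transformed parameter
\(\lambda/(1+\lambda) \in [0,1)\) with the boundary \(\lambda = 0\) checked
explicitly (negative variance estimates are truncated). On balanced designs
this reproduces the closed-form ANOVA method-of-moments estimator
(\(\hat\sigma^2_w = MSW\), \(\hat\sigma^2_b = (MSB-MSW)/n\), truncated at
0), which is also available as `method = "ANOVA"` and serves as the
independent oracle in the tests (together with `lme4` on unbalanced
designs).

The reported heterogeneity ratio is **within-line variance / total
variance** \(\in [0,1]\). The originating description uses the phrase
"ratio intra/inter" in one place and within/total in another; within/total
is the quantity whose reported values are all \(\le 1\), so it is the
default here, and the raw within/between ratio is returned alongside
(`ratio_intra_inter`) rather than resolving the discrepancy silently.

Correlation matrices use Spearman rank correlation by default (the columns
mix fractions, SUVs, counts/mm² and entropies; rank correlation is invariant
to their monotone scales), pairwise-complete, with cells under 3 complete
pairs flagged missing. Pearson is selectable.

## Random Forest classification

No random-forest implementation is assumed from the environment; the
classifier is implemented in C++ inside the package: CART trees grown to
purity on bootstrap samples, Gini split criterion, `mtry = floor(sqrt(p))`
candidate variables per node (the classification default), majority vote
with deterministic lowest-index tie-breaking, out-of-bag (OOB) accuracy,
and OOB permutation importance (per-tree decrease in OOB accuracy after
permuting one column, averaged over trees — reported in percentage points).
All randomness flows through R's RNG, so a single seed makes forests,
schemes and results bit-identical.

* **Shared-split repeated cross-validation.** 75%/25% train/test splits,
  repeated (1000 times at study scale; reduced counts for desk-scale runs),
  with the identical split list reused for every model so per-split
  accuracies are paired. Splits are stratified by line via largest-remainder
  allocation of the global training count: with 14 lines of ~5 tumors,
  unstratified 75/25 splits frequently lose a line from training entirely.
  Unstratified splitting remains available (`stratify = FALSE`) for
  fidelity runs; classes absent from training simply score as errors in
  test.
* **Imputation.** Median imputation is applied to the full table before
  cross-validation, replicating the upstream order of operations. This
  leaks a small amount of test information through the medians; with 3–5
  missing cells per affected column out of 72 the effect is negligible, but
  it is documented rather than hidden.
* **Paired comparison.** Two models on the same scheme are compared by a
  two-sided paired t-test on per-split accuracy differences. Comparing
  results from different schemes is refused. Degenerate cases (zero
  difference variance) are flagged: a model against itself gives mean
  difference exactly 0.
* **Subset sweep.** For subset sizes k = 1..8 over the 9 IHC parameters,
  every one of the \(\binom{9}{k}\) combinations (510 models in total) is
  evaluated on the shared scheme. Per-k summaries are the mean and SD over
  combination-level mean accuracies, and consecutive sizes are compared
  with Welch's two-sample t-test (combinations differ between sizes, so no
  pairing exists). Sweeps default to reduced tree counts; tree count is a
  recorded configuration field.

### Statistical caveats the tests surface deliberately

Two properties of this (faithful) design are worth knowing:

* **Cross-validated accuracy on pure noise is below nominal chance.** With
  14 balanced classes, chance is 1/14 ≈ 7.1%, but repeated-split CV on
  noise features scores ≈4%: a test sample's own class is under-represented
  in its training split, biasing votes toward other classes. The
  calibration check therefore uses a 99% binomial band around 1/14 at
  n = 70 (the cohort size — the resolution at which OOB accuracy is
  reported), which covers this intrinsic bias; a band at the total number
  of test predictions would reject CV itself, not the implementation.
* **The paired t-test over shared splits is anti-conservative.** Repeating
  random splits shrinks the standard error of the mean accuracy difference
  without adding independent information about the cohort, so the test
  targets the cohort-conditional difference — which is non-zero between any
  two finite noise models. Measured type-I rejection when comparing two
  independent 9-column noise models (200 simulated cohorts, 25 splits) is
  ≈35%, not 5%, and stays far above nominal at 10 splits. This is the
  well-documented behaviour of resampled t-tests (Dietterich 1998; Nadeau &
  Bengio 2003), inherited by any analysis of this form; the corresponding
  acceptance test asserts the nominal band and is expected to fail, as a
  permanent, honest record of the property.

## Synthetic data: what it emulates and what it does not

The generators state a fixed world; their defaults are not tuned.

* **Cohort generator.** 14 lines, 72 tumors (two lines with 6, twelve with
  5), 9 IHC parameters + 21 IHC features + 3 PET parameters + 2 PET
  features. Each column is Gaussian on a latent scale — line effects with
  variance \(\sigma^2_b\), residuals with \(\sigma^2_w\) — then transformed
  (logistic for fractions, exponential for positive quantities, identity
  for skewness). A Gaussian hierarchy is the minimal structure matching a
  random-intercept analysis; no per-tumor values were ever published, so
  grand means are set to plausible field ranges (staining fractions ≈ 0.2,
  SUV ≈ 1, VD ≈ 50/mm², entropies ≈ 3 bits) — chosen once. The per-column
  heterogeneity ratios reproduce the reported within/total table *on the
  latent scale*; the nonlinear transforms shift observed-scale ratios
  somewhat (upward for the exponential at these variances), which is why
  exact ratio-recovery tests use identity-transform columns while the
  study-shaped cohort is used for shape, missingness and classification
  behaviour. Missingness follows the observed pattern (PET 4, MCT4 5,
  BrdU 3 of 72, injected completely at random, knocking out a marker's
  parameter and features jointly).
* **Image phantom.** Blob staining rasterized to the target fraction of the
  viable area (ground truth is the realized pixel count, so oracle tests
  are exact), ribbon-like vessel walks separated by ≥ 2 px (a 1-px
  perfusion halo can then never touch a different vessel, keeping the
  perfused count exact), non-overlapping point nuclei, and a necrotic
  region of the requested fraction. No attempt is made at realistic
  histology texture; a green test establishes that the measurement
  operators are correct, not that they are robust to real tissue
  appearance.
* **Volume phantom.** One spherical hot region at plateau SUV in uniform
  background, with concentrations derived exactly from the injection
  metadata; optional Gaussian noise on the SUV scale. No PET physics,
  partial-volume or reconstruction effects.

## Numerical and interface choices

* Deterministic tie-breaks everywhere (vote ties to lowest class index,
  split ties to first candidate encountered, inclusive threshold), so a
  seed reproduces results byte-identically — the end-to-end pipeline writes
  a manifest with MD5 digests and reruns verify identity.
* Images are read and written as plain-text ASCII PGM (P2) and volumes as a
  text raw grid with a JSON sidecar; configuration files are JSON. These
  plain-text stand-ins for TIFF/PNG/NIfTI/YAML keep the artifact fully
  text-based and dependency-light; the in-memory contracts are unchanged.
* The 510-model sweep and the repeated evaluations run at reduced tree
  counts (hundreds rather than the 20000 headline trees); tree counts and
  repeat counts are configuration fields recorded in the run manifest, and
  accuracy differences between 500 and 20000 trees are well inside the
  split-to-split SD at this cohort size.

## Known limitations

* The forest does not implement class weights, proximity measures or
  regression mode; only what the characterization analysis needs.
* REML is specialized to the one-way layout (by design — no crossed or
  multi-factor random effects).
* The phantom generators make no attempt at realistic spatial texture, so
  texture features on phantoms exercise the arithmetic, not biological
  discrimination.
* Train-only imputation is available (`evaluate_model(impute = "train")`)
  but the default replicates the full-table convention; with heavier
  missingness than a few cells per column the default would be optimistic.
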