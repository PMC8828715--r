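---
title: "Fused feature signatures for radiogenomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fused feature signatures for radiogenomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the statistical model behind each stage, the parameters a user can turn and
why their defaults are what they are, what the synthetic cohort generator
does and does not emulate, and the decisions taken where the design was
genuinely open.

## The analysis chain

The object of study is the relationship between a tumour's appearance on a
CT-like volume and molecular measurements from the same patients. The chain
is:

1. **2.5D representation.** Three orthogonal 2D views (axial, sagittal,
   coronal) through the physical centroid of the tumour ROI stand in for
   the full 3D volume when feeding 2D feature extractors.
2. **Feature blocks.** 431 handcrafted features from the 3D ROI; two deep
   blocks of 3 × 2048 = 6144 features from the views.
3. **Fusion and selection.** Concatenation to 12,719 columns, then
   MAD filter → mRMR → cross-validated multinomial LASSO, conditioning on
   histology class; the survivors form the fused signature `FF_Sig` (and,
   per block, `HC_Sig`/`TL_Sig`/`FT_Sig`).
4. **Clinical association.** k-means patient clusters on the z-scored
   signature, tested against T stage by Pearson's chi-square.
5. **Gene side.** Probe collapse, three sequential bottom-quartile gene
   filters, Spearman RR calling at p < 0.001, RR counting/overlap and
   directional strength tests, and pre-ranked gene-set enrichment with a
   permutation-normalised NES.

The selection chain assumes the histology label is a biologically
meaningful conditioning variable (it drives both the mutual-information
relevance term and the LASSO likelihood), and the RR stage assumes
monotone — not necessarily linear — feature–expression relationships, which
is exactly what the Spearman correlation measures.

## The 2.5D view contract

A view is built by: taking the single slice through the voxel nearest the
physical ROI centroid; cropping to the in-plane bounding box of the ROI;
resampling in-plane to isotropic pixels (nearest neighbour, pixel size =
the smaller of the two in-plane spacings); zero-padding the shorter side to
a square; resizing to 224 × 224 (nearest neighbour); and mapping the source
intensity range, by default [0, 4096], linearly onto [0, 255].

Three decisions here were open and are worth stating:

- **Single slice, not a slab.** Whether neighbouring slices should be
  averaged is unspecified in the protocols this follows; the single
  centroid slice is the simplest reading and is what `extract_views()`
  does. If the centroid slice misses a non-convex ROI, the crop falls back
  to the ROI's projection onto that plane.
- **Isotropy before padding.** "Preserving the aspect ratio" is only
  meaningful in physical units, so anisotropic in-plane spacing is
  resampled to isotropic pixels *before* the square padding. A property
  test asserts the foreground's physical aspect ratio survives the whole
  transform to within quantisation.
- **No integer cast.** Normalised intensities stay continuous (2048 maps
  to exactly 127.5); casting to 8-bit before the resize would quantise
  twice. The linear map commutes with cropping and nearest-neighbour
  resizing, so its position in the sequence is immaterial.

## The handcrafted catalogue (431 features)

The catalogue is engineered as 19 first-order + 17 shape + 27 GLCM +
8 × (19 + 27) wavelet-band features = 431, preserving the four classic
families at the stated total. The exact item list is fixed in code
(`first_order()`, `shape_features()`, `glcm_features()`,
`wavelet_features()`) and name-stable across runs.

Numerical conventions that matter:

- **First-order entropy/uniformity** use a 32-bin equal-width histogram
  over the ROI's own range; a constant ROI has entropy 0 and uniformity 1.
  MAD-about-median is unscaled (no 1.4826 consistency factor): the MAD of
  {1,2,3,4,5} is exactly 1.
- **Shape.** Surface area uses the exposed-face convention (sum of
  foreground voxel faces not shared with another foreground voxel): a unit
  voxel has area 6 mm², a 2 × 1 × 1 block 10 mm². This convention is exact
  for the blocky fixtures the tests pin down, but for smooth digitised
  surfaces it converges to 1.5× the analytic area (the mean of
  |n₁|+|n₂|+|n₃| over a sphere), so sphericity of a digital ball plateaus
  near 2/3 rather than 1 — the tests assert agreement with a brute-force
  V/A oracle under the same convention, not closeness to 1. Axis lengths
  come from 4√λᵢ of the foreground coordinate covariance; the maximum 3D
  diameter is computed over surface voxels only (where the maximum is
  attained).
- **GLCM.** Intensities are quantised to 32 equal-width levels over the
  ROI range; co-occurrence counts accumulate over 13 unique 3D directions
  at distance 1 (one per opposite-direction pair), restricted to in-ROI
  voxel pairs, then the matrix is symmetrised and normalised to sum 1.
  Entropies are base-2. Degenerate cases are defined, not errors:
  correlation of a constant ROI is 1, the maximal correlation coefficient
  of a matrix with fewer than two occupied levels is 1; a single-voxel ROI
  (no pairs) is an error.
- **Wavelets.** A single-level *undecimated* 3D transform (Coiflet-1,
  periodic boundary, filters centred at tap 3) keeps all 8 subbands on the
  original voxel grid, so the original ROI mask applies unchanged — no
  mask-downsampling ambiguity. Each band contributes the 19 + 27
  first-order and GLCM statistics over the masked voxels. The analysis
  filters are applied as-is (low-pass sums to √2 per axis), so the LLL
  band of a constant volume is 2^{3/2} times the constant; detail bands of
  a constant volume vanish, which the tests assert.

## Deep blocks and the filter-bank stand-in

Training or fine-tuning a CNN is out of scope here; what the pipeline needs
is the *contract* of a pooled CNN layer: view (224 × 224) → `width` real
numbers, deterministically. `filterbank_standin(seed, width = 2048)`
fulfils it with an 8 × 8 average pooling, a bank of 5 × 5 kernels (a fixed
catalogue of oriented edge/line/blob/corner detectors followed by seeded
unit-norm Gaussian projections), a seeded bias, rectification, and global
average pooling. Two stand-ins with different seeds give distinct blocks
and play the roles of the transfer-learned and fine-tuned extractors in
synthetic runs. A real network can be dropped in behind the same
`view_extractor` contract without touching the rest of the chain.

The stand-in is *not* a CNN substitute in any representational sense; it
exists so that selection has plausible, texture-sensitive deep-block signal
to work with. A seeded test verifies that phantoms with different texture
amplitudes are separated by a usable fraction of stand-in features.

## Selection: MAD → mRMR → LASSO

- **MAD filter** (`drop_quantile = 0.25`): features whose MAD across
  patients falls strictly below the bottom quartile of the MAD distribution
  are dropped; zero-MAD features always are. The quartile mirrors the
  bottom-quartile convention of the gene filters; no published threshold
  exists for this stage, so it is configurable.
- **mRMR** (`k = 100`): features are discretised to 3 states at
  mean ± 1 sd, and greedy forward selection maximises the MID criterion
  `MI(f; y) − mean MI(f; selected)`. MID-with-3-state-discretisation is the
  canonical formulation of the method; ties break by original column order
  so the trace is deterministic, and the greedy trace is tested against an
  exhaustive evaluation on small instances.
- **LASSO**: multinomial rather than one-vs-rest (the histology label has
  three classes), grouped selection = any-class non-zero coefficient at
  λ*, features standardised inside the fit. The λ path is 100 values
  log-spaced over four decades below the smallest all-zero penalty; folds
  are class-stratified and seeded, and λ* minimises mean CV deviance. An
  empty selection is returned as an empty signature — the pipeline treats
  "signature not generated" as a reportable outcome, not a failure, because
  a block genuinely may contribute nothing after fusion.

## Gene filtering and RR calling

Probe collapse discards probes mapping to zero or several gene symbols and
averages the rest per gene. The three gene filters run *sequentially*, each
recomputing its quantile on the current survivors — the closer reading of
the narrated protocol ("the remaining genes were then filtered…"). With
continuous statistics this removes floor-quantile counts exactly
(100 → 75 → 56 → 42 at q = 0.25); ties at the entropy threshold can only
spare genes, never remove extra ones (strictly-below rule). "Absolute
expression level" is interpreted as the mean expression across patients;
the entropy filter uses a 16-bin histogram over each gene's own range, with
zero-range genes assigned entropy 0.

RRs use Spearman ρ via average ranks with the t approximation on n − 2
degrees of freedom, raw p < 0.001 and *no* multiple-testing correction, as
in the protocol this follows; a Benjamini–Hochberg mode exists but is off
by default. Zero-variance features or genes are skipped with a warning
(ρ undefined). Strength comparisons between signatures are one-sided Welch
t-tests on |ρ| within each correlation direction — the published protocol
says only "two-sample t-tests", so unequal variances (the safer choice) and
the one-sided "fused is stronger" alternative are this package's decisions;
identical inputs give t = 0, p = 0.5 rather than an error.

## Pre-ranked enrichment

The ranking metric is the *signed* ρ, descending, with lexicographic
tie-breaks ("strength of the correlation" could also be read as |ρ|; signed
ρ keeps the two-tail structure GSEA expects). The ES is the classic
weighted running sum (weight exponent p = 1; p = 0 recovers the unweighted
Kolmogorov–Smirnov statistic, which is tested against a direct oracle and
against fgsea). The null is random same-size gene subsets of the ranked
universe — with per-feature rankings there is no phenotype to permute — and
the NES normalises by the mean |null ES| of the *same sign* as the observed
ES, with add-one-smoothed permutation p-values. Gene sets are filtered to
15–500 members after intersection with the universe.

Two aggregation rules are this module's own: each signature feature ranks
only its RR-significant genes (p < 0.001), falling back — flagged — to the
full ranking when fewer than 15 such genes exist; and a gene set "has an RR
with the signature" when any feature scores it at permutation p < 0.05,
reporting the extreme-|NES| feature. The published protocol reports one NES
per set per signature without stating its combination rule.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the structure the pipeline consumes:

- **Volumes**: ellipsoidal tumours (base radius U(5, 13) mm, per-axis
  anisotropy U(0.85, 1.15)) on a 40³ grid at 1 mm spacing, tumour voxels =
  base intensity 1000 + a seeded sum of four low-frequency sinusoids
  (wavelengths 8–20 mm, amplitude = `texture_scale`) + Gaussian noise
  (sd 20), background noise only, clipped to [0, 4096]. The sinusoid
  texture is deterministic, spacing-aware, and rich enough to give GLCM and
  wavelet features real structure.
- **Clinical labels**: histology by texture-amplitude tertile (so the
  supervised selection stages have signal to condition on), T stage by
  realised tumour-volume quartile (so geometry-sensitive features associate
  with stage).
- **Expression**: gene baselines N(mean U(5, 11), sd U(0.4, 1.5)); planted
  genes are rank-coupled to the realised values of their target feature
  through a Gaussian copula with latent correlation r = 2 sin(πρₛ/6), the
  exact inverse of the bivariate-normal Spearman relation, so the expected
  realised Spearman equals the planted strength; strength 1 with zero rank
  noise gives ρ = 1 exactly. All other genes are independent of the images.
- **Gene sets**: planted sets draw ≥ 80% of members from the planted
  genes; decoys are uniform; GMT round-trips exactly.

What it does **not** emulate: CT physics and lung anatomy, segmentation
error, batch effects, expression platform differences, or correlated gene
modules beyond the planted links. Passing tests therefore demonstrate that
the *pipeline machinery* recovers known structure at realistic sample
sizes — not that any biological claim transfers to real cohorts.

## Problem sizes and seeds in the test-suite

The validation suites run at sizes chosen to make their statistics decisive
on a single CPU: oracle comparisons use ≤ 6³ ROIs, 8-feature mRMR
instances and 20-gene rankings; null calibration uses a link-free
40-patient, 25,000-gene cohort (10⁵ Spearman tests, so the expected 100
sub-α calls carry a ~±10 sampling sd against a ±50 acceptance band);
planted recovery uses 80 patients and 32 links of strength 0.6, where the
t-approximate detection threshold (|ρ| ≈ 0.36) leaves a large margin.
All randomness is seeded; the suites are deterministic.

## Known limitations

- The handcrafted catalogue matches the four families and the 431 total of
  the protocol it follows, but item-by-item identity with any external
  feature list is not claimed (no published inventory to match), and
  bit-compatibility with other radiomics software is a non-goal.
- The GLCM averages counts over directions before normalising; per-angle
  feature variants are not provided.
- The LASSO stage inherits glmnet's behaviour near saturated fits at the
  small-λ end of the path; the chain only consumes λ*, which lies among
  the converged solutions.
- The permutation null for enrichment treats genes as exchangeable within
  the ranked universe; correlated gene modules (absent from the generator
  except as planted links) would make it anti-conservative on real data.
- Only axis-aligned geometry is tested for rotation invariance; arbitrary
  rotations interact with voxelisation and are out of scope.
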