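---
title: "Methods: weighted-ensemble classification of pulmonary lesions in radial EBUS images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted-ensemble classification of pulmonary lesions in radial EBUS images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the model

Radial-probe endobronchial ultrasonography (EBUS) images a pulmonary lesion
as a 360° B-mode view around a miniature probe at the image centre. Benign
lesions tend to show homogeneous speckle; malignant lesions show
heterogeneous echotexture — hyperechoic dots and arcs, anechoic (necrotic)
patches. `ebusemble` classifies a lesion as benign or malignant by fusing
three complementary classifiers with a weighted soft vote:

1. **Tabular model (P1).** 85 radiomics features of the lesion region
   (shape-2D, GLCM, GLDM, GLRLM, GLSZM, NGTDM, and an adaptive weighted-sum
   GLCM heterogeneity statistic) plus 4 clinical covariates (gender, smoking
   history, age, lesion-size category), filtered by mutual information
   (keep MI > 0) and fed to a 1000-tree random forest. P1 is the soft vote:
   the fraction of trees voting malignant.
2. **Single-image model (P2).** The whole frame, resized to 64×64, through a
   frozen convolutional feature extractor with a trainable softmax head
   (the transfer-learning pattern), trained with SGD (learning rate 1e-4,
   momentum 0.9, batch 32) and cross-entropy.
3. **Multi-patch model (P3).** Every 32×32 window tiled inside the 2–5 mm
   annulus around the probe intersected with the lesion mask is classified
   independently by a small CNN (four 3×3 conv stages with 8/16/32/64
   kernels, batch-norm, ReLU, 2×2 max-pooling, dropout 0.25; FC 256 → 2;
   Adam, lr 0.001, batch 128). P3 is the malignant-patch ratio
   `nM / (nM + nB)`, and the per-image call is malignant iff `P3 > T` with
   `T = 0.63` (a value exactly at `T` is benign).

The fused probability is `P = w1·P1 + w2·P2 + w3·P3` with `w ≥ 0`,
`w1+w2+w3 = 1`; the lesion is malignant iff `P > c`. Defaults
`(w1, w2, w3) = (0.41, 0.08, 0.51)` and `c = 0.53` are the published
operating point; `optimize_ensemble()` re-derives weights and cutoff by
exhaustive grid search (step 0.01 on the simplex and on the cutoff),
maximizing calibration accuracy with ties broken toward the smallest cutoff
and then the lexicographically smallest weights. Because the simplex
vertices are on the grid, the optimized calibration accuracy can never fall
below that of any single model.

## Preprocessing

**Contrast stretching.** With intensities normalized to [0, 1], values
below `L` map to 0, above `H` to 1, and in-band values to `x^γ`. `L` and
`H` default to the 1st and 99th percentiles of the sorted intensities
(`percentile_thresholds()`), which widens a typical EBUS histogram to the
full 8-bit range. γ defaults to 1 — no reference value was available, so the
exponent is exposed in configuration rather than guessed. The map is
monotone for all valid parameters; a constant image has no contrast to
stretch and is rejected.

**Boundary detection.** `detect_boundary()` casts `n_rays` (default 360)
equally spaced rays from the probe centre. Each radial intensity profile is
smoothed (moving average, 5 px); the boundary radius is the first sample
past the probe disc where the profile stays below `drop_frac` (0.45) of its
running maximum *and* below an absolute dark floor (0.08) for `persist`
(20) consecutive samples — the floor distinguishes anechoic tissue inside
the lesion (which stays above it after contrast stretching) from true
background, and samples beyond the image edge count as dark. The running
maximum starts past `min_radius_px` so the bright probe disc cannot
dominate it. Radii are median-filtered over angle (window 5) and the mask
is filled as `r ≤ R(θ)` with `R` interpolated linearly in angle, so the
filled area is insensitive to the ray count (an 8-ray circle fills the same
area as a 360-ray one). These defaults were calibrated on phantoms, where
the detector reaches Dice ≥ 0.95 against ground truth; they are arguments,
not constants.

**Patch selection.** Ring radii (2 mm, 5 mm) are converted to pixels by the
image calibration (default 0.09 mm/px, making the annulus ≈ 33 px wide — one
row of 32×32 tiles). A window is kept when **all four corner pixels** lie
inside ring ∩ mask; this is stricter than a centre-inside rule and
guarantees windows touch only annulus-and-lesion tissue. The tiling is
greedy in row-major order from the top-left-most qualifying origin, since
the lattice phase is otherwise unconstrained; windows are axis-aligned,
non-overlapping, half-open `[r, r+32) × [c, c+32)`. The greedy rule is
regression-tested against an exhaustive enumeration oracle.

**Augmentation.** Training images only. Malignant images gain exact 90° and
180° rotations (3× total); benign images additionally gain horizontal and
vertical flips (5× total), balancing the classes (99/61 originals become
297/305). Only lossless 90°-multiple transforms are used — no interpolating
rotations — and masks, probe centres and metadata transform consistently.
Applying augmentation to the test split is an error by construction.

## Radiomics

In-mask intensities are quantized to 32 equal-width bins over the in-mask
range (fixed bin count; 32 levels is the standard operating point for
co-occurrence statistics on ultrasound, and the count is configurable).
GLCM features use distance-1 offsets at 0°/45°/90°/135°, symmetrized and
normalized, with features averaged over the four angles; GLRLM likewise
averages its four directions; GLDM, GLSZM and NGTDM are direction-free.
Conventions for degenerate regions are fixed and documented: correlation on
a constant region is 0, information-measure features are 0 when marginal
entropies vanish, coarseness is capped at 1e6 when its denominator
vanishes. GLDM dependence is `1 +` the number of in-mask 8-neighbours with
an identical level (tolerance 0). GLSZM zones are 8-connected.

The **AWS** feature ("adaptive weighted-sum of the upper and lower
triangular GLCM") is computed on the *unsymmetrized* normalized GLCM:
`S_U = Σ_{i<j} p(i,j)·|i−j|`, `S_L = Σ_{i>j} p(i,j)·|i−j|`,
`w = S_U/(S_U+S_L)` (0.5 when both vanish), `AWS = w·S_U + (1−w)·S_L`,
averaged over the four angles. It is zero exactly when all co-occurrence
mass is diagonal (perfectly homogeneous texture) and reduces to `S_U` on a
symmetric matrix. This is our reading of the feature's name and
heterogeneity semantics; the original closed form lives in prior work that
is not reproduced here, so the definition is documented as an
interpretation rather than inferred intent.

Shape-2D descriptors (area, contour perimeter, perimeter/area, major/minor
axis from 4·√eigenvalues of the coordinate covariance, elongation,
circularity `2√(πA)/P`, maximum diameter, equivalent diameter) use the
outer contour polygon; a single-pixel mask has maximum diameter 0 by
convention and perimeter falling back to its 4 exposed edges. Every matrix
feature is verified against an independent loop-based brute-force
implementation to 1e-9 on random grids, and angle-averaged features are
invariant under exact 90° rotation to 1e-9.

## Feature selection and the forest

Mutual information against the label uses the plug-in contingency estimate
for discrete features and the Ross (2014) k-nearest-neighbour estimator
(k = 3) for continuous ones — chosen for small-sample robustness; whether
the original analysis discretized its features is unknown, so the estimator
is a documented choice. Estimator noise around zero is clipped at 1e-6:
features with MI above that survive. The number selected is data-dependent
and therefore logged, not asserted (on our phantoms it is typically most of
the 89). If nothing survives, the top-scoring feature is kept with a
warning. The forest uses 1000 trees and Gini splits; `randomForest` exposes
terminal node size rather than a minimum split size, and its classification
default (nodesize 1) allows any node with ≥ 2 cases to split, which matches
a minimum-split of two. Clinical covariates are encoded ordinally (smoking
non/ex/current → 0/1/2); forests are invariant to monotone encodings, so
the choice is innocuous.

For ensemble calibration the training-set P1 uses **out-of-bag votes**: with
1000 trees the in-bag probabilities are essentially 0/1 and would tell the
grid search nothing about the forest's reliability. Whether weights should
be calibrated on the training set or a held-out split was an open design
point; calibration on training probabilities (OOB for the forest) is the
default, exposed as `calibration`.

## The CNN engine and the two image models

No deep-learning framework is part of this package's dependency set;
instead `ebusemble` carries a compact, fully seeded CNN engine (im2col
convolutions, 2×2 max-pooling, spatial batch-norm, inverted dropout, dense
layers, softmax cross-entropy, SGD+momentum and Adam) whose gradients are
validated against central differences in the test suite. Runs are
reproducible from one integer seed, single-threaded.

The patch CNN adopts same-padding convolutions so the spatial pyramid is
32 → 16 → 8 → 4 → 2 with a pool after every conv stage; the kernel counts
(8/16/32/64) and FC widths (256, 2) follow the published architecture. (The
published per-layer output sizes are mutually inconsistent with a pool
after every 3×3 conv; same-padding is the resolution that preserves every
other stated quantity.) The dropout rate is unstated in the source
material; 0.25 after each pool and after the FC stage is the default,
configurable. Patch-level class labels are inherited from the parent image,
the standard weak-labelling assumption of patch-based classification; the
per-image statistic counts hard argmax patch labels (ties toward benign)
because the aggregation rule is defined on patch counts, not probability
averages.

The single-image model's production configuration would consume a large
pretrained backbone; this package's first-class configuration is a compact
frozen extractor (8/16/32-kernel conv stages, seeded He initialization)
with only the softmax head trained — the same freeze-the-trunk,
train-the-head pattern. The freeze contract is asserted bitwise in tests.
Requesting a pretrained backbone name raises an informative error rather
than silently substituting. Epoch count was unstated; the head trains up to
50 epochs with early stopping on a training-loss plateau (patience 10).

## The phantom generator

`generate_phantom()` emulates the features the classifiers rely on: a
bright probe disc at the centre (radius 0.7 mm — a 20 MHz miniature probe);
a star-convex lesion (low-order harmonic perturbation of a base radius, so
the ray-cast detector has a well-posed target); multiplicative speckle as a
mean-one Rayleigh envelope smoothed with a small Gaussian kernel (standard
B-mode phantom practice); dark speckled background. Malignant phantoms add
hyperechoic dots (0.8 dots/mm², Gaussian bumps), 3 hyperechoic arcs, and
anechoic patches covering ≈ 6% of the lesion; benign phantoms are fully
homogeneous (dot density 0). The defaults were fixed once — chosen so the
two classes differ in the same qualitative way real benign/malignant
echotexture differs — and the class separation they induce (e.g. higher
mean per-patch GLCM contrast in malignant phantoms) is asserted in tests.
Frames are generated grayscale: B-mode is monochrome, and the models
replicate channels at input.

Cohort metadata is drawn class-conditionally from the study population's
distributions: malignant age ~ N(64.32, 13.21²), benign ~ N(57.63, 15.51²),
both truncated to [17, 86]; gender, smoking and lesion-size proportions
follow the published class-wise counts; the phantom's lesion radius is
drawn conditional on its size category (< 3 cm vs ≥ 3 cm diameter, capped
to fit the frame). The split is stratified 80:20 with `round(0.8·n)`
training cases per class — 124/76 gives exactly the published 99/61.

**What the phantoms do not emulate:** acoustic physics (attenuation,
shadowing, refraction), probe contact artefacts, air bronchograms,
calcification, operator variability, or inter-patient texture diversity.
Passing tests on phantoms demonstrates that the pipeline's machinery is
correct and that it can recover a known class structure — not that the
published clinical accuracies transfer to real data, which are not
distributable.

## Problem sizes and numerical choices

The full synthetic study (tests and `scripts/acceptance.R`) runs 124 + 76
phantoms at 388×388 px. The pixel calibration (0.09 mm/px) is unchanged, so
the 2–5 mm annulus geometry in pixels is identical to a full-size frame;
388 px simply bounds the lesion radius and keeps a complete run in a few
minutes of one CPU. Patch-CNN training defaults to 8 epochs and the head to
40 in the pipeline. Unit tests use smaller cohorts and shorter schedules.

Seeds fan out from the single global seed by fixed offsets (cohort +0,
forest +101, single-image +201, patch CNN +301), so each module is
reproducible in isolation. Ties in grid optimization resolve toward the
smallest cutoff, then lexicographically smallest weights; a fused
probability exactly at the cutoff is benign; a patch ratio exactly at T is
benign. Images with zero qualifying patches have undefined P3: the ensemble
renormalizes `(w1, w2)` for those images and records the fallback.

## Known limitations

- The boundary detector is a documented stand-in for the original
  ray-tracing reference, calibrated on phantoms; on real frames with probe
  contact loss or shadowing its absolute dark-floor assumption may need
  retuning.
- The AWS formula is an interpretation of its published name and semantics.
- Radiomics values are not bit-compatible with any specific external
  package version; cross-checks are tolerance-based against the built-in
  brute-force oracle.
- The single-image model's compact backbone is far smaller than a
  pretrained network; on real data its contribution (like the published
  w2 = 0.08) is expected to be the smallest of the three.
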