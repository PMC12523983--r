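---
title: "Methods: feature extraction, selection and classification in phenotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature extraction, selection and classification in phenotrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotrack)
```

# Overview

phenotrack turns a time-lapse movie with labelled masks and a tracking table
into fixed-length per-cell feature profiles, ranks those features by how well
they separate labelled populations, and classifies cells with boosted trees.
This vignette is the package's own account of the models and the choices
behind them: what is computed, with which conventions, why the defaults are
what they are, and what the synthetic tests do and do not demonstrate.

# Data model and conventions

Pixels are indexed 0-based with x = column and y = row; tracking coordinates
are real-valued and rounded half-away-from-zero when a mask label must be
looked up. Frames are indexed 0-based internally; TrackMate's `FRAME` column
already is, and the generic dialect declares its base via `frame_base`
(default 0) because tracker exports disagree. Label 0 is background.

Track rows whose rounded centroid lands on background are rescued by taking
the nearest non-zero label within a Chebyshev radius of 2 pixels
(configurable). The radius is deliberately small: centroids of correctly
segmented cells land inside or within a pixel or two of their region, while a
larger radius would start capturing neighbouring cells. Rows that remain
unresolved are dropped with a warning rather than guessed.

# Per-frame features (72)

The registry is fixed at 72 features — size 8, shape 12, texture 48,
movement 1, density 3 — and versioned in code (`feature_registry()`); the
downstream profile width of 1083 depends on it and is frozen.

**Size and shape.** Area is the pixel count; Perimeter counts unit pixel
edges between foreground and background (a 10×10 square has perimeter 40).
This edge-count convention is exactly computable and hand-checkable; smooth
(Crofton-style) estimators trade that away for lower bias on round objects
and are intentionally not used. The convex hull is taken over pixel centres;
ConvexArea counts pixels whose centres fall inside or on the hull, so a
convex mask has Solidity exactly 1. Major/MinorAxisLength come from the
ellipse with matching second central moments (4·√eigenvalue). Degenerate
conventions: a single-pixel mask reports AspectRatio 1 and Eccentricity 0;
skewness and kurtosis of constant data are 0. Boundary radius statistics use
the 4-connectivity boundary pixels; curvature statistics are the signed
turning angles along the Moore-traced outer boundary polygon. Disconnected
masks (which arise when touching cells overpaint each other) are reduced to
their largest 8-connected component with a warning. Cells touching the image
border are retained and flagged (`on_border`) for optional filtering.

**Texture.** Six first-order statistics of the masked intensities plus ten
co-occurrence statistics, at three scales: the original crop and 2× / 4×
block-mean downsamples (mask kept where at least half the block is
foreground). Intensities are quantised per cell to 16 grey levels by min–max,
which makes every co-occurrence statistic invariant under positive affine
intensity rescaling — i.e. robust to illumination and gain differences
between wells. Co-occurrence counts are accumulated symmetrically at distance
1 for the four offsets (0°, 45°, 90°, 135°); the ten statistics (ASM,
contrast, correlation, variance, homogeneity, sum average, sum entropy,
entropy, dissimilarity, sum variance) are computed per offset and averaged
over offsets that contain at least one valid pair. Computing per offset and
averaging (rather than pooling counts first) is the classical Haralick
treatment and keeps the hand-enumerable two-value checkerboard case exact:
horizontal and vertical contrasts of 15² = 225 and diagonal contrasts of 0
average to 112.5. A constant-intensity cell maps to a single level: ASM 1,
contrast 0, entropy 0, and correlation 0 by the zero-variance convention.

One caveat worth knowing: the block grid of the downsampled scales is
anchored at the crop origin, so the s2/s4 texture values are exactly
90°-rotation invariant only when the crop's bounding box is a multiple of the
block size; for other shapes the boundary blocks differ slightly. Size and
shape features are rotation invariant unconditionally, and everything is
translation invariant.

**Movement and density.** DisplacementFromPrev is the Euclidean distance to
the previous trajectory frame's centroid (0 on the first frame).
NeighbourCount counts other-cell centroids within 100 px (configurable — at
typical 20× magnification a few cell diameters); NearestNeighbourDistance
falls back to the image diagonal when the cell is alone, a finite sentinel
that keeps the feature defined; LocalDensity sums 1/max(d, 1) over other
cells, a soft crowding measure that saturates below one pixel.

# Time-series summarisation (15 per feature + 3)

Each feature series along a trajectory is summarised by mean, median, sample
SD, skewness, excess kurtosis and max, plus nine statistics from an
orthonormal Haar decomposition at levels 1–3: per level, the detail energy
Σd² and the largest positive and negative detail (MaxAscent/MaxDescent).
Detail coefficients are (x₂−x₁)/√2 on pairs, with deeper levels recursing on
the approximations (x₁+x₂)/√2; odd lengths are right-padded by repeating the
last value at each pairing step. On dyadic lengths the transform is exactly
orthonormal and the tests verify the Parseval identity (Σ level energies +
Σ approx² = Σx²) to 1e-10. The Haar summaries capture *when and how sharply*
a feature changes — a cell that rounds up abruptly and one that drifts slowly
can share identical means but differ strongly in level-1 detail energy.

Three whole-trajectory features close the profile: total track length, net
displacement and the convex-hull area of the visited centroids. Profiles are
ordered registry-major (feature 1's 15 summaries, then feature 2's, ...),
then the 3 trajectory features: 72 × 15 + 3 = 1083, always.

**Minimum track length and gaps.** Trajectories shorter than 8 frames are
excluded (with a logged reason, not an error): 8 = 2³ is the natural support
of a level-3 Haar analysis. Tracking gaps of up to 3 missing frames are
bridged by linear interpolation of the per-frame features and centroids —
this keeps the series contiguous for the wavelet transform and is exact for
locally linear drift; longer gaps split the trajectory at the gap and each
qualifying segment is profiled separately (ids suffixed `.1`, `.2`, ...).
Interpolation never alters a gap-free series.

# Separation scores and the elbow threshold

For G labelled classes, a feature's separation score is VB/VW with
VB = Σ n_g (x̄_g − x̄̄)² / (N−G) and VW = Σ (n_g−1) s²_g / (N−G). The score is
invariant under affine rescaling of the feature and under relabelling or
reordering of cells. Degenerate conventions: VB = 0 scores 0 regardless of
VW; VW = 0 with VB > 0 scores +Inf (classes internally constant yet
different — maximally discriminatory). Features with non-finite values in
some cells are scored on the finite subset and flagged.

The threshold is picked by the elbow method on the descending score curve:
interpolate a straight line from the maximum to the minimum score and take
the score with the greatest vertical distance *below* the line. Signed (not
absolute) distance is used deliberately: on a descending convex score profile
the elbow lies below the chord, and points above the chord are in the steep
initial descent, not at the transition to the plateau. Ties take the smallest
index (fewest features — conservative). Infinite scores are ranked first and
always selected but excluded from the chord fit so they cannot flatten the
line; with two or fewer finite scores the threshold degenerates to the
minimum (everything selected). Selection is inclusive (score ≥ threshold), so
the selected set is never empty. No multiple-testing control is applied —
this is a ranking procedure, not hypothesis testing.

# Classification, clustering, PCA

Classification uses a gradient-boosted decision-tree ensemble (XGBoost,
multiclass softprob), trained single-threaded with a fixed seed for exact
reproducibility. Defaults — 200 trees, depth 4, learning rate 0.1 — are
ordinary middle-of-the-road boosting settings for tabular data of this size
and are exposed in the config. Features are z-scored with training statistics
(stored in the model's metadata); trees do not need this, but it keeps one
shared preprocessing path with PCA and clustering, and predictions on new
tables are checked against the training feature schema by name. Accuracy is
reported per class as the TPR (100 · diagonal / row sum of the confusion
matrix) plus the macro average, which is the honest summary under class
imbalance. Train and test should come from independent acquisitions
(different wells or simulations); a seeded stratified splitter is provided
for convenience but no automatic splitting is imposed.

`regroup_labels()` remaps classes (e.g. cell lines → disease status) and
drops unmapped classes with a warning, so the same profile table can serve
several analytical groupings; scoring after regrouping equals scoring on
pre-grouped labels.

Clustering is Ward-linkage agglomerative on Euclidean distances over z-scored
selected features (deterministic). PCA z-scores columns by default (dropping
zero-variance columns with a warning); `scale = FALSE` gives covariance PCA,
whose explained-variance spectrum is invariant under orthogonal rotations of
the feature space — the z-scored variant is not, which is the expected
behaviour of correlation PCA, not a defect. Component signs are fixed by
making each component's largest-magnitude loading positive.

# The synthetic movie generator

`simulate_population()` is first-class, tested code, not a throwaway fixture.
Cells are rotated ellipses (pixel included iff its centre satisfies the
ellipse inequality) whose centroids follow isotropic Gaussian random walks,
reflected at the borders so cells never leave the frame and track lengths
stay well defined. Interior intensity is a class-level base plus Gaussian
noise; initial placements are rejection-sampled against overlap (100
attempts, then a capacity error). Per-frame labels are a seeded arbitrary
permutation — deliberately unstable across frames — so the track-to-mask
linking is genuinely exercised. Reproducibility protocol: one master seed,
with each cell's geometry, walk and noise drawn from substreams keyed by
(seed, cell index, frame), so adding a class appends cells without perturbing
existing trajectories. When moving cells touch, the later-painted cell
overwrites, but each cell's centroid pixel always keeps its own label, so
every track row remains resolvable; the resulting occasional disconnected
masks are exactly what the largest-component rule upstream handles.

The standard two-class motility fixture — 20 cells per class, 32 frames,
512×512, classes identical in every parameter except random-walk step SD
(0.5 vs 4.0 px/frame) — emulates a weakly vs strongly migratory cell-line
pair at desk scale. Those sizes keep a full simulate–extract–select–classify
cycle around half a minute while leaving the motility effect overwhelmingly
strong. What the simulator does *not* emulate: cell division and death,
shape dynamics (each cell's ellipse is constant over time), touching-cell
segmentation ambiguity, illumination drift, or realistic optical texture.
Passing tests on it therefore demonstrate the *mechanics* — dimension
contracts, invariances, formula correctness, recovery of a planted
between-class difference — not classifier accuracy on real imaging data,
where effect sizes are far smaller and features are correlated in ways the
generator does not reproduce.

# Numerical and degenerate-input choices

- Feature tables are plain CSV with full (15 significant digit) precision;
  round trips are lossless to at least 12 significant digits.
- Constant data: SD/skewness/kurtosis 0; single-bin entropy 0; single
  co-occurrence state gives ASM 1 and all contrast-type statistics 0.
- Elbow ties → smallest index; empty selection impossible by construction.
- Classifier requires ≥ 2 classes with ≥ 2 cells each; evaluation refuses
  test labels absent from training.
- Config files are YAML (`run_config()`), mirrored by CLI flags, with the
  CLI taking precedence; every pipeline stage writes a JSON metadata block
  with the resolved config, seed and registry version.

# Known limitations

- The 72-feature registry is this package's canon; other phenotyping tools
  compute overlapping but not identical sets, so absolute feature values are
  not portable across tools (rankings of strongly discriminatory features
  usually are).
- Gap interpolation is linear; cells manoeuvring sharply inside a gap are
  smoothed.
- The density features use raw centroid geometry and ignore cells that exist
  but were not tracked.
- Separation scores assume roughly comparable within-class spread; a single
  heavy-tailed class inflates VW for every feature simultaneously.
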