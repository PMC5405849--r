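---
title: "Super-region segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-region segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(surseg)
```

This vignette documents the science inside `surseg`: the models each stage
implements, what the tunable parameters mean, the numerical choices that
were genuinely open, and what the synthetic test bed does and does not
demonstrate about real data.

## The problem setting

Cryogenic soft X-ray and electron tomograms are 3D scalar grids with low
signal-to-noise ratio, low contrast, and (for limited tilt ranges)
anisotropic missing-wedge elongation. Fully manual voxel painting is slow
and subjective; fully automatic segmentation needs training data that
rarely exists for these modalities. `surseg` targets the semi-automatic
middle ground: sparse annotations, strong data representation, a
classifier, and spatial regularisation.

All volumes are arrays indexed `[z, y, x]` with `dim = c(nz, ny, nx)`;
indices on disk are 0-based and ranges half-open. Region ids at every
hierarchy level are contiguous 0-based integers. These conventions are
applied uniformly because the file formats involved (MRC, HDF5) disagree
about axis order; the I/O layer maps both onto this one convention
(MRC `mapc/mapr/maps` words are honoured; HDF5 datasets are stored so
C-order readers see `(z, y, x)`).

## Feature channels

Denoising and textural channels feed both the over-segmentation and the
descriptors:

* **Gaussian** smoothing (separable, reflect boundary padding). Sampled
  kernels are truncated at 4σ; derivative kernels are moment-corrected so
  that first-derivative kernels respond exactly with the slope on linear
  ramps and second-derivative kernels respond exactly on quadratics.
* **Total variation** (ROF: `0.5‖u−f‖² + w·TV(u)`, forward differences,
  Neumann boundaries) via Chambolle's dual projection, defaults
  `tol = 1e-4`, `max_iter = 200`. TV yields piecewise-smooth output with
  preserved edges — better for classification features — while Gaussian
  denoising, although it over-smooths, gives the more regular regions
  that suit supervoxel extraction; that is why `segment_volume()` runs
  SLIC on a Gaussian-denoised channel by default.
* **Derivative-based channels**: Gaussian derivatives (total order ≤ 2),
  difference of Gaussians, Laplacian of Gaussian, gradient magnitude,
  Hessian eigenvalues and structure-tensor eigenvalues (both via a closed
  form for symmetric 3×3 matrices, eigenvalues sorted descending).
* **Scale/rotation-invariant response**: per-voxel max of γ-normalised
  responses of a rotation-invariant base over a scale list. For the LoG
  base the normalisation exponent is the dimension-adapted
  `(D + 2)/2 = 2.5`: with the classic 2D exponent 2, the response of a 3D
  Gaussian blob of scale `s` would peak at `0.816 s` rather than `s`.

Every channel is deterministic and recomputable bit-exactly from its
stored parameters.

## The super-region hierarchy

**Supervoxels** are produced by a SLIC variant: localized k-means in joint
(intensity, z, y, x) space. Seeds sit on a fixed lattice of
`round(extent/spacing)` cells per axis; each cluster's assignment step
searches a window of ±spacing around its centre; the distance is
`D² = d_int² + m²·d_spatial²/S²` with `S` the geometric-mean spacing and
`m` the compactness (default 30, with intensity rescaled to [0, 100] so
compactness values are transferable between volumes). Five
assignment/update sweeps are enough in practice because seeds start on
the lattice. Afterwards each supervoxel is forced to be a single
26-connected component: fragments other than each label's largest
component merge into the face-adjacent region with the closest mean
intensity, ties resolved to the lowest label id, iterated until every
fragment is absorbed. The procedure contains no randomness. With the
default `spacing = c(10, 10, 10)` the mean supervoxel volume is ~1000
voxels (exactly 1000 on a 100³ grid, where the lattice fits perfectly).

Anisotropic voxel spacing is carried by the `volume` class but does not
currently influence the filters or the SLIC distance; on strongly
anisotropic data, per-axis `sigma` and `spacing` arguments are the
intended workaround.

**Megavoxels** group similar adjacent supervoxels. The construction here
is this package's own: greedy average-linkage agglomeration
(Lance–Williams updates) over the region adjacency graph, merging the
most similar adjacent pair while the descriptor distance is below
`similarity_threshold`, then absorbing megavoxels smaller than `min_size`
supervoxels into their most similar neighbour. Megavoxels are therefore
connected unions of whole supervoxels, and the three layers form an exact
nested cover. The full pairwise distance matrix is held in memory, which
is comfortable up to a few thousand supervoxels — the intended regime for
region-scale (not object-scale) work.

**Region adjacency graphs** record, for 6/18/26-connectivity, every pair
of regions with adjacent voxels and the exact count of such voxel pairs
(`boundary_count`), which later weights the MRF.

## Descriptors and classification

Supervoxel descriptors: per-channel **means**; **histograms** of k-means
quantised voxel descriptors (codebook fitted on a seeded 5% sample, 10
restarts); **textons** (PCA projection then k-means); and **sigma sets** —
per-region mean concatenated with the lower-triangular Cholesky factor of
the regularised channel covariance `Σ + εI`, `ε = 1e-6·tr(Σ)/C` (floored
at 1e-12 so the factor always exists; a single-voxel region degrades
gracefully to the `εI` factor). Histogram-type rows are probability
vectors; size-weighted mean rows reproduce the global channel means
exactly. Descriptors are z-scored per column by default.

Context is added by appending the unweighted mean of the graph
neighbours' descriptors (`φ_i = (s_i, mean_{j∈N_i} s_j)`), doubling the
width; an isolated region uses its own descriptor as the neighbour block.
Augmentation is single-ring: neighbours-of-neighbours already leak in
through the MRF, and recursing would blur small structures.

The default classifier is an **extremely randomized forest** (100 trees,
√C features per split, one random threshold per candidate feature,
single-threaded with a fixed seed for bit-reproducibility). Inverse
frequency class weights compensate for the extreme imbalance of stroke
annotations. Random forest, gradient boosting, an RBF-SVM with
probability calibration (noticeably slower), and multinomial logistic
regression are available behind the same interface. Probabilities are
renormalised to sum to one per region.

The **confidence** of a region is its maximum class probability (the
margin was the other candidate; maximum probability matches how the
confidence display is meant to be read and is bounded in `[1/L, 1]`).
`accept_by_confidence()` turns confident predictions into annotations
without ever overwriting existing ones, so iterating
annotate → train → accept grows the annotation set monotonically.

## MRF refinement

Unaries are `−log(max(p, 1e-6))` (the floor bounds the energy). Edge
weights are

```
w_pq = (b_pq / b_max) · exp(−‖φ_p − φ_q‖² / (2 σ_w²))
```

with `b_pq` the shared-boundary count normalised by the graph maximum
(per-graph normalisation keeps λ transferable between volumes) and `σ_w`
self-tuned to the median edge descriptor distance. The pairwise term is a
Potts *penalty on disagreement* `[c_p ≠ c_q]`: similar, well-connected
neighbours are pushed to the same label while dissimilar pairs (strong
boundaries) cost little to split.

Inference is alpha-expansion by repeated s-t min-cut (igraph max-flow).
For two labels a single cut gives the global optimum. For three or more
labels the expansion is warm-started from the ICM fixed point: expansion
moves only ever lower the energy from there, so the result is never worse
than ICM alone, and each individual expansion move is solved exactly via
the standard submodular reparameterisation. The reported energy is always
recomputed independently from the final labelling. With `λ = 0` the
result is exactly the per-region argmax. The default `λ = 1` is
deliberately gentle — it cleans up uncertain regions without fighting a
confident classifier; when the unaries are near-saturated (probabilities
≈ 0.95) visible smoothing needs λ of order 5–10.

A voxel-level variant (`refine_voxels_mrf()`) uses the chosen 6/18/26
neighbourhood with `b_pq ≡ 1`; it is intended for small regions of
interest, since the supervoxel-level problem is three orders of magnitude
smaller.

## Labels, post-processing and measurement

Labels form a forest; a child label's training and prediction are
restricted to regions with a *strict majority* of voxels inside the
parent segmentation (ties excluded — the conservative reading), and
regions outside keep the parent labelling. Painting works at any
hierarchy level: a stroke labels the voxels it crosses, or every voxel of
every supervoxel/megavoxel it touches.

Post-processing is per-label 3D binary morphology: hole filling (6-connected
background components not reaching the border) and opening/closing with a
ball element. Closing is implemented as the complement of the opening of
the complement, which preserves extensivity at the grid border; both
operations are idempotent. Cleaned masks are recombined
largest-object-first so no voxel ever carries two labels.

The object table reports, per 26-connected (configurable) component:
voxel count, half-open bounding box, centroid, and mean/variance/standard
deviation of a chosen channel. Variance is the *population* variance so a
single-voxel object has sd 0. "Location in X/Y/Z" is reported as both the
centroid and the bounding box, since either convention is used in
practice. Rule sets are AND-chains over these metrics, first matching
class wins, unmatched objects keep their source label, and recombination
after splitting is lossless.

## The synthetic test bed

`make_phantom()` builds what the acceptance harness runs on: an
ellipsoidal cell with nucleus, two nucleoli and non-overlapping random
organelles, phase means `(0.10, 0.35, 0.55, 0.75, 0.90)`, a smooth random
bias field of amplitude 0.05 (piecewise-smooth rather than constant, yet
below half the smallest phase gap so the noiseless phases remain exactly
threshold-recoverable), optional anisotropic z-blur mimicking the missing
wedge, and Gaussian noise with `sd = sd(clean)/snr`. At the default
`snr = 5` adjacent phase means sit ≥ 2.8 noise-sd apart: raw voxel
classification is unreliable at boundaries but region-level averaging is
well-posed — deliberately non-trivial, not hard. `sparse_annotations()`
emulates pen strokes: short straight runs inside each class, allocated
proportionally to class size, never exceeding the requested fraction.

The reference study conditions used throughout the tests are a 64³
phantom at snr 5 with 1% annotated voxels (the scaled-down analogue of
segmenting a ~950²×350 tomogram's central slab from two brief
annotations), plus a 100³ volume for the default supervoxel-size check;
these sizes keep the whole suite in tens of seconds while still
exercising every stage at realistic region counts.

What passing these tests shows: the pipeline recovers piecewise-smooth,
intensity-separated phases from sparse strokes under Gaussian noise, the
solvers attain their oracles, and all conservation/determinism contracts
hold. What it does not show: performance under structured reconstruction
artefacts (streaks, ringing), texture-defined (rather than
intensity-defined) classes, strong missing-wedge anisotropy, or
annotation noise — on real tomograms those are exactly the regimes where
the iterative annotate/train/accept loop and per-dataset channel choice
matter.

## Known limitations

* Megavoxel agglomeration is quadratic in supervoxel count (full distance
  matrix); use it for region-scale partitions, not object-scale ones.
* Voxel-level MRF refinement builds an explicit graph; it is meant for
  RoIs, not whole tomograms.
* Alpha-expansion with ≥ 3 labels is a strong local optimum, not global
  (global is NP-hard); on small random problems it sits within a fraction
  of a percent of the enumerated optimum.
* Voxel spacing is metadata only; filters treat the grid as isotropic.
* The SVM backend calibrates probabilities internally and is markedly
  slower than the forests on large region counts.
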