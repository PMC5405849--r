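# surseg — super-region segmentation of 3D biological volumes

Segmenting cellular volumes from cryo soft X-ray tomography, cryo electron
tomography or FIB-SEM is hard: the data are low-contrast and noisy, fully
automatic methods need training data that rarely exists, and manual voxel
painting of a 1000³ tomogram takes days. `surseg` implements the
middle road: a scriptable workbench that stretches a few minutes of sparse
user annotation over a whole volume.

The volume is first over-segmented into a three-layer **super-region
hierarchy** — voxels, *supervoxels* (SLIC: localized k-means in joint
intensity+space coordinates, ~1000 voxels each by default) and
*megavoxels* (agglomerated groups of similar adjacent supervoxels). Each
layer covers every voxel exactly once and respects strong image
boundaries, so annotating a handful of regions labels thousands of voxels
at a stroke. Regions are then described with 3D denoising and textural
feature channels (Gaussian, total variation, Gaussian derivatives,
DoG/LoG, gradient magnitude, Hessian and structure-tensor eigenvalues), a
probabilistic classifier (extremely randomized forest by default) is
trained on the annotated regions, and the per-region label probabilities
are spatially regularised by minimising the Potts Markov random field
energy

```
E(c) = Σ_p ψ_p(c_p) + λ Σ_(p,q) w_pq · [c_p ≠ c_q]
```

with unaries ψ_p(c) = −log p(c | x_p) and edge weights w_pq combining the
shared-boundary voxel count of regions p, q with the similarity of their
descriptors. Inference is alpha-expansion via s-t min-cut (exact for two
labels). Hierarchical label constraints (e.g. "nucleolus only inside
nucleus"), confidence-based acceptance for iterative annotation,
morphological clean-up, and per-object morphometry with rule-based label
splitting round out the workflow. MRC2014 and HDF5 volumes are read and
written natively; all intermediate products can persist in a single HDF5
sidecar file.

## Worked example

Everything is testable without data downloads through the built-in phantom
generator, which emulates a low-SNR cellular tomogram (background, cell
body, nucleus, nucleoli, organelles) with voxel-exact ground truth:

```r
library(surseg)

ph  <- make_phantom(shape = c(64, 64, 64), n_organelles = 8, snr = 5, seed = 1)
ann <- sparse_annotations(ph$labels, fraction = 0.01, seed = 2)  # ~1% strokes
res <- segment_volume(ph$volume, ann, seed = 3)

segmentation_accuracy(res$raw_labels, ph$labels)  # classifier alone
segmentation_accuracy(res$labels, ph$labels)      # after MRF refinement
```

which prints:

```
<phantom> 64x64x64 grid, 8 organelles, noise sd 0.02878
<annotation_volume> 64x64x64 grid, 2618 voxels labelled (0.999%)
<supervoxel_partition> 216 supervoxels on 64x64x64 grid (mean 1213.6 voxels)
raw voxel accuracy:     0.9453
refined voxel accuracy: 0.9497
```

From 1% annotated voxels the default pipeline labels ~95% of the volume
correctly, and the MRF refinement improves on the raw classifier argmax.
Supervoxel size is the main tuning knob: the default 10×10×10 spacing is
right for region-scale structures, while organelle-scale work wants finer
regions —

```r
res <- segment_volume(ph$volume, ann, spacing = c(6, 6, 6), seed = 3)
t   <- object_stats(res$labels, 4L, ph$volume$data)  # label 4 = organelles
nrow(t)  # objects found
```

```
<supervoxel_partition> 1331 supervoxels on 64x64x64 grid (mean 197.0 voxels)
refined voxel accuracy: 0.9569
organelle objects found: 7, sizes: 426, 262, 237, 223, 218, 217, 178
```

recovering 7 of the 8 generated organelles as separate objects, each with
size, bounding box, centroid and intensity statistics ready for rule-based
classification (`apply_rules()`, `split_labels()`) and CSV export
(`export_statistics()`).

A thin command-line wrapper is installed with the package
(`system.file("cli", "surseg", package = "surseg")`) with subcommands
`run` (declarative YAML pipelines with content-addressed caching),
`synth` and `supervoxels`; exit codes are 0 (ok), 2 (validation) and
3 (runtime error).

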