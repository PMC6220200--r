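---
title: "Methods: encoder-decoder segmentation of the proximal femur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoder-decoder segmentation of the proximal femur}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Structural MRI of the hip resolves the trabecular bone of the proximal
femur as a bright, marrow-filled network against darker soft tissue.
Quantitative measures of bone quality (topology of the trabecular
network, finite-element strength estimates) need a mask of the whole
proximal femur, and drawing that mask by hand takes an expert on the
order of hours per scan. `femurseg` implements the learning-based
alternative: voxelwise binary segmentation with encoder-decoder
convolutional networks, together with everything needed to train,
select, apply and evaluate such models reproducibly on a single CPU.

The network family is the U-net and its volumetric extension. An
architecture is fully determined by the tuple held in
`architecture_spec()`:

* `dims` — 2 for slice-stack networks (three consecutive coronal slices
  in, the center slice's mask out), 3 for whole-volume networks;
* `F` — feature maps in the first encoder level (doubling per level);
* `L` — number of encoder/decoder levels; each level is two `3^dims`
  convolutions with ReLU followed by `2^dims` max-pooling with stride 2,
  mirrored by a transposed-convolution decoder with skip concatenation;
* `padding` — `"padded"` (output size equals input size; no mirroring or
  tiling needed at inference) or `"unpadded"` (valid convolutions, 2D
  only; inference mirrors the image and averages overlapping tiles);
* `dilation_rates` — optional dilated-convolution pyramid replacing the
  two center convolutions: one padded convolution per rate (e.g.
  `r = 1, 2, 4, 8`), each with the plain center's feature-map count,
  concatenated along channels. This widens the receptive field of the
  center units (`receptive_field()`) so global connectivity of the femur
  can be captured without extra depth.

Weights are Xavier-uniform initialized and all biases start at 0.10. No
normalization layers are used — the reference protocol specifies none,
and the intent here is fidelity rather than modern defaults. Inputs are
z-scored per volume (MR intensities are in arbitrary units; some fixed
normalization is required for a stable optimization, and a per-volume
z-score is the weakest assumption available).

## The loss

With `y_i` the foreground indicator and `p_i` the softmax foreground
probability, the training loss is the class-re-weighted cross-entropy

```
CE = -(1/N) * sum_i [ (N_b/N) y_i log p_i + (N_p/N) (1 - y_i) log(1 - p_i) ]
```

where `N_p` and `N_b` count foreground and background voxels. The femur
occupies a few percent of the volume, so the re-weighting (foreground
errors weighted by the large background fraction) prevents the trivial
all-background solution. Weights are computed per training sample from
its own mask: the defining `N` is ambiguous between batch and corpus,
but at the stated batch size of 1 the two readings coincide, so the
per-sample reading is used. Probabilities are clipped at `1e-7` inside
the loss; single-class (degenerate) samples are excluded from training
with a warning rather than given zero weight.

## Training and model selection

`train_config()` defaults follow the reference protocol: Adam
(`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8` — canonical values, as
only the learning rate is specified upstream), learning rate `5e-5`,
batch size 1, left-right flip augmentation applied jointly to image and
mask with probability 0.5 (the cohort mixes left and right hips).
Early stopping monitors a validation score after a warmup of 30 epochs:
training stops when the score has not improved by at least `1e-4`
within the last 10 epochs, and the parameters of the best validation
epoch are returned. The monitored "validation accuracy" is not defined
precisely upstream; this package uses mean foreground Dice (DSC) at
threshold 0.5 over the validation subjects, recorded here as a design
gap. The patience window opens only after the warmup (a constant
validation score with warmup 30/patience 10 stops at epoch 40).

`stratified_folds()` performs stratified random sampling into `k`
disjoint folds whose total sizes differ by at most one and whose
per-stratum counts per fold differ by at most one; on an 86-subject
cohort with `k = 4` this yields the 21/21/22/22 split. The
stratification variable is the phantom cohort's binary stratum label
(emulating clinical fracture status, prevalence 36/86); the upstream
protocol does not name its stratification variable, so this is an
assumption. `crossvalidate()` trains one model per fold and predicts
each held-out subject exactly once.

The 2D unpadded variant is trained on full (admissible-size) slices
rather than patches; training on mirrored patches is a possibility left
open upstream and deliberately not taken, since it changes only the
sampling distribution, not the estimator.

## Inference

Padded models run in a single forward pass (per slice stack in 2D, per
volume in 3D); extents that are not multiples of `2^L` are zero-padded
to the next multiple and cropped back — the canonical 512/256/48 grids
never hit this path. Missing neighbours of edge slices in 2D are filled
by replicating the boundary slice.

Unpadded models see only a shrunken center of their input, so
`predict_tiled()` reflection-pads the image (edge voxel not duplicated)
and covers it with `plan_tiles()`: per axis the tile count is
`ceil(extent / output_extent)` with evenly spread, symmetric overlaps,
and per-voxel probabilities are averaged uniformly over all covering
tiles. The tile input size defaults to the largest admissible size whose
output window fits the image; the published 9-patch tiling is exactly
the plan produced when the output window is below half the image extent
on both axes. The exact tile offsets used upstream are unrecoverable;
only the covering/averaging contract is reproduced.

`binarize()` thresholds strictly (`p > t`; ties to background) and
`largest_component()` keeps the maximum-volume connected foreground
cluster, by default with 26-connectivity — the most permissive choice,
avoiding splits across the thin femoral neck; the upstream text does not
specify the adjacency. Post-processing defaults to on for 2D models
(which misclassify distant clusters) and off for 3D models, which learn
the global connectivity directly. When predictions made on a
downsampled working grid must be scored against the original grid, the
probability map is upsampled bicubically before thresholding
(`predict_subject(original_grid =)`); the upstream mapping back to the
original grid is unstated, and interpolating probabilities rather than
labels avoids inventing sub-voxel label geometry.

## Evaluation

`confusion()`, `dsc()`, `precision()`, `recall()`, `specificity()`
implement the standard overlap metrics; undefined ratios (zero
denominators) return flagged `NA` values that aggregation excludes and
counts. Surface distances use voxel-center coordinates in physical mm
(`(i*sx, j*sy, k*sz)`, 0-based), surfaces are foreground voxels with a
face-adjacent (6-neighbourhood) background or out-of-grid neighbour, and
`asd()`/`msd()` are the exact symmetric average / maximum (Hausdorff)
nearest-neighbour distances — brute-force exact, not approximated.

`curves()` builds ROC and precision-recall curves with thresholds at the
unique probability values (descending, predictions `p > t`, consistent
with `binarize()`), plus a final all-positive point. ROC area uses
trapezoids (conventional); average precision uses the step-wise sum
`sum (R_k - R_{k-1}) P_k`, so a perfect classifier scores exactly 1 with
no interpolation optimism. `optimal_threshold()` picks the PRC point
closest to `(P, R) = (1, 1)`, guarding simultaneously against over- and
under-segmentation; ties break to the lower threshold (favouring
recall). For threshold selection, voxels are pooled over the validation
subjects of a fold; per-subject APs are computed separately for the
statistics. Figure-style fold summaries average fold curves on a common
grid (`mean_curves()`); voxel pooling across folds is also available,
since the upstream choice between the two is not fully determined.

`wilcoxon_holm()` compares models by paired two-sided Wilcoxon
signed-rank tests on per-subject scores — exact null distribution for
n <= 25 without ties, normal approximation with tie and continuity
correction otherwise, zero differences discarded — with Holm's step-down
correction over all pairs and the usual `ns`/`*`/`**`/`***` coding.

# The phantom: a stated world

The study's MR dataset is available only on request, so the package
ships a parametric phantom (`generate_phantom()`) that emulates what the
networks must learn, not MR physics:

* geometry: a spherical femoral head, a cylindrical neck meeting a
  cylindrical shaft segment at the neck-shaft angle (default 130
  degrees) — the simplest shape with the head/neck/shaft topology the
  network must connect in 3D; no statistical shape model;
* appearance: bright marrow (default 180) on darker soft tissue (60),
  zero-mean band-limited trabecular texture inside the bone (Gaussian
  noise smoothed to a 1.5 mm correlation length, amplitude 12), a 1 mm
  darkened cortical rim at the boundary, and i.i.d. Gaussian noise
  (sd 8) everywhere;
* grid: desk-scale 96 x 96 x 48 voxels at (0.5, 0.5, 1.5) mm — this
  preserves the strong through-plane anisotropy of the
  0.234 x 0.234 x 1.5 mm acquisition while staying CPU-trainable;
  full-scale 512 x 512 x 48 generation is supported but not default;
* corruptions: `apply_lesion()` darkens a sphere-mask intersection
  (cyst-like hypointense focus; floored at background) and
  `apply_foldover()` adds a flipped, gain-scaled copy of one lateral
  band onto the opposite edge (aliasing). Both mirror documented failure
  modes; their magnitudes are free parameters, not calibrated claims,
  because the source describes the artifacts only qualitatively.

`generate_cohort()` draws per-subject geometry uniformly (by default
within +/-10% of the base parameters), assigns left/right laterality
with probability 0.5 (mirroring the geometry), and attaches a binary
stratum with probability 36/86 for stratified cross-validation.

What a green end-to-end test does and does not establish: phantoms are
high-contrast, artifact-free by default, and geometrically simple, so
recovering them (held-out DSC >= 0.90 with a 23k-parameter network in a
few epochs) validates the pipeline's plumbing — loss, optimization,
inference, threshold selection, metrics — not clinical segmentation
accuracy. The published accuracy figures (DSC ~0.95 on 86 subjects with
F = 32, L = 4 networks) require the clinical dataset and GPU-scale
training and are out of scope by design.

# Numerical choices and degenerate inputs

* Convolutions run as tap-wise gather + BLAS accumulation in C++;
  gradients are hand-derived and tested against central finite
  differences (max relative error < 1e-4 enforced; observed ~1e-7).
* Max-pool ties route the gradient to the first tap in scan order.
* Bicubic resampling uses Keys' cubic convolution kernel (a = -0.5) with
  replicated edges; it preserves constants exactly and is the identity
  at equal sizes. Masks resample nearest-neighbour to stay binary;
  probability maps are clipped back into [0, 1] after interpolation.
* Both-masks-empty DSC is 1.0 by convention, with a warning; empty-side
  surface distances are flagged `NA`.
* The dilated pyramid's concatenated channels feed the first decoder
  stage directly (its input width is set accordingly); no 1x1 reduction
  is inserted, because the source says only "concatenated". A reduction
  width can be added by editing the spec's decoder width, and the gap is
  recorded here deliberately.
* NIfTI-1 I/O is implemented in base R (no NIfTI package exists in the
  supported dependency set): little/big-endian, `.nii`/`.nii.gz`,
  uint8/int16/int32/float32/float64, `scl_slope/inter`, axis-aligned
  sform reorientation to a canonical order on read. It is validated
  against nibabel in the test suite.
* Seeding: one global seed fans out to per-component seeds through a
  fixed component-name hash (`derive_seed()`), so adding a pipeline
  stage never perturbs the randomness of earlier stages; all derived
  seeds stay below 2^31.

# Desk-scale acceptance settings

The end-to-end acceptance run trains the stated desk-scale
configuration (3D, `F = 4`, `L = 2`, padded; dilated variant
`r = c(1, 2)`) on twelve 96 x 96 x 48 phantoms for a fixed budget of 8
epochs with Adam at `1e-3`. These two values are the only deviations
from the paper-scale defaults (200-epoch ceiling, `5e-5`): a 23k-
parameter network on twelve high-contrast phantoms converges in a
handful of epochs, and the larger step size simply matches the tiny
problem scale. They were fixed from a single pilot run before the
acceptance thresholds were evaluated and are not tuned quantities.

# Known limitations

* No DICOM ingestion, bias-field correction, or multi-coil modeling.
* The phantom does not model intensity inhomogeneity, cortical
  microstructure, or realistic MR noise correlations.
* No hyperparameter search, learning-rate schedules, or mixed precision
  (explicitly deferred upstream as well).
* Uniform tile averaging only — no Gaussian blending, no test-time
  augmentation ensembling.
* Training is CPU-bound R/C++; paper-scale networks (F = 32, L = 4 at
  512 x 512 x 48) are out of reach in reasonable time, by design.
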