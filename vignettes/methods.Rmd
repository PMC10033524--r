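---
title: "Automated bladder wall and tumor segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated bladder wall and tumor segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bladder cancer staging hinges on whether a tumor has invaded the muscular
bladder wall, which makes separate, aligned delineations of the *wall* and
the *tumor* on T2-weighted MRI clinically valuable. Manual slice-by-slice
segmentation by radiologists is slow and rater-dependent. `bladderseg`
implements a fully automated volumetric pipeline: given a 3D T2 volume it
predicts, per voxel, one of three classes — background, bladder wall, or
tumor — with a family of 3D U-Nets that use *progressive dilated
convolutions*.

Clinical bladder MRI cohorts with expert masks are small and private, so
the package ships a synthetic phantom generator that reproduces the
geometry and contrast the pipeline assumes. Every stage can therefore be
exercised, tested, and benchmarked end to end on data generated in code.

## Data model and preprocessing

A case is three aligned NRRD volumes: the intensity image and two binary
masks (wall, tumor), indexed `(row, col, slice)` with the slice axis the
axial acquisition axis. Preprocessing follows a fixed recipe:

1. **ROI extraction** — the in-plane window rows/cols `[100, 400)` is
   cropped (the bladder reliably sits upper-central in this protocol),
   yielding `300 x 300 x 32`. The crop is 0-based half-open; the slice axis
   is centre-cropped or symmetrically zero-padded to 32 for volumes whose
   depth differs. Volumes narrower than 400 voxels in-plane are rejected —
   the fixed window is undefined for them.
2. **Resize** to `128 x 128 x 32` (trilinear for intensities,
   nearest-neighbour for masks so the label set survives). The reduction
   bounds memory during training.
3. **Normalization** to mean 0, standard deviation 1 per volume, over all
   voxels (not per slice, not foreground-restricted — the simplest reading
   of the recipe). A constant volume maps to zeros.
4. **Label encoding** — the two binary masks merge into one integer
   volume: wall 255, tumor 125, background 0, with overlap resolved to
   tumor (a tumor voxel is the clinically dominant call). One-hot channels
   are ordered (background, wall, tumor). The third class is
   "everything that is neither wall nor tumor", i.e. background as the
   complement, which includes the bladder lumen.

Resizing happens before normalization; the statistics are then computed on
exactly the voxels the network sees.

## Augmentation

Training cohorts are multiplied by a factor `na` per original volume, with
two standard scenarios:

| scenario | composition |
|---|---|
| `na = 10` | 3 positive rotations (5–10°) + 3 negative rotations (−10 to −5°), rotations 2/4/6 horizontally flipped, + 2 elastic fields × {original, flipped} |
| `na = 5`  | 2 positive + 1 negative rotation (rotation 3 flipped) + 1 elastic field × {original, flipped} |

Angles are drawn fresh per original volume. One further independently
drawn augmentation per case forms the validation set, so `x` originals
yield `x·(1 + na)` training and `x` validation volumes. All transforms are
applied with a single geometric map to image (trilinear) and labels
(nearest-neighbour), so image and label always move together.

Elastic deformation uses a smooth random displacement field: uniform
noise Gaussian-smoothed in 3D with `sigma` (default 8 voxels), normalised
to unit maximum and scaled by `alpha` (default 3 voxels — `alpha` *is* the
maximum displacement). The field displaces in-plane only; the slice axis
is left alone because slice spacing is coarse relative to the thin wall
shell. These defaults keep per-class voxel counts within 10% of the
original on phantoms, i.e. the deformation perturbs shape without
destroying class volume.

## Architecture

The segmentation network is an encoder–decoder with `B ∈ {4, 5, 6}`
resolution levels ("U-Net-4/5/6"). Unless noted, every convolution is
3×3×3, followed by batch normalization and PReLU.

* **Encoder** — per level, three convolutions with dilation rates 1, 2, 4
  (progressive dilation widens the receptive field without extra
  parameters); the first convolution of each level has stride 2 and
  performs the downsampling. The 5-level encoder therefore has 15
  convolutions. Striding applies at *every* level, including the first.
* **Bridge** — two normalized convolutions plus a residual block: two
  dilation-1 convolutions *without* normalization, PReLU-activated, summed
  with the block input through an identity path.
* **Decoder** — per level, parameter-free nearest-neighbour ×2 upsampling
  (inverting that level's stride, including clamped strides), channel
  concatenation with the dilation-4 encoder output at the matching
  resolution, then two normalized convolutions. The top decoder level has
  no encoder counterpart (level 1 already strides), so it upsamples and
  convolves without a merge.
* **Head** — a 3-filter (1,1,1) convolution + batch normalization + PReLU
  + softmax over the three class channels.

Filters start at `base_filters` (default 16) and double per level, capped
at 256; filter counts are not dictated by the architecture family, so they
are explicit, declared defaults. Skip merging is concatenation;
elementwise addition is available behind `merge = "add"` for
equal-channel configurations.

The default stride policy halves every axis per level while feasible; an
axis that can no longer halve (the 32-slice axis at level 6) keeps stride
1 from then on, e.g. the 6-level policy ends `(2, 2, 1)`. A custom policy
that would collapse an axis to nothing is rejected with the offending
level and axis.

Because no deep-learning framework is assumed, the package implements the
network directly: im2col + BLAS GEMM convolutions (forward and backward)
in C++, hand-derived backward passes for batch normalization, PReLU,
upsampling and the skip wiring, verified against numerical
differentiation. Batch normalization uses the current volume's statistics
at both training and inference time: with batch size 1 this is instance
normalization, which is deterministic and avoids calibrating running
averages on tiny cohorts.

## Training

Adam (learning rate 5e-4) minimizes voxel-wise categorical cross-entropy,
`mean over voxels of -Σ_i y_i log ŷ_i` over the three classes, with
probabilities clipped at 1e-7. The default batch size is 1 full volume —
full 128×128×32 volumes are memory-heavy, and the loss is averaged so the
scale is batch-size-independent.

After every epoch the validation loss and per-class validation Dice are
computed on plain argmax predictions (post-processing is a test-time
step); whenever the overall validation Dice improves on the running best
the model is checkpointed. Training stops at `max_epochs` (default 200) or
after `patience` (default 15) epochs without improvement; the patience
value is a declared default, since convergence epochs are data- and
hardware-dependent. A non-finite loss aborts with the offending epoch.

## Post-processing and evaluation

Predicted probability maps are cleaned with a bilateral filter before
thresholding: slice-wise 2D, per class channel, weighting neighbours by
spatial distance (`sigma_spatial = 3` voxels) and probability similarity
(`sigma_intensity = 0.4`), then channel renormalization. Bilateral kernels
are conventionally 2D and the filter's job is purely to suppress isolated
spurious responses while preserving region edges; the sigmas are exposed
configuration. Hard labels are the per-voxel argmax with ties broken
toward the lower class index (background < wall < tumor).

Segmentation quality is the Dice similarity coefficient
`2|A∩B| / (|A| + |B|)` per class. Two empty masks score 1 (the prediction
correctly found nothing); empty versus non-empty scores 0. The *overall*
Dice of a case is the unweighted mean of the background, wall and tumor
Dice — the only reading under which an overall value can exceed both
foreground values, as the large easy background class pulls the mean up.
`run_experiment()` crosses architectures × augmentation scenarios ×
training-set sizes with a seeded split and emits per-case rows plus cell
means, the layout used to compare U-Net-4/5/6 under `na = 5/10` and 7-
versus 14-volume training.

## The phantom generator

Each synthetic case is an ellipsoidal bladder: a bright fluid-like lumen
(urine is hyperintense on T2), a darker closed wall shell a few voxels
thick (outer ellipsoid minus inner ellipsoid), and an
intermediate-intensity spherical tumor centred on the inner wall surface,
clipped to the organ and carved out of the wall mask so the two masks are
disjoint. Intensities are configurable means (defaults 1000 lumen, 600
tumor, 300 wall, 100 background, arbitrary units) plus additive Gaussian
noise (default sd 30). Default geometry scales with the grid so that the
512×512×32 default places the organ inside the fixed ROI window; cohort
generation jitters radii, centre and tumor position uniformly within ±20%
(clamped to the legal box) and writes NRRD cases plus a manifest. A
configuration whose tumor sphere contains no wall voxel is rejected — the
pipeline's premise is a wall-attached lesion.

What the phantom does *not* emulate: MRI physics (bias fields, partial
volume, Rician noise — additive Gaussian is used absent any acquisition
statistics), multi-tumor cases, irregular tumor shapes, or
scanner-calibrated contrast. Tests passing on phantoms therefore
demonstrate the pipeline's mechanics (geometry handling, learning
capacity, metric correctness), not clinical-grade accuracy.

## Numerical choices and scale

* ROI indices are 0-based half-open `[100, 400)`; the off-by-one ambiguity
  of "from 100 to 400 pixels" is immaterial at this scale but fixed for
  reproducibility.
* Argmax ties break toward the lower class index; mask voxels are "any
  nonzero value counts as inside".
* The σ = 0 guard in normalization returns zeros rather than NaN.
* Weight initialization is He-scaled Gaussian; PReLU slopes start at 0.25.
* Test-suite problem sizes are deliberately small: unit tests run models
  at 16–64 voxels per axis, and the memorization capacity check trains a
  4-level, 8-filter model on two noiseless 64×64×16 phantoms. For that
  check the Adam learning rate is raised to 2e-2: with only two volumes
  there are two optimizer steps per epoch, and the production rate of
  5e-4 — tuned for thousands of steps over augmented cohorts — cannot move
  the batch-norm scales to confident-logit territory within a 200-epoch
  budget. A capacity check asks whether the architecture can drive its
  training loss toward zero, not whether a particular step size does.

## Known limitations

* The bladder localization is a fixed window, not learned; volumes from
  other protocols need their own ROI.
* Overall Dice averages background in, which flatters results; per-class
  values are always reported alongside.
* The experiment grids retrain from scratch per cell; at full 128×128×32
  scale on one CPU this is hours, so the shipped tests exercise the grid
  machinery at reduced scale.
* Checkpoints serialize the full parameter set as RDS; they are runtime
  artifacts, not a portable exchange format.
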