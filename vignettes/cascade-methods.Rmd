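---
title: "Methods: coarse-to-fine cascaded aneurysm segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-to-fine cascaded aneurysm segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Saccular intracranial aneurysms are focal bulges on cerebral arteries; on
vessel-enhanced angiography (typically time-of-flight MR angiography) they
appear as bright, roughly ellipsoidal protrusions attached to bright tubular
vessels. Voxelwise segmentation is hard for one dominant reason: the lesion
occupies a vanishing fraction of the volume (a 5 mm aneurysm is ~10 voxels
across at 0.5 mm resolution inside a 128³+ scan), so a single whole-volume
network both wastes capacity on background and tends to lose small-lesion
features with depth.

`cascseg` implements a two-stage cascade:

1. a **coarse network** sees the whole (single-channel) vessel volume and
   marks candidate regions;
2. a cubic **volume of interest (VOI)** — 64³ voxels at clinical scale — is
   cropped around the centroid of each 26-connected candidate component;
3. a **fine network** segments each VOI from **dual-channel** input: the
   vessel image and its **Sobel contour image**, which injects explicit
   wall/neck morphology that is otherwise easily lost;
4. fine masks are pasted back (logical OR where VOIs overlap) into
   full-volume space.

The fine network is trained with a **weighted soft-dice loss**

$$ L = -(1-D)^{\beta}\, D, \qquad
   D = \frac{2\sum_i g_i p_i + S}{\sum_i g_i + \sum_i p_i + S}, $$

with smoothing $S = 10^{-4}$ and $\beta \in [0,1]$. The factor
$(1-D)^\beta$ is strictly decreasing in $D$ on that interval, so poorly
overlapping predictions incur relatively larger loss than under the plain
dice loss ($\beta = 0$); $\beta = 0.1$ is the default operating point. By
default the weight is treated as a constant during backpropagation
(`detach_weight = TRUE`): the gradient is that of the plain dice loss,
rescaled per batch. With the weight differentiated as well, the chain-rule
term $+\beta(1-D)^{\beta-1}D$ partially cancels the descent direction near
$D \to 1$; detaching is the numerically safer reading and the package
implements both.

The implementation note that matters for the loss: the numerator is the
voxelwise product sum $\sum_i g_i p_i$ (standard soft dice). A product of
total counts would not reduce to the dice coefficient for binary inputs,
and the $\beta$-interval argument above explicitly identifies the
parenthetical factor with DSC.

## The synthetic phantom generator

The package is exercised end to end on synthetic vascular phantoms
(`phantom_spec()`, `generate_phantom()`, `generate_cohort()`); they stand in
for a clinical cohort that cannot ship with code. Each phantom contains:

* **vessels**: tubes of radius 1.0–2.5 mm swept along smooth random spline
  centerlines crossing the volume;
* **aneurysms**: ellipsoidal bulges (semi-axes jittered ±8%, random
  orientation) attached so that each bulge intersects a vessel wall. The
  label marks bulge voxels outside the parent tube lumen, with wall-overlap
  voxels assigned to the aneurysm — ground truth labels the lesion only,
  not the carrying vessel;
* **diameters** drawn from a lognormal moment-matched to the clinical
  cohort statistic 5.468 ± 3.283 mm and truncated to [2, 20] mm — the
  truncation keeps draws voxelizable at desk scale and clips the long
  lognormal tail;
* **intensities**: foreground/background Gaussian levels (defaults 160 ± 15
  vs 20 ± 5, arbitrary units) with a partial-volume soft edge, optional
  smooth multiplicative bias field, and additive voxel noise (sd 10).
  Intensity statistics of real scans are free parameters of the phantom;
  the defaults were chosen once to give clearly vascular contrast at
  moderate noise and are documented as free.

Default spacing is 0.5 mm isotropic — typical in-plane TOF-MRA resolution —
so a 5 mm aneurysm spans ~10 voxels and fits comfortably inside a 64³ VOI.
Generation is deterministic given the spec seed; cohorts derive per-sample
seeds from a master seed by a linear congruential hash.

What the phantoms deliberately do **not** model: MR flow physics and
flow-related artifacts, skull/soft-tissue background (the cascade assumes
already-extracted vessel volumes), bias-field structure of real coils
beyond a smooth low-order field, ruptured-aneurysm morphology, and contact
between distinct aneurysms. Passing tests on phantoms therefore demonstrate
that the pipeline's machinery is correct and that the networks can learn
the shape-versus-tube discrimination; they say nothing quantitative about
clinical performance.

## Preprocessing chain

Applied to each vessel volume (`zscore()`, `sobel_contour()`,
`adaptive_dilate_label()`, `augment_eightfold()`):

* **Z-score normalization** uses population moments over the whole volume.
  No vessel mask restricts the statistics: inputs are assumed
  already-extracted vessel volumes with controlled background.
* **Sobel contour extraction** runs on the normalized intensity image (not
  on a binarized mask); the pipeline order places contour extraction after
  normalization, and an intensity-domain gradient preserves partial-volume
  information at the wall. Borders are edge-replicated so uniform volumes
  produce an all-zero contour; the magnitude is rescaled to [0, 1] by its
  maximum.
* **Adaptive label dilation** (coarse stage only): per 26-connected
  component, a Euclidean-ball dilation of radius
  `max(1, round(0.25 * d_eq / mean(spacing)))` voxels, where `d_eq` is the
  component's equivalent-sphere diameter in mm. The 0.25 coefficient is the
  package's concretization of size-proportional dilation and is exposed as
  a configuration knob.
* **Eightfold augmentation** is cumulative: originals (N) plus z-flips
  (2N), plus Gaussian-filtered copies of those (4N), plus
  histogram-equalized copies of those (8N). Labels undergo only the
  geometric flip; contours are recomputed from each transformed vessel
  volume rather than transformed themselves (for the flip the two are
  identical; for intensity transforms recomputation is the consistent
  choice). The Gaussian sigma is specified in mm (default 0.5) and
  converted to voxels via the spacing; histogram equalization uses 256 bins
  over the volume range with the output mapped back onto that range.

## VOI geometry

Boxes are cubes in voxel index space (`voi_box()`): 1-based inclusive
bounds `lo..hi` plus per-side zero padding, with the invariant
`(hi - lo + 1) + pad_before + pad_after = side` per axis. Training crops
are centred on the label centroid (mean foreground index, rounded half-up).
At inference one box is proposed per 26-connected coarse component; boxes
whose centres fall within `side/2` Chebyshev voxels of each other are
merged at their count-weighted centroid so one lesion never receives two
fine passes. Borders are zero-padded (background in phantoms and extracted
vessel volumes is zero), and `paste_back()` discards pad regions and ORs
overlapping boxes. 26-connectivity and the merge threshold are choices the
underlying description leaves open; both are standard for 3D blob handling
and configurable.

## Network architecture

Both networks run on a self-contained 3D network engine (reverse-mode
autodiff tape in R over compiled direct-convolution kernels), so the
package trains and infers on one CPU with no external framework.

The **fine network** is a four-level encoder–decoder. The input layer is a
3×3×3 stride-1 convolution; each deeper encoder stage enters with a 3×3×3
stride-2 convolution followed by a **context block** — two 3×3×3 stride-1
convolutions with dropout (p = 0.3) between them — and a residual addition
from the stage entry to the context output. One textual contradiction had
to be resolved: describing the context block itself as a stride-2
convolution is incompatible with the residual addition (shapes would
differ) and with the variant 3D U-Net this architecture extends; the
package therefore keeps stride 2 only at stage entry. A
squeeze-and-excitation (SE) block follows the penultimate context block,
and another follows the first (deepest) upsampling block. Decoder stages
upsample by nearest-neighbour ×2 followed by a 3×3×3 convolution,
concatenate with the matching encoder output, and apply a localization
block (3×3×3 then 1×1×1 convolution). Segmentation heads at the two
coarsest decoder levels are upsampled and summed into the final 3×3×3
output head before the voxelwise softmax (deep supervision; the head count
is configurable since only "different layers" is prescribed). Blocks use
instance-style feature normalization and leaky ReLU (slope 0.01); the SE
reduction ratio defaults to 8. All of these fill-ins are flagged as
configuration knobs.

The **coarse network** is an explicit stand-in: the cited coarse
architecture is not reproduced in the source description, so the package
provides a small three-level single-channel encoder–decoder that honours
the stated contract (single-channel input at 128³ clinical scale, softmax
output, trained with the stated coarse-stage hyperparameters) while staying
within 10× the parameter count of the fine desk preset.

## Training schedules

* **Coarse**: 700 epochs, batch 10, RMSProp at 1e-3 with L1 1e-6 / L2 1e-4
  penalty gradients (`l1*sign(w) + l2*w`), plain soft-dice loss on dilated
  labels. The "gradually dropped" rate is concretized as ×0.5 every
  `ceiling(epochs/3)` epochs (knob).
* **Fine**: 500 epochs, batch 1, Adam at 5e-4; the rate halves when the
  validation loss fails to improve for 10 consecutive epochs, and training
  stops after 50 epochs without improvement. The mixed
  "iterations"/"epochs" wording is read as epochs throughout.
* Where the two stages' schedules are exercised in tests they are driven by
  scripted loss sequences, so the halving and stopping points are checked
  exactly.
* Fivefold cross-validation is the clinical-scale default
  (`train_plan(folds = 5)`); desk runs use 2 folds or a simple held-out
  split.

Prediction binarization is per-voxel argmax of the softmax (equivalent to a
0.5 threshold for two classes). At inference, normalization is global:
VOIs are cropped from the one z-scored volume rather than re-normalized
per crop, keeping the two channels consistent with training statistics;
whether per-crop renormalization was used originally is not decidable from
the description.

## Evaluation

`dice_coefficient()`, `hausdorff_mm()` and `volumetric_similarity()`
implement the three reported metrics. HD is the full symmetric maximum (not
a percentile) between foreground voxel-centre point sets in physical mm;
when either mask is empty the distance is undefined and reported as a
sentinel (`NA`), counted and excluded from cohort means. The dice
denominator is the cardinality sum $|GT|+|Pred|$ (the printed union symbol
with a 2× prefactor defines dice, not Jaccard). Cohort evaluation adds a
detection tally: a ground-truth component counts as segmented when any
predicted voxel overlaps it.

## Numerical choices and desk-scale problem sizes

* Convolution padding is "same" (zero) inside the networks; feature-map
  sides must be divisible by `2^(depth-1)`.
* Degenerate inputs have defined behaviour: constant volumes cannot be
  z-scored (error), but `cascade_infer()` short-circuits a featureless
  (constant) volume to an empty prediction with an empty VOI manifest;
  empty masks give dice/VS of 1 against empty references and an HD
  sentinel otherwise.
* Gradient correctness of the engine is tested against central finite
  differences end to end through the composed loss.
* Desk-scale presets used by the test-suite and the acceptance script —
  chosen once as the package's CPU-scale study conditions: 64³ phantom
  volumes at 0.5 mm (32³ for the smallest fixtures), 32³ VOI crops, fine
  network with `base_filters = 4` trained 12 epochs on a 30-phantom
  cohort, coarse network with `base_filters = 3` trained 80 epochs on
  label-centred 32³ patches (the network is fully convolutional, so
  patch-trained weights apply unchanged to whole volumes; patches cost a
  fraction of full-volume passes and balance the foreground). Full-scale
  presets (128³ inputs, 64³ VOIs, `base_filters = 16`, 700/500 epochs)
  reproduce the published hyperparameters verbatim for users with the
  hardware to run them.
* A desk-scale 32³ VOI spans 16 mm at 0.5 mm spacing, so lesions drawn
  near the 20 mm truncation bound cannot be fully contained — such cases
  cap the attainable fine-stage dice and are visible as the low tail of
  the held-out scores. At clinical scale the 64³ VOI (32 mm) contains the
  whole diameter range.

## Known limitations

* The coarse stand-in is not the original coarse architecture; at desk
  scale its candidate masks are noisier than a clinically trained
  detector's, which bounds the cascade's end-to-end phantom scores well
  below what the fine network achieves inside ground-truth-centred VOIs.
* Bias-field correction and cerebral-artery extraction are out of scope by
  design; the pipeline accepts pre-corrected, pre-extracted volumes (the
  phantom generator emits them directly).
* Orientation handling is minimal (spacing + origin; identity direction):
  phantoms control their own geometry, and resampling between differently
  oriented scans is a non-goal.
* The engine is single-threaded CPU R/C++; it is sized for desk-scale
  experiments, not clinical training runs.
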