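# cascseg

Coarse-to-fine cascaded 3D segmentation of saccular aneurysms in
vessel-enhanced angiographic volumes, with a built-in synthetic vascular
phantom generator so the whole pipeline runs end to end on one CPU with no
external data.

## The problem and the method

Unruptured cerebral aneurysms are saccular bulges on intracranial arteries;
on time-of-flight MR angiography they appear as small bright protrusions on
bright tubular vessels. Accurate voxelwise masks feed size/shape analysis
and rupture-risk assessment, but the lesion is a vanishing fraction of the
volume — a 5 mm aneurysm spans ~10 voxels at 0.5 mm resolution — so
single-pass whole-volume networks struggle.

`cascseg` implements a two-stage cascade:

* a **coarse network** scans the whole single-channel vessel volume for
  candidates;
* one cubic **volume of interest** (VOI, 64³ voxels at clinical scale) is
  cropped per 26-connected candidate component, centred on its centroid;
* a **fine network** (a four-level residual U-Net with context blocks,
  squeeze-and-excitation attention and deep supervision) segments each VOI
  from **dual-channel** input — the vessel image plus its **Sobel contour
  image**, which re-injects wall/neck morphology;
* fine masks are pasted back into full-volume space (logical OR on
  overlaps).

The fine stage trains with a **weighted soft-dice loss**

    L = -(1 - D)^beta * D,   D = (2 * sum(g*p) + S) / (sum(g) + sum(p) + S)

with S = 1e-4 and beta in [0, 1]: the (1-D)^beta factor is strictly
decreasing in D, so poorly overlapping predictions incur relatively larger
loss (beta = 0 recovers the plain dice loss; beta = 0.1 is the default).
Evaluation uses the dice similarity coefficient (DSC), the exact symmetric
Hausdorff distance in mm (HD), and volumetric similarity (VS).

Everything — including the trainable 3D convolution engine with
reverse-mode autodiff — is self-contained R/C++ (Rcpp); no deep-learning
framework is required.

## Worked example

Generate a small phantom cohort, train both stages at desk scale, and run
cascade inference on a held-out phantom:

```r
library(cascseg)

cohort <- generate_cohort(12, phantom_spec(), seed = 6)  # 64^3, 0.5 mm
train_set <- cohort[1:10]; test_ph <- cohort[[11]]

# coarse stage: label-centred 32^3 patches, dilated labels
set.seed(99)
coarse_cases <- prepare_coarse_cohort(train_set, crop_side = 32L, jitter = 6L)
fit_c <- train_coarse(coarse_cases,
                      train_plan("coarse", epochs = 30L, batch_size = 5L, seed = 8L),
                      coarse_config(base_filters = 3L))

# fine stage: dual-channel 32^3 VOIs, weighted dice loss (beta = 0.1)
fine_cases <- prepare_fine_cohort(train_set, side = 32L)
fit_f <- train_fine(fine_cases, train_plan("fine", epochs = 12L, seed = 11L),
                    loss_config(beta = 0.1), channels = 2L,
                    cfg = dunet_config(in_channels = 2L, base_filters = 4L))

res <- cascade_infer(test_ph$bundle$vessel, fit_c$net, fit_f$net, side = 32L)
seg_scores(test_ph$bundle$label, res$mask)
```

On the full desk run of `scripts/acceptance.R` with `--seed 1` (30
training phantoms at 64³, 32³ VOIs) the dual-channel fine network reaches
a validation mean DSC of 0.689 with mean HD 2.27 mm and mean VS 0.754
inside ground-truth-centred VOIs, and mean DSC 0.536 on six truly held-out
phantoms — the low tail being exactly the extreme diameters (a ~19 mm
lesion cannot fit a 16 mm desk VOI; ~2.6 mm lesions over-segment). The
full cascade is bounded by the small coarse stand-in's candidate quality
at this scale (seed 1: detection rate 0.33, mean DSC 0.10 over ~2.7 VOIs
per case; see the methods vignette for why); its scores are reported by
the acceptance script rather than asserted.

The package also installs a thin command-line front end
(`inst/cli/cascseg.R`) with `generate`, `preprocess`, `train-coarse`,
`train-fine`, `infer`, `evaluate` and `ablate-beta` subcommands; volumes
travel as NIfTI-1 (`.nii.gz`), VOI manifests as JSON, metrics as CSV.

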