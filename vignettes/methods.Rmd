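---
title: "Detecting new MS lesions with a cascaded registration + segmentation network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting new MS lesions with a cascaded registration + segmentation network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In longitudinal multiple-sclerosis imaging, the appearance of *new* lesions
between a baseline and a follow-up T2-FLAIR scan is a key biomarker of
disease activity.  Reading the two scans side by side is error-prone: new
lesions are small, residual misregistration between timepoints mimics
change, and the class imbalance is extreme (a handful of new-lesion voxels
in a multi-million-voxel volume).  `lesioncascade` implements an automated
pipeline for this task: a cascade of two identical 3D patch-wise fully
convolutional networks, each of which couples a learned deformable
registration block with a two-branch segmentation block and is trained
end-to-end.

## Model

Each stage operates on 3D patches (default $32^3$ voxels) cut from the
co-registered baseline/follow-up pair.

**Registration block.**  A 3D U-Net with four 2x down/upsampling steps and
core blocks of two $3^3$ stride-1 convolutions maps the 2-channel
(baseline, follow-up) patch to a dense displacement field $DF$ (3 channels,
voxel units).  Activations are leaky rectifiers so displacements can take
either sign.  A differentiable spatial transformer warps the baseline patch
by $DF$ (trilinear interpolation, clamp-to-edge borders), yielding the
*moved* baseline $B(DF)$.

**Segmentation block.**  A two-branch network: branch 1 is a U-Net (plain
rectifiers) over the image pair, branch 2 an identical U-Net over $DF$.
Their outputs are concatenated and a $1^3$ convolution with a logistic
output gives the per-voxel probability of "new lesion".

**Loss.**  Training minimizes the sum of a supervised and an unsupervised
part

$$L = L_{CE}(Seg, GT) \;+\; \frac{1}{N}\sum_i (F_i - B(DF)_i)^2
      \;+\; w_{reg}\sum_p \lVert \nabla DF(p) \rVert^2 ,$$

binary cross-entropy on the segmentation plus an image-similarity term and
a smoothness penalty on the spatial gradients of the field.  The printed
form of this loss fixes no trade-off scalars, and the similarity term is a
per-voxel mean while the smoothness term is a sum over voxels, so their
natural scales differ by the patch volume.  `loss_weights()` exposes the
three weights (defaulting to the unweighted sum); `training_config()`
defaults to $w_{seg} = w_{sim} = 1$ and $w_{reg} = 1/N$ with $N$ the patch
volume, which rewrites the smoothness sum as a per-voxel mean so that all
three terms share one scale.  This balance matters beyond aesthetics: the
segmentation branch receives $DF$ as an input, so with a much weaker
smoothness weight the cross-entropy gradient is free to inflate the field
into an arbitrary feature channel, which destroys the registration.

**Cascade.**  Stage one is trained on patches centred on *every*
ground-truth lesion voxel, making it sensitive; larger lesions contribute
more patches by construction.  Its thresholded output ($>0.5$, components
$<3\,\mathrm{mm}^3$ removed) on the training cases defines the
hard-example region — the union of lesion voxels and stage-one mistakes —
from which overlapped patches (step $8^3$) are extracted to train stage
two from scratch with a fresh seed.  At test time overlapped patches are
pushed through both networks, per-voxel probabilities are averaged over
overlapping patches and over the two stages, and the average is
thresholded at $>0.5$ with the same $3\,\mathrm{mm}^3$ component filter.

## Preprocessing

Inputs are assumed rigidly co-registered, brain-extracted and
bias-corrected; the package deliberately does not re-implement skull
stripping or bias-field correction (a `trivial_brain_mask()` threshold
mask is provided for phantoms and already-stripped data).  Intensities are
standardized by Nyul-style piecewise-linear histogram matching:
`fit_standardizer()` learns a standard scale on \[0, 100\] as the
per-landmark mean of the training volumes' foreground percentiles
(landmarks at the 1st, 10th, ..., 90th and 99th percentiles — the
canonical decile choice), and `normalize_volume()` maps each volume's
landmarks onto it, extrapolating linearly beyond the outer landmarks.
Percentiles are taken inside the brain mask when available, otherwise over
strictly positive voxels, so background zeros cannot dominate.  One
standardizer is fitted over both timepoints of all training cases jointly.

## Numerical and training choices

The architecture and the loss pin down most of the model; the remaining
details are genuinely open choices, fixed here as follows.

* **Optimizer** — Adam ("adaptive gradient descent"), learning rate in
  `training_config()`; gradients are averaged over mini-batches.  Three
  stabilizers proved necessary to train the composite model within a small
  epoch budget, and all are standard practice: a linear learning-rate
  warmup (default 100 steps; Adam's bias-corrected first steps are
  full-sized and can kill every rectifier unit of the narrow test networks
  before any feature forms), per-subnetwork gradient-norm clipping
  (default ceiling 1; binds only during loss spikes, and clipping per
  group keeps spikes in the registration terms from scaling away the
  cross-entropy signal), and a reduced learning rate on the registration
  path (`reg_lr_factor`, default 0.1; once displacements overshoot the
  patch, the warp gradient vanishes and the field cannot recover, so the
  flow must move slowly).
* **Flow-head initialization** — the $1^3$ projection to $DF$ starts with
  near-zero weights so optimization begins at the identity transform; this
  is the standard stabilization for spatial-transformer registration, and
  without it the similarity gradient through the warp is ill-behaved.
* **Classifier bias initialization** — the final logistic layer's bias
  starts at $-2.5$, near the prior logit of the new-lesion class inside
  lesion-centred patches.  Early epochs then refine features instead of
  re-learning the class prior.
* **Input scaling** — standardized intensities (scale 0-100) are
  multiplied by `input_scale = 0.01` before entering the networks and the
  similarity term, keeping activations near unit range.
* **Degenerate-fit restarts** — the imbalanced cross-entropy has a
  degenerate basin (a constant output at the class prior), and with narrow
  test networks whether a random initialization escapes it within a small
  epoch budget is essentially seed luck.  `train_stage()` therefore checks
  each fit against a structural yardstick — the cross-entropy of the best
  *constant* predictor on the validation labels — and restarts from a
  fresh, deterministically derived initialization when the fit does not
  clearly beat it (up to `max_restarts`, default 3).  Stuck fits are
  recognized by a probe after five epochs, so failed attempts are cheap;
  every attempt respects the configured epoch budget, and the whole
  procedure is reproducible given the seed.
* **LSUV-style calibration** — after random (He) initialization each
  convolution is rescaled and recentred so its pre-activations have zero
  mean and unit spread on a probe patch, equalizing gradient flow across
  depth without adding normalization layers to the architecture.
* **Validation split** — 25% of patches are held out, stratified by case
  (whole cases go to validation) so neighbouring patches of one lesion
  cannot straddle the split; training stops when the validation loss has
  not strictly decreased for `patience` epochs (defaults: 100 epochs,
  patience 10) and the best-epoch weights are kept.
* **Downsampling / skips** — max-pooling and channel-concatenation skips,
  the canonical U-Net choices; the two segmentation branches do not share
  weights; the classification step is a single $1^3$ convolution.
* **Displacements** are expressed in voxel units and the warper samples on
  the voxel grid; for anisotropic acquisitions one displacement unit along
  axis $a$ spans `spacing[a]` millimetres.
* **Connectivity** — lesions are 26-connected components; component
  volume is voxel count times voxel volume (product of spacings).
* **Threshold semantics** — strictly greater-than 0.5; components with
  volume strictly below 3 mm^3 are removed.
* **Lesion matching** — a ground-truth lesion counts as detected when
  predictions cover more than `min_overlap_fraction` (default 0.1) of it;
  a predicted component is a false positive only when it touches no
  ground-truth lesion.  Published lesion-wise evaluations rarely state
  their exact matching rule, so ours is configurable and should be quoted
  with any result.

## The phantom generator

Real two-timepoint MS data with new-lesion annotations is access-restricted,
so `phantom_spec()` / `generate_case()` synthesize the data regime instead:
an ellipsoidal "brain" with smooth internal texture and a darker
ventricle-like cavity; a follow-up produced by warping the baseline with a
smooth random deformation (Gaussian-smoothed white noise rescaled to a
maximum amplitude, default 1 voxel, smoothness 6 voxels); a global
follow-up intensity shift (default +5) mimicking scanner differences;
independent Gaussian voxel noise at both timepoints (default sd 2 against
tissue ~100); and a small number of bright ellipsoidal new lesions
(default 3 per case, semi-axes 1.1-2 mm, contrast +40) placed only in the
follow-up, pairwise separated, each larger than the 3 mm^3 post-filter.
Optional distractor blobs present at *both* timepoints bait
change-detection false positives.  A cohort draws a quarter of its cases
with no new lesions, echoing the share of radiologically stable patients
in longitudinal MS cohorts.  The default grid is $64^3$ at 1 mm isotropic:
large enough for meaningful patch lattices, small enough for CPU training.

What the phantoms do **not** model: MR physics (partial volume, bias
fields, scanner-specific noise spectra), anatomy beyond a two-compartment
ellipsoid, lesion texture, or confluent/enlarging lesions.  Passing the
end-to-end phantom tests therefore demonstrates that the machinery — patch
extraction, joint training, mining, averaging, post-filtering, evaluation —
is correct and that the cascade behaves qualitatively as designed; it does
not certify clinical performance.

## Desk-scale problem sizes

The test-suite and the acceptance script run the full pipeline at reduced
size, chosen so the whole suite trains several models on one CPU core:
channels (4, 8, 16, 32) instead of (64, 128, 256, 512), $16^3$ patches
instead of $32^3$ (the architecture requires divisibility by 16), $64^3$
phantoms, 8 training / 4 held-out cases, 10-12 epochs per stage with
mini-batches of 2 at learning rate 1e-2, and the degenerate-fit restart
enabled.  The lattice step stays at $8^3$ for mining and inference,
mirroring the full-scale setting.  Smaller side experiments (the
distractor comparison, the registration ablation, reproducibility checks)
use $48^3$ phantoms with two to three cases and five to six epochs.

## Known limitations

* The unsupervised terms help only when deformation actually carries
  information; on perfectly aligned phantoms the field head stays near the
  identity.
* Stage-one maps for mining are computed on the training cases themselves
  (as the cascade procedure prescribes); mining is therefore optimistic
  about stage-one errors — a held-out mining split would be a conservative
  variant.
* `evaluate_cohort()` excludes lesion-free cases from detection and
  segmentation means and reports their mean false-lesion volume
  (VolTested) separately; with very few cases these means are noisy.
* Whether stage one saw any lesion-free tissue depends entirely on what
  lesion-centred patches happen to contain; the cascade's second stage is
  the designed corrective for the resulting false positives.
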