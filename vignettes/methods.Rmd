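---
title: "Predicting clinical image-quality scores for low-count PET: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting clinical image-quality scores for low-count PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Reducing the injected radioligand dose in brain PET lowers radiation burden
and cost, but degrades the reconstructed image: fewer detected counts mean
more noise and less effective resolution. Whether a degraded image is still
*clinically* usable is a judgement call that experienced readers express on
an ordinal scale — here three metrics, each scored 0–3 in steps of 0.5:

* **GQR** (global quality rating): the aesthetic quality — noise,
  resolution;
* **PR** (pattern recognition): can a pathological uptake pattern still be
  recognised;
* **DC** (diagnostic confidence): how confidently a diagnosis could be made.

Clinician scores are expensive and scarce, so `petqc` trains a small
convolutional regression network to predict them from 2-D image patches,
and uses two label-free forms of pre-training to cope with few scored
volumes: transfer learning with block-wise freezing, and a *pretext task* —
regressing the injected dose (standardised by patient weight), a label that
comes for free with every acquisition and correlates with the clinical
scores.

Because clinically scored PET volumes cannot be redistributed, the package
carries a synthetic cohort generator that emulates the relevant properties
of such data; every experiment in the package runs end-to-end on this
phantom cohort.

## The synthetic cohort generator

`make_cohort()` produces patients in three steps.

**Anatomy.** `generate_phantom()` builds a piecewise-constant activity
volume: a head ellipsoid (semi-axes 0.8 of the half grid extent) containing
a high-uptake cortical shell (relative uptake 4), white-matter interior
(1), and two photopenic ventricles (0.25) — approximating the FDG
grey:white contrast of a real brain. Outside the head the activity is
exactly zero, so roughly 70% of voxels are true background, which is what
makes the patch background-threshold rule meaningful. Per-patient anatomy
jitters radii and uptakes by a few percent and adds 5% multiplicative voxel
texture so patients are non-identical.

**Dose reduction.** Real dose reduction resamples list-mode coincidence
events and re-runs the clinical reconstruction; that requires vendor tools
and raw data. `simulate_dose_fraction()` reproduces the two observable
consequences in image space instead: every voxel gets an independent
Poisson draw with mean `fraction * full_counts * activity / sum(activity)`
(so expected total counts are conserved exactly), and the count image is
then smoothed with a Gaussian whose FWHM grows as the fraction falls
(`4 mm + 3 mm` per decade of count reduction) — low-count reconstructions
are noisier *and* smoother. The seven fractions are 0.5%, 1% (low
quality), 5%, 10% (medium) and 25%, 50%, 100% (high); by default each
patient is scored at one fraction per quality category, mirroring how
clinical reading time is rationed. Volumes are normalised to [0, 1] before
any downstream use, deliberately destroying absolute-activity information.

**Scores.** `assign_scores()` draws each metric as
`slope * log10(dose_per_kg) + intercept + noise`, quantised half-up to the
0.5 grid and clipped to [0, 3], with `dose_per_kg = fraction * full_counts
/ weight_kg`. Slopes are positive for all metrics and the GQR
slope-to-noise ratio is the largest (slope 1.2, SD 0.30, vs 1.05/0.38 and
0.95/0.42), so GQR has the strongest dose association — the qualitative
pattern seen in clinical scoring. Rater-noise SDs near 0.35 score units
make repeated scorings differ by at least 0.5 roughly half the time, the
scale of real inter-session variability. Patient weights are
Normal(75, 10) kg truncated to [45, 120]; full-acquisition counts are
uniform in 4–6 million (no published distributions exist for either at
this phantom scale; these are ordinary clinical magnitudes). Between-
patient score variability beyond the weight/dose effect is not separately
modelled; the rater-noise SD absorbs it and is exposed as a parameter.

What the generator does **not** emulate: attenuation, randoms and scatter,
reconstruction artefacts, anatomical variability beyond ellipsoid jitter,
and any pathology. Passing tests on this cohort therefore demonstrate that
the pipeline's machinery works and that its relative orderings (more
pre-training helps; noise tracks dose), not clinical-grade absolute
performance.

## Patch pipeline

`extract_patches()` implements per-volume patch sampling: candidates drawn
uniformly over plane (transverse/sagittal/coronal), slice and corner; a
candidate is rejected as background when its mean pixel value is below
one-eighth of the whole-volume mean (equality survives); of the survivors,
equal numbers are sampled without replacement per plane (default 100 each,
300 per volume). If a plane falls short, fresh candidates are drawn for
that plane only, bounded at 50× the requested count, and an error names
the plane if foreground cannot be found. Patch size defaults to the
clinical 80 pixels and is automatically reduced to the largest multiple of
16 that fits the volume (with a warning) — desk-scale phantom grids are
smaller than clinical 344×344×127 grids. Patch locations are drawn
independently per volume (they are not shared across dose levels of a
patient); sharing could be added but would couple samples across dose
levels. Greyscale patches are replicated to three channels to match the
backbone input.

## Backbone, head and freezing

`build_backbone()` constructs a VGG16-shaped stack: five blocks of
(2, 2, 3, 3, 3) 3×3 convolutions with ReLU, each block closed by a 2×2 max
pool; channel widths are `base_width * (1, 2, 4, 8, 8)`. `base_width = 64`
is the full VGG16 layout; the desk-scale default of 8 (≈ 63k parameters)
preserves the block structure — and hence the meaning of "freeze the first
N blocks" — while training on a CPU in minutes. Global average pooling
before the head keeps the head size independent of the input size. The
clinical head is a single fully connected layer with three ReLU outputs
(one per metric); predictions are therefore nonnegative but *not* clipped
at 3 during training — clipping to [0, 3] happens only at evaluation, in
the patch-to-image aggregation. The dose head has one output, linear by
default (a rectifier would be equally defensible since the target is
nonnegative; linear avoids dead-output starts and the choice is
configurable). Head biases initialise at the target midpoint (1.5 clinical,
0.5 dose) so rectified units are alive from the first step; convolutions
use He-scaled Gaussian initialisation.

`freeze_policy(k)` trains the last `k` blocks plus the head and freezes the
rest. Frozen parameters carry a no-update contract that the tests verify
bit-for-bit. When `k = 0` the features are fixed, so the implementation
precomputes them once and optimises only the head — mathematically
identical, and the reason the fully frozen pretext pipeline is cheap.

## Training protocol and pipelines

`train()` runs minibatch Adam (batch 10) on the MSE loss and returns the
checkpoint with the lowest validation loss plus the full history.
Validation for clinical training uses one held-out patient from the
transfer cohort. Patient-level split hygiene (no id in more than one of
pretext / train / validation / test) is asserted before every run.

The pretext target is the injected dose standardised by patient weight.
The seven fractions span 2.3 decades, so the target is taken as
`log10(fraction * full_counts / weight_kg)`, min–max rescaled to [0, 1]
over the training cohort; on a linear scale the four lowest fractions
would occupy under 10% of the target range and receive almost no MSE
gradient. (The linear variant remains available via `log_target = FALSE`.)
Pretext evaluation reports MAE on the unit target, percentage exact
agreement after nearest-level assignment among the seven discrete
fractions, and the Spearman correlation between per-volume mean
predictions and the true fraction.

`run_pipeline()` implements the four pre-training routes: (a) random
initialisation, everything trainable; (b) ImageNet initialisation — an
optional path that needs an externally downloaded VGG16 weight file and
fails explicitly without one, never silently falling back; (c) pretext
pre-training from random initialisation with the convolutional weights
then fixed (`k = 0`) and a fresh clinical head trained; (d) as (c) from
ImageNet weights. For (c)/(d) the freeze depth is configurable because
retraining the last blocks instead of fixing everything is an equally
plausible reading of the protocol; the default keeps the weights fully
fixed.

## Evaluation

Per reconstructed image, the predicted score of a metric is the mean of
its patch predictions clipped to [0, 3] (the aggregation rule is the
package's choice; per-patch evaluation is available). Agreement metrics:
MAE on unrounded predictions; percentage exact agreement after rounding
predictions half-up to the 0.5 grid (clinician scores live on that grid —
without rounding, exact agreement of a continuous output would be a
probability-zero event); percentage close agreement (within ±0.5 after
rounding, the inter-session uncertainty band); and Spearman rank
correlation with average ranks on ties, reported as undefined (`NA` with a
warning) when either side has zero variance. All four are verified against
independent brute-force implementations on random score tables.

## Experiments and problem sizes

`run_freeze_sweep()`, `run_patient_sweep()` and
`run_pipeline_comparison()` orchestrate the three sweeps (freeze depth
0–5; nested transfer-cohort sizes; pipeline comparison), with per-cell
seeds derived from a master seed by a fixed splitting rule, long-format
result tables carrying seed, split ids and a config hash, and a fixed test
cohort throughout a sweep. The pretext backbone is trained once per sweep
and shared across runs; each run re-initialises the clinical head.

The package's experiment defaults are chosen for a single CPU: volumes
48×48×32 (training cohorts) or 96×96×64 (the generator default), patches
32×32, 8 per plane (24 per volume), `base_width` 8, 12 training epochs
with best-checkpoint selection, 5 runs per sweep cell. At these sizes the
pretext task reaches held-out Spearman ≈ 1 and the pipeline comparison
(7 transfer patients × 3 fractions, 3 test patients) completes in a few
minutes per pipeline. Paper-scale settings (80×80 patches, 100 per plane,
width 64, 1000 epochs) remain reachable through the same configuration
objects.

## Numerical and degenerate-input choices

* Quantisation ties round half-up (1.25 → 1.5); threshold equality
  survives (a patch mean exactly one-eighth of the volume mean is kept).
* `normalize_volume()` rejects all-zero volumes; thinning rejects
  activity without support and fractions outside (0, 1].
* The Gaussian resolution kernel is truncated at 4σ and normalised to
  unit sum; zero padding loses counts only within kernel range of the
  grid boundary, and the phantom keeps the head well inside the grid, so
  expected totals are conserved to well below Monte-Carlo noise.
* Training aborts with a diagnostic on non-finite losses; a validation
  tie keeps the earlier checkpoint (strict improvement required).
* Single-level pretext cohorts rescale to a constant 0 target instead of
  dividing by zero.
* All randomness flows through explicit seeds (`with_seed` restores the
  caller's RNG state), so cohorts, patch draws, initialisation, batch
  order and therefore whole sweeps are bit-reproducible on a fixed BLAS.

## Known limitations

The backbone and optimiser are implemented in the package (RcppArmadillo
kernels; exact-gradient backpropagation verified against finite
differences). Only what the experiments need is implemented: 3×3
convolutions, 2×2 pooling, ReLU, a dense head, Adam — no batch
normalisation, augmentation, schedulers or GPU path. The synthetic cohort
is deliberately easier than clinical data (no pathology, simple anatomy),
so absolute agreement numbers on it exceed what clinical readers' scores
would allow; only the directional comparisons between pipelines are
meaningful, and the package reports those with per-run values rather than
single runs.
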