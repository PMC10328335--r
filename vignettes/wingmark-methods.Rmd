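---
title: "Methods: two-tier wing landmark detection and alignment QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-tier wing landmark detection and alignment QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Geometric morphometrics of tsetse (*Glossina* spp.) wings rests on 11
homologous landmarks at wing-vein intersections. Archives of field-collected
wings hold tens of thousands of wing pairs taped to paper pages (up to 20
pairs per page), digitised at 1024 x 1280 pixels (about 0.007 mm per pixel)
and linked to per-fly dissection records — notably `wlm`, the wing length in
mm measured between landmarks 1 and 6. Manual landmarking at that scale is
infeasible, and two data-quality problems intervene: many wings are damaged
(most incomplete wings lack landmark 4 or 6), and photographing mistakes
(a duplicated or skipped image) misalign every subsequent image on a page
with its biological record.

`wingmark` implements the full workflow: a first-tier classifier rejects
incomplete wings; a second tier localises the 11 landmarks, either by direct
coordinate regression or by per-landmark disk segmentation; Procrustes
analysis checks that prediction error does not depend on wing shape; and a
page-level regression of predicted wing length on `wlm` detects misaligned
pages. A synthetic wing generator supplies ground truth so that every stage
is tested end to end without the original images.

## The synthetic wing generator

The generator is first-class, tested code, and its defaults define the
conditions under which the package's claims are evaluated.

A wing is rendered from a fixed skeleton of 16 quadratic Bezier vein curves
joining the 11 template landmarks (committed constants in
`R/synthetic.R`), so every landmark lies at a junction of at least two
rendered veins. Wings vary in:

* **size** — wing span a uniform fraction (default 0.60-0.80 for pages,
  0.58-0.80 for batches) of canvas width; at native resolution this gives
  `wlm` around 6.3 mm with a between-fly SD of about 0.35 mm, matching the
  scale of real tsetse wing lengths;
* **pose** — rotation uniform in +/-12 to +/-15 degrees and centre shifts of
  up to 5-6% of each canvas dimension;
* **photometry** — background brightness 0.2-0.3, vein contrast 0.45-0.65,
  additive Gaussian pixel noise (SD 0.02).

Damage modes: `missing_lm4` / `missing_lm6` erase a disk of radius 0.2 x
span centred on the landmark — a torn-off piece of wing, deliberately gross,
because real incomplete wings mostly lack a visible chunk containing the
landmark and the reference workflow curates unambiguous training examples;
`absent_wing` renders background only; `torn` and `stained` are small
defects placed away from all landmarks, so they populate the
defects-within-complete-wings class and never invalidate ground truth. The
completeness label is 1 exactly when landmark 4 or 6 (or the whole wing) is
gone.

Records on a synthetic page carry `wlm` = 0.007 x (landmark 1-6 pixel
distance) plus Gaussian measurement noise (SD 0.02 mm, emulating dissector
error). Right wings are exact mirrors of their left twin — real flies are
not perfectly symmetric, but left/right length correlation is high, and the
mirrored construction makes the flip contract exactly testable. Injected
misalignments act at line level: a duplicated image shifts the association
one step ahead from the error line; a skipped image shifts it one step
behind and leaves the last line unphotographed.

What the generator does **not** emulate: real vein texture, microscope
optics, lamination artefacts, species differences, or fluctuating
asymmetry. Passing tests therefore demonstrate that the algorithms and the
training protocol work as specified, not that the tiny networks would reach
any particular accuracy on real micrographs.

## Tier 1: incomplete-wing classifier

The classifier maps a 3-channel square input (grayscale replicated to three
channels) to a single fully connected output with a sigmoid; training uses
binary cross-entropy with Adam, keeping the weights at the lowest
validation loss. The reference protocol (30 epochs, batch 50, learning rate
1e-4, ImageNet-pretrained VGG16/ResNet18/Inception backbones at 224x224 or
299x299) is expressed by `classifier_config()`; those backbones need
pretrained weights that cannot ship with this package, so they error
informatively, and `tiny_test_net` — three stride-2 convolution blocks and
the size-1 head — runs the identical protocol on a CPU. The decision
threshold on the sigmoid score is 0.5.

Because the tiny network trains from scratch rather than fine-tuning a
pretrained feature extractor, it needs more data and steps than a
fine-tuning run: the package's desk-scale protocol uses 900 curated
balanced wings at 96 x 120 canvas, 32 x 32 input, 40 epochs at learning
rate 1e-3, batch 16, reaching about 95% held-out accuracy. Class balance is
enforced by construction of the curated set, mirroring the even class
distribution of the reference training data.

Evaluation uses `bootstrap_metrics()`: sensitivity, specificity, precision,
F1 and accuracy with percentile 95% intervals over 5000 resamples of 205
predictions drawn with replacement. A resample in which a metric is
undefined (no positives for precision, say) is excluded from that metric's
percentiles rather than imputed as 0 or 1, which would bias the interval
endpoints.

## Tier 2: landmark localisation

Both heads consume the image resized to the model input (default 224,
desk scale 32) and emit coordinates in native pixel space. Coordinate
rescaling uses plain per-axis factors (`W_native/W_model`,
`H_native/H_model`); the image resampler uses the same pure-scale map with
bilinear interpolation, so encoding ground truth and decoding it back is
exact to floating-point precision.

**Regression head.** A convolutional feature extractor, one additional
convolutional layer (3 x 3, width equal to the backbone output — the width
is a config default, not a reference value), then a fully connected layer
of 22 outputs: (x, y) for each of the 11 landmarks, normalised to [0, 1] by
the model input dimensions. MSE loss (mean over coordinates) under Adam,
two sessions of 100 epochs at learning rates 0.001 then 0.0001 in the
reference schedule; the desk-scale schedule is 60 + 20 epochs at the same
rates. Each session resumes from the best checkpoint so far, and the
minimum-validation-loss weights are kept.

**Segmentation head.** A fully convolutional encoder-decoder with 11
output channels at input resolution (the reference architecture is a nested
encoder-decoder with dense skip pathways; the tiny variant is two stride-2
blocks and two upsample-convolution blocks). Targets are binary disk maps:
channel *k* is 1 exactly on pixels within radius R (default 5 px in model
space) of landmark *k*; disks may overlap across channels and are clipped
at the frame. The loss is the average of binary cross-entropy and dice loss
(`1 - (2*sum(p*t)+eps)/(sum(p)+sum(t)+eps)`, eps = 1, averaged over
channels), computed on sigmoid outputs; 50 epochs (desk scale 40) at
learning rate 0.001.

**Map-to-coordinate inference.** Each output map passes through a sigmoid;
the landmark is the unweighted centroid of all pixels whose value is at
least the seventh-highest pixel value of the map, duplicates counted. The
multiset convention makes binary maps well defined (a filled disk of
13 pixels selects the whole disk), while on continuous post-sigmoid maps
ties have measure zero. The rule always emits a coordinate — a constant map
yields the grid centroid — which is the documented degenerate behaviour:
tier 2 never refuses to answer; tier 1 is responsible for removing wings
whose landmarks are absent.

**Baseline.** The mean-location predictor emits, for every image, the
per-landmark average of the training coordinates. Its error reflects pose
variation, and both trained heads must beat it.

## Joint affine augmentation

Training-time augmentation samples scaling and per-axis shifts uniformly
from +/-5% and rotation from +/-22 degrees, and applies one matrix — built
as rotation about the image centre, then scaling, then shifting, a declared
convention since the composition order is not specified by the protocol —
to the pixels (inverse-mapped, bilinear, background fill) and exactly to
the landmarks. Shift percentages are fractions of each image dimension,
applied per axis. Samples whose transformed landmarks leave the frame are
resampled once, then used untransformed. In the training loop augmentation
operates at model resolution on the pre-resized image (the affine family
commutes with the pure-scale resize, and warping 32 x 32 images keeps
epochs cheap); `apply_augmentation()` itself works in whatever space it is
given and is tested in native space, including the marker-coincidence
invariant (a marker painted at a landmark, after warping, lies within 1 px
of the transformed coordinate).

## Evaluation statistics

Prediction error is the Euclidean pixel distance per (image, landmark) in
native space. `distance_errors()` reports MAE, RMSE and — because the error
distributions are skewed — the empirical 2.5/50/97.5 percentiles (linear
interpolation between order statistics) overall and per landmark; a mean's
confidence interval could not contain the median the way the reported
intervals do, so the percentile reading is used. `per_image_mean_error()`
averages the 11 distances per image and feeds the shape-bias analysis.

## Shape bias via generalized Procrustes analysis

All test shapes are centred, scaled to unit centroid size, and iteratively
rotated (full Procrustes, scaling allowed, reflections never — wing
chirality is fixed once right wings are flipped) onto the running mean
shape, which is renormalised each round; convergence is a mean-shape change
below 1e-8, capped at 100 iterations. A specimen's disparity is its
Procrustes distance from the mean shape. Ground-truth shapes are used for
the alignment by default (the disparity should describe the wing, not the
predictor); aligning predicted shapes is supported. `bias_regression()`
then fits OLS of per-image mean error on disparity after removing points
more than 2 SD from either variable's mean (marginal rule, union removed),
reporting the slope and the R-squared both before and after removal. A
materially positive relationship would mean shape-dependent error — bias
against unusual wings in downstream morphometrics.

## Alignment QC with wing length as the quasi-identifier

Sampling margins use the normal approximation with finite-population
correction, `z * sqrt(p(1-p)/n) * sqrt((N-n)/(N-1))` with z = 1.96 — the
form that reproduces all three published sample margins (incomplete wings
13% +/- 4.63% and 10% +/- 4.13% at n = 200, N = 14,354; misaligned pages
2% +/- 2.56% at n = 100, N = 770).

For each page, `page_r_squared()` computes the squared Pearson correlation
between recorded `wlm` and the predicted landmark 1-6 length (mm; the
statistic is scale-invariant, so the unit is immaterial) over the page's
wings, flagging pages below the 0.1 threshold; pages with fewer than 3
usable wings or zero length variance are surfaced as degenerate for manual
review, never silently passed. Flagged pages get `suggest_corrections()`,
which searches one-step association shifts for the R-squared-maximising
repair and otherwise proposes page removal; `reconcile()` applies a
machine-readable correction log.

A statistical point the tests make explicit: a page misaligned from line 1
pairs every record with the wrong fly, so its R-squared is that of
independent pairs. The two wings of one fly share a length, so a full
20-line page contributes only about 20 effectively independent points, and
the null distribution of R-squared is approximately Beta(1/2, 9), giving a
per-page flag probability of `pbeta(0.1, 0.5, 9)` = 0.83 at threshold 0.1
— not certainty. Detection of a small number of injected misalignments in
a volume therefore fluctuates around that rate, while clean full pages are
essentially never flagged (their true R-squared is ~0.99). This is the
quantitative face of the known limitation that pages with few misaligned
lines, or late errors, often escape the threshold rule.

`length_agreement()` regresses predicted on measured length over the whole
corrected data set, flags points outside a global +/-1.96 residual-SE band
(a pointwise leverage-adjusted band changes nothing material at thousands
of points and the global band matches how the prediction interval is
drawn), and lists the flagged wings for review. Records measured on the
hatchet cell (landmarks 7-11) instead of landmarks 1-6 are excluded via an
explicit flag — the records give no reliable rule for identifying them, so
the package exposes the exclusion rather than guessing.

## Numerical and design choices

* 0-based pixel coordinates, x = column, y = row, stored in native image
  space; model-space views are derived. Landmark indices 1-11 follow the
  field's numbering.
* Warping is implemented in-package (inverse affine map + bilinear gather)
  so the pixel warp and the coordinate map share one convention, tested by
  the marker-coincidence invariant.
* BCE is computed on logits in a numerically stable form; `combined_loss()`
  on probabilities clamps at 1e-12 for reporting.
* The engine's gradients (conv, dense, ReLU, upsample, global pooling;
  BCE, MSE, BCE+dice) are verified against central differences in the test
  suite.
* Adam uses the standard bias-corrected moments (beta1 0.9, beta2 0.999,
  eps 1e-8); tier-2 batch size defaults to 16 (unspecified by the reference
  protocol) and dice eps to 1, both config-exposed, as is the disk radius R.
* Quantiles are type-7 (linear interpolation); exact-fit regressions guard
  the outlier rule with a 1e-9 floor on the residual band so floating-point
  noise is never flagged.
* Desk-scale problem sizes (96 x 120 canvas, 32 x 32 inputs, 500 annotated
  wings, 900 classifier wings, 60+20 / 40 / 40-epoch schedules) were chosen
  so the full suite trains in minutes on one CPU while every qualitative
  claim — both heads beat the baseline, augmentation helps the regression
  head, the gate's rejection rate tracks the injected damage rate — is
  comfortably reproduced.
* Every stage takes an explicit seed; one seed fixes generation, splits,
  initialisation, shuffling, augmentation and bootstrap draws end to end.

## Known limitations

The tiny networks establish protocol correctness, not attainable accuracy
on real images; no pretrained backbones are bundled. The generator's wings
are schematic — conclusions about robustness to staining, blur or
deformation do not transfer. The R-squared threshold rule inherits the
detection ceiling analysed above. And the package provides single point
predictions per wing; treating predicted landmarks as observed data
slightly understates downstream uncertainty.
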