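---
title: "Models and methods behind histoseg"
author: "histoseg maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind histoseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

histoseg implements two pipelines for H&E histopathology: instance
segmentation of nuclei in tissue tiles, and whole-slide classification of
non-small cell lung cancer into adenocarcinoma (LUAD) and squamous cell
carcinoma (LUSC). This vignette explains the models, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and do
not demonstrate.

## 1. Nucleus segmentation

### Problem and model

Nuclei in H&E tissue touch and overlap, so a pixel-level foreground mask is
not enough: the pipeline must also decide where one nucleus ends and the
next begins. Two convolutional networks handle the pixel level — one
predicts the nucleus *blob* mask (all nuclear pixels), the other the nucleus
*border* mask — and classical morphology turns the two into instances.

Both networks are deep residual aggregation networks (DRAN): an
encoder-decoder with a pre-activated 50-layer residual contracting path and
a decoder-based expanding path. The distinctive geometric choices:

* the 7x7 stem convolution is stride 1 with **no padding**, and the usual
  max pool is removed, so a 102x102 input enters stage 1 at 96x96;
* stage strides are (1, 2, 2, 2) with output channels (256, 512, 1024,
  2048), giving the spatial chain 96 -> 96 -> 48 -> 24 -> 12;
* the expanding path uses a 2x2 stride-2 transpose convolution (12 -> 24),
  three decoders of [5x5 conv, grouped 3x3 conv, 1x1 conv] — all **valid**
  convolutions, so each decoder shaves exactly 6 pixels per side — and
  nearest-neighbor x2 resizing between decoders;
* skip connections from the contracting path are merged by **addition**
  (cheaper than concatenation); because the expanding side is smaller than
  the matching contracting side, the skip tensor is center-cropped first
  (96 -> 60, 48 -> 36). Center cropping is the unique alignment that closes
  the 102 -> 54 chain, which `propagateShapes()` verifies structurally.

The network therefore maps a 102x102 RGB window to a 54x54 two-class map.
Training patches are 200x200 so that augmentation can sample outside the
input window without zero padding; the network input is the centered
102x102 crop and the target the centered 54x54 crop.

The multiscale variant (MDRAN) runs three DRAN bodies on the input at x0.5,
x1 and x2 scale (resized internally, bilinear), drops their softmax heads,
resizes each decoder1 output (128 channels) to the x1 output grid
(nearest-neighbor), sums them, and feeds the 128-channel sum through a
same-padded *decoder4* (5x5 -> 256 channels, grouped 3x3 with 64 groups,
1x1 -> classes). Fusion by addition rather than concatenation is forced by
decoder4's 128-channel input — the width of a single decoder1 output. Odd
intermediate sizes in the x0.5/x2 branches are handled by flooring strided
convolution outputs and resizing every branch to the common 54 grid.

### Training procedure

Adam (beta1 0.9, beta2 0.999, eps 1e-8), minibatch 32, L2 factor 1e-5 on
convolution kernels. DRAN trains in two phases: 35 epochs with the
contracting path frozen (learning rate 1e-4 dropping to 5e-5 / 1e-5 /
7.5e-6 at epochs 1 / 15 / 25 and 5e-6 at the phase boundary), then 40
epochs fully trainable at 5e-6. MDRAN loads pretrained branch weights,
trains only decoder4 for 10 epochs at 1e-4, then additionally the three
expanding paths for 35 epochs (1e-4 / 1e-5 / 1e-6 at epochs 0 / 15 / 30);
contracting paths never update. Frozen parts also keep their batch-norm
running statistics fixed. Weights are He-initialized; a hook accepts
externally pretrained contracting weights but the default builds entirely
offline.

The border task uses a class-weighted cross-entropy: border pixels weigh
5.0 when predicted correctly and 6.0 when missed as background; background
pixels weigh 1.0 and 4.0 respectively. The weight is chosen by the
*predicted* class (argmax; an exact 0.5 tie counts as background — a
convention, since the tie itself carries no information). The blob task
uses unweighted cross-entropy.

### Dataset construction

From each 200x200-capable tile: the NBL set slides a 200 window at step 54
plus 30 uniformly random crops per tile (random offsets come from a
per-tile RNG substream, so tile order cannot change patch content); the NBD
set centers one patch per nucleus whose centroid is at least 100 px from
every tile edge (so the patch fits without padding); the SN set duplicates,
three times, every NBL patch whose central 54x54 window holds at most 50%
nucleus pixels (inclusive). Augmentation draws a shift in ±5% of the side,
rotation ±45°, flips with probability 0.5 per axis, shear intensity
±0.4*pi, and rescale ratio 0.6–2.0, applied identically to the image
(bilinear) and the targets (nearest-neighbor, so targets stay binary);
out-of-source samples are filled by mirror reflection, which only triggers
at extreme draws thanks to the 200-pixel context.

Border ground truth is not uniquely defined by a labeled mask; histoseg
marks the pixels of each object that are 8-adjacent to background *or to a
different id* (so touching interfaces are border on both sides) and
thickens that outline to 2 px into the object. Two pixels keep the border
class learnable at 40x while leaving the 3x3 inference dilation meaningful.

### Inference and instance separation

Tiles are reflection-padded by 24 px and tiled by 102-windows at stride 54;
the abutting 54-outputs reassemble the tile exactly, and probabilities are
thresholded at 0.5 (inclusive). Instances are recovered by the published
recipe: dilate the border mask with a 3x3 box (one iteration, the kernel
read literally), subtract it from the blob mask, label the remaining cores
(8-connected), and assign every removed pixel to its geodesically nearest
core — implemented as a marker-controlled watershed, i.e. a multi-source
Dijkstra over the blob support with step costs 1 and sqrt(2) and
deterministic ties (smaller marker id). A brute-force Euclidean
nearest-core assigner serves as an independent oracle in the tests for
convex supports. A blob component whose core is entirely erased by the
dilated border falls back to being its own marker, so detections are never
silently deleted.

Finally the area filter removes objects smaller than 13 um^2 — below any
real nucleus, hence an artifact — using the tile's microns-per-pixel
(defaults 0.25 at 40x, 0.5 at 20x): 208 px at 0.25, 52 px at 0.5. The
comparison keeps objects at or above the threshold; since the step
eliminates artifacts, the *smaller* objects are the ones removed.

### Scoring

DICE_1 is the pixel Dice on binarized masks. DICE_2 ("Ensemble Dice") is
object-level: for direction A->B each object a is matched to the B-object
with maximal overlap (ties to the smallest id; no overlap leaves it
unmatched) and D(A->B) = sum 2|a∩b*| / sum(|a| + |b*|); DICE_2 is the mean
of the two directions. The published pseudo-code leaves the exact loop
structure open; this matching rule is symmetric, id-permutation-invariant,
reduces to DICE_1 when both masks hold one object, and strictly penalizes
splits and merges that DICE_1 ignores — splitting one object into two equal
halves scores exactly 2/3. The rule lives behind one internal function so
an alternative can be swapped without touching callers. Degenerate cases
the published description never states: two empty masks score 1.0, exactly
one empty mask scores 0.0. The tile score is the exact mean of the two
coefficients and the dataset score the mean over tiles; `printedScore()`
rounds half-up at three decimals, the convention the challenge tables use
(0.7755 prints as 0.776).

## 2. Whole-slide classification

### Patch classifier

256x256 patches at 20x are stain-normalized by Reinhard color transfer:
convert to the decorrelated l-alpha-beta space (Ruderman RGB->LMS matrix,
log10, orthonormal mixing — the constants are frozen in code and unit-tested
against a hand-computed pixel), standardize each channel by the source
statistics, rescale to a target image's statistics, and convert back. The
mapping is the identity on its own target and idempotent; a zero-variance
source channel is mean-shifted only (epsilon-guarded) rather than
amplified.

The classifier is a 32-layer ResNet variant: 3x3 first convolution (small
receptive fields suit sub-cellular features), four stages of bottleneck
units with the stage plan (2, 3, 3, 2) — ten units of three convolutions,
plus stem and fully-connected head = 32 weighted layers, with shortcut
projections uncounted per the ResNet naming convention. The stage plan is a
configuration key so any plan summing to ten units can be tested. The
published description fixes the 3x3 stem and the 32-layer count but not the
downsampling detail; histoseg uses a stride-2 stem plus stride-2 first
stage (strided convolutions rather than a max pool), keeping the engine's
layer vocabulary minimal. Training augmentation is a random 224 crop, axis
flips and multiples of 90°; inference uses the deterministic center crop.
Every epoch is checkpointed and the epoch with the greatest validation
accuracy is selected, ties to the earliest.

### Slide aggregation

Per-patch class probabilities are placed at their (row, col) patch-grid
cells, giving three congruent probability maps (ND / LUAD / LUSC); missing
cells are filled as pure ND. Two slide classifiers operate on the LUAD and
LUSC maps:

* **Max voting**: the class with more argmax-positive patches wins; count
  ties fall back to total probability mass, then LUAD.
* **Random-forest regression**: 50 features per slide — for each of the two
  maps: mean, median, population variance, positive-cell count and fraction
  at threshold 0.5, and the sizes of the five largest 8-connected
  components at thresholds 0.5 / 0.7 / 0.9 (descending, zero-padded);
  plus ten epsilon-guarded LUAD:LUSC ratios (mean, median, variance, total
  mass, positive counts and largest components at the three thresholds).
  The published account lists the feature *categories*; this 50-name
  manifest is a declared reconstruction, and every feature carries a stable
  name so selection is auditable. The top 25 features by Fisher score
  (mu1-mu2)^2 / (var1 + var2 + eps) — a simple deterministic realization of
  "class separability", ties in canonical name order — feed an ensemble of
  10 bagged regression trees (one third of variables per split, minimum
  leaf 5; labels encoded LUAD = 0, LUSC = 1). The forest's mean output is
  thresholded at 0.5 (at or above = LUSC); the threshold is a configuration
  key since the published account selected one without stating it.

## 3. Synthetic data: what it emulates and what it does not

The fixture module makes every stage testable offline. `generateNucleiTile`
renders filled ellipses with random orientation and eccentricity,
hematoxylin-dark-purple on eosin-pink with per-nucleus stain jitter and
Gaussian pixel noise; a stated fraction of nuclei is placed as touching
pairs sharing a small overlap (contested pixels go to the later id, keeping
the mask a partition), all other nuclei keep a clear margin. The default
semi-major axis range of 11–18 px corresponds to 5.5–9 um nucleus diameters
at 40x, above the 13 um^2 artifact threshold. All randomness flows through
one seeded stream per call; identical spec + seed is bit-identical.
`generateProbabilityMaps` mixes dominant-forced cells (probability =
`effect`) with uniform-Dirichlet cells, so the dominant argmax fraction is
effect + (1-effect)/3, linear in the effect.
`generateClassificationPatches` renders class-conditional colors and blob
textures (LUAD: many small dark blobs; LUSC: fewer, elongated, pinker; ND:
pale tissue) with balanced alternating slide labels and a configurable ND
fraction per slide (default 0.25).

These fixtures deliberately do **not** model stain chemistry, scanner
artifacts, chromatin texture, non-exhaustive region annotation, or the
morphological continuum between tumor types. Passing the learning-sanity
tests therefore shows that the optimization, geometry and aggregation
machinery are correct — not that the networks reach challenge-level
accuracy on real tissue, which requires the original slide corpus and
GPU-scale training.

## 4. Desk-scale problem sizes

The test suite and the reproduction script run reduced configurations,
chosen once as the package's desk-scale study conditions:

* overfit check: five 300x300 tiles with 35 nuclei (radius 6–14 px),
  width-1/32 DRAN, batch 8, 10 epochs x 12 steps at learning rate 1e-3
  (single phase, all parts trainable — the two-phase schedule with the
  published rates is exercised separately by the freeze-contract tests);
  held-out-crop pixel Dice is the measured outcome.
* slide recovery: 20 slides x 12 patches, strong class effect (0.9),
  width-1/8 classifier on 64-pixel inputs, 4 epochs; the forest trains on
  ten slides and is evaluated on the other ten against max voting.
* architecture checks build the full-width networks (67M parameters) and
  forward a single input.

## 5. Known limitations

* The engine is CPU-only and double-precision; full-width training is out
  of reach by design, and "deterministic" means up to BLAS floating-point
  non-associativity.
* DICE_2's matching rule is one faithful reading of a pseudo-code figure;
  alternatives (e.g. overlap-sum rather than best-match) would differ on
  pathological many-to-many overlaps.
* The 50-feature manifest and the border thickness are declared
  reconstructions where the published account is silent; both are config
  keys.
* Probability thresholding at 0.5 and argmax are equivalent for two
  classes; the inclusive-threshold convention matters only on exact ties.
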