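---
title: "Segmenting and measuring retinal microaneurysms from AOSLO videos"
author: "MAseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and measuring retinal microaneurysms from AOSLO videos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MAseg)
```

## The problem

Adaptive optics scanning laser ophthalmoscopy (AOSLO) resolves individual
retinal capillaries (~2.5 µm lateral resolution) and records each field as a
short video of aligned frames. Microaneurysms (MAs) — focal dilations of
capillaries and an early lesion of diabetic retinopathy — appear as
low-contrast blobs on a noisy background crowded with other vessels, some as
large as the MAs themselves. The clinically interesting quantities are the
MA body diameter (largest caliber, LC), the width of its feeding and
draining ("parent") vessels (narrowest caliber, NC), and their ratio
(body-to-neck ratio, BNR = LC/NC), which prior work associates with rupture
and thrombosis propensity. Measuring them requires a segmentation that
captures not only the body but also the thin parent vessels — which is what
makes the task hard, and what this package automates.

`MAseg` implements the full chain: multimodal preprocessing of the video,
an encoder–decoder segmentation network with a composite loss, ensemble
postprocessing, Dice/IoU evaluation, and medial-axis morphometry. Because
clinical AOSLO recordings are not redistributable, the package also ships a
seeded phantom generator that reproduces the statistical structure the
pipeline relies on, with exact geometric ground truth; the entire test
suite runs on phantoms.

## Preprocessing: two channels from one video

Perfused structures flicker from frame to frame (moving blood), static
tissue does not. The **perfusion map** is the per-pixel temporal standard
deviation across frames — population convention (denominator `n`), a choice
that is immaterial downstream because the map is min–max normalized, but
fixed and documented for testability (`computePerfusionMap()`). The raw map
is then passed through a four-step enhancement chain
(`enhancePerfusion()`), in this order:

1. fast non-local means denoising (patch 7, search window 21, strength
   `h = 0.1 ×` dynamic range),
2. min–max normalization to [0, 1] (a constant map becomes all zeros:
   "no signal" rather than 0/0),
3. CLAHE (8 × 8 tiles, clip limit 0.01 of the tile histogram, 256 bins),
4. gamma correction with γ = 0.8 (removes CLAHE's bright background
   stripes).

The method names are fixed; none of their parameters is prescribed by the
source method description, so all are defaults in `enhanceParams()` and
overridable. The chain is applied to the perfusion channel only — the
enhanced intensity channel (below) is left as is, matching the published
figures of the method this package follows.

The **enhanced image** (`computeEnhancedImage()`) is the frame average,
inverted (`1 − x`), then smoothed with a local mean filter (default window
5 px, reflective borders). Inversion makes perfused lumina bright; the
window size is a free parameter. The two modalities are resampled
bilinearly to the network size (512 px at full scale, 64 px in tests) and
concatenated in fixed order (enhanced, perfusion) by `makeTwoChannel()`.
Masks are always resampled with nearest-neighbour so they stay binary.

## Augmentation

`augmentPair()` produces exactly `N` outputs per input: rotation angles are
enumerated deterministically (`2πk/N`, k = 0…N−1, default N = 32) while
horizontal/vertical flips (probability 0.5 each) and a scale factor
(uniform in [0.7, 1.4]) are drawn per rotation slot from the config seed.
Enumerated rotation is the only reading consistent with the published
training-set count 63 × 32 = 2016; whether flips were drawn per source
image or per slot is not stated, so per-slot was chosen and is
seed-controlled. Images are interpolated bilinearly, masks with
nearest-neighbour; out-of-frame regions are filled with 0 (background), and
the canvas stays at the input size (rotate-then-crop) because the network
input size is fixed.

## Network, loss and training

The model (`buildNetwork()`) is a 5-level U-shaped encoder–decoder: each
encoder level halves the resolution and applies two 3×3 conv + ReLU
layers; each decoder block upsamples ×2, concatenates the matching encoder
skip and applies two 3×3 conv + ReLU layers; a 1×1 convolution with sigmoid
gives per-pixel probabilities in (0, 1). The full-scale recipe uses an
EfficientNet-b3-class encoder with decoder channels (256, 128, 64, 32, 16)
and ImageNet pretraining for fast convergence. Neither a deep-learning
framework nor pretrained weights are available in this package's offline
target environment, so convolutions, backpropagation and Adam are
implemented directly (Rcpp/Armadillo im2col + GEMM, verified against finite
differences in the test suite); the `"tiny"` encoder preset preserves the
5-level structure at CPU-trainable widths and is what the tests exercise,
while `"efficientnet-b3"` maps to a plain-convolution encoder of comparable
widths and `pretrained = TRUE` is an error.

The loss is `BCE + α · (1 − softDice)` with α = 0.2 (`compositeLoss()`).
Two notational choices deserve note: the printed form of the BCE omits the
conventional minus sign and calls the Dice *similarity* a loss; as written
those would be maximized by bad predictions, so the package uses the
standard negative BCE (per-pixel mean, which keeps α meaningful across
image sizes) and `1 − Dice`. The Dice term is soft (probabilities, no
threshold — the hard count is not differentiable) with smoothing constant 1
in numerator and denominator so empty masks are well defined.
Probabilities are clipped to `[ε, 1−ε]` (ε = 1e-7) before the logarithms.

Training (`trainModel()`) is minibatch Adam, learning rate 0.001, weight
decay 1e-8, batch size 16 (8 at test scale), up to 200 epochs, with a
plateau schedule: when the validation loss has not decreased for 5 epochs
the learning rate is multiplied by 0.1. The best-validation checkpoint is
returned together with the per-epoch history. A non-finite loss aborts with
a stage diagnostic.

`makeSplit()` reproduces the published data split: one fifth of the ids
(`⌊n/5⌋`, which yields the printed 63:7:17 for n = 87) is reserved as test;
the remaining pool is divided into 10 cross-validation folds as equally as
possible. Images are split at random (not grouped by subject), matching the
source procedure; grouped splitting would be a straightforward extension
but is deliberately not the default.

## Postprocessing

`binarize()` thresholds at 0.5 with the `≥` convention (exactly 0.5 is
foreground — measure-zero for sigmoid outputs but fixed for testability).
`clearFragments()` removes 8-connected components smaller than 1024 px
(strictly below: exactly 1024 px survives); 8-connectivity is the tolerant
choice for thin diagonal vessels, and the 1024 px threshold is calibrated
to 512 × 512 inputs — scale it by `(size/512)²` elsewhere, which the
pipeline config does automatically. `selectAndUnion()` takes the 3 best of
10 cross-validated models by mean validation Dice (validation loss is the
config alternative; the source does not define "performance on the
validation set" precisely) and returns the pixel-wise OR of their masks.
Clearing is applied per model before the union by default — the order is
unspecified in the source; union-then-clear is available by calling the
functions in the other order.

## Morphometry

`medialProfile()` thins the mask (Zhang–Suen) to its skeleton, prunes spur
branches shorter than 3 px (raw thinning grows boundary spurs whose tiny
radii would corrupt NC), and attaches to each skeleton point the exact
Euclidean distance to the nearest background pixel center. Then:

* `LC = 2 · max(D)` — twice the largest medial radius,
* `NC = 2 · mean` of the 10 smallest radii in ascending order (stable sort
  for ties; shorter skeletons use all points),
* `BNR = LC / NC`.

NC is computed over the whole object (body + vessels): on a correct
segmentation the 10 smallest radii fall on the vessels, and this is the
reading implied by defining D over all skeleton points. Multi-component
masks are reported per 8-connected component (`morphometry()`), since one
image may contain several MAs. Skeleton points whose medial disk would
cross the image frame are flagged as border-contaminated and excluded from
the calibers by default instead of silently biasing NC low on clipped
crops. Distances are float pixels; micron values are attached only when
the caller supplies a scale.

**Caliber convention.** Radii are measured to the nearest background pixel
*center* — exactly the stated distance-transform procedure. On the integer
grid this makes even rasterized widths exact and overestimates odd widths
by 1 px (a width-5 vessel reads NC = 6). No half-pixel correction is
applied, because the corrected estimator is exact for odd widths but
*under*-reads even ones; the convention is fixed, documented, and inside
the stated tolerances everywhere it is tested.

## The phantom world

`generatePhantom()` renders a stated world, not a tunable benchmark: MA
bodies (disks, ellipses with the semi-minor axis defining the diameter, or
fusiform spindles built from two mirrored circular arcs whose inscribed
radius equals half the diameter) with axis-aligned attached vessels running
to the frame edge, plus free-floating distractor vessels that flicker
identically to real vessels — reproducing the clinical difficulty that
background vessels interfere with segmentation. The ground-truth mask
contains bodies and attached vessels only; BNR truth is
`diameter / min attached width` exactly, by construction.

Temporal structure: perfused pixels are i.i.d. Gaussian per frame around
the structure intensity (the pipeline only consumes the temporal sd, so any
zero-mean model with controlled sd suffices); the background keeps one
frozen noise texture. The noise statistics of real AOSLO are not quantified
in the source, so the levels here are fixed free choices, made once:
structure intensity 0.35, background 0.60 (low contrast), flicker sd 0.12,
background texture sd 0.08, 75 frames as acquired clinically. Structures
are *darker* than background, as in multiply-scattered-light AOSLO frames —
that is what makes the inversion step of the enhancement chain meaningful,
and it is the only orientation under which both channels of the two-channel
input end up brighter on the MA than on background.

Geometry is rasterized with strict interior tests (`< r`) on pixel centers
at integer coordinates, with centers snapped to the parity that renders the
stated extent exactly (half-integer centers for even diameters). The
default fixture ranges use even diameters (14–30 px) and even vessel widths
(4–8 px) with axis-aligned vessels: a calibration-grid choice under which
the caliber convention above is exact, analogous to validating a measuring
tool on a grid-aligned bar target. Oblique and odd-width cases are covered
by the separate rotation-robustness and tolerance-banded tests.

What a green phantom test does **not** establish: performance on clinical
data. Phantoms have no point-spread function, no eye-motion warp or
registration residue, no intensity inhomogeneity, no thrombosed
(non-perfused) MA regions, and their vessels are straight and axis-aligned.
The phantom suite verifies that the machinery is correct — that each stage
computes what it claims and the geometry is recovered where it is knowable
— not that the trained tiny network would segment patient images.

## Numerical choices and degenerate inputs

* Perfusion of a single frame is an error (temporal sd undefined for the
  purpose); a constant video gives an all-zero map.
* Constant input to the enhancement chain stays constant; CLAHE of a
  constant maps to a constant.
* Bilinear resizing uses the half-pixel-center convention, so same-size
  resampling is the identity; identity augmentation (N = 1, no flip, scale
  1) reproduces the input bit-for-bit.
* A single isolated mask pixel has skeleton size 1 and medial radius 1.
* Empty masks: errors for morphometry; Dice/IoU of two empty masks is 1
  (perfect agreement on absence).
* Ensemble ties break toward the lower model index; all randomness flows
  from one global seed through named per-stage substreams (`deriveSeed()`),
  so rerunning a pipeline config reproduces every artifact hash.

## Limitations

The tiny encoder is a correctness vehicle, not a clinical model; training
at 512 px with the wide encoder is possible but far outside CPU test
budgets, and ImageNet pretraining is unavailable offline. TIFF/PGM I/O
covers the uncompressed grayscale subset the package writes (plus 8/16-bit
unsigned reads), not arbitrary TIFF. Morphometry assumes the object of
interest is the largest component when asked for a single profile, and its
calibers inherit ±1 px rasterization granularity — at the clinical scale of
~2.5 µm/px that is the resolution floor of the instrument, not of the
method.
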