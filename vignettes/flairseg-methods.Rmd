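---
title: "Weakly supervised tumor segmentation from feature-map gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised tumor segmentation from feature-map gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flairseg)
```

## The problem and the idea

Pixel-accurate tumor masks are expensive: an expert has to outline the
lesion on every slice, and different experts disagree. `flairseg`
implements a two-stage pipeline that needs only a per-slice *binary*
label — tumor or not tumor — at training time, and still produces a
pixel mask at test time.

1. **Classification.** An 18-layer 2D CNN is trained on FLAIR MRI
   slices to answer "is there a tumor in this slice?". FLAIR is used
   because tumor plus peritumoral edema appears hyperintense there,
   which makes the whole lesion visible to a single modality.
2. **Segmentation.** For a slice the classifier calls a tumor, the 32
   feature maps of the last convolution layer are turned into a single
   saliency map: each map's **spatial intensity gradient** is computed
   by forward differences, each map is re-weighted by the mean and the
   maximum of its gradient magnitude, the weighted maps are averaged,
   normalized to grayscale, upsampled to the slice geometry,
   thresholded, and cleaned by morphological post-processing.

The gradients here are *image-space* derivatives of the feature maps
(`H[i,j] = X[i,j+1] - X[i,j]`, `V[i,j] = X[i+1,j] - X[i,j]`), not
back-propagated gradients: maps whose content varies strongly — sharp,
compact activations over the lesion — receive large weights, while flat
maps are suppressed. It is a Grad-CAM-like construction built entirely
from forward quantities.

## The classifier

The layer stack is fixed: five 3x3 stride-1 SAME convolutions with
512, 256, 128, 64 and 32 filters, ReLU after each, 2x2 stride-2 max
pooling after the ReLUs of layers 2, 7 and 12, a flatten (8192
features for a 128 x 128 input), a 32-unit fully connected ReLU layer
and a 2-unit softmax. The printed layer table has stride-1
convolutions, and only that reading is consistent with its own output
shapes (`architecture_shapes()` reproduces them exactly); the
accompanying prose mentions stride 2, which we take to describe the
pooling layers.

A `scale` divisor (1, 2, 4, 8) shrinks all filter counts uniformly.
`scale = 8` — filters 64/32/16/8/4, about 58k parameters — is the
desk-scale variant used throughout the tests; every spatial size and
the whole pipeline are unchanged, only capacity shrinks.

Training minimizes the clipped binary cross-entropy of the softmax
pair (for one-hot targets this equals the negative log-likelihood)
with Adam at `alpha0 = 1e-4` and the polynomial decay

    alpha(e) = alpha0 * (1 - e / Ne)^0.9,

applied per epoch (epoch `k` of `Ne` runs at `alpha(k - 1)`, so the
first epoch uses `alpha0` and the rate never quite reaches zero while
training is still in progress). Kernels start from a seeded
Glorot-style uniform draw, biases at zero; He-uniform initialization
was also evaluated and made no practical difference on the phantom
study, so the simpler convention stayed. The engine (im2col-free
shifted-GEMM convolutions over a zero-padded batch layout, direct BLAS
`sgemm`) is single-precision — the customary arithmetic for CNN
training — strictly sequential, and therefore bit-reproducible for a
fixed seed; its gradients were verified against an independent
double-precision im2col implementation (agreement ~1e-6, the float
resolution) and that oracle in turn against central finite differences
(~1e-8).

## Input preparation and augmentation

Volumes are read from NIfTI-1; the default working plane is axial
slice 90 (0-based) of the 155-slice BraTS geometry. Slices are cropped
to the centered 192 x 152 window (the brain is centered in BraTS
volumes; the margins are background) and bilinearly resized to
128 x 128, the input size the layer table is dimensioned for. The crop
and the 128 x 128 input are both published settings; the resize
reconciles them.

Training data are enlarged by horizontal/vertical flips (probability
0.5 each), exact +/-90 degree rotation, a 20-pixel shift with zero
fill, additive Gaussian noise (sd = 0.05 of the intensity range) and
Gaussian blur (sd 1 px, reflective boundary). The noise and blur
levels are not stated in the source table ("random noisy", "Gaussian
blur"); 0.05 and 1 px are visible but label-preserving. In the default
sampling mode each non-flip family is included with probability 1/2
and rotation picks one direction at random, giving an expected 4x
enlargement — the same ratio as the published augmented dataset
relative to its patient count. Ground-truth masks ride along through
geometric transforms and are untouched by noise and blur. Z-score
normalization (mean 0, population sd 1 per slice) is applied *after*
augmentation, because noise and blur change the moments it removes.

## From feature maps to mask

For a tumor-called slice, with `F_k` the 32 x 32 post-ReLU maps of the
last convolution layer (taken before the final pooling; the published
feature-map figures are at this resolution, and a flag exposes the
pooled 16 x 16 variant):

1. `H_k, V_k` — forward differences of `F_k`; the trailing column/row,
   where the difference is undefined, is set to 0, which is neutral
   for the pooling that follows.
2. `G_k = sqrt(H_k^2 + V_k^2)` — the per-pixel gradient magnitude. The
   source text pools a `(32, 32, 32)` object, so the two-vector
   gradient must be scalarized; the Euclidean norm is the standard
   choice.
3. `w_k = mean(G_k) * max(G_k)` — both pooled vectors act on map `k`.
   The source multiplies "those vectors" (plural) with the filters yet
   reports exactly 32 weighted images; the product is the reading that
   satisfies both, and a `combine = "stack_mean"` alternative averages
   the mean-weighted and max-weighted stacks instead.
4. The weighted maps are averaged, negatives clamped, scaled by the
   global maximum into `[0, 1]` (an all-zero response stays all-zero),
   and bilinearly upsampled to the slice geometry.
5. Thresholding: in deployment (`mode = "fixed"`) a single threshold,
   default `tau = 0.5`, is applied — no reference mask is needed
   anywhere. In evaluation (`mode = "sweep"`) the grid
   `tau = 0.33, 0.35, ..., 0.85` (27 values) is scored by Dice against
   the reference and the argmax is kept, ties broken toward the
   smallest threshold. The sweep exists to characterize the saliency
   map's best attainable quality; it is the published evaluation
   protocol, and it does use the ground truth — the mask-free claim
   applies to the fixed mode and to training.
6. For display, the saliency map is passed through a deterministic
   jet-style colormap (gray 0 -> dark blue (0,0,0.5), gray 1 -> dark
   red (0.5,0,0)) and added onto the slice with weight `alpha = 0.4`
   (the source specifies addition without a weight), clipped to the
   display range.

## Post-processing

Raw thresholded masks carry two artifact classes: speckle and spurious
responses hugging the scan border. `postprocess_mask()` applies
morphological opening with a 3 x 3 box (anti-extensive, monotone,
idempotent — properties the tests check on random masks), then deletes
every 8-connected component confined to a 10-pixel border band (a
component with any deeper pixel survives intact), then an optional
minimum-size filter (off by default). Opening runs first so that a
thin bridge between a border artifact and genuine tumor is cut before
the component decision. The pixel count never increases and the
composition is idempotent.

## The phantom generator

Real BraTS volumes cannot ship with the package, so the generator
builds the *appearance the method assumes*: a centered bright
elliptical "brain" (semi-axes 70-85% of the half-side, softly
blurred edge) over zero background, tissue texture as a smooth
low-frequency field (sd 0.03, 16-px scale) plus per-pixel Gaussian
noise (sd 0.05), and — with probability `tumor_prob` — one elliptical
hyperintense lesion (semi-axes 6-20 px, Gaussian-smoothed edge) whose
amplitude is `lesion_contrast = 3` tissue standard deviations. The
texture is deliberately subordinate to the lesion: in FLAIR the edema
is conspicuously the brightest structure, and the saliency method's
premise is exactly that the highest-intensity compact region is the
tumor. The binary mask is the lesion's support; the slice label
follows from the mask (at least `tumor_pixel_min = 1` lesion pixels).

What the phantoms do **not** model: anatomy (ventricles, sulci, skull
remnants), multi-focal or infiltrative lesions, intensity
inhomogeneity, partial-volume effects, or other hyperintense mimics
(small-vessel disease). Passing the phantom study therefore shows the
pipeline is implemented correctly and recovers planted lesions under
its own assumptions — not that it reaches any particular accuracy on
clinical data.

## The phantom study and its outcome

`run_phantom_experiment()` is the package's end-to-end study: 400
phantoms at the defaults above, sampled augmentation, normalization,
a stratified 70:30 split (the dataset-then-split order of the
published protocol; note this places augmented variants of training
slices into the held-out set), 15 epochs of training at batch 20, then
sweep-mode segmentation with post-processing of every held-out slice
whose ground truth has a lesion. Slices the classification gate
rejects score Dice 0. All randomness derives from one seed via
`stage_seed()`, and two runs with the same seed agree to the last bit.

At these conditions the median held-out Dice (about 0.77 before and
after post-processing; post-processing rarely changes the already
compact phantom masks, so the two medians essentially coincide)
comfortably exceeds 0.70, while held-out classification accuracy
reaches about 0.74 after 15 epochs — short of the 0.90 that the
corresponding acceptance check asserts. Two factors contribute. The
dominant one is the optimization budget: 15 epochs of 56 batches is
~840 Adam steps at a rate that decays from 1e-4 to zero, whereas the
published configuration trains 45 epochs (~1700 steps on its real
dataset) to reach its 91%; running the identical pipeline for 45
epochs lifts held-out accuracy to about 0.88. The remainder is task
hardness at desk scale: the smallest permitted lesions (6-px
semi-axis, ~100 px) and their shifted/blurred augmented variants are
genuinely subtle for a 58k-parameter network. The acceptance test
keeps the 15-epoch condition and fails honestly rather than quietly
training longer; the test suite documents this as the one red check.

Problem sizes were chosen so the whole study trains a ~58k-parameter
network on ~1100 augmented slices in a few minutes of one CPU:
`scale = 8` preserves every shape ratio of the full 4.7M-parameter
network while keeping the study re-runnable.

## Numerical conventions worth knowing

* Slice indexing is 0-based ("slice 90" is index 90 of 0..154).
* `+90` rotation is counter-clockwise; `[[1,2],[3,4]]` becomes
  `[[2,4],[1,3]]`.
* A resize to the current size is an exact identity; bilinear values
  never leave the input's range.
* `dice()` on two empty masks returns 1 with a `both_empty` flag — a
  correct "no tumor" call, never a division error. Undefined
  precision/recall are `NA` with a flag, never silent zeros.
* Max-pooling ties break toward the first window element in scan
  order; the sweep's Dice ties break toward the smallest threshold.
* Constant slices are rejected by `zscore_normalize()` (sd = 0), and
  NaN voxels are rejected at load time with their count.
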