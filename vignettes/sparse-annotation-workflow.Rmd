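---
title: "Segmenting fossil micro-CT with sparse annotations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting fossil micro-CT with sparse annotations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paleoseg)
```

## The problem

Micro-CT scans of fossils embedded in rock matrix routinely run to
thousands of slices of several megapixels each. Manual segmentation of the
fossil (drawing a region-of-interest mask on every slice) can take an hour
per slice, which makes full manual extraction of a specimen infeasible.
`paleoseg` implements a workflow that reduces the manual effort to one to
two percent of the slices: annotate every Nth slice, train a convolutional
encoder-decoder on those few slices, predict the remaining ones, then
refine by annotating the midpoints between the original slices (correcting
the model's own predictions, which is far faster than drawing from
scratch) and retraining.

The segmentation itself is hard for classical thresholding because fossil
bone and the encasing matrix attenuate X-rays similarly: the contrast
between the two classes is small relative to noise and reconstruction
artefacts, and the fossil occupies only a few percent of each slice.

## The model

The network is a UNet: an encoder of conv(3x3)-norm-ReLU blocks with 2x2
mean pooling, a bottleneck block, and a decoder that upsamples (nearest
neighbour), concatenates the matching encoder feature map, and convolves
down a strictly decreasing channel ladder to a 1x1 logit head. The depth
equals `length(decoder_channels)`; the production-scale ladder is
`c(512, 256, 128, 64, 32)`, and the desk default is `c(16, 8)`. Each
interior convolution is followed by per-channel normalization over the
current batch (the batch-statistics form of batch normalization; statistics
always come from the input being processed, so inference is deterministic
and independent of batch composition). The head carries no normalization
and its bias starts at the prior log-odds of a fossil pixel (`qlogis(0.1)`),
so the network begins at the base rate instead of predicting 0.5
everywhere — with the small step budgets of the prescribed learning-rate
schedule, both choices matter for reaching a useful optimum.

There is no deep-learning framework dependency: the forward and backward
passes (im2col/GEMM convolutions in compiled code, explicit backpropagation
through normalization, pooling, upsampling and skip concatenation) are part
of the package, and every gradient path is verified against central finite
differences in the test suite.

### Training recipe

* **Loss**: mean binary cross-entropy on the per-pixel probabilities
  (computed from logits in a numerically stable form).
* **Optimizer**: AdamW — Adam with decoupled weight decay 0.01 (decay on
  convolution weights only, not biases or normalization parameters).
* **Learning rate**: the linear-scaling heuristic
  `initial_lr = 0.01 * batch_size / 256`, so 0.0003125 at batch size 8;
  encoder-group parameters train at one tenth of the decoder rate. The
  schedule ramps linearly from zero over the first 10 epochs, then follows
  a half-cosine down to zero.
* **Epoch**: one pass through the epoch schedule — one
  positive-pixel-guaranteed crop per training slice plus exactly two
  negative crops drawn from documented fossil-free ranges, shuffled and
  consumed in batches of `batch_size` without replacement. The negative
  count is a fixed ratio (2 per epoch) regardless of how many positive
  slices there are.
* **Checkpointing**: after every epoch the full held-out slice is
  predicted (without test-time augmentation) and its Dice against the
  held-out annotation recorded; the weights with the best validation Dice
  are returned.
* **Mixed precision**: the configuration accepts the flag for
  compatibility, but the CPU engine computes in double precision
  throughout, so it has no numerical effect here.

### Sampling and augmentation

Positive crops are guaranteed to contain fossil: a positive mask pixel is
drawn uniformly, then the crop origin uniformly among all origins that keep
that pixel inside the crop and the crop inside the slice. This satisfies
the protocol's guarantee and gives every fossil pixel non-zero sampling
mass; it is not uniform over all fossil-containing origins (origins near
large fossil regions are modestly favoured), which is harmless for training
and keeps the construction exact. If a training slice's mask is empty the
crop falls back to an unconstrained uniform origin.

Negative crops come only from slice ranges documented fossil-free — never
from merely unannotated slices, which may contain fossil.

Each training crop (image and mask together) receives a random rotation
uniform in [0, 360) degrees plus independent horizontal and vertical
flips. Multiples of 90 degrees are exact index permutations; other angles
resample the image bilinearly and the mask by nearest neighbour so masks
stay strictly binary. Corners rotated in from outside the frame are filled
with the crop's median intensity — in practice the matrix level — rather
than black, which a scanner never produces. Augmentation applies to
training crops only; validation and inference inputs are never augmented.

### Inference

Full slices are predicted at native resolution. Test-time augmentation
runs the model on all eight dihedral variants of the slice (four rotations,
four reflections, implemented as exact index permutations), realigns the
probability maps, and averages them *in probability space* before
thresholding at 0.5 (both configurable). Soft averaging was chosen over
binarize-then-vote: it is the natural reading of "averaging predictions"
and empirically dominates majority voting. The eight maps are combined by
a pairwise tree sum, so a symmetry-invariant model passes through TTA
bit-exactly.

## The annotation protocol

`select_initial_slices(start, end, step)` returns the every-`step`
arithmetic grid across the *visible extent* of the fossil — an explicit
human input, not auto-detected. Refinement (`refine_plan`) halves the
stride: it inserts the midpoints of consecutive annotated pairs and
extends the halved grid to the extent end, so nine initial slices at
stride 200 over a 1701-slice extent become exactly the eighteen slices of
stride 100 (8 interior midpoints plus one tail slice). This is the only
reading that reconciles "nine further slices" with "every 100th slice, 18
in total". Refinement never removes indices, requires an even stride
(midpoints must be integral), and preserves the validation slice.

The validation slice is chosen by mask complexity, proxied by the
positive-pixel count (ties break to the lowest slice index): the
`"simplest"` mask is held out by default, matching the production choice
of reserving the simplest region of interest for validation in both
iterations. Holding out the same slice across iterations keeps the two
hold-out Dice values comparable.

Dice is defined as `2|A∩B| / (|A| + |B|)` with the both-empty case scored
as 1: an empty prediction of a fossil-free slice is perfect, and the
convention is required for scoring negative slices at all. Aggregates are
reported both as the mean of per-slice Dice and as pooled-counts Dice;
the two differ when slice sizes or difficulty vary.

## The synthetic phantom

The phantom emulates the features of the real data that drive failure
modes, with exact ground truth:

* **Low contrast**: fossil renders at `matrix_level + contrast`
  (defaults 0.35 + 0.15) under additive Gaussian noise
  (`noise_sigma = 0.03`), i.e. contrast is five times the noise standard
  deviation — comfortably solvable, as a learning sanity floor should be,
  but far from binary-clean.
* **Structure**: hollow vertical tubes (long-bone shafts) crossed by
  internal struts, thin plates at arbitrary orientation, and exactly one
  tube carrying a foramen — a channel of exactly `foramen_width_vox`
  background voxels cut through its wall over a three-slice band. The
  default width of 13 voxels is what a 130 µm nutrient foramen spans at
  10 µm voxels. All solids are analytic and voxelized exactly, so Dice
  accounting against ground truth is exact.
* **Fossil-free margins**: the first and last `empty_margin` slices carry
  no fossil, providing the documented negative ranges.
* **Artefacts** (off by default): concentric sinusoidal ring bands and
  high-intensity streak lines, clipped to [0, 1]. Artefacts perturb
  intensities only and never the masks, mirroring real scans where
  reconstruction artefacts corrupt images, not anatomy.

Generation is a pure function of the parameter set including its seed: a
single generator is seeded once per volume and consumed in a documented
order (tubes, plates, struts, foramen position, per-slice noise, artefact
phases). Mask fractions on fossil-bearing slices stay within a sparse
0.5–20% band under the defaults.

What the phantom does *not* emulate: X-ray physics (beam hardening,
photon statistics, reconstruction from projections), texture inside bone
and matrix, erosion of cortical bone, and high-density inclusions. Tests
passing on the phantom therefore demonstrate that the pipeline's
machinery — sampling, optimization, checkpointing, TTA, bookkeeping — is
correct and that the workflow learns a genuinely low-contrast noisy task;
they do not by themselves establish accuracy on any particular scanner's
output.

## Desk-scale study conditions

The package's defaults are a scaled-down analogue of the production run,
sized so the full two-iteration study runs on one CPU core in minutes:

| quantity | production | desk default |
|---|---|---|
| slices | 2159 of 2560×2560 | 96 of 192×192 |
| crop size | 512 | 64 |
| batch size | 8 | 8 |
| epochs | 5000 | 200 |
| decoder ladder | 512…32 | 16, 8 |
| annotation stride | 200 → 100 | 10 → 5 |
| encoder | large pretrained backbone | `"tiny"` built-in |

Under these conditions iteration 1 trains on 7 slices (8 annotated, 1 held
out) and iteration 2 on 15 (16 annotated). Across seeds the held-out Dice
lands in the high 0.8s after iteration 1 and does not degrade — typically
improves — after refinement, the desk analogue of the production
improvement from 0.93 to 0.96. The production-scale values themselves are
not reproducible at desk scale: they require the original scan volume, the
manual annotations, GPU-scale training, and a large pretrained encoder.

## Numerical choices and degenerate inputs

* Intensities normalize by the dtype maximum (`v / (2^bits − 1)`), not
  per-slice min-max, so fossil/matrix contrast is stationary along the
  stack axis.
* Slice indices are 0-based everywhere (matching the common numbering of
  exported slice files); image-stack files are ranked by the numeric
  component of their names, mask files carry the slice index itself.
* Inputs whose sides are not divisible by `2^depth` are zero-padded on
  the bottom/right for the forward pass and cropped back afterwards;
  non-square slices under TTA require an explicit `pad_to_square`.
* Probabilities are clamped to `[1e-7, 1 − 1e-7]` inside the exposed BCE
  loss; training computes the loss from logits and cannot overflow.
* A non-finite training loss raises an error naming the epoch rather than
  being silently clipped (gradient clipping is off by default).
* Binarization uses `>=`, so a probability exactly at the threshold is
  positive, and positive counts are non-increasing in the threshold.
* With an empty negative-range list the trainer proceeds with positive
  crops only and says so.

## Known limitations

* The engine is CPU-bound and sized for desk-scale problems; production
  volumes need hours, not the minutes of the phantom study.
* The built-in `"tiny"` encoder is the only backbone shipped; the
  configuration field exists so alternatives can be plugged in, and no
  pretrained weights are bundled.
* 2.5D (three-slice) input is supported but the desk defaults use single
  slices, mirroring the production finding that one-channel input was
  slightly better for a high-capacity model.
* The refinement step on phantoms takes corrected masks from ground
  truth; with real data those come from a human editing the predicted
  stack, whose errors the phantom cannot model.
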