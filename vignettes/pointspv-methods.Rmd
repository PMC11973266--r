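---
title: "Methods: end-to-end phosphene encoding with gaze-centered viewing patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: end-to-end phosphene encoding with gaze-centered viewing patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cortical visual prostheses evoke *phosphenes* — punctate light percepts —
by electrically stimulating the visual pathway through an electrode
array. A representation method decides which electrodes to drive given
camera input. This package implements a task-oriented, gaze-aware
pipeline for simulated prosthetic vision (SPV): instead of filtering
the whole camera image, it samples *viewing points* on a target object,
crops a gaze-centered patch, and learns an encoder that turns that
patch into a binary electrode activation map whose rendered phosphenes
are optimized to be recognizable.

The pipeline has four parts, trained end to end:

1. **Encoder** `E`: a fully convolutional network mapping a viewing
   patch `I` (default 100×100 RGB) to a binary activation map (default
   32×32).
2. **Simulator** `V`: a fixed, non-trainable renderer mapping each
   active electrode to an equally sized dot phosphene at a preassigned
   location in a frame (default 256×256).
3. **Blind unit** `B`: a classification network that sees only the
   phosphene frame, acting as a surrogate implant user. Its early
   stages are the feature extractor, the rest the classifier.
4. **Sighted unit** `S`: a frozen copy of the feature extractor applied
   to the background-free patch `I'`, providing the perceptual
   reference.

Training minimizes

$$L = \gamma \, L_P + (1-\gamma)\, L_{CE}, \qquad
L_P = \frac{\lVert S_i(I') - B_i(V(E(I))) \rVert_2^2}{W_i H_i C_i},$$

with `gamma = 0.75` by default, where `i` is the feature-extractor
split stage and `(W_i, H_i, C_i)` the feature-map shape. Gradient
routing follows the computation graph: the encoder and the blind
feature extractor receive both terms, the blind classifier receives
only the cross-entropy term, and the sighted unit receives nothing.

## Encoder architecture and size reconciliation

The encoder is a 13-group fully convolutional network: channels
3–8–16–32–64 on the way in (groups 3 and 4 pool), four 64-channel
residual blocks, and a decoder 64–32–16–8–3–1 (group 9 pools). All
kernels are 3×3, stride 1, pad 1; batch normalization on groups 1–11;
leaky rectifiers (slope 0.01) on groups 1–12; sigmoid on group 13.

Three 2× poolings cannot map a 100-pixel input onto a 32-cell grid
(100 → 50 → 25 → 12), so the patch is bilinearly resized to
`internal_size = grid_size * 8` (256 for the default grid) before the
network; this preserves both the 100×100 patch contract and the 32×32
map contract. Pooling is 2×2 max pooling; residual blocks are
conv–BN–act–conv–BN with an identity skip and activation after the
addition. A `width` multiplier scales the 8–16–32–64 channel spine for
desk-scale work without changing the architecture's shape.

## Binarization and the straight-through estimator

Contemporary cortical prostheses offer little graded control of
phosphene brightness, so activation is binary. The output stage
composes the group-13 sigmoid with a Heaviside step: an element is
active iff its sigmoid output strictly exceeds `binarize_threshold`
(default 0.5); values exactly at the threshold are inactive. The step
has zero gradient almost everywhere, so training uses a
straight-through estimator: the backward pass treats the thresholding
as the identity on the sigmoid outputs. The suite verifies that this
backward equals the backward of the sigmoid-only network by finite
differences.

## Simulator

The frame is divided into `grid_size²` equal cells; electrode `(r, c)`
renders at the cell-centered pixel `((r + 0.5)s, (c + 0.5)s)`,
`s = frame_size / grid_size` (0-based coordinates, origin top-left —
the package-wide convention). The dot profile is an isotropic Gaussian
with `sigma = s/4` (a flat disk is available), peak brightness 1,
truncated at radius `s/2 − 1` so each phosphene stays strictly inside
its cell. The truncation keeps phosphenes of neighboring electrodes
disjoint, which makes "rendered blob count = active electrode count" a
testable invariant and keeps rendering a fixed linear operator
followed by clipping — hence deterministic, composable with
gradient-based training, and exactly adjoint-differentiable.

## Recognition units

At full scale the blind/sighted units would wrap a large pretrained
residual classification network split after its early units
(`split_index = 6`). To keep the package self-contained and
download-free, the default is a compact 8-stage surrogate residual
network (`split_index = 4`) trained from scratch on synthetic scenes;
a registry allows other backbones to be plugged in by name. The
backbone is pretrained on background-free viewing patches with
cross-entropy; the frozen copy of its feature extractor becomes the
sighted unit (playing the role of the fixed pretrained reference) and
a trainable copy initializes the blind unit.

Two shape questions are open in the underlying design and resolved
here as follows. First, the sighted path sees a patch and the blind
path a frame of a different size; the sighted input is resized to the
frame size before feature extraction so the two feature maps are
shape-compatible — the precondition of the perceptual loss. Second,
phosphene frames are single-channel; they are replicated to three
channels (not learned projection) to match the backbone's input
convention.

## Optimization choices

The source design leaves the optimizer unspecified. Defaults, all
exposed in `loss_config()`:

- **Adam**, learning rate 2e-3, batch size 8; cross-entropy and the
  perceptual term are both averaged over the batch.
- **Per-epoch learning-rate decay** (0.6×): short schedules otherwise
  oscillate near the end because the binarized bottleneck makes the
  loss surface piecewise constant in places; annealing makes the final
  epoch approximate the best epoch.
- **Gradient clipping** at global norm 5 per component: the
  straight-through estimator occasionally produces large spurious
  gradients when many elements sit near the threshold.
- **Batch normalization momentum 0.25** (running statistics): the
  phosphene statistics drift quickly while the encoder learns, and the
  evaluation-mode running averages must keep up within a few hundred
  steps.
- The best-validation checkpoint is retained; divergence (non-finite
  loss) aborts with a diagnostic rather than returning garbage.

All randomness flows through explicit integer seeds; with a fixed seed
(and single-threaded BLAS) training, rendering and session replay are
bit-reproducible.

## Synthetic data: what it emulates and what it does not

The generator stands in for photographs with object segmentation
masks. Each scene has one target object from one of `K` classes on a
filtered-noise background (a plain light background mode reproduces
the ceiling-effect scenario in which both representation methods
saturate). The two default classes differ the way animal categories
do, in correlated global and local cues:

- class 0: roundish blob with 5–8 sinusoidal protrusions and a
  *spotted* coat;
- class 1: elongated ellipse (aspect 2.5–4.5, random orientation) with
  a *striped* coat perpendicular to the body axis.

Silhouettes alone separate the classes: a hand-written second-moment
(elongation) classifier reaches ≥ 90% on 200 scenes, which the suite
checks. The coat texture (period 20–30 px) matters for a different
reason: a gaze-sized patch often sees only part of the object, and
local texture is what makes the class recoverable from such views —
the analogue of fur patterns in the animal-discrimination task. Object
color and background are randomized per scene so neither is
informative.

What the generator does *not* emulate: photorealistic appearance,
cluttered multi-object scenes, occlusion, and human oculomotor
dynamics (gaze logs are draws biased toward the object's bounding box
with plausible fixation durations, not a saccade model). Passing tests
therefore show that the pipeline can learn task-relevant encodings and
that every operation is internally correct — not that the learned
encoder transfers to natural images.

## Gaze-contingent rendering and the edge-detection baseline

The offline presentation engine replays a gaze log against a stimulus:
for each sample it crops the patch around the gaze location (window
clamped at borders, as in patch sampling), processes it with the
selected method, resizes the result into the aperture's bounding box,
masks it with a circular aperture (radius default = half the patch
size; the radius used in the original experiment is not stated), and
composites it on a black screen. Frames are rendered during saccades
too; a flag blanks them for illustration-style output.

The baseline is the Canny edge detector (Gaussian blur σ = 1.0, Sobel,
non-maximum suppression, hysteresis at 100/200 on the 8-bit scale —
thresholds configurable since the original values were empirical). By
default the edge map is max-pooled onto the electrode grid, binarized,
and rendered by the same simulator, so both methods are compared as
phosphene patterns of identical geometry; a raw-edges mode bypasses
the simulator for sensitivity analyses.

## Behavioral metrics

Per (participant, method) cell: accuracy, mean reaction time, mean
saccade count (saccade events are consumed from the log, not detected
from raw traces), and mean stimulus coverage. Coverage models each
fixation as an unnormalized 2-D Gaussian with peak 1 (σ = 50 px,
assumed pixels), composes overlapping fixations by per-pixel maximum,
and normalizes the heatmap sum by the pixel count of the full image.
Peak-1 kernels are the only choice under which fixating every pixel
yields exactly 100% coverage, which is the stated limit law; a
density-normalized kernel could not reach it. Group heatmaps average
per-participant max-composed maps pixelwise.

Method comparisons use a repeated-measures ANOVA with one two-level
within factor on (1, n−1) degrees of freedom, fitted via `aov` with a
participant error stratum; for this design F equals the squared paired
t statistic, which the suite verifies on random data. The four metric
tests are reported uncorrected by default (Holm-adjusted p-values are
available behind a flag). Identical condition vectors are a degenerate
zero-variance case and return F = 0, p = 1 by convention.

## Problem sizes used by the test suite

The structural checks run the full reference configuration (100×100
patches, 32×32 grid, 256×256 frames). The learning checks run a
deliberately scaled-down study: 80 scenes × 5 viewing points = 400
patches (320/80 image-level split), an 8×8 grid with 64×64 internal
and frame resolution, encoder width 0.5 with two residual blocks, a
6-channel-base surrogate backbone pretrained for 4 epochs, then 5
end-to-end epochs for each of three seeds. These sizes are the
package's chosen desk-scale experiment: small enough to run routinely
on one CPU, large enough that validation accuracy separates a learning
pipeline (≥ 85%) from a broken one (50%).

## Known limitations

- The simulator is deliberately simple: homogeneous, equally sized,
  binary phosphenes on a regular grid. Cortical magnification, current
  spread, temporal dynamics and electrode dropout are out of scope,
  but the renderer is pluggable.
- The surrogate backbone is not a stand-in for human perception; the
  blind unit measures machine recognizability of the encoding.
- Patch-level splitting (provided for protocol fidelity) leaks
  near-duplicate views between train and validation; image-level
  splitting is the default for honest validation numbers.
- The Canny baseline's thresholds are scene-dependent; the defaults
  are reasonable for the synthetic scenes, not universal.
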