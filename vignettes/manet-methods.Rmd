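---
title: "Multi-attention segmentation networks for liver-tumor CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-attention segmentation networks for liver-tumor CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(manet)
```

## The problem and the model

Automatic liver-tumor segmentation labels each pixel of an abdominal CT
slice as tumor or background. Tumors are small, low-contrast and variable
in number and size, so plain encoder–decoder networks tend to miss them or
bleed across their fuzzy boundaries. The architecture implemented here — a
multi-attention U-Net, **MANet** — augments a three-stage residual
encoder–decoder with four attention mechanisms, each recalibrating features
at a different point of the network:

* **Channel attention (CA)**, after every encoder block. Global max- and
  average-pooled channel descriptors pass through a *shared*, bias-free
  two-layer perceptron whose hidden width is half the channel count;
  the sigmoid of the summed outputs gates each channel:
  `att = sigmoid(MLP(maxpool(x)) + MLP(avgpool(x)))`.
* **Spatial attention (SA)**, on the upsampled features entering every
  decoder block. Per-pixel max and mean over channels are concatenated into
  a two-channel descriptor map, convolved with a single 7×7 kernel
  (zero padding 3, preserving the extent) and squashed by a sigmoid into a
  per-pixel gate.
* **CBAM**, their sequential composition (CA then SA), applied once at the
  bridge — the deepest, most semantic representation.
* **Skip-connection attention gates (SCAG)** on each skip path. The shallow
  encoder features `x_SF` and the deep gate signal `x_DF` (the bridge
  output for the deepest skip, then each decoder stage's output) are
  projected by 1×1 convolutions to half the shallow width — the shallow
  path with stride 2 and *no bias*, the gate path with a bias, exactly as
  the defining equations write them — summed, passed through ReLU, a 1×1
  convolution and a sigmoid, and the resulting single-channel map is
  upsampled bilinearly back to the skip resolution before multiplying
  `x_SF`.

Encoder blocks are residual: two 3×3 convolutions (the first with stride 2
from stage 2 on — there is no pooling anywhere), each followed by batch
normalization and ReLU, plus a 1×1 projection on the shortcut whenever
channels or resolution change; the shortcut is normalized but not activated
before the addition, with a final ReLU after it (standard residual
practice). The decoder mirrors the encoder with plain double-convolution
blocks; upsampling uses 2×2 stride-2 transposed convolutions. The head is
a 1×1 convolution with an element-wise sigmoid over three output channels
(background / liver / tumor slots); channel 3 is the tumor probability
map, binarized at 0.5 for evaluation.

## Reconstructing the exact topology

The published structure table pins the fifteen numbered convolutions
(kernel, filters, stride, output size) but not the transposed-convolution
widths, and the narrative leaves the decoder wiring order terse. Two
published totals constrain the reconstruction strongly: 7.83 M trainable
parameters and 132.37 GMac at a 512×512×3 input. We enumerated the
plausible wiring space (up-conv widths and kernels, gate-projection
conventions, bias placements) under an otherwise-literal reading of the
structure table. Neither textbook convention fits: symmetric U-Net
up-convs (272/136/68) overshoot both totals (7.85 M, 137.4 GMac), strict
channel-halving (272/68/34) undershoots badly (7.74 M, 124.4 GMac). The
adopted wiring — up-conv widths **272, 136, 34**, i.e. the encoder widths
shifted down one stage and ending at the final width, matching the table's
own 68→34 narrowing — reproduces the totals best: **7,820,368 parameters
(7.82 M, −0.12%)** and **129.54 GMac (−2.1%)**. No natural wiring we found
reproduces both printed values to two decimals; the residual gap is
documented rather than hidden, and `manet_config()` exposes
`upconv_widths` should different evidence surface.

The MAC convention is declared, not inferred: kernel elements × input
channels × output channels × output positions for every convolution and
transposed convolution, both pooled branches of each attention perceptron,
and nothing for normalization, activations or pooling — the convention of
the common profiler tools.

One self-inconsistency in the surrounding contracts is resolved
deliberately: channel widths are *not* rejected when odd. The reduced
benchmark configuration (encoder 17/34/68) requires odd widths, so every
width-halving step (`c/2` hidden layers, SCAG projections, the final
width) uses integer division instead. For even widths — including the
full-scale defaults — this is exactly the halving the equations state.

## Training protocol

Training follows the published protocol: soft Dice loss (smoothing
constant `s = 1`, the probability formulation, averaged over batch and
foreground channels), Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) at an initial
learning rate of 1e-4 attenuated ×0.1 every 30 epochs, batch size 4,
real-time augmentation (vertical flip, shift, scale, rotate — limits ±10%,
±10%, ±15°, each with probability 0.5; the source names the operations but
not the limits), and **no validation split**: the checkpoint with the
highest test-set Dice during training is kept. That selection rule is
optimistic by construction; every reported Dice inherits it.

Weights start from the deep-learning framework's default Kaiming-uniform
flavor, `U(±1/sqrt(fan_in))`, with zero biases; batch-normalization scales
start at 1, shifts at 0, running statistics at (0, 1) with momentum 0.1.

All compute is single-threaded and single-precision by default (the
framework convention the protocol was defined in); a double-precision path
exists and is what the finite-difference gradient checks use, since float
noise at step sizes near 1e-5 would otherwise mask real errors. One
genuine subtlety the test suite documents: with zero-initialized biases
many ReLU inputs sit *exactly* on the kink, where the analytic subgradient
and a central difference legitimately disagree — gradient checks therefore
jitter the biases first.

## CT preprocessing

Intensities are clipped to the soft-tissue window [−150, 250] HU, then
globally histogram-equalized (256 bins — the source says only "histogram
equalization", so the plain global variant is used rather than CLAHE) and
min–max normalized to [0, 1]; a constant slice maps to zeros. Slices are
kept when their mask has at least one tumor pixel (threshold
configurable). Splits are 4:1 train:test, drawn at slice level or — to
prevent leakage — at volume level, where every slice of a volume lands on
one side.

## Evaluation

Seven metrics per case: Dice, Jaccard (IoU), VOE = 1 − Jaccard, accuracy,
sensitivity, specificity from pixel confusion counts, and the average
symmetric surface distance (ASSD). Boundaries are foreground pixels with a
4-connected background neighbour (the image border counts as background);
distances are exact Euclidean point-to-boundary distances from a
Felzenszwalb–Huttenlocher distance transform, in pixels by default or
millimetres when NIfTI spacing is available. Aggregation reports mean ±
population standard deviation; volume grouping pools confusion counts and
slice-boundary distances per volume before computing metrics (the method
operates on 2-D slices; true 3-D surfaces are out of scope). Policy for
degenerate cases: both masks empty → Dice = Jaccard = 1 and ASSD
undefined; prediction empty against a non-empty truth → Dice 0, ASSD
undefined, and the case flagged in a non-segmentation tally. Sensitivity
is reported missing, never silently zero, when `TP + FN = 0`.

## The phantom generator

Real CT volumes are large external downloads, so every end-to-end check
runs on synthetic phantoms instead: an elliptical "liver" (≈ 60 HU, random
center/axes/orientation, fixed within a volume) on a darker background
(≈ −100 HU), containing 1–3 circular tumors of radius 3–12 px at 45 HU
below the liver, with Gaussian-blurred edges (σ 1.5 px) and additive
Gaussian noise (σ 10 HU) on a 96 px grid. The mask marks the pre-blur
tumor supports exactly. Tumor radii stay uniformly distributed because the
radius is drawn once and only the position is re-sampled upon rejection;
a tumor that cannot fit inside the ellipse raises an error instead of
silently shrinking. NIfTI headers carry a 0.7×0.7 mm in-plane spacing so
the millimetre ASSD path is exercised. These defaults were chosen once so
that a small network can learn the task on a CPU in minutes while the
signal still survives windowing and equalization; they are an artifact
decision, not a claim about LiTS-scale difficulty.

What passing on phantoms does and does not show: the phantoms reproduce
the *structural* assumptions (bright organ, darker focal lesions, fuzzy
boundaries, class imbalance, tumor-count variability) but none of the
anatomical context, scanner variability, or annotation noise of real CT —
phantom Dice says the implementation optimizes and generalizes on its own
task, not that it would reach any particular score on clinical data.

## Reference experiment sizes

The packaged reference experiment (`phantom_benchmark()`) trains a
quarter-width network (encoder 17/34/68, bridge 136 — 0.49 M parameters,
0.29 GMac per 96² forward pass) on 200 phantom slices (ten volumes, split
4:1) for 15 epochs, and reports the best held-out Dice; three seeded
replicates summarize as a median. These sizes keep a full replicate within
a few minutes of single-core CPU time while remaining large enough for the
median Dice to clear 0.70 comfortably. The ablation harness runs all eight
variants (plain U-Net through the full model) at reduced widths by
default; at full width the factory is exercised build-and-forward only.

## Numerical choices and degenerate inputs

* Convolution arithmetic runs in single precision through batched
  GEMM kernels (an implicit-GEMM path for the ubiquitous 3×3/stride-1
  case); a templated double path backs the gradient checks. Tolerances:
  1e-6 against scalar-loop oracles for the attention operators, 1e-9 for
  ASSD against the all-pairs oracle.
* Channel-max pooling routes gradients to the argmax, splitting equally on
  ties; bilinear upsampling uses half-pixel centers with clamped edges.
* Spatial extents must be divisible by 2^depth (8 on defaults); violations
  raise an error naming the divisor rather than silently cropping.
* The 7×7 spatial-attention convolution uses zero padding, so a constant
  field yields a constant attention map only away from the 3-pixel border
  frame — the tests check the interior.
* Training aborts with a diagnostic on a non-finite loss instead of
  continuing with poisoned weights.

## Known limitations

* 2-D slices only; no volumetric kernels, no cascaded liver-then-tumor
  inference, no test-time augmentation.
* The published LiTS/3DIRCADb scores require the external datasets and
  GPU-scale training and are explicitly not reproduced here; the phantom
  benchmark replaces them as the executable evidence.
* Best-on-test checkpoint selection (the protocol's own choice) means
  reported Dice values are optimistically biased.
* The exact transposed-convolution widths of the original network are
  unpublished; ours are the closest reconstruction under the published
  totals, and the two headline totals are reproduced to −0.12% and −2.1%
  rather than exactly.
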