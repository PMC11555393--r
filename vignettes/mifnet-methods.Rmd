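---
title: "MIFNet: model family, complexity calculus, and pipeline methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MIFNet: model family, complexity calculus, and pipeline methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifnet)
```

## The problem and the model family

Benign/malignant classification of lung-nodule candidates is usually
posed as binary classification of small grayscale CT patches: a 50x50
axial crop around an annotated candidate position, labelled nodule
(positive) or background (negative).  Clinically useful models must run
on modest hardware, so the architecture of interest here is
deliberately lightweight: the multi-scale interleaved-fusion network
(MIFNet) family, a three-stage convolutional network whose flagship
member has roughly 0.7 million trainable parameters.

A MIFNet is built from three *stages*.  Each stage starts with a
**scaling layer** (a 1x1 convolution that sets the stage's channel
width, 16/32/64 by default) and is followed by a **MIF block**, then a
2x2 stride-2 pooling (max pooling after stage one, average pooling
after stages two and three) with dropout (rates 0.1/0.2/0.3).  The
classification head is a global average pool over the final feature
map followed by a dense layer with two outputs and a softmax.

A MIF block runs **three parallel branches**, each a chain of `k`
bottleneck **mini-blocks**.  One mini-block is three Conv-BN-ReLU
composites:

1. a 1x1 convolution reducing the branch width to the stage's
   bottleneck width (4/8/16 by default),
2. a 3x3 *grouped* convolution at the bottleneck width (groups
   4/4/4 by default, padding "same"),
3. a 1x1 convolution expanding back to the branch width,

with an identity shortcut from the mini-block input added before the
final ReLU.  Grouping the 3x3 kernels divides their parameters and
multiply-accumulates by the group count; the cost is that channels
stop exchanging information across groups, which the next ingredient
repairs.

**Interleaved channel fusion.**  After every mini-block, each branch's
next input is the channel-wise concatenation of `C` consecutive branch
outputs, cyclically: branch *i* receives branches *i*, *i+1*, ...,
*i+C-1* (mod 3).  `C = 1` means no cross-branch mixing; `C = 2` is the
default.  Because the concatenation is not reduced back down, the
per-branch width grows geometrically: after `j` mini-blocks a branch
carries `C^j` times the stage width.  This growth is the defining
feature of the family's complexity scaling — parameter counts roughly
double with every added mini-block at `C = 2` — and it is why the
initial stage widths are kept small.  At the end of a block the three
branch streams are merged element-wise and handed to the next stage.

The family is indexed by a **nominal depth** label `3 + 6k + 1`
(`k` mini-blocks per branch per stage): presets `mifnet10` through
`mifnet46` cover `k` = 1, 3, 4, 5, 6, 7, and `mifnet46_wide` doubles
the bottleneck widths to (8, 16, 32).

```{r presets}
g <- assemble_mifnet(mifnet_preset("mifnet40"))
complexity_report(mifnet_preset("mifnet40"))
```

## How the topology was fixed

Several details of the block wiring admit more than one reading, and
small wiring changes move the parameter count by integer factors.  We
therefore treated the family's published complexity figures — the
parameter, model-size and FLOP columns reported for depths 10 through
46 — as the ground truth for the wiring and enumerated candidate
topologies against them.  The published parameter series approximately
doubles per added mini-block, which rules out any scheme that reduces
the fused concatenation back to a fixed stage width (such schemes are
linear in `k` and land around 0.13 M at depth 40 instead of 0.7 M).
The adopted wiring — three-conv bottleneck mini-blocks, grouping on
the 3x3 kernels only, fusion after every mini-block with unreduced
concatenation, element-wise branch merging, biased convolutions,
non-affine batch normalisation, and a global-average-pooled head —
reproduces the published series to within 3.3% at every depth and
exactly at the one-decimal precision of the flagship's 0.7 M figure,
with FLOPs within 8% (exact at depth 10).  The residual 1–3%
discrepancies follow a pattern (a geometric term slightly below ours
plus a per-mini-block constant slightly above) that no enumerated
variant removed; we froze the best-fitting wiring and regression-test
its exact counts rather than chase unpublishable internals of the
original training framework.

Two consequences of the calibration are worth stating explicitly:

* **Batch normalisation carries no learnable scale/shift.**  The
  neighbouring biased convolutions can absorb an affine
  reparameterisation, so the non-affine form loses no expressiveness,
  and counting 2 parameters per BN channel would push the flagship to
  0.77 M, contradicting the published figure.  `count_parameters()`
  still implements the `2 * channels` rule for affine BN layers.
* **The head pools globally before the dense layer.**  A flattened
  7x7 head would add ~200k parameters at depth 40 and is incompatible
  with the published counts; the global-average-pool head matches them
  and the family's architectural description.

## Complexity conventions

* Output sizes follow `v_out = round((v_in + 2p - k) / s) + 1`, with
  floor rounding for convolutions and ceil rounding for the 2x2
  stride-2 poolings — ceil mode is forced by the published spatial
  trajectory 50 → 25 → 13 → 7.
* The jump (accumulated stride) multiplies: `c_l = c_{l-1} * s`; the
  receptive field grows by `(k_l - 1)` times the accumulated stride of
  everything before: two stacked 3x3 stride-1 convolutions see 5x5.
  The propagation is cross-checked in the tests by an enumeration
  oracle that back-traces the input support of one output unit.
* FLOPs are multiply-accumulates of convolution and dense layers for
  one forward pass at the stated input size; batch normalisation,
  activations and pooling count zero.  The single-MAC (not 2x)
  convention was fixed once against the published depth-40 figure and
  frozen.  Scaling layers and the dense layer are included.
* Model size is 4 bytes per parameter (`4 P / 2^20` MB), validated
  against the published (parameters, MB) pairs.

## Preprocessing pipeline

Annotated CT volumes arrive as MetaImage (`.mhd` header + `.raw`
voxels) with candidate tables in world-frame millimetre coordinates.
The pipeline is:

1. **world to voxel**: `index = round((world - origin) / spacing)`
   per axis, zero-based, (x, y, z) order; nearest-integer rounding
   keeps the round-trip error within half a voxel per axis.
2. **Hounsfield windowing**: clip to [-1000, 400] HU (air to the
   soft-tissue/bone boundary, the usual lung window) and map affinely
   to [0, 1].
3. **patch extraction**: a 50x50 axial crop at the annotation's z
   slice, centred so the annotated voxel lands at (zero-based) pixel
   (25, 25); out-of-volume pixels are zero.
4. **rebalancing**: negatives are seeded-uniformly undersampled to 5
   per original positive (one nodule patch in six images), and each
   positive is emitted in four axis-aligned orientations (0/90/180/270
   degrees — axis-aligned rotations avoid interpolation artefacts).
5. **export**: a seeded shuffle and 0.8/0.2 train/test split, written
   as 8-bit grayscale PNGs plus a manifest table; every run records
   its seed and paths, and the whole pipeline is a pure function of
   (input files, seed).

In-memory volumes are `[x, y, z]` arrays (x fastest, matching both the
MetaImage payload order and R's column-major layout).

## Synthetic fixtures

The generator produces the two kinds of inputs the pipeline consumes.
*Scans*: Gaussian background at -800 ± 50 HU (aerated lung) with hard
spheroids of additive amplitude 850 HU (plateau ≈ +50 HU,
soft-tissue-like) at stated world positions, plus candidate tables
whose negatives are rejection-sampled at least two radii from every
nodule.  *Patch sets*: Gaussian-noise backgrounds (mean 0.35, sd
`noise_sd`) where positives carry a centred bright disc (radius
uniform in 4–12 px, amplitude `separation * noise_sd`) and negatives
carry either nothing or an off-centre distractor at 30% amplitude;
classes are exactly balanced and `separation = 0` makes them
identically distributed.  A separation of 8 at `noise_sd = 0.05` is
verified separable by a pixel-mean threshold classifier before any
training test relies on it.

These fixtures exercise the pipeline's geometry, file formats and
learnability, but they do not model CT texture, anatomy, partial
volume effects or scanner physics — passing tests on them demonstrates
that the machinery is correct, not that the model reaches any
particular accuracy on real CT data.

## Training and evaluation

Training is seeded mini-batch gradient descent with softmax
cross-entropy, Xavier-uniform initial weights, and ADAM
(`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`), SGDM (momentum 0.9) or
RMSprop (decay 0.9).  The reference regime is 50 epochs, batch 32,
constant learning rate 0.001, no validation split or early stopping.
Dropout and shuffling draw from the single training seed, so identical
seeds and data reproduce histories bit for bit.

Batch normalisation uses batch statistics during training and running
statistics at inference.  Because a short run's exponentially-weighted
running averages lag the final weights, training ends with a
**finalisation pass**: one sweep over the training set with the final
weights, replacing the running statistics with the average batch
statistics.  Without this pass, a five-epoch run can sit at ~1%
training error under batch statistics yet collapse at inference.

Evaluation reports the confusion matrix with the malignant/nodule
class positive, and accuracy, F1, precision, sensitivity and
specificity as percentages; ratios with zero denominators are reported
as undefined (`NA`), never as zero.  Predictions are the argmax of the
class probabilities with exact ties going to the positive class, and a
per-sample table of predicted labels with confidences supports
instance-level inspection.

## Numerical choices and degenerate inputs

* BN epsilon 1e-5; running variance stored with the unbiased
  correction `M / (M - 1)`.
* Ceil-mode average pooling divides by the number of in-volume cells,
  so edge windows are true averages, not zero-padded ones.
* Max-pooling ties resolve to the first cell in column-major window
  order (deterministic).
* A learning rate of zero is allowed and freezes the loss exactly
  (used as a diagnostic).
* Non-finite losses abort training with the offending epoch; empty
  datasets and non-binary labels are rejected at the door.
* The cross-entropy clamps probabilities at 1e-12 before the log.

## Problem sizes in the shipped tests

The test suite runs everything at desk scale: unit and property tests
use a reduced configuration (stage widths 4/8/8 on 12-pixel inputs),
gradient checks probe every parameterised layer against central finite
differences, and the end-to-end learnability check trains the depth-10
preset for the reference five epochs on 640 generated patches (100
optimizer steps), evaluating on 100 held-out patches.  These sizes
were chosen so a single CPU completes the suite in a few minutes while
leaving the learnability margin wide (the shipped run reaches ~99%
training and ~100% held-out accuracy against thresholds of 95% and
90%).

## Known limitations

* Real-data accuracy columns of the family's published ablations are
  out of scope; nothing here trains on LUNA16 itself.
* The exact published parameter/FLOP figures are matched to 1–3%
  (exactly at the flagship's printed precision), not digit-for-digit;
  the residual is documented above.
* Convolutions support stride 1 with odd kernels ("same" padding),
  which is all the family uses; there is no 3D variant.
* The width-variant presets double only the bottleneck widths; the
  published width-ablation table is consistent with more than one
  reading and is not regression-tested.
* The MetaImage reader covers the little-endian scalar types used by
  LUNA16-style archives, not the full MetaIO specification.
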