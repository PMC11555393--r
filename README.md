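# mifnet

Lightweight multi-scale interleaved-fusion networks (the MIFNet
family) for benign/malignant classification of 50x50 lung-nodule CT
patches — implemented as a configurable model family in R, together
with its analytic complexity calculus, the LUNA16-style preprocessing
pipeline, a synthetic fixture generator, and a seeded training and
evaluation engine.

## The model in brief

A MIFNet stacks three stages on a single-channel 50x50 patch.  Stage
*s* is a 1x1 **scaling convolution** to width *w_s* (16/32/64),
followed by a **MIF block**: three parallel branches of *k* bottleneck
mini-blocks

&nbsp;&nbsp;&nbsp;&nbsp;1x1 conv (width → *b_s*) → BN → ReLU → 3x3
*grouped* conv (*b_s* → *b_s*, *g* = 4) → BN → ReLU → 1x1 conv
(*b_s* → width) → BN → (+ identity shortcut) → ReLU

with **interleaved channel fusion** after every mini-block: branch *i*
next consumes the concatenation of branches *i … i+C−1* (mod 3), so
the branch width grows by the fusion factor *C* (default 2) at every
step.  Blocks are merged element-wise, down-sampled by 2x2 stride-2
pooling (spatial trajectory 50 → 25 → 13 → 7, ceil mode), and
classified through a global average pool, a dense layer and softmax.
Nominal depth is 3 + 6*k* + 1; the depth-40 flagship (`mifnet40`,
*k* = 6) has 715,978 ≈ 0.7 M trainable parameters.

The complexity calculus propagates output sizes
(`v' = round((v + 2p − k)/s) + 1`), jumps (`c' = c·s`) and receptive
fields (`r' = r + (k − 1)·∏ strides`) along layer chains — two stacked
3x3 stride-1 convolutions see a 5x5 field — and counts parameters and
multiply-accumulate FLOPs per layer over the assembled graph.

## Worked example

```r
library(mifnet)

## architecture analysis
print(complexity_report(mifnet_preset("mifnet40")))
#> MIFNet complexity report (nominal depth 40)
#>   parameters: 715,978  (0.716 M)
#>   model size: 2.731 MB (4 bytes/parameter)
#>   FLOPs:      2.340 x 10^8  (multiply-accumulates; conv and dense layers only)
#>   receptive field at stage boundaries:
#>     stage1         v=25  jump=2   r=14
#>     stage2         v=13  jump=4   r=40
#>     stage3         v=7   jump=8   r=92

## train the depth-10 preset on generated, separable patches
ds      <- make_patch_dataset(96, separation = 8, noise_sd = 0.05, seed = 1)
heldout <- make_patch_dataset(32, separation = 8, noise_sd = 0.05, seed = 2)
fit <- train(mifnet_preset("mifnet10"),
             list(images = ds$images, labels = ds$labels),
             train_config(epochs = 5, batch_size = 32, seed = 1))
print(fit)
#> MIFNet fit: 5 epochs (adam, lr 0.001); final loss 0.0893, error 0.00%

evaluate(fit, list(images = heldout$images, labels = heldout$labels))
#> confusion:  tp 23  fp 0  tn 32  fn 9
#> Acc 85.94%  F1 83.64%  Prec 100.00%  Sens 71.88%  Spec 100.00%
```

The fit reaches 0% *running* training error within five epochs; at
this small training size (192 patches, 30 optimizer steps) the
held-out accuracy is 85.9%, dominated by missed small-radius discs
(sensitivity 71.9% at perfect specificity).  The shipped end-to-end
test runs the same regime at 640 training patches (100 steps) and
reaches ~99% training / ~100% held-out accuracy.  `evaluate()` also
returns a per-sample table of predicted labels with confidences.

A full shell pipeline is available through the bundled entry point:

```sh
MIFNET=$(Rscript -e 'cat(system.file("exec","mifnet",package="mifnet"))')
Rscript $MIFNET generate --patches --n 50 --seed 7 --out data/
Rscript $MIFNET analyze  --preset mifnet40 --out reports/mifnet40
Rscript $MIFNET train    --data data/ --preset mifnet10 --epochs 5 --seed 7 --out run/
Rscript $MIFNET evaluate --model run/model.rds --data data/ --out run/eval
```

`preprocess` turns MetaImage volumes plus a candidate table into
balanced, seeded train/test patch splits; `generate` can also emit a
synthetic annotated scan (`--out` without `--patches`) to exercise
that path end to end.

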