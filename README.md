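# manet — multi-attention encoder–decoder networks for liver-tumor segmentation in CT

`manet` is an R implementation of a multi-attention U-Net (MANet) for
liver-tumor segmentation in computed tomography, together with everything
needed to exercise it end to end on a CPU with no external data: CT
preprocessing, Dice-loss training, a seven-metric evaluation suite, an
eight-way architecture-ablation factory, feature-map visualization and a
synthetic liver-phantom generator.

## The model

The network is an encoder–decoder with three encoder stages (68/136/272
channels), a 544-channel bridge and a mirrored decoder, augmented with four
attention mechanisms:

* **Channel attention** after each encoder block:
  `att = σ(MLP(maxpool(x)) + MLP(avgpool(x)))`, a shared bias-free
  two-layer perceptron with hidden width c/2, gating channels.
* **Spatial attention** in each decoder stage: per-pixel channel max/mean
  descriptors → 7×7 convolution → sigmoid, gating positions.
* **CBAM** (channel then spatial attention, composed) at the bridge.
* **Skip-connection attention gates**: additive attention
  `σ(W_φ·ReLU(W_x·x_SF + W_g·x_DF + b_g) + b_φ)` weighting each encoder
  skip with the deeper decoder signal before concatenation.

Encoder blocks are residual (two 3×3 convolutions + 1×1 projection, batch
norm and ReLU throughout, stride-2 first convolutions instead of pooling);
the head is a 1×1 convolution with a per-channel sigmoid. Training uses the
soft Dice loss `1 − (2Σpt + s)/(Σp + Σt + s)` with Adam (lr 1e-4, ×0.1
every 30 epochs, batch 4) and best-on-test checkpoint selection. On
defaults the network carries **7,820,368 trainable parameters (7.82 M)**
and costs **129.5 GMac** per 512×512×3 forward pass under the declared
convolution-MAC convention. Evaluation reports Dice, ASSD, Jaccard, VOE,
accuracy, sensitivity and specificity, per slice or pooled per volume.

## Worked example

Generate phantoms, train a reduced network for a few epochs, evaluate:

```r
library(manet)

ph   <- phantom_dataset(phantom_spec(), n_volumes = 10, seed = 101)  # 200 slices
imgs <- preprocess_slices(ph$images)            # HU window + equalize to [0,1]
sp   <- split_dataset(dim(imgs)[3], seed = 101) # 160 train / 40 test

fit <- manet(imgs[,, sp$train], ph$masks[,, sp$train],
             config = manet_config(encoder_widths = c(17, 34, 68),
                                   bridge_width   = 136),
             epochs = 15, seed = 101,
             test = list(x = imgs[,, sp$test], y = ph$masks[,, sp$test]))
#> epoch   1  loss 0.9439  lr 1.0e-04  test dice 0.0995
#> epoch   6  loss 0.9181  lr 1.0e-04  test dice 0.7357
#> epoch   9  loss 0.9160  lr 1.0e-04  test dice 0.7625
#> epoch  15  loss 0.9110  lr 1.0e-04  test dice 0.7028

fit$best_epoch                      # 9 — checkpoint with the best test Dice
report <- evaluate_manet(fit, imgs[,, sp$test], ph$masks[,, sp$test])
print(report)
```

The per-epoch lines show the Dice loss falling while the held-out tumor
Dice climbs from ~0.10 to a best of **0.76 at epoch 9**; the kept weights
are that epoch's. `evaluate_manet()` then prints the seven metrics
(mean ± sd over the 40 held-out slices). The same run is packaged as
`phantom_benchmark(seed)`.

Architecture inspection works without training:

```r
trace_layers(manet_config())   # the 15-row topology table + attention layers
count_parameters(manet_config()) / 1e6  # 7.82
count_macs(manet_config(), 512) / 1e9   # 129.54
```

A thin command-line front end lives in `exec/manet`
(`manet summarize`, `manet train`, `manet evaluate`, `manet ablation`,
`manet generate-phantoms`, `manet visualize`).

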