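# ddrnet

Four-class white blood cell image classification with a compact dilated
residual attention network, implemented end to end in R.

Differential leukocyte classification — deciding whether a stained blood
smear cell is an **eosinophil**, **lymphocyte**, **monocyte** or
**neutrophil** — rests on morphological cues: multilobed nuclei
(neutrophil), kidney-shaped nuclei (monocyte), a nucleus filling most of
the cell (lymphocyte), granular cytoplasm (eosinophil). This package
implements DDRNet, a convolutional architecture built around those cues,
for researchers who want a fully inspectable, dependency-light
implementation of the method: every forward and backward pass is authored
in this package (with small C++ kernels for the convolutions), and the
whole pipeline runs on synthetic data, so nothing needs a download or a
GPU.

## The model

Input images (224×224×3 by default) pass through four stages:

1. **Stem** — 3×3 convolution (32 filters), 2×2 max pooling, group
   normalization (32 groups), ReLU.
2. **Dilated residual block (DRDB)** — six parallel residual branches
   `x + T(x)`, `T` = conv–GN–ReLU–conv–GN with 3×3 kernels; branches
   2, 4, 6 use dilations 1, 2, 4 (two stacked 3×3 kernels at dilation *d*
   span `2(3 + 2(d−1)) − 1` pixels). The six outputs are concatenated
   (6 × branch width) and reduced by a 1×1 convolution.
3. **Global/local feature enhancement (GLFEB)** — three conv–GN–ReLU
   layers (widths 64/128/64) on the residual path, concatenated with a 1×1
   projection of the stem ("global") feature and squashed by tanh, giving
   2c channels in (−1, 1).
4. **Channel and spatial attention (CSAB)** — channel gates
   `Q_c = σ(MLP(GAP(A)) + MLP(GMP(A)))` and a spatial map
   `Q_s = ReLU(W ∗ A) / Σ ReLU(W ∗ A)` from a 5×5 convolution; the block
   output is `A[h,w,c] · Q_c[c] · Q_s[h,w]`, summed with a 1×1 projection
   of the GLFEB conv path, then batch norm, dropout (0.2), global average
   pooling and a softmax head.

Training follows the recipe: Adam, constant learning rate 0.01, seeded and
bit-reproducible. Evaluation reports per-class one-vs-rest precision,
recall, F1 and Matthews correlation from the confusion matrix, plus macro
averages. Grad-CAM heatmaps and per-channel feature-map grids expose what
the network attends to. An ablation harness trains all seven block subsets
(stem … full DDRNet) on identical splits. The default DDRNet has ~0.68 M
trainable parameters (676,245), versus ~11.2 M (11,178,564) for a standard 18-layer residual
network at the same input/output sizes.

## Worked example

Generate a synthetic dataset, train a width-reduced model at 32×32, and
evaluate:

```r
library(ddrnet)

data <- generate_synthetic_cells(synthetic_cell_spec(seed = 42), n_per_class = 100)
data <- split_train_test(data, train_frac = 0.8, seed = 42)

cfg   <- model_config(input_size = c(32, 32, 3), stem_channels = 16,
                      drdb_branch_width = 16, glfeb_widths = c(16, 32, 16))
model <- ddrnet_init(cfg, seed = 42)
fit   <- train_model(model, data, train_config(epochs = 15, seed = 42), verbose = TRUE)
#> epoch   1 | iter    10 | train loss 1.1757 acc 0.5219 | val loss 1.2470 acc 0.2500
#> epoch   3 | iter    30 | train loss 0.0996 acc 1.0000 | val loss 0.0903 acc 0.9969
#> epoch  15 | iter   150 | train loss 0.0005 acc 1.0000 | val loss 0.0000 acc 1.0000

ev <- evaluate_model(fit$model, data, "test")
ev$metrics
#> Overall accuracy: 1.0000
#>       class precision recall f1 mcc accuracy
#>  eosinophil         1      1  1   1        1
#>  lymphocyte         1      1  1   1        1
#>    monocyte         1      1  1   1        1
#>  neutrophil         1      1  1   1        1
#> Macro: precision 1.0000 | recall 1.0000 | F1 1.0000 | MCC 1.0000
```

The per-epoch lines show the loss falling and training accuracy saturating
within a few epochs; the synthetic classes are morphologically separable
by construction, so a correctly implemented network should reach perfect
held-out accuracy at this scale — which is exactly what the acceptance
checks assert. Attribution for one test image:

```r
img <- resize_bilinear(data$images[[which(data$split == "test")[1]]], 32, 32)
cam <- grad_cam(fit$model, img, "eosinophil")
cam
#> Grad-CAM heatmap (32x32) for class 'eosinophil' at layer 'drdb'
```

A command-line interface wraps the same functions
(`Rscript inst/cli/ddrnet.R` for usage): `synth`, `train`, `evaluate`,
`predict`, `gradcam`, `ablate`.

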