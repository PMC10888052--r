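# nlinet

An R implementation of an N-shaped lightweight 3-D network for
multi-sequence MRI brain-tumor segmentation, together with everything needed
to exercise it end to end on one CPU: the sub-region-weighted combo loss, an
evaluation suite (IoU, Dice, 95th-percentile Hausdorff distance), NIfTI case
handling with z-score normalization and augmentation, a seed-reproducible
phantom generator, analytic parameter/MAC accounting, and a CPU training
loop with an AdamW optimizer. All tensor primitives — grouped 3-D
convolution, trilinear resampling, an exact Euclidean distance transform —
and all reverse-mode gradients are implemented in R and C++ (Rcpp); no
deep-learning framework is required.

## Who this is for

Researchers and methods developers who want a fully inspectable,
desk-scale reference implementation of this family of architectures: every
ablation variant is constructible from configuration alone, every layer's
parameters and gradients are plain R arrays, and every computation is
covered by oracle-based tests (finite differences for gradients, brute-force
all-pairs surface distances for HD95, exhaustive enumeration for parameter
counts).

## The model in brief

The network couples a U-Net-style encoder–decoder with a parallel limb of
**multiple feature-pyramid (MFP) paths**: path *i* trilinearly downsamples
the raw 4-sequence input by 1/2^i and processes it with *i* chained blocks,
feeding encoder level *i* — the "N" shape. Skip connections pass through
channel attention before concatenation. The building unit is the **DSPC
block** (Depthwise conv → spatial attention → Pointwise conv → Channel
attention, with GroupNorm/ELU and a residual add), a depthwise-separable
convolution with hybrid attention placed *inside* the block.

Training minimizes the combo loss over the nested sub-regions
K = {ET, TC, WT}:

    L = L_Dice + L_WCE
    L_Dice = 1 - (2/|K|) * sum_k  (sum_i y_ik p_ik) / (sum_i y_ik + sum_i p_ik)
    L_WCE  = -(1/N) * sum_i sum_k w_k y_ik ln(p_ik),   w_k = |WT| / |k|

so the smallest region (enhancing tumor) carries the largest weight.
Evaluation reports per-region IoU, Dice and HD95 (max of the two directed
95th-percentile surface distances, exact distance transform, linear
percentile interpolation).

## Worked example

A complete cycle on synthetic phantoms — generate, normalize, train a tiny
configuration, evaluate on held-out cases:

```r
library(nlinet)

# 14 phantom cases: 10 train, 4 held out
cases <- lapply(1:14, function(i)
  zscore_normalize(generate_phantom(phantom_params(seed = 2000 + i),
                                    case_id = sprintf("phantom_%02d", i))))

cfg <- model_config(levels = 3, stem_channels = 8,
                    encoder_channels = c(8, 16, 32), input_channels = 4,
                    seed = 1)
model <- build_model(cfg)
res <- train(model, cases[1:10], val_cases = cases[11:14],
             cfg = train_config(lr = 3e-3, epochs = 20, seed = 1))
cat(sprintf("training loss %.3f -> %.3f; best val dice %.3f (epoch %d)\n",
    res$history$loss[1], tail(res$history$loss, 1),
    res$best_val_dice, res$best_epoch))
tab <- evaluate_cases(model, cases[11:14])
print(tab[, c("case_id", "dice_ET", "dice_TC", "dice_WT",
              "dice_mean", "hd95_mean")], digits = 3)
```

Output (about a minute on one CPU core):

```
training loss 1.025 -> 0.003; best val dice 0.998 (epoch 20)
     case_id dice_ET dice_TC dice_WT dice_mean hd95_mean
1 phantom_11       1   1.000   0.988     0.996         0
2 phantom_12       1   1.000   1.000     1.000         0
3 phantom_13       1   1.000   0.999     1.000         0
4 phantom_14       1   0.987   1.000     0.996         0
5       mean       1   0.997   0.997     0.998         0
```

The loss falls by two orders of magnitude over 200 optimizer steps and the
network recovers all three nested sub-regions on held-out phantoms (Dice ≈ 1,
HD95 = 0 voxels). Phantoms are far easier than clinical data — see the
methods vignette (`vignettes/segmentation-methods.Rmd`) for what this does
and does not demonstrate.

The lightweight comparison contrasts the DSPC-based reference network with
the identical topology built from standard 3×3×3 convolutions:

```r
lightweight_comparison()
#> params: 2,664,300 vs 28,616,291  ratio 0.0931
#> MACs:   98,891,745,372 vs 900,284,299,136  ratio 0.1098 (input 192x192x128)
#> Assumptions: channel plan per configuration; 1 MAC = multiply+add;
#> ELU/GroupNorm/sigmoid/interpolation excluded from MACs;
#> convolutions before GroupNorm are bias-free.
```

## Command line

`exec/nlinet` wraps the package functions as a thin CLI:

```sh
nlinet generate --out data/ --n 12 --seed 1
nlinet split    --dir data/ --seed 1
nlinet train    --config run.yaml --data data/ --checkpoint model.rds
nlinet evaluate --checkpoint model.rds --data data/ --out metrics.csv
nlinet predict  --checkpoint model.rds --case data/phantom_001 --out preds/
nlinet count    --shape 192x192x128
```

`run.yaml` holds `model:` and `train:` sections mapping directly onto
`model_config()` / `train_config()` arguments.

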