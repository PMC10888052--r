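---
title: "An N-shaped lightweight network for brain-tumor segmentation: model, losses, metrics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An N-shaped lightweight network for brain-tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlinet)
```

## The problem and the model

Multi-sequence MRI brain-tumor segmentation assigns each voxel of a
co-registered, skull-stripped 3-D study (T1, T1ce, T2, FLAIR) to nested tumor
sub-regions: the enhancing tumor (ET), the tumor core (TC = ET plus the
necrotic/non-enhancing core NCR), and the whole tumor (WT = TC plus edema ED).
Two difficulties dominate: tumors vary enormously in size and shape, and the
classes are severely imbalanced — ET is typically a few percent of WT, and WT
a few percent of the brain.

`nlinet` implements an N-shaped lightweight network for this task. It extends
a U-Net-style encoder–decoder with a third, parallel limb of *multiple
feature-pyramid (MFP) paths*: path $i$ downsamples the raw input by $1/2^i$
with trilinear interpolation and processes it with $i$ chained convolution
blocks, feeding encoder level $i$ directly. The encoder therefore sees, at
every depth, both the downsampled stream and a freshly extracted multi-scale
view of the raw data — the "N" shape. Skip connections from the stem and the
encoder into the decoder pass through channel attention (HCA), which
re-weights feature channels before concatenation.

The building unit is the **DSPC block**: a depthwise-separable convolution
with hybrid attention interleaved *inside* it, in the fixed order

1. depthwise 3×3×3 convolution (per-channel spatial filtering), GroupNorm;
2. spatial attention (channel-pooled mean‖max maps → single-channel sigmoid
   gate), then ELU;
3. pointwise 1×1×1 convolution (channel mixing), GroupNorm, ELU;
4. residual addition of the block input (via a 1×1×1 projection when widths
   differ);
5. channel attention (global average pool → bottleneck MLP → per-channel
   sigmoid gates).

The placement matters: the spatial gate acts where spatial features are made
(after the depthwise step) and the channel gate where channels are mixed
(after the pointwise step). Setting both attention slots to `"none"` yields
the plain depthwise-separable (DSC) block; block type `"conv"` replaces the
pair with one standard 3×3×3 convolution — these are the ablation baselines,
and every published variant (attention-slot grid, skip-attention choice,
block family, MFP on/off) is constructible from `model_config()` alone.

The output head is multi-label: three independent sigmoid channels, one per
sub-region, thresholded at 0.5 with ties mapping to 1. Predicted masks are
*not* forced to nest; `enforce_nesting = TRUE` intersects them from the
outside in as an optional post-process.

## The combo loss and sub-region weighting

Training minimizes $L = L_{\text{Dice}} + L_{\text{WCE}}$ over the three
sub-region channels $K = \{ET, TC, WT\}$:

$$L_{\text{Dice}} = 1 - \frac{2}{|K|} \sum_{k \in K}
\frac{\sum_i y_i^k p_i^k}{\sum_i y_i^k + \sum_i p_i^k}, \qquad
L_{\text{WCE}} = -\frac{1}{N} \sum_i \sum_{k \in K} w_k\, y_i^k \ln p_i^k,$$

with per-sample weights $w_k = |WT| / |k|$ from the ground-truth voxel
counts. Because the sub-regions nest, these weights grade smoothly from 1
(WT) up to large values for ET, making the loss most sensitive to the
smallest, clinically critical region. Numerical choices: Dice smoothing
$\varepsilon = 10^{-5}$ in numerator and denominator (an empty region with an
empty prediction contributes a perfect term instead of 0/0); probabilities
clamped to $[10^{-7}, 1-10^{-7}]$ before the logarithm; an empty sub-region
gets $w_k = 0$. The cross-entropy carries only the positive-class term —
exactly as the weighting is defined — so on its own it is minimized by
predicting 1 everywhere; the Dice term supplies the false-positive penalty,
and the test suite asserts both facts. A `full_bce`-style both-term variant
is available as the `dice_ce` training objective.

## Evaluation

Per region, the suite reports IoU $TP/(TP+FP+FN)$, Dice $2TP/(2TP+FP+FN)$,
and the 95th-percentile Hausdorff surface distance. Surfaces are mask voxels
with a 6-neighbor outside the mask (volume borders count as surface);
directed distances are computed with an exact Euclidean distance transform
(separable parabolic-envelope algorithm, anisotropic spacing); HD95 is the
max of the two directed 95th percentiles, with percentiles linearly
interpolated between order statistics (the pooled-percentile alternative is a
flag). Conventions for degenerate cases are always flagged in the report:
both masks empty → IoU/Dice 1 and HD95 0; exactly one empty → HD95 equals
the volume-diagonal sentinel. A brute-force all-pairs surface-distance oracle
in the tests pins the fast implementation to 1e-9.

## Data pipeline and the phantom generator

Cases follow the standard layout (`<case>_<seq>.nii.gz` + `<case>_seg.nii.gz`;
label code 4 for ET is remapped to 3 internally). Preprocessing is per-volume
z-score normalization over nonzero (brain) voxels — the background stays at
exactly 0. Augmentation (training only) applies, in order: random axis flips
(p = 0.5 each), a random in-plane rotation uniform in ±15° about the
through-plane axis (trilinear for images, nearest-neighbor for labels, so the
label alphabet survives), pad-then-random-crop to the target shape
(192×192×128 at full scale), and additive Gaussian noise with σ = 0.1 in
z-scored units on images only. Datasets are split 7:1:2 with a
floor/floor/remainder rule under a fixed seed. Open choices made here:
rotation restricted to small in-plane angles (least destructive for
anisotropic targets), z-scoring per volume over brain voxels, and noise σ
set to 0.1 because no canonical value exists.

The phantom generator stands in for real multi-sequence data in every test
and demo. A brain ellipsoid sits on a zero background; each tumor is a
triplet of concentric ellipsoids with radius ratios ET : TC : WT =
0.45 : 0.7 : 1, giving a voxel-count ratio $|ET|/|WT| \approx 0.09$ — the
strong imbalance regime the weighting is designed for. Per-sequence contrast
offsets emulate the clinical appearance (edema bright on the FLAIR-like
channel, enhancing tumor bright on the T1ce-like channel), and generation
aborts unless adjacent regions are separated by at least 3 noise standard
deviations on some channel, so every phantom is segmentable in principle.
What the phantoms do **not** emulate: real anatomy and texture, bias fields,
multi-focal and infiltrative growth patterns, inter-scanner intensity
variation. Passing the synthetic end-to-end test therefore demonstrates that
the architecture, gradients, loss and pipeline work as specified — not that
the network reaches clinical accuracy on real data.

## Training

The optimizer is AdamW (decoupled weight decay). The full-scale defaults in
`train_config()` are the protocol the architecture targets: learning rate
1e-4, weight decay 1e-5, batch size 1 (which also makes the per-sample
$w_k$ exact), 200 epochs, constant learning rate, best-validation-Dice
checkpoint selection (no early stopping). Desk-scale runs — the tiny plan
(stem 8, encoder [8, 16, 32]) on 32×32×16 phantoms, 10 training cases, 20
epochs ≈ 200 optimizer steps — use learning rate 3e-3: an Adam-style update
moves each weight by roughly the learning rate per step, so 1e-4 cannot
traverse the initialization noise in 200 steps. The value was fixed with a
coarse range test ({3e-4 … 5e-3}) judged on training-loss convergence and
stability only; everything from 2e-3 to 5e-3 behaves equivalently. Two
further numerical choices help small regions: Kaiming fan-in initialization
behind a single seeded generator, and the output-head bias initialized to −2
(initial foreground probability ≈ 0.12) so the positive-only WCE term does
not flood the smallest region with false positives during the first epochs.

Weight initialization, data shuffling, augmentation and splitting all derive
from explicit seeds, so a generate → split → train → evaluate cycle is
reproducible end to end on one platform.

## Lightweight accounting

`model_complexity()` walks the architecture analytically: parameters and
multiply-accumulates (1 MAC = one multiply + one add) per layer, with
convolutions and attention MLPs/gate convolutions counted and ELU, GroupNorm,
sigmoid and interpolation excluded. Convolutions immediately followed by
GroupNorm are bias-free, which makes the counts exactly reproducible; the
test suite pins the analytic totals to exhaustive enumeration of built
models. `lightweight_comparison()` contrasts the DSPC-based reference
network with the identical topology in which every DSPC block is replaced by
a standard 3×3×3 convolution of the same in/out widths with the attention
slots removed — the most literal "original configuration".

Two caveats are printed with every report. First, the reference channel plan
(stem 32, encoder [64, 128, 256, 320, 384], mirrored decoder) is this
package's choice; published descriptions of such networks often omit exact
widths, and the ratios move with the plan. Second, at 3×3×3 a
depthwise-separable block costs roughly $1/27 + 1/C_{\text{out}}$ of its
standard counterpart, so under this plan the whole-model ratios land near
0.09 (parameters) and 0.11 (MACs at 192×192×128) — the DSPC build is, if
anything, lighter than headline factors of ~0.24/~0.52 would suggest. The
report states its ratios and assumptions rather than tuning the plan to
match any external number.

## Degenerate inputs and numerical conventions (summary)

* GroupNorm group count: requested groups clamped to the largest divisor of
  the channel count ≤ 8.
* Channel-attention bottleneck: reduction clamped to the channel count;
  hidden width at least 1; ELU inside the MLP so gradients never die.
* Trilinear resampling uses half-pixel centers (`align_corners = FALSE`
  semantics), exact for power-of-two factors; the MFP precondition (spatial
  dims divisible by $2^i$) is enforced with an error naming the axis.
* Residual adds across width changes go through 1×1×1 projections (stem and
  blocks alike) — the minimal shape-consistent reading of a residual between
  different widths.
* The decoder loop runs from the deepest level up to full resolution and the
  head consumes its final, full-resolution feature, the only
  shape-consistent reading of an encoder–decoder that reconstructs the input
  resolution.
* Thresholding ties ($p =$ threshold) map to foreground, making the
  discretization deterministic.

## Problem sizes used by the test suite

Unit tests run on 6³–16³ feature maps and 2–8 channels; gradient checks pin
hand-written backward passes to central finite differences at relative error
< 1e-4. The end-to-end demonstration trains the tiny plan on 10 phantoms for
20 epochs and evaluates on 4 held-out phantoms; it completes in about a
minute on one CPU core and reaches held-out mean Dice ≥ 0.7 (typically
> 0.95). These sizes were chosen so the full suite exercises every code path
at desk scale; full-scale 192×192×128 training is out of reach of a plain
CPU implementation and is not attempted.

## Known limitations

* CPU-only: the tensor primitives are single-threaded C++; full-scale
  training is impractical (a forward pass at 192×192×128 with the reference
  plan is ~1e11 MACs).
* Batch size is fixed at 1 (matching the training protocol); there is no
  sliding-window inference or test-time augmentation.
* The phantom generator's realism limits (above) mean synthetic results do
  not transfer to claims about clinical data.
* The printed lightweight factors of the original design are not exactly
  reproducible without its unpublished channel plan; the package reports its
  own honestly computed ratios instead.
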