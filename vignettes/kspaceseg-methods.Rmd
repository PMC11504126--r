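---
title: "Dual-path K-space/image fusion segmentation: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-path K-space/image fusion segmentation: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kspaceseg)
```

## Why K-space

Convolutional encoders lose global context as they down-sample, while each
sample of an MRI slice's K-space (its 2D Fourier transform, the domain the
scanner actually acquires) carries information about the whole image. The
networks in this package therefore run two encoders in parallel — a local,
image-domain one and a global, K-space one operating in complex arithmetic —
and fuse their feature pyramids level by level before decoding a
segmentation mask.

## Fourier conventions and half-plus-one sampling

All transforms are unshifted, per-channel, orthonormal 2D DFTs: the DC bin
sits at index (1, 1) and energy is preserved exactly
(`sum(|x|^2) == sum(|k|^2)`). The unshifted convention makes the conjugate
index map exact integers: for a real image,
`k[u, v] == Conj(k[(-u) mod H, (-v) mod W])`. A centered view
(`kspace_center()`) exists for display only.

`half_plus_one_mask(H)` keeps rows `u = 0 .. floor(H/2)` — the DC row, all
positive frequencies and (for even H) the Nyquist row — `floor(H/2) + 1`
rows in total. The remaining rows follow from conjugate symmetry
(`conjugate_complete()`), so for real-valued sources the full spectrum is
recovered to machine precision; `apply_sampling_mask()` +
`conjugate_complete()` is an exact round trip. Which rows a half-acquisition
should keep is a genuine design choice; the DC-anchored contiguous block was
chosen because it is the unique set for which conjugate completion covers
the grid exactly, without interpolation. If the source image has a genuine
imaginary component (e.g. phase errors), conjugate completion is wrong by
construction — this is inherent to any half-Fourier scheme and is surfaced
in the tests rather than hidden.

K-space is computed inside the network's forward pass from the already
z-scored (and, if enabled, augmented) image batch, so both encoder paths
always see the same geometry; augmenting K-space directly is not defined.

## Complex-valued building blocks

A complex convolution with kernel `W = A + iB` on input `x = a + ib` is
evaluated as four real convolutions,
`(A*a − B*b) + i(B*a + A*b)`, each via im2col + GEMM. CReLU rectifies the
real and imaginary parts independently, and complex normalization is
"split": the real normalization applied to each part separately (batch mode
per channel, layer mode per sample). The covariance-whitening complex
normalization from the wider complex-network literature is a documented
extension point, not implemented — the split form is what the defining
equations state. Both weight banks are initialized with the standard
fan-in (He) scheme independently; biases are complex and on by default.
The K-space encoder (KFEM) down-samples by stride-2 complex convolution
(there is no canonical complex pooling) and converts to real maps for
fusion by the elementwise magnitude, which preserves the channel schedule
and is invariant to a global phase — a property the tests verify on a
linear-only configuration.

KFEM consumes the conjugate-completed full grid rather than the half grid:
the fusion stage demands spatial alignment with the image pyramid at every
level, which a half-height grid cannot provide. The half-plus-one form is
the stored/transmitted representation; completion is cheap (index
arithmetic and conjugation).

## Encoders and the feature pyramid

All encoders emit five levels with channels {32, 64, 128, 256, 512} and
spatial size `H/2^i`; inputs must be divisible by 32. The image encoder
comes in two flavors: a U-Net style convolutional stack
(Conv3x3-BN-ReLU-maxpool per level) and a simplified hierarchical
window-attention encoder (stride-2 patch-merge projection, then a pre-norm
single-head self-attention residual within non-overlapping windows,
followed by a 1x1 output projection). The attention window prefers size 7 —
224-derived level sizes (112, 56, 28, 14, 7) are all divisible by 7 — and
falls back to the largest divisor of the level size not exceeding 7 (4 for
power-of-two sizes). A per-stage patch size of 2 (rather than a single 4x4
patch embed) is what makes the attention encoder honor the same
five-level half-resolution pyramid contract as the convolutional one.

## Fusion

The dual-path attention fusion module receives the image feature `xi` and
K-space feature `xk` of one level. Both gates share the input `X = xi + xk`
and a Conv1x1(C→C/r)-BN-ReLU-Conv1x1(C/r→C)-BN-sigmoid bottleneck with
separate weights; r = 4 by default (the reduction ratio is open in the
defining description; 4 is the customary squeeze ratio and is
configurable). The local gate weights positions individually,
`xl = xi·Wl + xk·(1 − Wl)`; the global gate acts on the spatially pooled
descriptor and is broadcast, `xg = xi·(1 − Wg) + xk·Wg`. Note the reversed
orientation — `Wl` multiplies `xi` but `Wg` multiplies `xk` — which is
implemented exactly as the defining equations print it (whether the
reversal is intentional there is unknowable; both forms are expressively
equivalent up to a sigmoid sign flip). The two convex combinations are
summed, so fusing a feature with itself yields exactly twice the feature —
an identity the tests exploit. Fusion is instantiated independently at all
five levels (the deepest feeds the decoder bottleneck, the others the
skips); a bottleneck-only placement and a parameter-free addition fusion
(ablation variant No.3) are configuration flags. The pooled gate's BN runs
over the batch of pooled vectors and is epsilon-guarded so batch size 1 is
safe.

## Decoder and losses

From the fused level-5 map the decoder repeats {bilinear 2x up-sampling →
concatenation with the matching skip → Conv3x3 → instance norm → ReLU}
with channels {256, 128, 64, 32}, then a final 2x up-sample and 1x1
convolution to class logits at input resolution. Concatenation-then-conv
realizes both the "merge" and the "reduce channels" clauses of a residual
skip decoder; bilinear was chosen for the unspecified interpolation kind.

Training minimizes `alpha·L_CE + beta·L_Dice` (defaults 1, 1; the weights
are exposed). Cross-entropy is the mean over pixels of `−sum_c y_c log p_c`
with probabilities clamped at 1e-8. The Dice loss uses the
squared-denominator soft form per foreground class with smoothing
eps = 1e-5 in numerator and denominator (so a perfect binary prediction
scores exactly zero), averaged over foreground classes; background is
excluded from the Dice term but present in CE. Evaluation Dice uses hard
argmax masks and confusion counts; the loss uses soft probabilities — two
deliberately different formulas.

HD95 is the field-standard 95th percentile (linear-interpolation
definition) of the two directed boundary-distance distributions, max of
the two directions, in mm. A printed variant with a 1/0.95 scale factor
inside the max/min appears in some descriptions of this metric; it does
not reduce to the standard percentile form and would not be comparable
with reported values elsewhere, so the standard form is implemented and
the brute-force all-pairs oracle in the tests pins it down. Conventions:
identical masks → 0; both empty → 0; exactly one empty → a configurable
penalty (image diagonal) with a warning. Dice of two empty regions is 1.

## Synthetic phantoms

`generate_phantom()` emulates what the networks need from a BraTS-style
slice and nothing more: a brain ellipse; inside it an edema ellipse
(label 2); inside that a core whose outer annulus is the enhancing rim
(label 4) and whose interior is necrosis (label 1). Containment is
guaranteed arithmetically (child semi-axes plus center offsets never exceed
the parent's), mirroring the nested evaluation regions ET ⊆ TC ⊆ WT. Each
tissue class has a fixed four-channel intensity signature qualitatively
mimicking T1/T1Gd/T2/FLAIR contrast; the `contrast` parameter scales the
signatures (region mean differences are exactly proportional to it when
noise is off) and `noise_sigma` adds white Gaussian noise. Defaults —
64x64, contrast 1, noise 0.05 — give high-contrast, mildly noisy,
smooth-boundary slices: "easy" by clinical standards, which is the point
of a desk-scale phantom. A cardiac profile (LV disc, myocardium ring,
adjacent RV; labels 3/2/1) shares the generator. What the phantoms do
*not* emulate: MR physics (no relaxation, bias fields, Rician noise,
partial volume), anatomical texture, multi-focal or irregular lesions.
Passing tests therefore demonstrate that the architecture, gradients, and
pipeline are correct and trainable — not that clinical-grade accuracy
carries over to real scans.

Augmentation applies a seeded random subset of histogram matching (exact
rank mapping against a reference phantom, generated from a derived seed
when none is given), rotation (±15°), translation (±10%), scaling
(0.9–1.1), elastic deformation (coarse Gaussian displacement grid,
bilinearly up-sampled — effectively the smoothing step — with bilinear
image warping), and horizontal mirroring. One composed geometric map is
applied to image (bilinear) and mask (nearest-neighbor), so labels stay in
vocabulary and nesting survives.

## Training mechanics and numerical choices

There is no external learning framework: convolution (im2col + BLAS GEMM),
pooling, bilinear interpolation and the in-place Adam update are compiled
code; normalizations, attention, fusion and the losses are vectorized R.
Every backward pass is analytic and checked against central finite
differences, both per layer and end-to-end through the assembled network
(probes are taken in triplicate because ReLU/magnitude kinks make single
finite differences ill-defined at isolated points). Determinism: model
construction, batch sampling, phantom generation and augmentation all
derive from explicit seeds, and checkpoints store every parameter and
running statistic, so a reloaded model reproduces predictions bit-for-bit.

Numerical guards: normalization variances are epsilon-guarded (1e-5);
magnitude gradients use `1/max(|z|, 1e-12)`; softmax subtracts the row
max; CE clamps probabilities at 1e-8; a NaN loss aborts training with a
diagnostic rather than continuing. Raw labels {0, 1, 2, 4} are remapped to
contiguous {0, 1, 2, 3} internally and restored on output.

Desk-scale defaults (64x64 slices, a handful of phantoms, a few hundred
optimizer steps, batch 4–8) are deliberately small enough to train on one
CPU core in minutes; the configuration object accepts the full-scale
settings (224x224, batch 8, 600 epochs worth of steps) unchanged for
anyone with the patience or hardware.

One empirical behavior worth knowing: with Adam at the default lr 3e-4,
each parameter moves at most ~lr per step, so 200 steps bound total
per-parameter movement by ~0.06. On the 8-phantom tiny-overfit run this is
enough to reach mean region Dice ≈ 0.98 (hard masks are correct) but the
combined loss plateaus near 0.4, because soft probabilities cannot saturate
under that movement budget; driving the training loss itself below 0.1
within 200 steps requires either more steps or a larger learning rate, not
a different implementation. The acceptance script reports the loss actually
attained under the default settings.

## Known limitations

Single-coil K-space only (no coil dimension or sensitivity maps);
Cartesian sampling only; the attention encoder is a simplified single-head
variant (no shifted windows, no MLP blocks, no pretrained weights); 2D
slices only; the phantom generator is geometric, not physical. The
parameter/FLOP profile of the full model (~7.4M parameters at 4 classes)
is reported by `count_params()` but is not tuned to match any published
budget.
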