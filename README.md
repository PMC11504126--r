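# kspaceseg

Dual-path semantic segmentation of multi-modal 2D MRI slices that exploits
the raw acquisition domain: alongside a conventional image-domain encoder, a
second encoder extracts **global** features directly from the complex-valued
K-space (2D Fourier) representation of the slice, and the two feature
pyramids are merged by a sigmoid-gated dual-path attention fusion module
before decoding to per-class masks. The package targets researchers studying
frequency-domain learning for segmentation (brain-tumor or cardiac MRI) who
want a fully inspectable, CPU-trainable reference implementation: every
layer — including the complex-valued ones — ships with an analytic backward
pass, and no external deep-learning framework is required.

## The model

For a slice `x` (4 modalities, H x W), K-space is the per-channel unitary
2D DFT, `k = F(x)`, with `x = F^-1(k)`. Because `x` is real-valued, K-space
is conjugate-symmetric, `k(-u, -v) = conj(k(u, v))`, so only the
`floor(H/2) + 1` "half-plus-one" frequency rows need to be acquired; the
rest are filled in by conjugate completion before feature extraction.

Three five-level encoders produce aligned feature pyramids with channels
{32, 64, 128, 256, 512} and spatial size `H/2^i` at level `i`:

* **CFEM** — U-Net style: Conv3x3 → BatchNorm → ReLU → 2x max-pool;
* **TFEM** — hierarchical window attention: stride-2 patch merging followed
  by pre-norm single-head self-attention in non-overlapping windows;
* **KFEM** — complex-valued: complex convolution
  `W * x = (A*a − B*b) + i(B*a + A*b)` (with `W = A + iB`, `x = a + ib`),
  split complex normalization `CLN(K) = LN(Kr) + i LN(Ki)`, and
  `CReLU(K) = ReLU(Kr) + i ReLU(Ki)`, down-sampled by stride-2 complex
  convolutions, with per-level magnitude maps feeding the fusion stage.

At every level the **DAFFM** fuses the image feature `xi` with the K-space
feature `xk`. With `X = xi + xk` and a Conv1x1–BN–ReLU–Conv1x1–BN–sigmoid
bottleneck (reduction ratio r = 4):

```
local:   Wl = sigmoid(gate(X)),          xl = xi . Wl + xk . (1 − Wl)
global:  Wg = sigmoid(gate(avgpool(X))), xg = xi . (1 − Wg) + xk . Wg
fused:   xl + xg
```

A skip-connected decoder (bilinear 2x up-sampling, concat, Conv3x3,
instance norm, ReLU) restores full resolution and a 1x1 head emits logits.
Training minimizes `L = alpha * L_CE + beta * L_Dice` (pixelwise
cross-entropy plus squared-denominator soft Dice over foreground classes)
with Adam at lr 3e-4. Evaluation reports Dice `2TP/(2TP + FP + FN)` and the
95th-percentile symmetric Hausdorff boundary distance (HD95, mm) over the
BraTS region sets WT = {1,2,4}, TC = {1,4}, ET = {4} (or the cardiac
RV/Myo/LV sets).

Five ablation variants are built from the same parts: No.1 CFEM, No.2 TFEM,
No.3 CFEM+KFEM (addition fusion), No.4 TFEM+KFEM+DAFFM, No.5
CFEM+KFEM+DAFFM (the full model).

Since no scanner data can be bundled, a seeded phantom generator produces
multi-modal slices with nested tumor-like regions (enhancing rim within
core within edema, mirroring ET within TC within WT) plus the standard
augmentation pipeline (z-scoring, histogram matching, rotation,
translation, scaling, elastic deformation, mirroring).

## Worked example

```r
library(kspaceseg)

## K-space: half-plus-one sampling and conjugate completion
slice <- zscore_normalize(generate_phantom(seed = 1, H = 64, W = 64))
k     <- image_to_kspace(slice$image)
half  <- apply_sampling_mask(k, half_plus_one_mask(64))
print(half)
#> <kspace_grid> 64 x 64, 4 channel(s), 33/64 rows acquired (unshifted)
completed <- conjugate_complete(half)
max(Mod(completed$data - k$data))
#> 7.444292e-15

## Full dual-path model: brief training on 8 phantoms, then evaluation
cfg   <- ablation_config(5, image_size = 64, seed = 7)
model <- build_model(cfg)
print(model)
#> <kseg_model> encoder=cfem kfem=TRUE fusion=daffm (per_level), 4 classes, 7420820 params
ds  <- generate_phantom_dataset(8, seed = 11)
fit <- train_model(model, ds, steps = 60, batch_size = 4)
tail(fit$history, 3)
#>  step      loss        ce      dice
#>    40 1.0845382 0.7045760 0.3799622
#>    50 0.9487876 0.6318131 0.3169745
#>    60 0.8999643 0.5993375 0.3006268
evaluate_model(model, ds)
#> <kseg_eval> 8 case(s)
#>  region      dice      hd95
#>      WT 0.8941320 17.363944
#>      TC 0.9836863  4.190160
#>      ET 0.9607035  1.314656
```

The half grid stores 33 of 64 rows yet completes to the full spectrum at
machine precision — that is the conjugate-symmetry saving that halves the
K-space encoder's input. After only 60 optimizer steps the combined loss
has fallen from ~3.5 to 0.90 and the model already localizes the tumor
core and enhancing rim well (TC Dice 0.98, ET Dice 0.96); the whole-tumor
boundary (HD95 17 mm) still needs more steps — see the tiny-overfit runs
in the tests, which train to TC/ET/WT Dice > 0.95.

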