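# ctdenoise

Low-dose CT (LDCT) slice denoising in R: an encoder-decoder convolutional
network built from improved residual dense blocks, trained with a two-phase
schedule in which a binary mask — obtained by thresholding the difference
between the reference and the current prediction — singles out poorly
restored pixels for an additional *correction loss*. The package is aimed at
researchers who want a fully inspectable, dependency-light implementation of
this training mechanism, together with a physics-based simulator that makes
the whole pipeline testable without clinical data.

## The method

Given a registered pair (low-dose slice `L1`, normal-dose slice `N1`) on a
common `[0, 1]` scale, the network `f` is trained on the composite loss

    L(I, N) = λ1 · MSE(I, N) + λ2 · (1 − MS-SSIM(I, N)) + λ3 · MSE(I ⊗ K, N ⊗ K)

with `λ = (1, 0.15, 0.8)` and the fixed zero-sum high-pass kernel
`K = [[−1,−1,−1], [0,0,0], [1,1,1]]`. After a pretraining phase on
`L(f(L1), N1)` alone, each step of the second phase computes

    I1 = f(L1);  D1 = N1 − I1;  M = 1{ |D1| > t }
    L2 = L1 ⊙ M; N2 = N1 ⊙ M;   I2 = f(L2)
    L_total = L(I1, N1) + L(I2, N2)

so the regions the network currently restores badly (|difference| above the
threshold `t`, e.g. 0.04 for a chest regime) are emphasized through a second
forward pass on the mask-filtered images. The network is a 7×7 stem, four
encoder levels (2×2 max-pool + improved residual dense block), four decoder
levels (×2 upsampling, skip concatenation, two deconvolutions with ReLU +
batch norm) and a 1×1 single-channel head.

Convolutions and reverse-mode gradients are implemented inside the package
(Rcpp + a small autodiff tape) — no external deep-learning framework is
needed, and every run is deterministic given its seeds.

The simulator generates random ellipse phantoms, forward-projects them
(parallel-beam Radon transform), draws Poisson photon counts at a
configurable dose fraction, and reconstructs with ramp-filtered
backprojection, producing paired slices whose noise and streak structure
emulate the clinical low-dose regime (about 23 dB LDCT PSNR at 10 % dose
under the defaults).

## A worked example

```r
library(ctdenoise)

# a paired 64x64 slice at 10 % dose
spec    <- phantom_spec(image_size = 64, n_ellipses = 6, seed = 42)
phantom <- generate_phantom(spec)
pair    <- simulate_pair(phantom, sim_config(dose_fraction = 0.1, seed = 42))
pair
#> <image_pair> 64 x 64, provenance: synthetic
sprintf("LDCT vs NDCT:  PSNR %.2f dB   SSIM %.3f",
        psnr(pair$ldct, pair$ndct), ssim(pair$ldct, pair$ndct))
#> LDCT vs NDCT:  PSNR 23.66 dB   SSIM 0.491

# a desk-scale model (same code path as the full-size network)
cfg   <- network_config(stem_channels = 4, growth_channels = 4,
                        dense_layers_per_block = 2, n_levels = 2,
                        decoder_channels = 8)
model <- build_model(cfg, seed = 1)
model
#> <denoising_model> 2 levels, train mode
#>   stem 7x7 (4 ch) | 2 max-pools | 2 IRDBs | 2 upsamplings | 4 deconvolutions | 1x1 head
#>   parameters: 5117

# one mechanism step: difference image -> mask -> filtered pair -> two losses
st <- mechanism_step(set_mode(model, "eval"), pair,
                     mechanism_config(threshold = 0.04),
                     params = msssim_params(n_scales = 3))
sprintf("retained pixels: %.1f%%  original %.4f  correction %.4f  total %.4f",
        100 * mean(st$mask), st$original_loss, st$correction_loss, st$total)
#> retained pixels: 60.2%  original 0.2857  correction 0.2862  total 0.5719
```

At 60 % retention this untrained model's threshold is too low to be
selective — after pretraining, `threshold_scan()` reports the retained
fraction over a threshold grid and suggests a value that keeps roughly
5–20 % of the pixels. `train()` runs the full two-phase schedule and logs
per-epoch loss terms and validation PSNR/SSIM to CSV; `evaluate()` compares
low-dose and denoised images against the reference per image and on
average.

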