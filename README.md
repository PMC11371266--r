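# safir — spatially adaptive iteratively reweighted L1 image reconstruction

`safir` reconstructs images from noisy or undersampled linear measurements
`y = Hx + n` — denoising (`H = Id`) and single-coil compressed-sensing MRI
(`H` a column-undersampled unitary Fourier transform) — by solving a
sequence of convex, spatially re-weighted L1-analysis problems

```
x_{k+1} = argmin_x  1/2 ||H x − y||²  +  λ Σ_c ⟨Λ_c(x_k), |W_c x|⟩ ,
```

where the `W_c` are learned zero-mean convolution filters and the mask
`Λ_c(x_k)` is a per-channel, per-pixel weight field generated from the
*previous* reconstruction. The masks decay on image structure (edges,
texture) and stay high in flat, noise-dominated regions, so the regularizer
becomes progressively attentive to the image as the iteration refines.

Two mask generators are implemented:

* **MMR** — `Λ_c(x) = B_cᵀ ψ′_c(B_c |W_c x|)` with simplex-constrained
  nonnegative mixing kernels `B_c` and learned concave potentials `ψ_c`
  (`ψ′_c` non-increasing in `[0, 1]`, `ψ′_c(0) = 1`). The refinement is then
  an exact majorization–minimization scheme for the energy
  `1/2 ||Hx − y||² + λ Σ_c ⟨1, ψ_c(B_c |W_c x|)⟩`, and the recorded energy
  trace is provably non-increasing.
* **SAFI** — a small three-layer convolutional network with learnable
  linear-spline activations and sigmoid outputs generates masks in `(0, 1)`;
  the refinement is a fixed-point iteration whose update operator maps into
  a ball of radius `2‖y‖/σ_min(H)` for invertible `H`.

Each convex subproblem is solved by accelerated forward–backward splitting,
with the weighted-L1 proximal map evaluated through its dual by accelerated
projected gradient. The package also contains the shape-constrained spline
nonlinearities, a reduced-scale unrolled training loop (with its own
reverse-mode tape — no external autodiff framework), λ fine-tuning by
coarse-to-fine grid search, synthetic phantom/patch/k-space generators,
PSNR/SSIM metrics, and a command-line interface
(`inst/scripts/safir-cli.R`: `denoise`, `reconstruct`, `train`,
`tune-lambda`, `fixtures`).

Who this is for: researchers in computational imaging who want an
interpretable, theoretically grounded alternative to black-box learned
reconstruction — every step of the pipeline is a convex solve with an
explicit penalty, and the masks can be inspected as images.

## Worked example

Denoise the ten-ellipse head phantom at noise level 25/255 with a
random-initialization SAFI mask generator:

```r
library(safir)
ph  <- makePhantom(c(64, 64), "shepp_logan")
y   <- addNoise(ph, 25/255, seed = 2)
H   <- makeForwardModel("identity", c(64, 64))
g   <- safiMaskGenerator(channels = 8, kernelSize = 5, init = "random", seed = 4)
out <- safiReconstruct(H, y, g, solverConfig(lam = 0.05, epsOut = 1e-4))

round(out$trace@e, 6)
#> [1] 12.373453  0.249615  0.012930  0.003345  0.001016  0.000313  0.000098
round(c(noisy = psnr(y, ph), safi = psnr(out$x, ph)), 2)
#> noisy  safi
#> 20.12 24.03
round(ssim(out$x, ph), 3)
#> [1] 0.652
```

The trace `e` is the relative outer residual `||x_{k+1} − x_k|| / ||x_k||`:
the iteration reaches a fixed point (residual below `1e-4`) in seven
refinements, and the reconstruction gains about 3.9 dB over the noisy input.

The same machinery reconstructs 4-fold undersampled single-coil MRI
measurements (complex k-space with noise level `2e-3`):

```r
ph    <- makePhantom(c(32, 32), "shepp_logan")
model <- makeForwardModel("masked_fourier", c(32, 32), list(Macc = 4), seed = 5)
ymri  <- simulateMeasurements(model, ph, sigma = 2e-3, seed = 6)
gm    <- mmrMaskGenerator(channels = 8, kernelSize = 5, init = "random", seed = 3)
rec   <- mmrReconstruct(model, ymri, gm, solverConfig(1e-3, Kfbs = 300))

round(c(zero_fill = psnr(applyOp(model, ymri, adjoint = TRUE), ph),
        mmr = psnr(rec$x, ph)), 2)
#> zero_fill       mmr
#>     15.91     18.00
```

Training a reduced-scale denoiser and fine-tuning λ:

```r
ck  <- trainDenoiser(config = trainingConfig("mmr", sigma = 25/255, seed = 1))
gen <- thetaToGenerator(ck$theta)
```

See the vignette (`vignettes/attentive-reweighting.Rmd`) for the model,
the solver details, and every design choice.

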