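# cpnp: constrained plug-and-play image restoration

`cpnp` is an R toolkit for deblurring and denoising 2-D images — beads,
filaments, cells, or any grayscale/channel-wise color data — degraded by
the linear model

```
b = A x + η
```

with `A` a Gaussian point-spread-function blur (width `σ_A` pixels) and `η`
additive white Gaussian noise of standard deviation `σ_η` (0–255 intensity
scale). It is aimed at image-analysis practitioners who want model-based
restoration with a plug-in denoiser as the prior, but without hand-tuning a
regularization weight.

## The method

Plug-and-play (PnP) schemes replace the proximal step of a splitting
algorithm with an off-the-shelf denoiser `D`, so the prior is defined
implicitly by the denoiser. The *constrained* formulation solved here,

```
min_x ρ(x)   s.t.   ||A x − b||₂ ≤ R,     R = τ √n σ_η ,
```

replaces the unphysical regularization weight of classical PnP with a
residual constraint whose radius is the expected noise norm (the
discrepancy principle): `τ = 1` when `σ_η` is known, `τ = 0.98` when it is
estimated from the data (the wavelet-MAD estimator over-estimates on
textured content). The solver is an ADMM with three blocks — an exact
FFT-domain x-update, the denoiser step `v = D(x + λ_v/β_v)`, a projection
of the residual onto the `ℓ₂` ball — plus dual ascent and a geometric
penalty schedule `β ← γβ`. Every iteration records the discrepancy
statistic `σ_x = ||A x − b||₂ / √(n−1)`, which at convergence with `τ = 1`
matches `σ_η`.

Also included: the unconstrained PnP baseline solved by half-quadratic
splitting (`pnp_hqs_restore`), the regularization-by-denoising ADMM
baseline (`red_admm_restore`), exact proximal denoisers
(Tikhonov, soft-threshold), total-variation and non-local-means denoisers,
a plugin hook for learned denoisers, PSNR/SSIM metrics, a seeded phantom
generator, and PNG/TIFF I/O.

## Worked example

```r
library(cpnp)
x  <- generate_phantom(phantom_spec("beads", c(128, 128), seed = 7))
op <- make_operator(gaussian_psf(1.2), dim(x))
b  <- degrade(x, 1.2, 30, seed = 7, op = op)          # blur + σ_η = 30 noise

res <- cpnp_restore(b, op,
                    make_constraint(tau = 1, sigma_eta = 30, n = length(b)),
                    make_denoiser("tv", 3),
                    solver_config())
res
#> <restoration_result> method = cpnp denoiser = tv
#>   iterations: 100 (iteration cap)
#>   sigma_x*:  30.0553

psnr(b, x);  psnr(res$x_star, x)
#> 17.48      25.55
ssim(b, x);  ssim(res$x_star, x)
#> 0.1715     0.9378
estimate_sigma(b)
#> 29.56
```

`sigma_x_star ≈ 30` shows the residual constraint is active and calibrated:
the restored image absorbs exactly the amount of misfit the injected noise
accounts for, while PSNR improves by ~8 dB and SSIM from 0.17 to 0.94. The
noise estimate from the degraded image alone (29.56) is why `τ = 0.98` is
the default in the estimated-noise mode.

## Command line

A thin CLI over the same functions lives at `inst/cli/cpnp.R`
(`system.file("cli", "cpnp.R", package = "cpnp")` after installation):

```sh
Rscript inst/cli/cpnp.R simulate --config cfg.yaml --outdir out/
Rscript inst/cli/cpnp.R restore  --config cfg.yaml --estimate-noise --outdir out/
Rscript inst/cli/cpnp.R sweep    --config cfg.yaml --sweep penalty --outdir out/
Rscript inst/cli/cpnp.R compare  --config cfg.yaml --outdir out/
```

Configurations are YAML files round-tripped by `read_config()` /
`write_config()`; every run writes its resolved settings next to its
outputs so it can be reproduced bit-for-bit.

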