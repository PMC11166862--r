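# effcnr

Effective contrast-to-noise ratio (CNR) analysis for CT image quality.

## The problem

The conventional CNR of a CT image,

```
CNR = (P_signal − P_background) / NoiseSD ,
```

summarizes low-contrast detectability from two ROI means and the background
pixel SD. It breaks down for images produced by nonlinear reconstructions —
iterative reconstruction (IR) and deep-learning reconstruction (DLR) — which
suppress the pixel SD while introducing spatial noise correlation ("blocky"
texture) and edge blur. Two images with identical CNR can look, and detect,
very differently. `effcnr` implements a CNR variant that folds both effects
back in:

* **Apparent noise** `σ_Apparent`. An `r × r` moving-average filter is slid
  across a homogeneous ROI (stride 1) for `r = 1 … 20` and the SD of the
  window means, `σ_SD(r)`, is recorded. For spatially uncorrelated noise the
  central limit theorem gives `σ_SD(r) = σ_Apparent / r`; the index is the
  slope-fixed log–log fit of this 1/r law over `r = 5 … 10`. Correlated
  noise decays more slowly than 1/r at these filter sizes, so texture
  inflates `σ_Apparent` above the pixel SD — exactly the information the
  conventional noise SD discards.

* **Sharpness index.** The angle-averaged radial edge profile of a circular
  insert (360 rays, 50 mean CT numbers) is fitted with the closed-form
  solution of a stochastic differential equation for CT numbers,

  ```
  f(t) = B + C0 · Φ(g(t)),   g(t) = [λ + (γ + σ²/2)(T − t)] / (σ √(T − t)),
  ```

  with `Φ` the standard normal CDF, `T = 50`, `λ = ln 10⁻¹³` fixed, and
  `(C0, σ, γ, B)` estimated by bounded Levenberg–Marquardt least squares.
  The differential (slit-like) profile subtracts model values one pixel
  apart; its maximum over a fine grid (step `Δt = 0.10`) is the sharpness
  index `C1/C0 ∈ (0, 1]` — 1 for an unblurred edge, smaller with blur.

* **Effective CNR.** `|C0 × SharpnessIndex| / σ_Apparent`: blur-attenuated
  contrast over texture-aware noise.

A synthetic phantom generator (uniform water-equivalent background,
circular insert with sub-pixel anti-aliasing, Gaussian noise with optional
correlation texturing and edge blur) provides ground truth for every stage,
including `phantom_preset()` triples that emulate FBP-, IR- and DLR-like
reconstructions.

## Worked example

```r
library(effcnr)

spec       <- phantom_preset("dlr_like", seed = 3)        # SD 6.8 HU, corr 0.7 px, blur 0.4 px
noise_img  <- ct_image(noise_field(c(64, 64), spec$noise_sd_hu,
                                   spec$noise_corr_sigma, seed = 3))
signal_img <- disk_phantom(spec)                          # 60 HU insert, r = 20.5 px

effective_cnr_analysis(noise_img, signal_img, signal_center = spec$insert_center)
#> Effective CNR report
#>   noise:    SD 6.79 HU, sigma_apparent 15.06 HU  [in-memory]
#>   signal:   P_signal 62.52 HU, P_background 0.00 HU  [disk_phantom(seed=3)]
#>   contrast: C0 61.81 HU, sharpness index 0.590, effective contrast 36.45 HU
#>   conventional CNR: 9.203
#>   effective CNR:    2.420
```

Reading the report: the DLR-like noise texture roughly doubles the
effective noise (`σ_Apparent` 15.06 HU vs pixel SD 6.79 HU); the fitted
contrast (61.8 HU) is attenuated by the sharpness index 0.59 — the edge
spreads the differential profile's unit mass over ~2 px — so the effective
CNR (2.42) is far below the conventional 9.20. Comparing presets shows why
that matters: conventional CNR ranks the heavily smoothed IR-like
reconstruction above the DLR-like one, while effective CNR reverses the
order, matching how observers rate such images.

A command-line wrapper ships in `inst/cli/effcnr.R`
(`simulate | noise | edge | cnr | demo`); `demo --seed 7` runs the
three-preset ranking comparison.

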