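---
title: "Effective CNR: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective CNR: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effcnr)
```

This vignette documents the models behind `effcnr`, the parameters that
matter, the numerical choices, and — importantly — what the synthetic
phantom experiments do and do not demonstrate about real scanner images.

## Why conventional CNR is not enough

Conventional CNR divides an ROI contrast by the background pixel SD. Two
properties of modern nonlinear reconstructions (iterative and
deep-learning) defeat it:

1. **Noise texture.** IR/DLR pipelines suppress the pixel SD but leave
   low-frequency, spatially correlated noise ("blocky" grain). The pixel SD
   measures amplitude only; two images with equal SD but different
   correlation lengths have very different perceived noise.
2. **Edge blur.** The same pipelines trade sharpness for noise. Contrast
   measured as an ROI mean difference is blind to how crisply the lesion
   boundary is rendered.

`effcnr` replaces both ingredients: noise by the *apparent-noise index*,
contrast by the *effective contrast* (contrast × sharpness index).

## Apparent noise

For an `r × r` moving-average filter slid at stride 1 across a homogeneous
square ROI (fully contained windows only — `(side − r + 1)²` windows for a
`side × side` ROI), let `σ_SD(r)` be the sample SD of the window means.
When pixels are independent, `Var(mean) = σ²/r²`, so

`σ_SD(r) = σ_Apparent / r`

with `σ_Apparent` equal to the pixel SD. The index is estimated by the
least-squares fit of `log σ_SD = log σ_Apparent − log r` with the slope
*fixed at −1* (the law has one parameter); the unconstrained slope is
reported as a linearity diagnostic, and `single_point_apparent_noise()`
provides the shortcut `r·σ_SD(r)` for a single filter size inside the
linear range. Correlated noise violates the 1/r decay at filter sizes
comparable to the correlation length: window means shrink more slowly, so
`r·σ_SD(r)` — and hence the fitted `σ_Apparent` — exceeds the pixel SD.
That inflation is the texture signal.

Defaults and their rationale:

* **ROI 40 × 40 px at the image center** — the conventional noise-QA ROI;
  both configurable.
* **Curve over `r = 1 … 20`, fit over `r = 5 … 10`** — below `r ≈ 5`
  short-range reconstruction correlations bend the curve even for
  well-behaved images; above `r ≈ 10` a 40-px ROI yields too few
  independent windows.
* **Sample SD (n − 1)** and **stride-1 overlapping windows** — the usual QA
  conventions; the estimator is slightly conservative (overlapping windows
  share pixels), which is visible as a ~2–3 % downward bias of
  `σ_Apparent` on white noise, well inside the method's noise floor.

## The SDE edge model and the sharpness index

The angle-averaged radial edge profile of a circular insert is modeled by
the closed-form solution of a stochastic differential equation for CT
numbers:

$$f(t) = B + C_0\,\Phi(g(t)), \qquad
g(t) = \frac{\lambda + (\gamma + \sigma^2/2)\,(T - t)}{\sigma\sqrt{T - t}},$$

where `t` is the radial distance along the profile (re-anchored so the
first profile point is `t = 0`), `T = 50` px is the profile length,
`λ = ln 10⁻¹³ ≈ −29.93` is a fixed constant, `σ > 0` is the diffusion
coefficient, `γ` shapes the edge position, `C0` is the contrast and `B` a
baseline. With `λ < 0`, `g` falls from large positive values to `−∞` as
`t → T`, so `f` decays from the signal plateau `B + C0` to the background
`B`. The half-maximum sits where the numerator of `g` vanishes, at
`T − t = −λ/(γ + σ²/2)` — the initializer inverts exactly this relation.

The baseline `B` is a deliberate addition to the three-parameter form:
measured profiles ride on the background CT number, and absorbing it in a
fitted parameter is more robust than pre-subtracting a tail mean (the
alternative remains available by passing a profile with the tail mean
removed). `γ` is fitted, not fixed: it is the only parameter that can move
the edge position, which varies with insert radius.

**Differential profile convention.** The measured slit-like profile
subtracts mean CT numbers *one pixel apart*. Its model counterpart is
therefore the per-pixel difference `D(t) = Φ(g(t)) − Φ(g(t+1))`, evaluated
on a fine grid of step `Δt = 0.10` over `[0, T − 1)`, and

`SharpnessIndex = max D(t) ∈ (0, 1]`.

Only this convention calibrates correctly: when the entire unit step of
`Φ∘g` falls between two adjacent samples, the maximum difference is exactly
1 and `C1 = C0`. The continuous derivative `dΦ(g(t))/dt = φ(g(t))·g′(t)`
with `g′(t) = −(a u − λ)/(2σu^{3/2})`, `u = T − t`, `a = γ + σ²/2`, is
exposed alongside (`model_differential()$ddt_analytic`) as a diagnostic
and is verified against numerical differentiation in the test suite. The
index is independent of `C0`, which cancels in `C1/C0`.

**Fitting.** `fit_edge_model()` minimizes squared HU residuals over
`(C0, σ, γ, B)` with bounded Levenberg–Marquardt (`minpack.lm::nls.lm`),
box constraints `σ ∈ [10⁻³, 50]`, `|C0| ≤ 5000` HU, `B` within the
observed HU range widened by one range width, `γ ∈ [−10⁶, 10⁶]`.
Initialization: `B₀` = mean of the outer 20 % of the profile, `C0₀` =
inner-20 % mean − `B₀`, edge position at the first half-maximum crossing,
`γ₀ = −λ/(T − t_half) − σ₀²/2` with `σ₀ = 1`. Non-convergence triggers
three *deterministic* perturbed restarts (scaling the initial contrast and
diffusion, flipping the shape term) — determinism keeps refits
reproducible without touching the RNG — and is flagged, not raised. A fit
that stops at the iteration cap with an essentially zero residual
(RMSE ≤ 10⁻⁸·|C0|) is accepted as converged: step-like noiseless profiles
drive `σ` toward its lower bound and the optimizer keeps polishing an
already perfect fit. Profiles whose initial contrast estimate falls below
1 HU (configurable) raise a "flat profile" error instead of returning
nonsense.

## Effective CNR

`EffectiveCNR = |C0 × SharpnessIndex| / σ_Apparent`. The absolute value
makes the index non-negative, as befits a detectability measure; the
signed contrast is preserved in the report. The noise and signal images
may differ (noise is best measured in a uniform region, contrast on a
magnified insert image); `effective_cnr_analysis()` records both
provenances. For conventional CNR the report uses a small (10 × 10 px)
ROI at the signal center for `P_signal` and the noise ROI's mean and SD
for `P_background` and `NoiseSD`.

## The synthetic phantom: what it emulates, and what it does not

`disk_phantom()` renders `background + contrast · (blurred disk) + noise`:

* **Anti-aliased disk.** Pixel coverage is a linear ramp one pixel wide
  (`clamp(radius − dist + 0.5, 0, 1)`), so `edge_blur_sigma = 0` yields a
  well-defined 1-px edge rather than an aliased staircase. The default
  radius 20.5 px is half-integer so that the edge falls between two
  integer sample radii.
* **Gaussian edge blur** convolves that indicator (FFT, periodic
  boundary; specs require the insert at least `3σ` from the border).
  For blur ≪ radius, the radial profile is the error-function ramp of a
  blurred step — the suite checks it against the closed form
  `coverage(d) = pchisq((R/s)², df = 2, ncp = (d/s)²)`, the noncentral
  chi-square expression for a bivariate Gaussian landing inside a disk.
* **Noise texturing.** White Gaussian noise, optionally smoothed with a
  Gaussian kernel of scale `noise_corr_sigma` and rescaled to the exact
  target marginal SD: correlation changes, amplitude does not. Texture is
  stationary — imposed on the whole field, not only the background.

The `phantom_preset()` triples emulate three reconstruction families at a
fixed 60 HU (iodine-like) insert: `fbp_like` (white noise SD 30 HU, edge
blur 1.2 px — smooth-kernel FBP is noisy and not particularly sharp),
`ir_like` (SD 4.8 HU, correlation 1.3 px, blur 1.0 px) and `dlr_like`
(SD 6.8 HU, correlation 0.7 px, blur 0.4 px). The noise SDs and the
correlation scales were chosen so the presets land at apparent-noise
inflation factors of ≈1.0, ≈3.7 and ≈2.3 — the regimes typical of the
three families — and the blur ordering mirrors their characteristic edge
rendition (DLR sharpest, smooth-kernel FBP softest). These are *qualitative
stand-ins*: real IR/DLR noise is non-Gaussian, nonstationary and
anisotropic, and no projection/reconstruction physics is simulated. What
the preset experiment demonstrates is the method's discriminating
behavior — conventional CNR ranks IR-like above DLR-like, effective CNR
reverses the pair, FBP-like is lowest under both — not any vendor's
absolute numbers.

```{r presets}
analyze_preset <- function(name, seed) {
  spec <- phantom_preset(name, seed = seed)
  noise_img <- ct_image(noise_field(c(64, 64), spec$noise_sd_hu,
                                    spec$noise_corr_sigma, seed = seed))
  effective_cnr_analysis(noise_img, disk_phantom(spec),
                         signal_center = spec$insert_center)
}
do.call(rbind, lapply(c("fbp_like", "ir_like", "dlr_like"), function(nm) {
  cbind(preset = nm, as.data.frame(analyze_preset(nm, seed = 7)))
}))[, c("preset", "noise_sd", "sigma_apparent", "sharpness_index",
        "conventional_cnr", "effective_cnr")]
```

## Numerical choices and degenerate inputs

* **Coordinates** are 1-based `(row, col)` with pixel centers at integer
  coordinates, as in R matrix indexing; all sub-pixel positions
  (insert centers, ray samples) live in that frame.
* **Profile extraction** uses bilinear interpolation at 360 rays × 50
  integer radii by default; nearest-neighbor is available for strict
  pixel-value replication. Rays start at radius 1 from the supplied (or
  centroid-estimated) center, so the profile has exactly `T = 50` points
  and skips the degenerate center sample. Rays that would exit the image
  raise an error naming the maximum usable radius.
* **Extraction resolution bound.** Anti-aliased rendering (a 1-px
  coverage ramp) plus bilinear sampling at integer radii act together as
  ≈0.5 px of Gaussian-equivalent blur. An unblurred *rendered* disk
  therefore fits to a sharpness index of ≈0.65–0.70, not 1 — the ideal
  calibration (index → 1) is exact only for an ideal step *profile*, and
  the test suite checks both facts separately. By the same mechanism the
  white-noise/no-blur effective CNR sits ≈30 % below conventional CNR
  rather than converging to it exactly. Interpreting absolute sharpness
  indices therefore requires a fixed extraction protocol; comparisons
  across reconstructions with the same protocol (the method's use case)
  are unaffected.
* **Degenerate inputs**: constant ROIs raise "flat" errors from both the
  apparent-noise fit (log of zero) and the edge fit (contrast floor);
  `t ≥ T` is rejected everywhere `g` is evaluated; filter sizes larger
  than the ROI, out-of-bounds ROIs and rays, non-rectangular CSV grids
  and unknown run-config keys all raise informative errors.
* **Problem sizes.** All simulation-based checks use 40 × 40 noise ROIs,
  128 × 128 or 160 × 160 phantoms and 5–20 seeds per quantity; at these
  sizes the full test suite and the acceptance script each run in
  seconds, and every reported mean is stable to well inside its stated
  tolerance.

## Known limitations

* No noise-power-spectrum or observer-model (d′, NPWE) computation; the
  apparent-noise index is a deliberately simple texture summary.
* Circular inserts only; the centroid estimator assumes a bright,
  reasonably clean signal (pass the known center for noisy images).
* Single-slice 2-D analysis; pixel units throughout (spacing is carried
  as metadata only).
* File I/O covers CSV grids and 16-bit TIFF/PNG with JSON sidecars;
  DICOM is not read directly — convert to one of those first.
* The SDE closed form is implemented as stated; its derivation from the
  underlying stochastic differential equation is outside the package's
  scope.
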