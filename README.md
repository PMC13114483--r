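# sfdibruise

Simulation-driven spatial frequency domain imaging (SFDI) for detecting and
grading subsurface bruises in fruit.

Subsurface bruises leave the peel intact while damaging the flesh beneath
it, so they are nearly invisible to ordinary inspection. SFDI separates the
two optical transport coefficients of turbid tissue — the absorption
coefficient μa and the reduced scattering coefficient μs′ (both mm⁻¹) — by
projecting sinusoidal illumination at several spatial frequencies and
phases and demodulating the reflected images. Bruising collapses cell
structure and depresses μs′ while barely moving μa, which makes μs′ maps a
sensitive bruise indicator.

`sfdibruise` implements the full pipeline for researchers working on
optical fruit inspection:

- **Forward model** — diffusion-approximation diffuse reflectance
  Rd(μa, μs′, fx) = 3A(μs′/μtr) / ((μeff′/μtr + 1)(μeff′/μtr + 3A)),
  with μtr = μa + μs′, μeff′ = (3 μa μtr + K²)^½, K = 2π fx, and
  A = (1 − Reff)/(2(1 + Reff)) from the boundary reflection polynomial
  Reff(n).
- **Synthetic scenes** — an analytic structured-illumination renderer that
  turns per-pixel (μa, μs′) maps of apple-, pear- and phantom-like samples
  (circular bruises, lenticel speckle, planar or spherical-cap surfaces)
  into phase-shifted image stacks, and batch-generates paired
  reflectance/label datasets with ground truth exact by construction.
- **Demodulation and calibration** — three-phase AC demodulation
  M_AC = (2/3)·[(I1−I2)² + (I2−I3)² + (I3−I1)²]^½ and conversion to
  quantitative Rd against a 0.99-reflectivity reference.
- **Inversion** — per-pixel bounded nonlinear least squares for
  (μa, μs′) from the two-frequency Rd pair, with a lookup-table mode that
  is orders of magnitude faster at <1% deviation.
- **Profile correction** — four-step phase-shifting profilometry, phase
  unwrapping, height recovery and the curved-surface correction
  R_correct = R_uncorrect / c with c = h/h_max.
- **Neural translator** — a conditional adversarial U-Net with channel and
  spatial attention that maps Rd images directly to coefficient labels
  (adversarial + λ·L1 objective, λ = 60), trained with Adam; implemented
  natively in R with analytically verified backpropagation.
- **Discrimination** — the two-step rule: coefficient of variation (CV) of
  the global μs′ map separates bruised from sound fruit; the
  bruised-to-sound mean ratio M with a ROC/Youden-selected threshold
  grades mild vs severe bruises.

## Worked example

Render a bruised apple scene, recover its optical properties, and score it:

```r
library(sfdibruise)

spec  <- fruit_scene_spec("apple", size = 64, severity = 1, seed = 42)
scene <- make_fruit_map(spec)
stack <- render_stack(scene$map, fx_ac = 0.2, noise_sd = 0)
ref   <- render_reference_stack(0.2, c(64, 64), pixel_size_mm = 100 / 64)
cal   <- demodulate_stack(stack, ref)
est   <- invert_map(cal$rd_dc, cal$rd_ac, pixel_size_mm = 100 / 64)

coefficient_of_variation(est$mu_s_prime)
#> [1] 0.07678274
mean_ratio(est$mu_s_prime, scene$bruise_mask, scene$sound_mask)
#> [1] 0.7039397
```

The CV of ~0.077 is far above that of a sound apple (~0.04 under the same
render noise), so step 1 calls the sample bruised; the mean ratio ~0.704
equals the bruised/sound scattering ratio 1.215/1.726 of severely bruised
apple tissue, which a Youden-selected threshold grades as severe. A whole
cohort runs through `simulate_cohort()` + `two_step_pipeline()`:

```r
cohort <- simulate_cohort(20, 20, "apple", severity = 1, size = 64, seed = 42)
res <- two_step_pipeline(cohort)
res$step1_accuracy
#> [1] 1
```

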