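---
title: "Models and methods behind sfdibruise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sfdibruise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sfdibruise` builds a complete, self-contained simulation-and-analysis
pipeline for spatial frequency domain imaging (SFDI) of fruit tissue. This
vignette explains the models it implements, the parameters that matter,
what the synthetic data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The forward model

Diffuse reflectance of a homogeneous turbid medium under sinusoidal
illumination at spatial frequency $f_x$ (mm$^{-1}$) follows the diffusion
approximation:

$$R_d(f_x) = \frac{3A\,\mu_s'/\mu_{tr}}
  {(\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)},$$

with transport coefficient $\mu_{tr} = \mu_a + \mu_s'$, effective
attenuation $\mu_{eff}' = (3\mu_a\mu_{tr} + K^2)^{1/2}$, $K = 2\pi f_x$,
and the boundary constant $A = (1-R_{eff})/(2(1+R_{eff}))$ where
$R_{eff} = 0.0636\,n + 0.668 + 0.71/n - 1.44/n^2$. The refractive index
defaults to $n = 1.43$, typical of fruit flesh.

Two dialects of $\mu_{eff}'$ are supported. Some presentations of the
model write the frequency term as $K$ rather than $K^2$ inside the root,
which is dimensionally inconsistent with the standard diffusion form; the
package defaults to the squared dialect (`mueff_dialect = "squared"`) and
exposes `"printed"` for comparison. The two agree identically at DC, which
a test asserts bit-for-bit.

The model is only trusted in the scattering-dominated regime. A property
test asserts strict monotonicity (decreasing in $\mu_a$, increasing in
$\mu_s'$ at DC) for $\mu_s' \ge 0.8$ mm$^{-1}$: below that, at
$f_x = 0.2$ mm$^{-1}$, $R_d$ genuinely increases with $\mu_a$ — a
property of the formula itself, not a bug — and boundedness
$R_d \in (0, 1]$ is asserted over the full phantom design range
($\mu_a \in [0, 0.5]$, $\mu_s' \in (0, 4]$ mm$^{-1}$).

## Synthetic scenes and the paired dataset

The generator replaces a physically rendered (ray-traced) simulation with
analytic rendering through the forward model, which makes the ground
truth exact by construction. A scene is a per-pixel $(\mu_a, \mu_s')$ map
on a 100 mm field of view (default 256×256 px, i.e. 0.39 mm/px; tests and
the desk-scale studies use 64×64). Sound-tissue coefficients are anchored
to SFDI measurements of real fruit: apples (0.0324, 1.726) mm$^{-1}$,
pears (0.0418, 2.102) mm$^{-1}$, with fully bruised $\mu_s'$ of 1.215
(apple) and 1.702 (pear). A circular bruise of radius 15 mm (a typical
single equatorial impact) interpolates $\mu_s'$ linearly with `severity`:
0.5 emulates a mild impact, 1.0 a severe one. Pear maps receive seeded
multiplicative lognormal speckle (sd 0.03) emulating lenticels; the value
is a qualitative choice, as only the existence of lenticel texture is
documented, not its statistics.

Rendering projects $I_i = g\,[a_0 R_d(0) + a_1\cos(2\pi f_x x + \psi_i)
R_d(f_x)]$ with phases $\psi = 0, 2\pi/3, 4\pi/3$, plus a dedicated DC
frame, with illumination $a_0 = a_1 = 0.5$, gain 1, and Gaussian read
noise of sd 0.5% of full scale by default (no noise model is prescribed
anywhere; 0.5% FS is a realistic 16-bit-camera figure). The calibration
reference is the same renderer with $R_d \equiv 0.99$.

`build_dataset()` sweeps 20 absorption × 40 scattering levels — exactly
800 paired samples, split 7:3 (560/240) by a seeded shuffle — writing the
calibrated AC reflectance (float TIFF), the 8-bit RGB label (R = $\mu_a$
scaled on [0, 0.5], G = $\mu_s'$ on [0, 4], B = 0) and a JSON manifest.
Quantization bounds the label round-trip error by half a step
($\mu_a$: 0.5/510, $\mu_s'$: 4/510 mm$^{-1}$).

What the generator does *not* emulate: real peel texture and gloss,
wavelength dependence, camera optics and vignetting, sub-surface depth
structure of bruises, and the domain gap between simulated and measured
reflectance. Passing tests therefore demonstrate internal consistency of
the pipeline and correctness of the algorithms, not field performance on
real fruit.

## Demodulation, calibration, inversion

Demodulation uses the three-phase formula with the 2/3 prefactor
$M_{AC} = \tfrac{2}{3}[(I_1-I_2)^2 + (I_2-I_3)^2 + (I_3-I_1)^2]^{1/2}$.
The conventional prefactor is $\sqrt{2}/3$; the difference is a global
factor that cancels exactly in calibration
$R_d = (M_{sample}/M_{reference}) \cdot 0.99$, which a test asserts to
machine precision. The DC channel is the dedicated $f_x = 0$ frame
itself, calibrated with the same reference treatment so constants cancel.

Inversion minimizes $[R_d(\theta,0)-\hat R_{d,0}]^2 +
[R_d(\theta,f_x)-\hat R_{d,f_x}]^2$ over $\theta = (\mu_a, \mu_s')$ with
bounded Levenberg–Marquardt: start (0.05, 1.5), bounds
$[10^{-5}, 0.5] \times [0.01, 4]$ mm$^{-1}$ (the phantom design ranges),
residual tolerance $10^{-10}$, 200 iterations. The `"lut"` mode tabulates
the forward model on a 40×60 grid, finds the nearest node per pixel via a
BLAS cross-product distance, and applies three vectorized Gauss–Newton
refinements; it agrees with the full fit to well under 1% and is the
default for maps. Noiseless round trips recover coefficients to better
than $10^{-3}$ absolute; under the default render noise the $\mu_s'$ NMAE
on a 64×64 scene is about 0.03.

## Profilometry and profile correction

Curved fruit surfaces imprint a center-bright/edge-dark distortion on the
reflectance. The package models the surface as a spherical cap and injects
the distortion as pixelwise multiplication by $c = h/h_{max}$ (clamped at
$c_{min} = 0.05$), so the correction $R_{correct} = R_{uncorrect}/c$ is
its exact inverse — a deliberate closure property used by the tests. The
$c$ field is normalized by the realized pixel maximum of $h$ so the most
elevated pixel is exactly undistorted. Dividing by $h/h_{max}$ is a
heuristic correction, not a Lambertian cosine model; it is implemented as
stated. Correction operates on demodulated reflectance maps, not raw
intensities.

Height comes from four-step phase-shifting profilometry: fringe images at
phases $0, \pi/2, \pi, 3\pi/2$ give the wrapped phase
$\varphi_w = \mathrm{atan2}(F_4-F_2,\, F_1-F_3)$; row-wise 2π-jump removal
with a first-column seam reconciliation unwraps it (the output differs
from the input by exact multiples of 2π, asserted); the height is the
linear map $h = k_{height}\,\Delta\varphi$ against a flat-plane reference
rendered through the same pipeline. On noiseless caps the recovered
height is within 2% of the cap height and correction strictly reduces
the reflectance CV.

## The adversarial translator

The neural predictor maps a calibrated reflectance image to the RGB
coefficient label. It is a U-Net with residual blocks and skip
connections; a channel-then-spatial attention block follows each
down-sampling stage and precedes each up-sampling stage (2 × depth blocks
total). Channel attention gates channels by
$\sigma(\mathrm{MLP}(\mathrm{avgpool}) + \mathrm{MLP}(\mathrm{maxpool}))$
with a shared bottleneck MLP (reduction ratio 16, clipped to the channel
count); spatial attention gates pixels by a 7×7 convolution over the
channelwise mean and max maps. The discriminator is conditional — it
scores the channel concatenation of the input and a candidate label — and
consists of exactly three convolutional layers with average-pooling
between them, producing a patch grid of scores.

The objective is $L_{GAN} + \lambda L_1$ with $\lambda = 60$:
$L_{GAN} = E[\log D(x,y)] + E[\log(1-D(x,G(x)))]$ (natural log, means
over batch and patches, outputs clamped at $10^{-7}$), and $L_1$ the mean
absolute deviation. The generator update uses the standard
non-saturating surrogate $-\log D(x, G(x))$. Training is alternating
Adam with lr $2\times10^{-4}$, $\beta = (0.5, 0.999)$. Inputs are
normalized to $[-1, 1]$; labels live in $[0, 1]$ behind a sigmoid head
and are rescaled to physical units at decoding.

Everything — convolutions (im2col + BLAS), attention, pooling, losses,
Adam — is implemented in R with hand-derived backward passes, each
verified against numeric finite-difference gradients in the test suite to
about $10^{-10}$.

Desk-scale study conditions: 64×64 images, generator depth 4 with base
width 8 (capped at 64), 40 paired scenes (28 train / 12 validation),
20 epochs, batch size 1. Batch size 1 — the original image-to-image
translation convention — is used at this scale because 28 training images
give too few optimizer steps per epoch at larger batches; the package
default remains 4. Under these conditions training takes a few minutes on
one CPU core and the trained generator reduces the validation
$\mu_s'$ NMAE to well under half of its value at random initialization,
which is the property the acceptance test asserts. At full scale (256×256,
800 pairs, depth 6) the same code applies unchanged but is not exercised
by the tests.

## Discrimination

Step 1: the coefficient of variation $CV = \sigma(\mu_s')/\bar\mu_s'$ of
the *global* map (population standard deviation; the sample convention is
a documented switch) separates bruised from sound fruit — a sample is
called bruised when CV strictly exceeds the threshold, with boundary
equality called sound. Step 2, applied only to samples called bruised:
the mean ratio $M = \bar\mu'_{s,D}/\bar\mu'_{s,N}$ between the bruise
disc and an equal-area annulus of adjacent sound tissue of the *same*
sample grades severity — $M$ strictly below the threshold is severe.

Thresholds are selected by maximizing the Youden index
(sensitivity + specificity − 1) over a ROC sweep of the observed scores;
fixed thresholds are also accepted. The sweep places thresholds between
consecutive unique scores plus sentinels, integrates the AUC by
trapezoid, and is exactly equal to Mann–Whitney pair counting with ties
at 1/2 (asserted on random fixtures). Youden ties break toward higher
sensitivity, then the lower threshold.

## Metrics

NMAE $= \sum|p_i - p_{i,ref}| / \sum p_{i,ref}$; PSNR
$= 10\log_{10}(255^2/\mathrm{MSE})$ on maps rescaled to the 0–255 label
convention; SSIM with $C_1 = (0.01\cdot255)^2$, $C_2 = (0.03\cdot255)^2$
computed from global image statistics by default (the formula is stated
with global moments; an 11×11 Gaussian-windowed mean SSIM is available).
Model comparisons use the two-tailed paired Student's t-test on matched
per-image errors with significance bands at 0.05/0.01/0.001;
zero-variance differences are flagged degenerate rather than scored.

## Known limitations

- The analytic renderer's closure properties (exact distortion inversion,
  exact ground truth) are design choices that make correctness testable;
  they do not hold for physical imagery.
- The diffusion approximation breaks down for weakly scattering media
  ($\mu_s' \lesssim 0.8$ mm$^{-1}$ at $f_x = 0.2$ mm$^{-1}$), where the
  forward model is non-monotone in $\mu_a$; inversions there are
  formally defined but physically unreliable.
- Exactly two spatial frequencies (0 and 0.2 mm$^{-1}$) are supported;
  multi-frequency schemes, Monte Carlo transport, depth-resolved
  inversion and multi-wavelength modeling are out of scope.
- The severity grades are binary (mild/severe); no bruise segmentation is
  produced beyond the nominal impact-site masks.
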