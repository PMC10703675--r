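---
title: "Fluorescence actinometry: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluorescence actinometry: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinometry)
```

## The measurement principle

A fluorescent actinometer is a molecular system whose photoconversion under
constant illumination is first order in the light intensity. When a jump of
constant light of intensity $I$ (photon flux density, E m$^{-2}$ s$^{-1}$,
where one einstein is a mole of photons) is applied, the fluorescence signal
relaxes monoexponentially,

$$F(t) = F_\infty + (F_0 - F_\infty)\, e^{-t/\tau}, \qquad
  \tau = \frac{1}{\sigma I},$$

where $\sigma$ (m$^2$ mol$^{-1}$) is the photoconversion cross section at the
excitation wavelength. Fitting $\tau$ and inverting $I = 1/(\sigma\tau)$
yields the *absolute* light intensity, per pixel if the kinetics are imaged.
Two features make the approach robust: the fluorescence quantum yield never
enters $\tau$ (so detection efficiency, concentration and emission-side
drifts cancel), and the photon-based unit is wavelength independent.

The package ships a registry of five actinometers covering the UV to red
range (`load_actinometer()`): two irreversible UV-A chemical actinometers
(one intrinsically fluorogenic, one dark-to-dark and reported through the
inner filter effect on an inert co-dissolved fluorophore), a reversibly
photoswitchable fluorescent protein for the blue range, a donor-acceptor
Stenhouse dye for the green-red range, and the photosynthetic apparatus of
microalgae, whose fluorescence-induction fast phase has a rate constant
$k_1 = \sigma_{PA} I$. Each entry carries $\sigma(\lambda_{exc})$, the
reliably measurable intensity range, and the minimum measurement duration
$5\tau_{min}$ at the top of that range. Photon-flux bounds are stored as the
authoritative values; energy-unit (W m$^{-2}$) bounds are always recomputed
through $N_A h c/\lambda$ (`photon_to_energy()`), never stored, because the
tabulated photon bounds reproduce the energy bounds at their printed
precision with a single documented exception (the protein's 500 nm upper
bound, whose printed energy value is inconsistent with the photon value by a
factor ~3 and is excluded from consistency checks; the photosynthetic rows'
energy bounds also appear rounded beyond two significant figures and are
excluded from exact checks).

## Kinetic fitting

`fit_monoexp()` fits the three-parameter model by variable projection: for a
trial $\tau$ the plateau and amplitude are linear and solved in closed form,
reducing the problem to a 1-D minimisation over $\log(\tau/\mathrm{span})$.
This parameterisation was chosen deliberately:

* it is robust down to *exactly noiseless* data (zero residual), where
  general-purpose nonlinear least squares iterations can fail to start;
* the optimisation variable is dimensionless and $O(1)$, so the fitted
  $\tau$ is exactly covariant with the time unit and invariant under any
  positive rescaling of the signal;
* it is fast enough to run independently at every pixel of an image stack.

Standard errors come from the Gauss-Newton $J^\top J$ at the optimum; tests
verify both against an independent Levenberg-Marquardt fit
(`minpack.lm::nlsLM`) and check that the reported $\tau$ standard error is
honest (truth within $\pm 2$ SE in $\ge 90\%$ of simulated repeats). A fit
whose amplitude falls below $5\times$ a roughness-based noise estimate
(`mad(diff(y))/sqrt(2)`, insensitive to smooth trends) is rejected as "no
kinetics detected"; a fitted $\tau$ beyond $10\times$ the observation span
raises an "observation window too short" flag. The plateau is free by
default even for nominally irreversible actinometers, because backgrounds
and offsets exist; `fix_plateau` gives the 2-parameter variant.

### Exposure-time bookkeeping

`frames_to_times()` maps frame index to cumulative illuminated time. In
wide-field mode that is $n \times$ frame interval. In raster (confocal)
scanning each pixel is illuminated exactly one dwell time per frame
regardless of scan position, so the axis is $n \times$ dwell time; the
kinetics then play out on cumulative illuminated time rather than wall-clock
time. Whether a frame's signal is assigned to the start or the midpoint of
its exposure is not standardised across instruments, so the convention is an
explicit `timing_model()` flag (default `"start"`, i.e. $t_n = n\,\Delta$).
For solution samples in raster mode, `fit_stack(roi_fraction = 1/3)`
restricts analysis to the central portion of the field to limit the
interference of molecular diffusion; the 1/3 linear fraction is a
conventional default, not a tuned constant.

## Intensity maps, validity and uncertainty

`map_intensity()` applies $I = 1/(\sigma\tau)$ per pixel and flags pixels
outside the actinometer's reliable range rather than dropping them: the
range expresses where the light-driven step is rate limiting (mechanistic
validity), not numerical failure. Statistics are computed over valid
in-range pixels; the identity $I\sigma\tau = 1$ holds for every reported
value by construction and is asserted in the test suite.

Relative uncertainty combines the tabulated cross-section uncertainty
(10% for the chemical and protein actinometers, 20% for the photosynthetic
apparatus) with the fit uncertainty in quadrature
(`propagate_uncertainty()`), since $I$ is a product of independent
multiplicative factors. With a typical fit error this reproduces the ~20%
achievable overall uncertainty of the method. The exact decomposition of
that budget is a documented package choice.

`calibrate_scale()` fits measured intensities against an instrument's
percentage (or current) scale by weighted linear least squares with a free
intercept, reporting whether the intercept is consistent with zero within
two standard errors. Fitting slope *and* intercept, rather than forcing
proportionality, is deliberate: the calibration verifies linearity instead
of assuming it.

## Wavelength transfer and polychromatic sources

A photochemically inert, broad-absorbing fluorophore held below absorbance
0.15 emits in proportion to the light intensity, with the quantum yield
cancelling in ratios. `transfer_intensity()` implements
$I_2 = I_1 (F_2/F_1)(\epsilon_1/\epsilon_2)$ from readings at a calibrated
and an unknown wavelength.

For sources with spectral width, the *action spectrum* is the pointwise
product of the source's unit-integral emission spectrum with the molecule's
excitation (or cross-section) spectrum - an overlap product followed by
integration, **not** a shift-convolution, despite the photochemical
literature's use of the word "convolution". `effective_sigma()` integrates
$\sigma(\lambda) s_{norm}(\lambda)$ so that $S_I = 1/(\sigma_{eff}\tau)$,
and `polychromatic_transfer()` extracts the integral photon flux
$S_I = (F_{target}/F_{ref})\, I_{ref} \big/ \int s_{norm}\epsilon_{norm}\,
d\lambda$ together with the scaled spectral intensity
$I(\lambda) = S_I s_{norm}(\lambda)$. The reference source is treated as
monochromatic at the normalization wavelength by default; when its bandwidth
matters, its spectrum can be passed explicitly and the numerator is weighted
by the reference's own overlap integral. Spectra are resampled onto a common
1-nm grid and integrated trapezoidally - adequate because real emission and
excitation bands are $\ge 10$ nm wide and smooth; the triangle-spectrum
tests bound the quadrature error. The registry tabulates $\sigma$ only at
discrete wavelengths and never interpolates between them (matching uses a
0.5 nm tolerance); continuous $\sigma(\lambda)$ for polychromatic work must
be supplied as a measured cross-section spectrum
(`attach_cross_section()`).

## The forward simulators

The synthetic-data module generates every input the analysis code is tested
on. `simulate_timeseries()` is the exact closed form above.
`simulate_stack()` evolves the normalized distance from the photostationary
state $u(x,y,t)$ by

$$\partial u/\partial t = -\sigma I(x,y)\, u + D \nabla^2 u$$

with no-flux boundaries, recording frames as
$\mathrm{detection} \times (F_\infty + (F_0-F_\infty)u)$ plus noise. Choices
and what they emulate:

* **Reversible photoswitching** is reduced to relaxation toward a plateau
  with a single effective $\tau = 1/(\sigma I)$; the underlying multi-step
  photocycle is deliberately not modelled, since the measurement protocol
  itself fits monoexponentials within the validated intensity range.
  Thermal recovery in darkness is neglected (illumination is constant
  during a measurement).
* **Diffusion** uses explicit forward-time centred-space stepping with
  operator splitting: the reaction substep is applied exactly
  ($u \leftarrow u\,e^{-k\,\delta t}$), the diffusion substep by an Euler
  update, with $\delta t \le \min(\Delta x^2/(4D),\ \tau_{min}/20)$ chosen
  automatically. With $\sigma = 0$ the scheme conserves total signal to
  $10^{-9}$ over 1,000 steps (tested); with $D = 0$ the exact per-pixel
  closed form is used, so the stack reduces to 0-D kinetics to $10^{-9}$.
  This reproduces the experimentally observed behaviour that free solution
  blurs a patterned illumination map while a gel preserves it, at equal
  mean intensity.
* **Inner-filter reporting** uses the path-averaged attenuation factor
  $(1-10^{-A})/(A\ln 10)$ (computed via `expm1` for small $A$). The model
  is isolated behind the simulator interface because published variants of
  the expression differ; the forward-simulate-then-fit tests quantify the
  resulting small bias in $\tau$ and verify it shrinks as the working
  absorbance decreases (≈6% at $A_0 = 0.15$, <0.5% at $A_0 = 0.01$).
* **Photosynthetic rise** is a two-exponential rise with
  $k_1 = \sigma_{PA} I$ and $k_2 = 0.05\,k_1$ by default; only $k_1$ is
  physically constrained, and the slow-phase ratio is a free parameter kept
  below 0.2 so the phases remain separable.
* **Noise** defaults to additive Gaussian at 1% of the initial signal;
  a scaled-Poisson `"shot_like"` model is available. Identical seeds give
  bit-identical realizations without touching the caller's RNG stream.

What the simulators do *not* emulate - optical point-spread functions,
aberrations, camera-specific noise, 3-D illumination structure - bounds
what passing tests show: they validate the estimators against the stated
kinetic model, not against instrument physics. In particular a 3-D
inhomogeneous light profile cannot be recovered from a 2-D $\tau$ map; only
the thickness-averaged intensity is meaningful there.

## Numerical choices and degenerate inputs

* $\tau$ search: 41-point log-spaced grid from $\Delta t_{min}/20$ to
  $100\times$ span (plus a data-driven $1/e$-crossing candidate), then
  Brent minimisation in the bracketing interval at tolerance $10^{-12}$ on
  $\log(\tau/\mathrm{span})$.
* Wavelength equality against the registry uses a 0.5 nm absolute
  tolerance; no interpolation between tabulated rows.
* The $5\tau_{min}$ consistency deviation is computed relative to the exact
  value $5/(\sigma I_{max})$, because the stored tabulated value is the
  rounded one; all 17 kinetic entries agree within 1%.
* Per-pixel fits failing outright or with $r^2 < 0.9$ (default) are
  masked, not imputed; an all-masked map is an error.
* TIFF output maps the data affinely onto the unit interval (32-bit
  samples) with offset and scale in a JSON sidecar, because noisy frames
  can be negative and TIFF sample interpretation across readers is
  otherwise ambiguous.
* Degenerate cases error eagerly with actionable messages: fewer than 4
  frames (an under-determined 3-parameter fit), constant series,
  non-increasing time axes, spectra with duplicated wavelengths or negative
  values, resampling outside a spectrum's support, diffusion step budgets
  implying a finer grid than requested.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on simulated data:
the end-to-end uniform-field recovery uses a $128 \times 128 \times 50$
stack at 1% noise (mean intensity recovered to ~0.01%, 99.9% of pixels
within 5%), gradient-direction recovery a $64 \times 64 \times 50$ stack
(angle recovered within $1^\circ$ of the simulated $3^\circ$), and the
diffusion-blur comparison $48 \times 48 \times 40$ stacks with
$D = 2\times 10^{-9}$ m$^2$ s$^{-1}$ on a 1 µm grid (diffusion length about
two pixels over the measurement). These sizes were chosen to exercise the
per-pixel statistics meaningfully; all quantities are recomputed from
scratch at run time.

## Known limitations

* Time resolution is set by the photoconversion kinetics; time-varying
  intensity profiles faster than $\tau$ are not resolvable.
* The monoexponential reduction holds only inside each actinometer's
  tabulated intensity range; out-of-range pixels are flagged accordingly.
* Raster-mode diffusion during the *unilluminated* part of the scan is not
  modelled separately: the simulator advances diffusion on the cumulative
  exposure axis, which slightly understates blurring for slow scans.
* No drift/registration correction and no double-exponential
  bleaching-background decomposition are provided.
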