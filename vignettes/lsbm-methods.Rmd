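---
title: "Line-scan Brillouin spectral analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line-scan Brillouin spectral analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsbrillouin)
```

## The measurement and its model

Spontaneous Brillouin scattering shifts a small fraction of the incident
laser light by the acoustic phonon frequency

$$\nu_B = \frac{2 n V \sin(\theta/2)}{\lambda},$$

where $n$ is the refractive index, $V$ the longitudinal sound velocity,
$\theta$ the scattering angle and $\lambda$ the vacuum wavelength
(`brillouin_shift_physics()`). For water-like material at 780 nm this is
about 5.1 GHz in backscattering and $1/\sqrt{2}$ of that in the
orthogonal 90° geometry. The spectrum at one spatial point consists of
the Rayleigh (elastic) line at 0, a Stokes peak at $-\nu_B$ and an
anti-Stokes peak at $+\nu_B$, each a Lorentzian of width $\Gamma_B$
convolved with the spectrometer's instrument function.

A VIPA etalon maps optical frequency to position on the camera, with the
whole spectrum repeating every free spectral range (FSR); a line-scan
instrument stacks hundreds of such spectra, one per camera row. The
package's frequency convention is signed GHz relative to the laser line,
so "Stokes" and "anti-Stokes" are operationally the negative- and
positive-frequency halves of one order, and each order's Rayleigh anchor
defines its 0 GHz. This is the only convention under which "fit the two
peaks separately, then average" is unambiguous, and it is forced by the
fact that the remapping depends only on the Rayleigh position and the
FSR.

## Calibration

`detect_order_anchors()` finds the per-order elastic peaks as the most
prominent set of local maxima lying on a consistent arithmetic
progression (one peak per consecutive order index), then refines each to
sub-pixel accuracy by 3-point parabolic interpolation of log-intensity —
exact for Gaussian-topped peaks and bias-free for symmetric ones.
Restricting anchors to a periodic progression is what rejects Brillouin
peaks and other reference lines: decoys either sit off the pitch or lose
the prominence contest within it.

`fit_dispersion()` regresses the known reference-line frequencies on
their pixel offsets from the nearest anchor (least squares, linear by
default, optional quadratic term), and reports the FSR as the frequency
spanned by one inter-anchor pitch. With the shipped Rb-87 D2 line set
the main anchor is the 6.834683 GHz ground-state splitting; the
fine-structure companions (~0.27 GHz away) are deliberately omitted from
the default table because they are unresolvable at the ~0.7 GHz
instrument resolution and would blend with the main line. Calibration
frames are simulated with the notch disabled; how a real instrument
obtains Rayleigh anchors through the notch is an acquisition detail
outside this package's scope.

## The reconstruction pipeline

1. **Remap** (`remap_to_linear()`): each order's pixels are converted to
   signed frequency and resampled onto a common uniform grid by cubic
   spline (`stats::splinefun`, "fmm"). Samples coincident with source
   pixels pass through unchanged, since a spline interpolates its knots
   exactly. The grid spans ±(FSR/2 − 2 px) — the two-pixel margin absorbs
   integer-pixel truncation at order edges, so interior orders are never
   flagged as truncated.
2. **Sum** (`sum_orders()`): sample-wise sum of ≥ 3 orders (configurable;
   strict or warning mode). Orders see independent photon noise, so
   summing $k$ orders improves precision by $\sqrt{k}$.
3. **Fit** (`fit_spectrum()`): independent weighted least-squares fits
   (Levenberg–Marquardt via minpack.lm) on the negative- and
   positive-frequency ranges. Models: plain Lorentzian,
   Lorentzian + linear/quadratic baseline, or the instrument-broadened
   line (Lorentzian ⊛ Gaussian kernel). Starting values are the range
   argmax (centre), half the range (width) and max − baseline
   (amplitude); convergence at relative tolerance 1e-8 or 100
   iterations. A non-converged fit, a centre pinned to a range edge, or
   $R^2$ below 0.5 flags the measurement invalid — invalid voxels
   propagate as NA through all maps and statistics rather than raising
   errors, because a fit failure in one row must never abort a frame.

The reported shift is $(|c_S| + |c_{AS}|)/2$ and the linewidth the
average of the two widths; if exactly one side is valid the measurement
falls back to it and is flagged. SNR is recorded as the fitted Stokes
amplitude over the residual standard deviation of its fit range, in dB
with the amplitude convention $20\log_{10}$ (the convention is stored so
a power-convention reading can be reconstructed).

### Numerical accuracy of the remap–fit chain

Cubic-spline resampling of a peak sampled at 0.25–0.5 GHz/px is the
pipeline's main numerical error source. Design experiments with a
dense-grid oracle showed that a bare 0.4 GHz Lorentzian at 0.5 GHz/px
carries a few-MHz centre bias through any spline remap; with the
instrument broadening included (the physical case — the measured line is
~0.9 GHz wide) and the default 0.25 GHz/px sampling, the residual bias
of the full remap–sum–fit chain is below ~1 MHz when averaged over
Stokes/anti-Stokes and three orders. Two defaults follow from this:
`spectral_sampling = 0.25` GHz/px (the fine end of the instrument's
range) and a remap target step of 0.1 GHz, which lets the fit average
the spline error over many points. Accuracy degrades gracefully towards
0.5 GHz/px; the property tests pin the ~1 MHz level at 0.25–0.4 GHz/px.

## The simulator

`simulate_row_spectrum()` builds the intrinsic spectrum on a 5 MHz fine
grid: Lorentzian Brillouin peaks, plus a *Gaussian* elastic line of
0.02 GHz width — an elastic line modelled as a Lorentzian would carry
unphysical $\nu^{-2}$ power-law tails that, multiplied by the 10⁴
Rayleigh-to-Stokes ratio, leak past the narrow notch and bias the
Brillouin fits; the real elastic line has the laser's sub-MHz width and
no such tails. The notch multiplies by
$\exp(-OD\,e^{-\nu^2/2\sigma_D^2})$ (Doppler FWHM 0.55 GHz; OD defaults
to $\ln 10^8$ = 80 dB at line centre), the instrument kernel (Gaussian,
σ = 0.3 GHz, i.e. ~0.7 GHz resolution FWHM) is applied by discrete
convolution, and the result is sampled through the per-order dispersion
law (linear slope, optional quadratic term, anchors pitched exactly one
FSR apart). Camera detection is Poisson photon statistics × gain +
Gaussian read noise (2 counts rms), rounded and clipped to
[0, full well].

`photon_budget` is defined as the expected Stokes + anti-Stokes photons
per order per spectrum — a pure scale factor, so shot-noise scaling
studies sweep it directly. The 5.05 GHz / 0.4 GHz water phantom is the
reference sample for precision studies; `simulate_timelapse_phantom()`
ramps a masked folding domain by a configurable 10–20 MHz and carries
the domain geometry in a fluorescence channel at 2.5138× finer pixels.

What the simulator does **not** emulate: optical aberrations, sample
scattering and absorption, spectral drift between frames, EMCCD
excess-noise factor, cosmic rays/hot pixels, and any asymmetric
instrument line shape. Passing tests therefore demonstrate correctness
of the analysis chain under an ideal-optics forward model, not
robustness to every artefact of real data.

## Characterization studies

- `precision_study()` mirrors the instrument's water measurement: 50
  frames, full pipeline per row, the central 16 spectra of each frame
  (the centre of the field of view, where intensity is flat) averaged
  into one shift per frame; precision = sd of the 50 values, in MHz. A
  single spectrum at a fitted amplitude/residual ratio of 10 has a
  centre uncertainty of several tens of MHz for a ~0.9 GHz-wide line
  sampled at 0.25 GHz/px — it is the line-scan multiplexing (averaging
  the selected spectra of each line) that brings the per-frame figure
  below 20 MHz at that operating SNR.
- `tune_photon_budget()` finds the budget realizing a target fitted SNR
  ratio by secant iteration on pilot frames — the operating condition is
  defined by the measured ratio, not by a hard-coded budget.
- `shot_noise_scaling()` regresses log precision on log budget with read
  noise disabled (the shot-noise-limited regime; read noise steepens the
  apparent slope at low budgets). The expected slope is −1/2.
- `folding_phantom_study()` is the end-to-end check: simulate a
  two-timepoint folding phantom, image, calibrate, reconstruct, rescale
  (bilinear, 2.5138), register with the fluorescence mask, quantify the
  masked region, and report the recovered shift increase. The ROI is
  eroded by two fluorescence pixels before quantification so the
  statistic samples the domain interior — bilinear rescaling mixes
  boundary voxels with the surround, which would otherwise bias the
  recovered step low by design rather than by noise.

## Mapping and registration conventions

Output sizes of the bilinear rescale are `floor(input × scale)` with the
half-pixel-centre convention, so a constant map is preserved exactly and
the inverse resample returns it bit-identically; the validity mask uses
nearest-neighbour. In `register_overlay()` the y offset names the
fluorescence row aligned with the Brillouin centre (the half-diameter
convention, 450 px for a 900 px frame; `NULL` centres automatically) and
the x offset is a landmark-derived translation supplied by the user —
landmark selection is a manual step by design and no automatic
registration is attempted. Median projections use the mean-of-central-
pair rule for even counts, IQR uses linear-interpolation quantiles
(type 7), and invalid voxels are excluded from every statistic, never
zero-filled. Both re-slice layouts (three projections of two slices, or
projections of three slices) are expressible through the `slabs`
argument.

## Problem sizes and defaults

The default simulated sensor is 3 orders × 60.6 px/order (~194 pixels)
with 48-row frames: large enough for three complete orders plus margins,
small enough that a full precision study (50 frames, 2400 spectra) runs
in seconds to tens of seconds. `line_length = 48` stands in for the
instrument's several-hundred-point line; studies that need more spectra
(shot-noise scaling, order-gain) raise it per call. All stochastic
functions take explicit integer seeds and derive child seeds internally;
no hidden RNG state crosses function boundaries.

## Known limitations

- The broadened-line fit uses a Gaussian instrument kernel; a VIPA's
  true instrument function is Airy-like. Peak *centres* — the reported
  quantity — are insensitive to symmetric kernel shape, but fitted
  linewidths are kernel-dependent and should be interpreted relative to
  the configured kernel.
- `measure_spectral_resolution()` fits a Lorentzian to the (Gaussian-
  broadened) elastic line; the fitted FWHM of a Gaussian-shaped peak
  under a Lorentzian model is ~20% below its true half-maximum width.
  The tests compare against an independent oracle of the same
  definition.
- Calibration assumes at least two resolvable reference lines; with a
  single line per order the quadratic dispersion term is not
  identifiable (the fit correctly refuses).
- No drift tracking across time-lapses and no conversion of shift to
  longitudinal modulus is provided.
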