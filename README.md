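# lsbrillouin

Spectral analysis for **line-scan Brillouin microscopy (LSBM)** with a
VIPA spectrometer, plus a physics-based simulator so the whole pipeline
can be validated without instrument hardware.

Brillouin microscopy measures the frequency shift ν_B (GHz) of laser
light inelastically scattered by thermally excited acoustic phonons — an
all-optical, label-free probe of longitudinal mechanical properties. In a
line-scan instrument, hundreds of points along an illumination line are
dispersed simultaneously by a virtually imaged phased array (VIPA) onto a
camera, each point producing a spectrum that repeats across several VIPA
diffraction orders with a period of one free spectral range
(FSR = 15.15 GHz here). A rubidium-87 vapour cell suppresses the elastic
(Rayleigh) line by ~80 dB so the weak Brillouin peaks survive.

The pipeline implemented here processes each spectral row in three steps:

1. **Remap** the camera pixels of each order into linear frequency space,
   ν = s·(p − p₀) (+ optional quadratic term), anchored on the Rayleigh
   peak position p₀ of each order, using cubic-spline interpolation;
2. **Sum** the signal of at least three orders to raise the effective SNR;
3. **Fit** the Stokes (−ν_B) and anti-Stokes (+ν_B) peaks **separately**
   with Lorentzian (or instrument-broadened) line shapes; the reported
   shift is the average of the two absolute centre frequencies.

Calibration estimates the FSR and the pixel→GHz dispersion from frames
containing Rb D₂ hyperfine lines of known frequency (the 6.834683 GHz
ground-state splitting ships in `inst/extdata/rb87_d2_lines.csv`).
Downstream tools assemble per-line measurements into shift maps, rescale
them (bilinear, factor 2.5138) onto the fluorescence camera grid,
register the two modalities, form median re-slice projections, and
quantify masked regions as mean ± sd or median + IQR time series relative
to a reference timepoint — the fluorescence-guided analysis used for
tissue-folding studies. The simulator generates spectrometer frames,
calibration frames and 3D/4D embryo-like phantoms (including a folding
domain whose shift rises by 10–20 MHz) with Poisson photon statistics,
camera gain/read noise, notch suppression and instrument broadening, with
exact ground truth attached.

## Worked example

```r
library(lsbrillouin)

config <- spectrometer_config()             # FSR 15.15 GHz, 0.25 GHz/px
calib  <- calibrate_frame(simulate_calibration_frame(config))
print(calib)
#> VIPA calibration: 3 orders, FSR 15.1500 GHz, 0.2500 GHz/px
#>   anchors (px): 36.36, 96.96, 157.56
#>   residual rms: 1.899e-14 GHz

phantom <- water_phantom_line(config$line_length)   # 5.05 GHz water line
frame   <- simulate_frame(phantom, config, photon_budget = 300, rng_seed = 42)
meas    <- process_frame(frame, calib)
head(meas[, c("row", "shift", "linewidth", "snr_db", "valid")], 3)
#>   row    shift linewidth   snr_db valid
#> 1   1 5.060720 0.8181447 28.18242  TRUE
#> 2   2 5.100713 0.7181703 28.82712  TRUE
#> 3   3 5.028476 0.8819086 28.47015  TRUE
```

The recovered free spectral range matches the simulated 15.15 GHz to
machine precision, and the 48 spectra of this single frame average
5.0556 GHz with a per-spectrum precision of 25.5 MHz at ~27 dB fitted
SNR. `measure_precision()`, `precision_study()`, `shot_noise_scaling()`
and `folding_phantom_study()` run the corresponding characterization
studies (water-frame precision, the 1/√energy shot-noise law, and
end-to-end recovery of an injected 15 MHz folding signal).

A command-line wrapper is included:

```sh
Rscript inst/cli/lsbm.R simulate    --out sim --frames 10 --seed 1
Rscript inst/cli/lsbm.R calibrate   --frame sim/calibration.tif --out calib.json
Rscript inst/cli/lsbm.R reconstruct --frames sim/frames.tif --calib calib.json --out meas.csv
Rscript inst/cli/lsbm.R quantify    --measurements meas.csv --out summary.csv
```

File formats (multi-page TIFF + JSON sidecars, calibration JSON, CSV
tables, YAML run configuration) are documented in `inst/FORMATS.md`; the
modelling choices and their rationale are in
`vignettes/lsbm-methods.Rmd`.

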