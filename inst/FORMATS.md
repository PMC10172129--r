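# File formats

## Spectrometer frames — multi-page TIFF + JSON sidecar

`write_frames()` / `read_frames()` store one frame per TIFF page as
16-bit unsigned integers (camera counts; lossless up to 65535, the
default full well). A sidecar `<path>.json` holds one record per page:

```json
[{"exposure": 0.1,
  "truth": {"shift": [5.05, ...], "linewidth": [0.4, ...]},
  "photon_budget": 300, "rng_seed": 42}, ...]
```

Simulated frames carry their ground truth under `truth`; frames from real
acquisitions simply omit it.

## Calibration model — JSON

`write_calibration()` / `read_calibration()`; all numbers are written at
full double precision:

```json
{"order_anchors": [36.36, 96.96, 157.56], "fsr": 15.15,
 "slope": 0.25, "quad": 0, "pitch": 60.6, "n_pixels": 194,
 "residual_rms": 1.9e-14}
```

Units: anchors/pitch in pixels, `fsr` GHz, `slope` GHz/px,
`quad` GHz/px², `residual_rms` GHz.

## Shift maps / volumes — multi-page float TIFF + JSON sidecar

`write_volume()` / `read_volume()`: four 32-bit float pages in the order
`shift`, `linewidth`, `snr`, `valid`. Each page is stored as
`(value - offset) / scale` to fit the TIFF float [0, 1] convention; the
per-page `offsets` and `scales` plus `dims`, `voxel_size` (µm),
`geometry` (O-LSBM / E-LSBM) and `timepoints` (minutes) live in the
sidecar. Invalid voxels are marked by the `valid` page and restored to
`NA` on read. Storage precision is float32 (~1e-7 relative, i.e. sub-kHz
on a GHz-scale shift).

## Measurement tables and ROI summaries — CSV

`write_measurements()` / `read_measurements()`: plain CSV with numeric
fields printed at 17 significant digits, so GHz values survive a round
trip at full double precision. Per-row measurement tables use columns
`row, shift, linewidth, amplitude, snr_ratio, snr_db, r2_stokes,
r2_antistokes, iterations, valid, fallback` (+ `frame` when several
frames are concatenated). ROI time series use
`timepoint_min, stat_ghz, dispersion_ghz, n_voxels`.

## Reference line tables — CSV

Columns `label`, `frequency_ghz` (offset from the laser lock line),
`relative_intensity`. The shipped default is the Rb-87 D2 set
(`inst/extdata/rb87_d2_lines.csv`).

## Run configuration — YAML

Sections `spectrometer`, `notch`, `camera`, `geometry`, `fit`,
`registration`, `simulation`, `run`; unknown sections or keys are
rejected before any stage runs, and values are validated by the typed
constructors. Example:

```yaml
spectrometer: {fsr: 15.15, n_orders_visible: 3, spectral_sampling: 0.25}
camera:       {read_noise: 2, gain: 1, exposure: 0.1}
fit:          {model_kind: lorentzian, target_df: 0.1, min_orders: 3}
run:          {seed: 1}
```
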