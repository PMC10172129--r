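# Shared fixtures: one default spectrometer and its calibration, computed
# once per test run.  All synthetic data are generated in code.

default_config <- spectrometer_config()

default_calibration <- calibrate_frame(
  simulate_calibration_frame(default_config),
  expected_orders = default_config$n_orders_visible)

water_material <- list(shift = 5.05, linewidth = 0.4, reflectivity = 1e4)

# run the single-spectrum reference path: remap, sum, fit, average
reference_shift <- function(row_counts, calib = default_calibration,
                            target_df = 0.1) {
  sp <- suppressWarnings(remap_to_linear(row_counts, calib, target_df))
  s <- sum_orders(sp[!vapply(sp, `[[`, logical(1), "truncated")],
                  strict = FALSE)
  f <- fit_spectrum(s)
  compute_shift(f$stokes, f$antistokes)
}
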