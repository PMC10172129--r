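test_that("remapping is a pass-through for coincident samples and constants", {
  calib <- default_calibration
  # constant spectrum stays constant (splines reproduce constants)
  const_row <- rep(42, calib$n_pixels)
  sp <- remap_to_linear(const_row, calib)
  for (s in sp)
    expect_equal(s$intensity[is.finite(s$intensity)],
                 rep(42, sum(is.finite(s$intensity))))
  # a target grid coincident with source pixel frequencies passes through:
  # integer-pixel anchors make grid points land exactly on source pixels
  # when the target step equals the pixel sampling
  calib_int <- calibration_model(c(40, 100, 160), fsr = 15, slope = 0.25,
                                 n_pixels = 200)
  row <- sin(seq_len(200) / 7) + 2
  sp2 <- suppressWarnings(remap_to_linear(row, calib_int, target_df = 0.25))
  s2 <- sp2[[2]]
  px_at <- frequency_to_pixel(calib_int, 2, s2$freq_grid)
  coincident <- abs(px_at - round(px_at)) < 1e-9 & is.finite(s2$intensity)
  expect_true(any(coincident))
  expect_equal(s2$intensity[coincident], row[round(px_at[coincident])],
               tolerance = 1e-12)
  expect_error(remap_to_linear(row, calib, target_df = 2), "target_df")
})

test_that("order summation is sample-wise, commutative and guarded", {
  calib <- default_calibration
  row <- simulate_row_spectrum(water_material, default_config, 500)$noiseless
  sp <- remap_to_linear(row, calib)
  # three identical spectra sum to three times the amplitude
  s3 <- sum_orders(list(sp[[2]], sp[[2]], sp[[2]]))
  expect_equal(s3$intensity, 3 * sp[[2]]$intensity)
  expect_identical(s3$n_orders_summed, 3L)
  # permutation invariance
  expect_equal(sum_orders(sp[c(3, 1, 2)])$intensity,
               sum_orders(sp)$intensity)
  # grid mismatch and strictness
  other <- linear_spectrum(seq(0, 1, by = 0.1), rep(1, 11))
  expect_error(sum_orders(list(sp[[1]], other)), "grid")
  expect_error(sum_orders(sp[1:2], min_orders = 3, strict = TRUE), "minimum")
  expect_warning(sum_orders(sp[1:2], min_orders = 3, strict = FALSE),
                 "minimum")
})

test_that("noiseless peaks are recovered to about a megahertz", {
  calib <- default_calibration
  cs <- reference_shift(simulate_row_spectrum(water_material, default_config,
                                              500)$noiseless)
  expect_true(cs$valid)
  expect_lt(abs(cs$shift - 5.05) * 1e3, 3)   # single spectrum, fixed phase
  # linewidth recovered on the broadened-line scale
  expect_gt(cs$linewidth, 0.4)
  expect_lt(cs$linewidth, 1.3)
})

test_that("a flat spectrum yields invalid fits, not errors", {
  grid <- seq(-7, 7, by = 0.1)
  flat <- linear_spectrum(grid, rep(5, length(grid)))
  f <- fit_spectrum(flat)
  expect_false(f$stokes$valid)
  expect_false(f$antistokes$valid)
  cs <- compute_shift(f$stokes, f$antistokes)
  expect_false(cs$valid)
  expect_true(is.na(cs$shift))
})

test_that("shift averaging and the single-peak fallback follow the contract", {
  mk <- function(center, valid = TRUE)
    structure(list(center = center, fwhm = 0.8, amplitude = 10,
                   residual_sd = 0.1, valid = valid), class = "peak_fit")
  # average of absolute Stokes and anti-Stokes centres
  expect_equal(compute_shift(mk(-5.00), mk(5.02))$shift, 5.01)
  # symmetric fits: the shift equals either magnitude
  expect_equal(compute_shift(mk(-5.05), mk(5.05))$shift, 5.05)
  # one invalid fit: fall back to the valid one, flagged
  cs <- compute_shift(mk(-9, valid = FALSE), mk(5.03))
  expect_equal(cs$shift, 5.03)
  expect_true(cs$fallback)
})

test_that("SNR follows the amplitude-ratio dB convention", {
  f <- structure(list(amplitude = 100, residual_sd = 10, valid = TRUE),
                 class = "peak_fit")
  expect_equal(compute_snr(f)$db, 20)
  expect_equal(compute_snr(f)$ratio, 10)
  perfect <- structure(list(amplitude = 100, residual_sd = 0, valid = TRUE),
                       class = "peak_fit")
  expect_identical(compute_snr(perfect)$db, Inf)
  # quadrupling the photon budget raises the SNR by about 6 dB
  cfg <- spectrometer_config(line_length = 24)
  calib <- default_calibration
  ph <- water_phantom_line(24)
  snr_at <- function(pb, seed) {
    m <- process_frame(simulate_frame(ph, cfg, pb, rng_seed = seed), calib)
    mean(m$snr_db[m$valid & is.finite(m$snr_db)])
  }
  gain <- mean(vapply(1:3, function(k)
    snr_at(480, 400 + k) - snr_at(120, 500 + k), numeric(1)))
  expect_equal(gain, 6, tolerance = 1.5)
})

test_that("frame processing is row-independent and matches the reference path", {
  cfg <- default_config
  calib <- default_calibration
  ph <- water_phantom_line(cfg$line_length)
  fr <- simulate_frame(ph, cfg, 300, rng_seed = 31)
  m <- process_frame(fr, calib)
  expect_equal(nrow(m), cfg$line_length)
  # uniform water frame: every valid row within a few sd of the mean
  sh <- m$shift[m$valid]
  expect_lt(max(abs(sh - mean(sh))), 6 * sd(sh))
  # reversing the row order leaves per-row results identical
  fr_rev <- fr
  fr_rev$counts <- fr$counts[rev(seq_len(nrow(fr$counts))), ]
  m_rev <- process_frame(fr_rev, calib)
  expect_equal(m_rev$shift, rev(m$shift), tolerance = 1e-12)
  # batch path equals the single-spectrum reference fitter within 0.1 MHz
  for (i in seq(1, cfg$line_length, by = 7)) {
    ref <- reference_shift(fr$counts[i, ], calib)
    expect_lt(abs(ref$shift - m$shift[i]) * 1e3, 0.1)
  }
})

test_that("spectral precision is the sample sd in MHz", {
  expect_equal(measure_precision(rep(5.05, 10)), 0)
  set.seed(42)
  draws <- rnorm(50, 5.05, 0.010)
  expect_equal(measure_precision(draws), 10, tolerance = 3.5)
  expect_error(measure_precision(5.05), "at least 2")
})

test_that("spectral resolution recovers the instrument linewidth", {
  cfg <- default_config
  calib <- default_calibration
  # strong elastic peak, notch off; expected width: intrinsic 0.02 GHz
  # Gaussian line through the 0.3 GHz sigma instrument kernel ~ 0.71 GHz
  row <- simulate_row_spectrum(list(shift = 5.05, linewidth = 0.4,
                                    reflectivity = 50),
                               cfg, 500, notch_on = FALSE)$noiseless
  sp <- remap_to_linear(row, calib)
  summed <- sum_orders(sp, strict = FALSE)
  res <- measure_spectral_resolution(summed)
  expect_true(res$reliable)
  # oracle: the Rayleigh line is a ~0.707 GHz FWHM Gaussian (0.02 GHz line
  # through the 0.3 GHz sigma kernel); the pipeline reports the FWHM of a
  # LORENTZIAN fitted to it, reproduced here with an independent optimiser
  # on the dense analytic profile
  sg <- sqrt(cfg$instrument_sigma^2 + (0.02 / 2.3548)^2)
  dense <- seq(-2, 2, by = 0.001)
  gauss <- exp(-dense^2 / (2 * sg^2))
  obj <- function(p) sum((gauss - p[1] * (p[2] / 2)^2 /
                            (dense^2 + (p[2] / 2)^2))^2)
  oracle_fwhm <- optim(c(1, 0.7), obj)$par[2]
  expect_equal(res$fwhm_ghz, oracle_fwhm, tolerance = 0.1)
  # and the direct half-maximum width of the spectrum matches the kernel
  half <- summed$intensity >= max(summed$intensity, na.rm = TRUE) / 2
  direct <- diff(range(summed$freq_grid[which(half)]))
  expect_equal(direct, 2 * sqrt(2 * log(2)) * sg, tolerance = 0.25)
  # doubling the grid step leaves the recovered FWHM within a coarse step
  sp2 <- remap_to_linear(row, calib, target_df = 0.2)
  res2 <- measure_spectral_resolution(sum_orders(sp2, strict = FALSE))
  expect_lt(abs(res2$fwhm_ghz - res$fwhm_ghz), 0.2)
  # no elastic peak: error
  grid <- seq(-7, 7, by = 0.1)
  expect_error(measure_spectral_resolution(
    linear_spectrum(grid, rep(1, length(grid)))), "elastic")
})

test_that("noiseless fit bias stays at the megahertz level across samplings", {
  # shift-recovery invariant at instrument-realistic pixel samplings
  for (samp in c(0.25, 0.4)) {
    cfg <- spectrometer_config(spectral_sampling = samp, line_length = 1)
    calib <- calibrate_frame(simulate_calibration_frame(cfg),
                             expected_orders = 3)
    set.seed(round(samp * 100))
    errs <- vapply(runif(12, 4.6, 5.4), function(cen) {
      row <- simulate_row_spectrum(list(shift = cen, linewidth = 0.4,
                                        reflectivity = 1e4),
                                   cfg, 500)$noiseless
      reference_shift(row, calib)$shift - cen
    }, numeric(1))
    expect_lt(mean(abs(errs)) * 1e3, 1.6)
    # Stokes/anti-Stokes symmetry at high SNR: the signed bias is small
    expect_lt(abs(mean(errs)) * 1e3, 1.6)
  }
})
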