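test_that("rubidium notch transmission follows exp(-OD) at line centre", {
  g <- seq(-7, 7, by = 0.01)
  y <- rep(100, length(g))
  # OD = 0 is the identity
  expect_equal(apply_rb_notch(y, g, notch_config(optical_depth = 0)), y)
  # transmission exactly exp(-OD) at the line centre
  for (od in c(1, 5, log(1e8))) {
    out <- apply_rb_notch(y, g, notch_config(optical_depth = od))
    expect_equal(out[g == 0], 100 * exp(-od), tolerance = 1e-12)
  }
  # OD = ln(1e8) means 80 dB suppression at centre
  out <- apply_rb_notch(y, g, notch_config(optical_depth = log(1e8)))
  expect_equal(-10 * log10(out[g == 0] / 100), 80, tolerance = 1e-9)
  # far from the line the notch is transparent
  expect_equal(out[abs(g) > 4], y[abs(g) > 4], tolerance = 1e-6)
})

test_that("camera noise has Poisson variance plus read-noise floor", {
  cam <- camera_config(read_noise = 0, gain = 1)
  mu <- rep(400, 4000)
  counts <- apply_camera_noise(mu, cam, rng_seed = 1)
  # gain 1, no read noise: variance equals the mean (Poisson)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.1)
  # zero signal, read noise sigma: variance sigma^2 (allowing rounding)
  cam2 <- camera_config(read_noise = 5, gain = 1)
  counts2 <- apply_camera_noise(rep(0, 4000), cam2, rng_seed = 2)
  # clipping at 0 halves the distribution; compare against clipped oracle
  oracle <- pmax(0, round(rnorm(1e5, 0, 5)))
  expect_equal(var(counts2), var(oracle), tolerance = 0.15)
  expect_error(apply_camera_noise(c(-1, 2), cam, 1), "noiseless")
})

test_that("doubling the photon budget reduces relative peak noise by sqrt(2)", {
  cfg <- spectrometer_config(line_length = 1)
  cfg$camera$read_noise <- 0
  rel_noise <- function(pb) {
    base <- simulate_row_spectrum(water_material, cfg, pb)$noiseless
    pk <- which.max(base)
    draws <- vapply(1:300, function(k)
      apply_camera_noise(base, cfg$camera, rng_seed = 5000 + k)[pk],
      numeric(1))
    sd(draws) / mean(draws)
  }
  expect_equal(rel_noise(200) / rel_noise(400), sqrt(2), tolerance = 0.2)
})

test_that("row spectra place symmetric Stokes/anti-Stokes peaks in each order", {
  cfg <- default_config
  out <- simulate_row_spectrum(water_material, cfg, 1000)
  y <- out$noiseless
  anchors <- lsbrillouin:::anchor_pixels_truth(cfg)
  dpx <- water_material$shift / cfg$spectral_sampling
  for (a in anchors) {
    # local maxima within one pixel of the expected Stokes/anti-Stokes spots
    for (sgn in c(-1, 1)) {
      expect_lt(abs(which.max(y * (abs(seq_along(y) - (a + sgn * dpx)) < 8)) -
                      (a + sgn * dpx)), 1)
    }
  }
  # notch suppresses the Rayleigh line: with notch off it towers instead
  y_off <- simulate_row_spectrum(water_material, cfg, 1000,
                                 notch_on = FALSE)$noiseless
  expect_gt(y_off[round(anchors[2])] / max(y[round(anchors[2]) + -2:2]), 1e3)
  # aliasing guard
  expect_error(simulate_row_spectrum(list(shift = 7.5, linewidth = 0.4,
                                          reflectivity = 1),
                                     cfg, 100), "outside")
})

test_that("frames are deterministic given a seed and homogeneous per row", {
  cfg <- default_config
  ph <- water_phantom_line(cfg$line_length)
  f1 <- simulate_frame(ph, cfg, 300, rng_seed = 99)
  f2 <- simulate_frame(ph, cfg, 300, rng_seed = 99)
  expect_identical(f1$counts, f2$counts)
  f3 <- simulate_frame(ph, cfg, 300, rng_seed = 100)
  expect_false(identical(f1$counts, f3$counts))
  # homogeneous phantom: all noiseless rows identical
  nl <- simulate_frame(ph, cfg, 300)$counts
  expect_true(all(apply(nl, 2, function(col) max(col) - min(col)) == 0))
  # a single high-shift row displaces only that row's Brillouin peaks
  sh <- rep(5.05, cfg$line_length); sh[7] <- 5.45
  ph2 <- brillouin_phantom(array(sh, cfg$line_length))
  nl2 <- simulate_frame(ph2, cfg, 300)$counts
  changed <- which(apply(abs(nl2 - nl) > 1e-9, 1, any))
  expect_identical(changed, 7L)
  expect_error(simulate_frame(water_phantom_line(cfg$line_length + 1), cfg, 300),
               "line_length")
})

test_that("noisy frames converge to the noiseless expectation in the mean", {
  # pure Poisson statistics (with read noise, clipping negatives at zero
  # lifts the mean of dark pixels, which is a camera artefact, not bias)
  cfg <- spectrometer_config(line_length = 1,
                             camera = camera_config(read_noise = 0))
  base <- simulate_row_spectrum(water_material, cfg, 500)$noiseless
  n <- 400
  acc <- matrix(0, n, length(base))
  for (k in 1:n)
    acc[k, ] <- apply_camera_noise(base, cfg$camera, rng_seed = 7000 + k)
  mu <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(n)
  # every pixel's Monte-Carlo mean within 4 standard errors of the oracle
  expect_true(all(abs(mu - base) < 4 * pmax(se, 0.2)))
})

test_that("calibration frames follow FSR periodicity and linear dispersion", {
  cfg <- default_config
  pitch <- lsbrillouin:::order_pitch_px(cfg)
  # two lines one FSR apart land on identical pixels in adjacent orders
  fr <- simulate_calibration_frame(cfg, reference_lines = c(0, cfg$fsr))
  y <- colMeans(fr$counts)
  pk <- lsbrillouin:::find_peaks(y)
  pk <- pk$pixel[pk$prominence > 0.3 * max(pk$prominence)]
  expect_equal(sort(diff(sort(pk))), rep(round(pitch), length(pk) - 1),
               tolerance = 0.02)
  # Rb ground-state splitting: pixel separation = (6.8347/15.15) * pitch
  # between each order anchor and the splitting line within that order
  fr2 <- simulate_calibration_frame(cfg)
  y2 <- colMeans(fr2$counts)
  pk2 <- lsbrillouin:::find_peaks(y2)
  pk2 <- sort(pk2$pixel[pk2$prominence > 0.2 * max(pk2$prominence)])
  anchors <- detect_order_anchors(y2, 3)
  for (a in anchors) {
    inord <- pk2[pk2 > a + 2 & pk2 < a + pitch / 2]
    expect_length(inord, 1)
    expect_equal(inord - a, 6.834683 / 15.15 * pitch, tolerance = 0.04)
  }
  expect_error(simulate_calibration_frame(cfg, reference_lines = 0),
               "at least 2")
})

test_that("time-lapse phantom ramps only the masked domain", {
  base <- brillouin_phantom(matrix(5.05, 8, 6))
  mask <- matrix(FALSE, 8, 6); mask[3:5, 2:4] <- TRUE
  ph <- simulate_timelapse_phantom(base, mask, 0.015, c(0, 10, 20, 30))
  # endpoint: masked mean minus t0 mean is exactly the injected delta
  expect_equal(mean(ph$shift[, , 4][mask]) - mean(ph$shift[, , 1][mask]),
               0.015)
  # voxels outside the mask are time-invariant
  outside <- ph$shift[rep(!mask, 4) &
                        slice.index(ph$shift, 3) %in% 1:4]
  expect_equal(ph$shift[, , 2][!mask], ph$shift[, , 1][!mask])
  expect_equal(ph$shift[, , 4][!mask], ph$shift[, , 1][!mask])
  # zero delta: all timepoints identical
  ph0 <- simulate_timelapse_phantom(base, mask, 0, c(0, 10))
  expect_equal(ph0$shift[, , 1], ph0$shift[, , 2])
  # fluorescence carries the mask geometry at the finer pixel size
  expect_equal(dim(ph$fluorescence)[1:2], floor(c(8, 6) * 2.5138))
  expect_gt(mean(ph$fluorescence[, , 1]), 0)
  expect_error(simulate_timelapse_phantom(base, matrix(TRUE, 2, 2), 0.01, 0:1),
               "mask")
})
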