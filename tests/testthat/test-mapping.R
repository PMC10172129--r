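make_measurements <- function(shift, snr = 20) {
  data.frame(row = seq_along(shift), shift = shift, linewidth = 0.8,
             amplitude = 100, snr_ratio = 10, snr_db = snr,
             r2_stokes = 0.99, r2_antistokes = 0.99, iterations = 5,
             valid = is.finite(shift), fallback = FALSE)
}

test_that("volumes assemble in scan order with correct geometry", {
  lines <- lapply(1:10, function(k) make_measurements(rep(5 + k / 100, 264)))
  vol <- assemble_volume(lines, seq(0, by = 1.5, length.out = 10),
                         spatial_sampling = 0.7)
  expect_identical(dim(vol$shift), c(264L, 10L))
  expect_equal(vol$voxel_size, c(0.7, 1.5))
  expect_equal(vol$shift[1, ], 5 + (1:10) / 100)
  # single line: one-slice volume
  v1 <- assemble_volume(lines[1], 0)
  expect_identical(dim(v1$shift), c(264L, 1L))
  # shuffled positions sort back to the same volume
  perm <- sample(10)
  vol2 <- assemble_volume(lines[perm], seq(0, by = 1.5, length.out = 10)[perm])
  expect_equal(vol2$shift, vol$shift)
  expect_error(assemble_volume(list(make_measurements(rep(5, 3)),
                                    make_measurements(rep(5, 4))), 1:2),
               "line lengths")
})

test_that("bilinear rescale follows the floor-size and constancy rules", {
  tr <- registration_transform(xy_scale = 2.5138)
  m <- matrix(rnorm(100 * 40, 5.05, 0.01), 100, 40)
  out <- rescale_to_fluorescence(m, tr)
  expect_equal(dim(out), c(floor(100 * 2.5138), floor(40 * 2.5138)))
  expect_equal(nrow(out), 251)
  # identity at scale 1
  expect_equal(rescale_to_fluorescence(m, registration_transform(xy_scale = 1)), m)
  # constants are preserved exactly
  cm <- matrix(5.05, 20, 12)
  expect_equal(max(abs(rescale_to_fluorescence(cm, tr) - 5.05)), 0,
               tolerance = 1e-12)
  # round trip through the inverse scale recovers a constant map exactly
  up <- rescale_to_fluorescence(cm, tr)
  down <- lsbrillouin:::bilinear_resample(up, 20, 12)
  expect_equal(down, cm)
})

test_that("overlay registration crops per the centre/landmark conventions", {
  tr0 <- registration_transform(xy_scale = 1, y_offset = NULL, x_offset = 0)
  fluo <- matrix(runif(50 * 60), 50, 60)
  bril <- matrix(runif(50 * 60), 50, 60)
  # equal sizes, default offsets: identity overlay
  ov <- register_overlay(fluo, bril, tr0)
  expect_equal(ov$fluorescence, fluo)
  # y_offset 450 on a 900-pixel frame centres the crop
  fluo9 <- matrix(seq_len(900 * 900) %% 7, 900, 900)
  bril9 <- matrix(0, 100, 100)
  ov9 <- register_overlay(fluo9, bril9,
                          registration_transform(xy_scale = 1, y_offset = 450,
                                                 x_offset = 0))
  expect_equal(ov9$fluorescence, fluo9[1:100, 401:500])
  # known 12-pixel x shift: applying the true offset aligns the landmark
  domain <- matrix(0, 80, 80); domain[30:45, 30:45] <- 1
  fluo_shift <- matrix(0, 120, 90)
  fluo_shift[12 + (1:80), 1:80] <- domain
  ov12 <- register_overlay(fluo_shift, domain,
                           registration_transform(xy_scale = 1,
                                                  y_offset = 80 / 2,
                                                  x_offset = 12))
  cen <- function(m) colMeans(which(m > 0.5, arr.ind = TRUE))
  expect_lt(max(abs(cen(ov12$fluorescence) - cen(domain))), 1)
  expect_error(register_overlay(fluo, bril,
                                registration_transform(xy_scale = 1,
                                                       y_offset = 500)),
               "outside")
})

test_that("median projections ignore invalid voxels with the stated tie rule", {
  arr <- array(5.00, c(4, 3, 6))
  arr[2, 2, ] <- c(5.00, 5.10, 5.02, 5.00, NA, 5.04)
  # slab of identical slices returns that slice
  p <- reslice_and_median_project(arr, list(c(1, 4)))
  expect_equal(p[[1]][1, 1], 5.00)
  # median of {5.00, 5.10, 5.02} is 5.02
  p3 <- reslice_and_median_project(arr, list(1:3))
  expect_equal(p3[[1]][2, 2], 5.02)
  # one invalid of three: median of the remaining pair = their mean
  p2 <- reslice_and_median_project(arr, list(4:6))
  expect_equal(p2[[1]][2, 2], (5.00 + 5.04) / 2)
  # fully invalid slab stays invalid
  arr[1, 1, 1:2] <- NA
  expect_true(is.na(reslice_and_median_project(arr, list(1:2))[[1]][1, 1]))
  expect_error(reslice_and_median_project(arr, list(5:9)), "out of range")
})

test_that("ROI statistics follow the mean/sd and median/IQR definitions", {
  m <- matrix(5.05, 6, 6)
  mask <- matrix(FALSE, 6, 6); mask[2:4, 2:4] <- TRUE
  q <- roi_quantify(m, mask, "mean_sd")
  expect_equal(q$stat, 5.05); expect_equal(q$dispersion, 0)
  expect_equal(q$n, 9)
  # order statistics on a known five-point set
  m2 <- matrix(NA_real_, 1, 5)
  m2[1, ] <- c(5.00, 5.01, 5.02, 5.03, 5.04)
  q2 <- roi_quantify(m2, matrix(TRUE, 1, 5), "median_iqr")
  expect_equal(q2$stat, 5.02)
  expect_equal(q2$dispersion, unname(diff(quantile(m2[1, ], c(.25, .75)))))
  # statistics are invariant under voxel permutation within the mask
  perm <- matrix(m2[1, sample(5)], 1, 5)
  expect_equal(roi_quantify(perm, matrix(TRUE, 1, 5), "median_iqr")$stat, q2$stat)
  expect_error(roi_quantify(m, matrix(FALSE, 6, 6)), "empty mask")
})

test_that("relative time series subtract the reference timepoint only", {
  maps <- lapply(c(5.05, 5.055, 5.065), function(v) matrix(v, 4, 4))
  mask <- matrix(TRUE, 4, 4)
  ts <- roi_timeseries(maps, mask, c(0, 10, 20))
  rel <- relative_timeseries(ts, 1)
  expect_equal(rel$stat_ghz, c(0, 0.005, 0.015))
  expect_equal(rel$dispersion_ghz, ts$dispersion_ghz)
  # constant series: all zeros
  cts <- roi_timeseries(lapply(1:3, function(i) matrix(5.05, 2, 2)),
                        matrix(TRUE, 2, 2), 0:2)
  expect_equal(relative_timeseries(cts)$stat_ghz, rep(0, 3))
})

test_that("bead PSF fits recover a known Gaussian width", {
  # closed-form sampled Gaussian: FWHM 1.5 um scanned at 0.1 um steps
  x <- seq(-3, 3, by = 0.1)
  sig <- 1.5 / (2 * sqrt(2 * log(2)))
  y <- 800 * exp(-x^2 / (2 * sig^2)) + 20
  fit <- bead_psf_fwhm(x, y)
  expect_equal(fit$fwhm_um, 1.5, tolerance = 0.05)
  expect_equal(fit$fwhm_um / fit$sigma_um, 2 * sqrt(2 * log(2)),
               tolerance = 1e-9)
  expect_error(bead_psf_fwhm(x, rep(7, length(x))), "flat")
  expect_error(bead_psf_fwhm(x, seq_along(x)), "monotone")
  expect_error(bead_psf_fwhm(1:5, c(1, 2, 5, 2, 1)), "7 samples")
})
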