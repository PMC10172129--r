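# Precision / SNR characterization studies: the virtual analogues of the
# instrument's water-frame precision measurement and of the shot-noise
# (precision ~ 1/sqrt(energy)) scaling analysis.

# 4-neighbour binary erosion of a logical matrix
erode_mask <- function(m) {
  e <- m
  e[-1, ] <- e[-1, ] & m[-nrow(m), ]
  e[-nrow(m), ] <- e[-nrow(m), ] & m[-1, ]
  e[, -1] <- e[, -1] & m[, -ncol(m)]
  e[, -ncol(m)] <- e[, -ncol(m)] & m[, -1]
  e
}

#' Tune the photon budget to a target fitted SNR
#'
#' Finds the photon budget at which the mean fitted Stokes
#' amplitude-to-residual-sd ratio of pipeline-processed water spectra
#' matches a target (the instrument's operating condition is a ratio of
#' about 10).  Secant-style iteration on pilot frames; the empirical
#' budget-to-ratio exponent of the forward model (~0.6, between the pure
#' shot-noise 0.5 and the read-noise 1.0 limits) sets the update step.
#'
#' @param config A [spectrometer_config()].
#' @param calib A [calibration_model()].
#' @param target_ratio Target amplitude/residual-sd ratio (default 10).
#' @param seed Integer seed for the pilot frames.
#' @param budget0 Starting budget in photons/order (default 100).
#' @param pilot_rows Rows per pilot frame used (default 12).
#' @param n_iter Pilot iterations (default 4).
#' @return List with `photon_budget` and `achieved_ratio`.
#' @export
tune_photon_budget <- function(config, calib, target_ratio = 10, seed = 1,
                               budget0 = 100, pilot_rows = 12, n_iter = 4) {
  phantom <- water_phantom_line(config$line_length)
  seeds <- child_seeds(seed, n_iter)
  pb <- budget0
  ratio <- NA_real_
  for (it in seq_len(n_iter)) {
    fr <- simulate_frame(phantom, config, pb, rng_seed = seeds[[it]])
    m <- process_frame(fr, calib)
    r <- m$snr_ratio[m$valid & is.finite(m$snr_ratio)]
    ratio <- mean(utils::head(r, pilot_rows))
    pb <- pb * (target_ratio / ratio)^(1 / 0.6)
  }
  list(photon_budget = pb, achieved_ratio = ratio)
}

#' Water-frame spectral precision study
#'
#' The virtual analogue of the instrument precision measurement: simulate
#' repeated spectrometer frames (lines) of a homogeneous water phantom,
#' run the full remap-sum-fit pipeline on every row, select the spectra
#' from the centre of the field of view, and report one averaged shift per
#' frame.  The spectral precision is the sample standard deviation of the
#' per-frame shifts, in MHz.
#'
#' @param config A [spectrometer_config()].
#' @param calib A [calibration_model()]; calibrated internally if NULL.
#' @param photon_budget Photons per order per spectrum.
#' @param n_frames Number of frames (default 50).
#' @param center_rows Number of central rows selected per frame
#'   (default 16).
#' @param shift,linewidth Water ground truth (GHz).
#' @param seed Integer seed.
#' @return List with `per_frame_shift` (GHz), `precision_mhz`,
#'   `mean_snr_ratio`, `mean_snr_db`, `n_frames`.
#' @export
precision_study <- function(config = spectrometer_config(), calib = NULL,
                            photon_budget = 80, n_frames = 50,
                            center_rows = 16, shift = 5.05, linewidth = 0.4,
                            seed = 1) {
  if (is.null(calib))
    calib <- calibrate_frame(simulate_calibration_frame(config),
                             expected_orders = config$n_orders_visible)
  phantom <- water_phantom_line(config$line_length, shift, linewidth)
  lo <- max(1, floor((config$line_length - center_rows) / 2) + 1)
  hi <- min(config$line_length, lo + center_rows - 1)
  seeds <- child_seeds(seed, n_frames)
  per_frame <- vapply(seeds, function(s) {
    fr <- simulate_frame(phantom, config, photon_budget, rng_seed = s)
    m <- process_frame(fr, calib)
    sel <- m$valid & m$row >= lo & m$row <= hi
    c(mean(m$shift[sel]), mean(m$snr_ratio[sel & is.finite(m$snr_ratio)]))
  }, numeric(2))
  ratios <- per_frame[2, ]
  list(per_frame_shift = per_frame[1, ],
       precision_mhz = measure_precision(per_frame[1, ]),
       mean_snr_ratio = mean(ratios, na.rm = TRUE),
       mean_snr_db = 20 * log10(mean(ratios, na.rm = TRUE)),
       n_frames = n_frames)
}

#' Shot-noise scaling of spectral precision
#'
#' Measures the per-spectrum shift precision at several photon budgets and
#' regresses log10(precision) on log10(budget).  Under shot-noise-limited
#' conditions the slope is -1/2 (precision falls as the square root of the
#' detected energy); read noise steepens the apparent slope at low budgets,
#' so the study runs with read noise disabled by default.
#'
#' @param config A [spectrometer_config()] (its camera read noise is
#'   zeroed unless `keep_read_noise`).
#' @param budgets Photon budgets spanning at least one decade.
#' @param n_rows Spectra per budget (default 48: one frame).
#' @param seed Integer seed.
#' @param keep_read_noise Keep the configured read noise (default FALSE).
#' @return List with `budgets`, `precision_mhz`, `slope`.
#' @export
shot_noise_scaling <- function(config = spectrometer_config(),
                               budgets = c(100, 180, 320, 560, 1000),
                               n_rows = 150, seed = 1,
                               keep_read_noise = FALSE) {
  if (!keep_read_noise)
    config$camera$read_noise <- 0
  config$line_length <- n_rows
  calib <- calibrate_frame(simulate_calibration_frame(config),
                           expected_orders = config$n_orders_visible)
  phantom <- water_phantom_line(n_rows)
  seeds <- child_seeds(seed, length(budgets))
  prec <- vapply(seq_along(budgets), function(i) {
    fr <- simulate_frame(phantom, config, budgets[i], rng_seed = seeds[[i]])
    m <- process_frame(fr, calib)
    measure_precision(m$shift[m$valid])
  }, numeric(1))
  slope <- stats::coef(stats::lm(log10(prec) ~ log10(budgets)))[[2]]
  list(budgets = budgets, precision_mhz = prec, slope = slope)
}

#' End-to-end folding-phantom recovery study
#'
#' Full-pipeline integration study: a two-timepoint embryo-like phantom
#' with a folding domain whose Brillouin shift ramps up by `delta_shift`
#' is imaged frame by frame, calibrated, reconstructed, rescaled to the
#' fluorescence pixel grid, registered with the fluorescence channel that
#' carries the domain geometry, and quantified as a masked relative time
#' series.  Recovery of the injected shift increase validates every stage
#' jointly.
#'
#' @param config A [spectrometer_config()]; its `line_length` sets the
#'   phantom x extent.
#' @param n_lines Scan positions in y (default 10).
#' @param delta_shift Injected shift increase in GHz (default 0.015).
#' @param photon_budget Photons per order per spectrum (default 800).
#' @param transform A [registration_transform()] (default: the 2.5138
#'   rescale with a centred crop).
#' @param erode_px Erode the fluorescence-derived ROI by this many pixels
#'   before quantification (default 2), so the statistic samples the
#'   domain interior rather than boundary voxels blurred by the bilinear
#'   rescale.
#' @param seed Integer seed.
#' @return List with `recovered_delta_mhz`, `truth_delta_mhz`,
#'   `timeseries`, `n_roi_voxels`.
#' @export
folding_phantom_study <- function(config = spectrometer_config(line_length = 32),
                                  n_lines = 10, delta_shift = 0.015,
                                  photon_budget = 800,
                                  transform = registration_transform(y_offset = NULL),
                                  erode_px = 2, seed = 1) {
  nx <- config$line_length
  base <- brillouin_phantom(matrix(5.05, nx, n_lines),
                            voxel_size = c(config$spatial_sampling, 1.5))
  mask <- matrix(FALSE, nx, n_lines)
  mask[seq(max(1, nx / 2 - nx / 4), min(nx, nx / 2 + nx / 4)),
       seq(max(1, n_lines / 2 - n_lines / 4),
           min(n_lines, n_lines / 2 + n_lines / 4))] <- TRUE
  timepoints <- c(0, 30)
  ph4 <- simulate_timelapse_phantom(base, mask, delta_shift, timepoints,
                                    fluorescence_scale = transform$xy_scale)
  calib <- calibrate_frame(simulate_calibration_frame(config),
                           expected_orders = config$n_orders_visible)
  seeds <- child_seeds(seed, 2 * n_lines)
  maps <- lapply(seq_along(timepoints), function(t) {
    lines <- lapply(seq_len(n_lines), function(yix) {
      line <- list(shift = ph4$shift[, yix, t],
                   linewidth = ph4$linewidth[, yix, t],
                   reflectivity = ph4$reflectivity[, yix, t])
      fr <- simulate_frame(line, config, photon_budget,
                           rng_seed = seeds[[(t - 1) * n_lines + yix]])
      process_frame(fr, calib)
    })
    vol <- assemble_volume(lines, seq_len(n_lines) * 1.5,
                           spatial_sampling = config$spatial_sampling)
    m <- vol$shift
    m[!vol$valid] <- NA_real_
    rescale_to_fluorescence(m, transform)
  })
  # registration: the fluorescence channel carries the domain geometry at
  # the fluorescence pixel size; a centred overlay recovers the ROI mask
  ov <- register_overlay(ph4$fluorescence[, , 1], maps[[1]], transform)
  roi <- ov$fluorescence > 0.5
  for (i in seq_len(erode_px)) roi <- erode_mask(roi)
  ts <- roi_timeseries(maps, roi, timepoints, statistic = "mean_sd")
  rel <- relative_timeseries(ts, t0_index = 1)
  list(recovered_delta_mhz = rel$stat_ghz[nrow(rel)] * 1000,
       truth_delta_mhz = delta_shift * 1000,
       timeseries = rel, n_roi_voxels = ts$n_voxels[1])
}
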