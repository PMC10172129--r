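# The three-step spectral pipeline: remap each VIPA order onto a common
# linear frequency axis (cubic spline), sum >= 3 orders, and fit the Stokes
# and anti-Stokes peaks separately.  Also the characterization metrics:
# spectral precision, SNR and spectral resolution.

#' A spectrum on a uniform signed frequency grid
#'
#' Frequencies are signed GHz relative to the laser line: the Stokes peak
#' sits at -shift, the anti-Stokes peak at +shift, the Rayleigh line at 0.
#'
#' @param freq_grid Strictly increasing, uniform frequency grid (GHz).
#' @param intensity Intensities (same length; may contain NA where an edge
#'   order did not cover the grid).
#' @param n_orders_summed Number of orders summed into this spectrum.
#' @param source_row Originating spatial row index (optional).
#' @param truncated TRUE when part of the grid fell outside the source
#'   order's valid pixel range.
#' @return An object of class `linear_spectrum`.
#' @export
linear_spectrum <- function(freq_grid, intensity, n_orders_summed = 1L,
                            source_row = NA_integer_, truncated = FALSE) {
  if (length(freq_grid) != length(intensity))
    stop("intensity length must equal grid length", call. = FALSE)
  df <- diff(freq_grid)
  if (any(df <= 0) || (length(df) > 1 && max(abs(df - df[1])) > 1e-9))
    stop("freq_grid must be strictly increasing and uniform", call. = FALSE)
  structure(list(freq_grid = freq_grid, intensity = intensity,
                 n_orders_summed = as.integer(n_orders_summed),
                 source_row = source_row, truncated = truncated),
            class = "linear_spectrum")
}

#' Remap one spectral row into linear frequency space, per order
#'
#' Converts each calibrated order of a raw camera row onto a common uniform
#' signed-frequency grid spanning (-FSR/2, FSR/2) by cubic spline
#' interpolation.  Grid samples that coincide with source pixels pass
#' through unchanged (the spline interpolates its knots exactly); grid
#' samples outside an order's valid pixel range are NA and flag the
#' spectrum as truncated.
#'
#' @param frame_row Counts of one spatial row (vector).
#' @param calib A [calibration_model()].
#' @param target_df Target frequency sampling in GHz per grid step,
#'   within \[0.1, 1\] (default 0.1).
#' @param orders Orders to remap (default: all calibrated orders).
#' @return List of [linear_spectrum()], one per order.
#' @export
remap_to_linear <- function(frame_row, calib, target_df = 0.1,
                            orders = NULL) {
  stopifnot(inherits(calib, "calibration_model"))
  if (target_df < 0.1 || target_df > 1)
    stop("target_df must be within [0.1, 1] GHz", call. = FALSE)
  y <- as.numeric(frame_row)
  if (is.null(orders)) orders <- seq_along(calib$order_anchors)
  # leave a two-pixel margin at the order edges: integer-pixel coverage of
  # an order loses up to one pixel per edge to rounding, and the anchor's
  # sub-pixel phase can shift coverage by up to one more
  gmax <- floor((calib$fsr / 2 - 2 * calib$slope) / target_df) * target_df
  grid <- seq(-gmax, gmax, by = target_df)
  lapply(orders, function(k) {
    rng <- order_pixel_range(calib, k)
    px <- seq(ceiling(rng[1]), floor(rng[2]))
    freq_px <- pixel_to_frequency(calib, k, px)
    sp <- stats::splinefun(freq_px, y[px], method = "fmm")
    inside <- grid >= min(freq_px) & grid <= max(freq_px)
    intens <- rep(NA_real_, length(grid))
    intens[inside] <- sp(grid[inside])
    truncated <- !all(inside)
    if (truncated)
      warning(sprintf("order %d covers only [%.2f, %.2f] GHz of the target grid",
                      k, min(freq_px), max(freq_px)), call. = FALSE)
    linear_spectrum(grid, intens, n_orders_summed = 1L, truncated = truncated)
  })
}

#' Sum remapped spectra from several VIPA orders
#'
#' Sample-wise sum of order spectra defined on the identical grid; summing
#' at least three orders raises the effective signal-to-noise ratio since
#' the photon noise of different orders is independent.
#'
#' @param order_spectra List of [linear_spectrum()] on one common grid.
#' @param min_orders Minimum number of orders (default 3).
#' @param strict Error when fewer than `min_orders` spectra are given
#'   (default); otherwise warn and sum what is available.
#' @return A [linear_spectrum()] with `n_orders_summed` recorded.
#' @export
sum_orders <- function(order_spectra, min_orders = 3, strict = TRUE) {
  stopifnot(length(order_spectra) >= 1)
  grids <- lapply(order_spectra, `[[`, "freq_grid")
  for (g in grids[-1])
    if (length(g) != length(grids[[1]]) || max(abs(g - grids[[1]])) > 1e-9)
      stop("order spectra are not on the identical grid", call. = FALSE)
  if (length(order_spectra) < min_orders) {
    msg <- sprintf("summing %d order(s); configured minimum is %d",
                   length(order_spectra), min_orders)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  total <- Reduce(`+`, lapply(order_spectra, `[[`, "intensity"))
  linear_spectrum(grids[[1]], total,
                  n_orders_summed = length(order_spectra),
                  source_row = order_spectra[[1]]$source_row,
                  truncated = any(vapply(order_spectra, `[[`, logical(1),
                                         "truncated")))
}

# ---- peak fitting ----------------------------------------------------------

invalid_peak <- function(reason) {
  structure(list(kind = NA_character_, amplitude = NA_real_,
                 center = NA_real_, fwhm = NA_real_, background = NA_real_,
                 r_squared = NA_real_, residual_sd = NA_real_,
                 n_iterations = NA_integer_, converged = FALSE,
                 valid = FALSE, reason = reason), class = "peak_fit")
}

# weighted least-squares fit of one peak over `freq`/`intens`
fit_single_peak <- function(freq, intens, model_kind, instrument_sigma = 0.3,
                            r2_threshold = 0.5, weights = NULL,
                            max_iterations = 100, tol = 1e-8) {
  ok <- is.finite(intens)
  freq <- freq[ok]; intens <- intens[ok]
  if (length(freq) < 5) return(invalid_peak("fewer than 5 samples in range"))
  baseline <- min(intens)
  a0 <- max(intens) - baseline
  if (a0 <= 0) return(invalid_peak("no peak in range"))
  c0 <- freq[which.max(intens)]
  g0 <- diff(range(freq)) / 2
  step <- freq[2] - freq[1]
  if (is.null(weights)) weights <- rep(1, length(freq))
  env <- new.env()
  model <- switch(model_kind,
    lorentzian = intens ~ lorentzian_profile(freq, A, c, G),
    lorentzian_quadratic =
      intens ~ lorentzian_profile(freq, A, c, G) + b0 + b1 * freq,
    broadened = {
      assign("sig", instrument_sigma, envir = env)
      intens ~ broadened_brillouin_profile(freq, A, c, G,
                                           kernel = list(type = "gaussian",
                                                         sigma = sig))
    },
    stop("unknown model kind: ", model_kind, call. = FALSE))
  start <- list(A = a0, c = c0, G = g0)
  lower <- c(A = 0, c = min(freq), G = step / 4)
  upper <- c(A = Inf, c = max(freq), G = 4 * diff(range(freq)))
  if (model_kind == "lorentzian_quadratic") {
    start <- c(start, list(b0 = baseline, b1 = 0))
    lower <- c(lower, b0 = -Inf, b1 = -Inf)
    upper <- c(upper, b0 = Inf, b1 = Inf)
  }
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(model, start = start, lower = lower, upper = upper,
                      weights = weights,
                      data = list2env(list(freq = freq, intens = intens), env),
                      control = minpack.lm::nls.lm.control(
                        maxiter = max_iterations, ftol = tol, ptol = tol))),
    error = function(e) NULL)
  if (is.null(fit)) return(invalid_peak("fit did not converge"))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / max(sum((intens - mean(intens))^2), 1e-300)
  niter <- fit$convInfo$finIter %||% NA_integer_
  converged <- isTRUE(fit$convInfo$isConv) || is.null(fit$convInfo)
  pinned <- cf[["c"]] <= min(freq) + step / 2 || cf[["c"]] >= max(freq) - step / 2
  valid <- converged && !pinned && r2 >= r2_threshold
  reason <- if (valid) NA_character_
    else if (pinned) "center pinned to range edge"
    else if (!converged) "no convergence"
    else sprintf("goodness of fit R^2 = %.3f below threshold", r2)
  structure(list(kind = model_kind, amplitude = cf[["A"]],
                 center = cf[["c"]], fwhm = cf[["G"]],
                 background = if ("b0" %in% names(cf)) cf[["b0"]] else 0,
                 r_squared = r2, residual_sd = stats::sd(res),
                 n_iterations = niter, converged = converged,
                 valid = valid, reason = reason), class = "peak_fit")
}

#' Default Stokes / anti-Stokes fit ranges
#'
#' Stokes range `[-FSR/2 + margin, -inner]`, anti-Stokes range
#' `[inner, FSR/2 - margin]`; user-overridable in [fit_spectrum()].
#'
#' @param fsr Free spectral range (GHz).
#' @param inner Inner edge excluding the Rayleigh region (default 2 GHz).
#' @param margin Outer margin at the order boundary (default 0.2 GHz).
#' @return List with `stokes` and `antistokes` interval pairs.
#' @export
default_fit_ranges <- function(fsr = 15.15, inner = 2, margin = 0.2) {
  list(stokes = c(-fsr / 2 + margin, -inner),
       antistokes = c(inner, fsr / 2 - margin))
}

#' Fit the Stokes and anti-Stokes peaks of a spectrum
#'
#' Runs an independent least-squares peak fit on the negative-frequency
#' (Stokes) and positive-frequency (anti-Stokes) ranges.  Initial values:
#' centre at the range argmax, width half the range, amplitude max minus
#' baseline.  Convergence at relative tolerance 1e-8 or 100 iterations;
#' non-convergence or a centre pinned to a range edge flags the fit invalid
#' rather than raising an error.
#'
#' @param spectrum A [linear_spectrum()].
#' @param model_kind One of "lorentzian", "lorentzian_quadratic",
#'   "broadened".
#' @param fit_ranges List with `stokes` and `antistokes` GHz intervals
#'   (default [default_fit_ranges()] for the spectrum's span).
#' @param instrument_sigma Gaussian kernel sigma for the broadened model.
#' @param r2_threshold Minimum R^2 for a valid fit (default 0.5).
#' @param weighted Use inverse-variance (shot noise) weights (default
#'   FALSE: unweighted least squares).
#' @return List with `stokes` and `antistokes` peak-fit objects.
#' @export
fit_spectrum <- function(spectrum, model_kind = "lorentzian",
                         fit_ranges = NULL, instrument_sigma = 0.3,
                         r2_threshold = 0.5, weighted = FALSE) {
  stopifnot(inherits(spectrum, "linear_spectrum"))
  if (is.null(fit_ranges))
    fit_ranges <- default_fit_ranges(2 * max(spectrum$freq_grid) +
                                       diff(spectrum$freq_grid[1:2]))
  one <- function(rng) {
    sel <- spectrum$freq_grid >= rng[1] & spectrum$freq_grid <= rng[2]
    fr <- spectrum$freq_grid[sel]
    it <- spectrum$intensity[sel]
    w <- if (weighted) 1 / pmax(it, 1) else NULL
    fit_single_peak(fr, it, model_kind, instrument_sigma, r2_threshold, w)
  }
  list(stokes = one(fit_ranges$stokes), antistokes = one(fit_ranges$antistokes))
}

#' Combine Stokes and anti-Stokes fits into the reported shift
#'
#' The reported Brillouin shift is the average of the absolute Stokes and
#' anti-Stokes centre frequencies; the linewidth is averaged likewise.
#' When exactly one fit is valid the measurement falls back to it and is
#' flagged; when both are invalid the measurement is invalid.
#'
#' @param stokes,antistokes Peak-fit objects from [fit_spectrum()].
#' @return List with `shift` (GHz), `linewidth` (GHz), `valid`, `fallback`.
#' @export
compute_shift <- function(stokes, antistokes) {
  sv <- isTRUE(stokes$valid); av <- isTRUE(antistokes$valid)
  if (!sv && !av)
    return(list(shift = NA_real_, linewidth = NA_real_, valid = FALSE,
                fallback = FALSE))
  if (sv && av)
    return(list(shift = (abs(stokes$center) + abs(antistokes$center)) / 2,
                linewidth = (stokes$fwhm + antistokes$fwhm) / 2,
                valid = TRUE, fallback = FALSE))
  f <- if (sv) stokes else antistokes
  list(shift = abs(f$center), linewidth = f$fwhm, valid = TRUE,
       fallback = TRUE)
}

#' Signal-to-noise ratio of a fitted peak
#'
#' Ratio of the fitted peak amplitude to the standard deviation of the fit
#' residuals over the fit range, reported in dB with the amplitude
#' convention `20 log10(amplitude / residual sd)`.  A perfect noiseless
#' fit (zero residual sd) reports `Inf`.
#'
#' @param fit A peak-fit object.
#' @return List with `ratio` and `db`.
#' @export
compute_snr <- function(fit) {
  if (!isTRUE(fit$valid) || !is.finite(fit$amplitude))
    return(list(ratio = NA_real_, db = NA_real_))
  if (!is.finite(fit$residual_sd) || fit$residual_sd < 1e-12)
    return(list(ratio = Inf, db = Inf))
  r <- fit$amplitude / fit$residual_sd
  list(ratio = r, db = 20 * log10(r))
}

#' Process a full spectrometer frame into per-row measurements
#'
#' Applies remap, order summation and separate Stokes/anti-Stokes fitting
#' to every spatial row of a frame.  Rows are processed independently, so
#' the result is invariant to row ordering (the parallelizable contract);
#' per-row fit failures are flagged in the output, never aborting the
#' frame.
#'
#' @param frame A [spectral_frame()].
#' @param calib A [calibration_model()].
#' @param fit_config List of pipeline settings: `model_kind`, `target_df`,
#'   `fit_ranges`, `min_orders`, `instrument_sigma`, `r2_threshold`,
#'   `weighted` (all optional).
#' @return Data frame with one row per spatial row: `row`, `shift`,
#'   `linewidth`, `amplitude`, `snr_ratio`, `snr_db`, `r2_stokes`,
#'   `r2_antistokes`, `iterations`, `valid`, `fallback`.
#' @export
process_frame <- function(frame, calib, fit_config = list()) {
  stopifnot(inherits(frame, "spectral_frame"))
  fc <- utils::modifyList(list(model_kind = "lorentzian", target_df = 0.1,
                               fit_ranges = NULL, min_orders = 3,
                               instrument_sigma = 0.3, r2_threshold = 0.5,
                               weighted = FALSE), fit_config)
  rows <- seq_len(nrow(frame$counts))
  out <- lapply(rows, function(i)
    process_row(frame$counts[i, ], calib, fc, row = i))
  do.call(rbind, out)
}

# single-row reference path; process_frame is defined as one call of this
# per row, which is what makes the batch path trivially order-invariant
process_row <- function(frame_row, calib, fc, row = NA_integer_) {
  meas <- tryCatch({
    spectra <- suppressWarnings(
      remap_to_linear(frame_row, calib, target_df = fc$target_df))
    complete <- vapply(spectra, function(s) !s$truncated, logical(1))
    use <- if (any(complete)) spectra[complete] else spectra
    summed <- sum_orders(use, min_orders = fc$min_orders, strict = FALSE)
    fits <- fit_spectrum(summed, model_kind = fc$model_kind,
                         fit_ranges = fc$fit_ranges,
                         instrument_sigma = fc$instrument_sigma,
                         r2_threshold = fc$r2_threshold,
                         weighted = fc$weighted)
    cs <- compute_shift(fits$stokes, fits$antistokes)
    snr <- compute_snr(fits$stokes)
    data.frame(row = row, shift = cs$shift, linewidth = cs$linewidth,
               amplitude = fits$stokes$amplitude,
               snr_ratio = snr$ratio, snr_db = snr$db,
               r2_stokes = fits$stokes$r_squared,
               r2_antistokes = fits$antistokes$r_squared,
               iterations = max(fits$stokes$n_iterations,
                                fits$antistokes$n_iterations, na.rm = TRUE),
               valid = cs$valid, fallback = cs$fallback)
  }, error = function(e)
    data.frame(row = row, shift = NA_real_, linewidth = NA_real_,
               amplitude = NA_real_, snr_ratio = NA_real_, snr_db = NA_real_,
               r2_stokes = NA_real_, r2_antistokes = NA_real_,
               iterations = NA_integer_, valid = FALSE, fallback = FALSE))
  meas
}

#' Spectral precision of repeated shift measurements
#'
#' Sample standard deviation of repeated Brillouin shift measurements of a
#' homogeneous sample, reported in MHz.
#'
#' @param repeated_shifts Numeric vector of shifts in GHz (>= 2 values).
#' @return Precision in MHz.
#' @export
measure_precision <- function(repeated_shifts) {
  x <- repeated_shifts[is.finite(repeated_shifts)]
  if (length(x) < 2)
    stop("need at least 2 shift measurements", call. = FALSE)
  stats::sd(x) * 1000
}

#' Spectral resolution from the Rayleigh line
#'
#' FWHM of a Lorentzian fitted to the elastic (Rayleigh) signal of a
#' remapped-and-summed spectrum; requires a visible elastic peak (notch
#' disabled or a strongly scattering sample).
#'
#' @param spectrum A [linear_spectrum()] with a strong elastic peak near 0.
#' @param window Half-width of the Rayleigh fit window in GHz (default 2).
#' @return List with `fwhm_ghz` and `reliable` (FALSE when the peak is
#'   sampled by fewer than 4 points above half maximum).
#' @export
measure_spectral_resolution <- function(spectrum, window = 2) {
  stopifnot(inherits(spectrum, "linear_spectrum"))
  sel <- abs(spectrum$freq_grid) <= window & is.finite(spectrum$intensity)
  fr <- spectrum$freq_grid[sel]; it <- spectrum$intensity[sel]
  if (length(fr) < 5 || max(it) - min(it) <= 1e-9 * max(abs(it), 1))
    data_error("no elastic peak found near 0 GHz")
  fit <- fit_single_peak(fr, it, "lorentzian", r2_threshold = 0)
  if (!isTRUE(fit$converged) || !is.finite(fit$fwhm))
    data_error("no elastic peak could be fitted near 0 GHz")
  n_above <- sum(it > max(it) / 2)
  list(fwhm_ghz = fit$fwhm, reliable = n_above >= 4, fit = fit)
}
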