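# Forward model of the VIPA spectrometer: multi-order dispersion, Rb notch,
# instrument broadening, photon statistics.  This is the ground-truth
# generator the reconstruction pipeline is validated against.

# ---- dispersion truth ------------------------------------------------------

# pixel pitch between adjacent order anchors
order_pitch_px <- function(config) config$fsr / config$spectral_sampling

# Rayleigh (elastic, 0 GHz) anchor pixel position per visible order
anchor_pixels_truth <- function(config) {
  pitch <- order_pitch_px(config)
  0.6 * pitch + (seq_len(config$n_orders_visible) - 1) * pitch
}

n_pixels_truth <- function(config) {
  pitch <- order_pitch_px(config)
  ceiling(max(anchor_pixels_truth(config)) + 0.6 * pitch)
}

# effective linear slope: with a quadratic term q the slope is adjusted so
# that the frequency at the next anchor (dp = pitch) is exactly one FSR,
# keeping the dispersion law FSR-periodic at the anchors
dispersion_slope_truth <- function(config) {
  pitch <- order_pitch_px(config)
  (config$fsr - config$dispersion_nonlinearity * pitch^2) / pitch
}

# signed frequency (GHz, relative to the nearest order's Rayleigh anchor)
# of every pixel, plus the order index each pixel belongs to
pixel_frequency_truth <- function(config, pixels) {
  anchors <- anchor_pixels_truth(config)
  pitch <- order_pitch_px(config)
  s <- dispersion_slope_truth(config)
  q <- config$dispersion_nonlinearity
  k <- pmax(1L, pmin(length(anchors),
                     as.integer(round((pixels - anchors[1]) / pitch)) + 1L))
  dp <- pixels - anchors[k]
  list(order = k, freq = s * dp + q * dp^2)
}

# ---- spectral content ------------------------------------------------------

#' Apply the rubidium notch filter to a spectrum
#'
#' Multiplies a spectrum sampled on a GHz grid by the notch transmission
#' \eqn{\exp(-OD \cdot g(\nu))}, where g is a Gaussian (Doppler) absorption
#' profile of unit peak per configured line centre.  Transmission at a line
#' centre is exactly `exp(-optical_depth)`.
#'
#' @param counts Spectrum intensities.
#' @param freq_grid Frequencies (GHz) of `counts`, relative to the laser.
#' @param notch A [notch_config()].
#' @return Filtered intensities.
#' @export
apply_rb_notch <- function(counts, freq_grid, notch) {
  stopifnot(inherits(notch, "notch_config"), length(counts) == length(freq_grid))
  if (notch$optical_depth == 0) return(counts)
  sigma <- notch$doppler_fwhm / (2 * sqrt(2 * log(2)))
  od <- rep(0, length(freq_grid))
  for (c0 in notch$line_centers)
    od <- od + notch$optical_depth * exp(-(freq_grid - c0)^2 / (2 * sigma^2))
  counts * exp(-od)
}

#' Apply camera noise to a noiseless photon image
#'
#' Poisson photon statistics scaled by the camera gain, plus additive
#' Gaussian read noise, rounded to integer counts and clipped to
#' `[0, full_well]`.
#'
#' @param noiseless Expected photon numbers (>= 0), vector or matrix.
#' @param camera A [camera_config()].
#' @param rng_seed Integer seed (reproducible); `NULL` uses the current RNG.
#' @return Integer-valued counts with the shape of `noiseless`.
#' @export
apply_camera_noise <- function(noiseless, camera, rng_seed = NULL) {
  stopifnot(inherits(camera, "camera_config"))
  if (any(noiseless < 0)) stop("noiseless must be >= 0", call. = FALSE)
  with_seed(rng_seed, {
    n <- length(noiseless)
    counts <- camera$gain * stats::rpois(n, as.vector(noiseless)) +
      stats::rnorm(n, 0, camera$read_noise)
    counts <- pmin(camera$full_well, pmax(0, round(counts)))
    if (is.matrix(noiseless))
      matrix(counts, nrow(noiseless), ncol(noiseless)) else counts
  })
}

# Expected photons per pixel for one spectral component set.
# `components`: data.frame(center GHz, fwhm GHz, amplitude rel. units,
# shape "lorentzian"|"gaussian").  Brillouin peaks are Lorentzian; elastic
# lines (laser-linewidth narrow) are Gaussian so they carry no unphysical
# power-law tails.  Amplitudes are intrinsic peak photon numbers per pixel
# before instrument broadening; broadening is area-preserving.
row_expected_photons <- function(components, config, notch_on = TRUE,
                                 fine_df = 0.005) {
  fsr <- config$fsr
  pad <- 6 * config$instrument_sigma + 2
  fine <- seq(-fsr / 2 - pad, fsr / 2 + pad, by = fine_df)
  y <- rep(0, length(fine))
  if (is.null(components$shape)) components$shape <- "lorentzian"
  for (i in seq_len(nrow(components))) {
    for (m in -1:1) {          # wrapped copies from the adjacent orders
      ctr <- components$center[i] + m * fsr
      if (ctr > min(fine) - 5 && ctr < max(fine) + 5) {
        y <- y + if (components$shape[i] == "gaussian") {
          sg <- components$fwhm[i] / (2 * sqrt(2 * log(2)))
          components$amplitude[i] * exp(-(fine - ctr)^2 / (2 * sg^2))
        } else
          lorentzian_profile(fine, components$amplitude[i], ctr,
                             components$fwhm[i])
      }
    }
  }
  if (notch_on) {
    centers <- config$notch$line_centers
    nt <- notch_config(line_centers = unique(c(centers, centers + fsr,
                                               centers - fsr)),
                       optical_depth = config$notch$optical_depth,
                       doppler_fwhm = config$notch$doppler_fwhm)
    y <- apply_rb_notch(y, fine, nt)
  }
  if (config$instrument_sigma > 0) {
    sg <- config$instrument_sigma
    kern <- stats::dnorm(seq(-5 * sg, 5 * sg, by = fine_df), 0, sg)
    kern <- kern / sum(kern)
    yc <- stats::filter(y, kern, sides = 2)
    ok <- !is.na(yc)
    fine <- fine[ok]; y <- as.numeric(yc[ok])
  }
  px <- seq_len(n_pixels_truth(config))
  pf <- pixel_frequency_truth(config, px)
  stats::approx(fine, y, xout = pf$freq, rule = 2)$y
}

rayleigh_intrinsic_fwhm <- 0.02  # GHz; effective elastic-line intrinsic width

# intrinsic peak-amplitude (photons/px) of the Stokes line such that the
# Stokes + anti-Stokes photons of ONE order sum to `photon_budget`
stokes_amplitude_from_budget <- function(photon_budget, linewidth, config) {
  photon_budget * config$spectral_sampling / (pi * linewidth)
}

#' Simulate the spectrum of one spatial row
#'
#' Places the Rayleigh line plus Stokes (at -shift) and anti-Stokes
#' (at +shift) Brillouin peaks in every visible VIPA order, applies the
#' rubidium notch and the Gaussian instrument broadening, and maps the
#' result through the per-order dispersion law onto camera pixels.
#'
#' @param material List with `shift` (GHz), `linewidth` (GHz) and
#'   `reflectivity` (pre-notch Rayleigh/Stokes peak ratio).
#' @param config A [spectrometer_config()].
#' @param photon_budget Expected detected Brillouin (Stokes + anti-Stokes)
#'   photons per order (> 0).
#' @param rng_seed Integer seed for the photon noise; `NULL` for the
#'   noiseless channel only.
#' @param notch_on Apply the Rb notch (default TRUE).
#' @return List with `noiseless` (expected counts) and `noisy` (counts with
#'   camera noise; `NULL` when `rng_seed` is `NULL`).
#' @export
simulate_row_spectrum <- function(material, config, photon_budget,
                                  rng_seed = NULL, notch_on = TRUE) {
  stopifnot(inherits(config, "spectrometer_config"))
  if (photon_budget <= 0) stop("photon_budget must be > 0", call. = FALSE)
  shift <- material$shift
  if (shift <= 0 || shift >= config$fsr / 2 - 1)
    stop(sprintf(
      "Brillouin peaks at %.2f GHz fall outside the unambiguous range for FSR %.2f GHz",
      shift, config$fsr), call. = FALSE)
  amp <- stokes_amplitude_from_budget(photon_budget, material$linewidth, config)
  comp <- data.frame(
    center = c(0, -shift, shift),
    fwhm = c(rayleigh_intrinsic_fwhm, material$linewidth, material$linewidth),
    amplitude = c(material$reflectivity * amp, amp, amp),
    shape = c("gaussian", "lorentzian", "lorentzian"))
  photons <- row_expected_photons(comp, config, notch_on = notch_on)
  noiseless <- config$camera$gain * photons
  noisy <- if (!is.null(rng_seed))
    apply_camera_noise(photons, config$camera, rng_seed) else NULL
  list(noiseless = noiseless, noisy = noisy)
}

#' A raw spectrometer frame
#'
#' @param counts Matrix, spatial row x spectral pixel, non-negative.
#' @param exposure Exposure time in seconds.
#' @param metadata Named list of acquisition tags.
#' @return An object of class `spectral_frame`.
#' @export
spectral_frame <- function(counts, exposure = 0.1, metadata = list()) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(counts = counts, exposure = exposure, metadata = metadata),
            class = "spectral_frame")
}

#' Simulate a full spectrometer frame from a phantom line
#'
#' One [simulate_row_spectrum()] per spatial row; rows are statistically
#' independent.  Noiseless spectra are cached per unique material so that
#' homogeneous phantoms cost a single forward evaluation.
#'
#' @param phantom_line A 1D [brillouin_phantom()] (or list of vectors
#'   `shift`, `linewidth`, `reflectivity`) whose length equals the
#'   configured `line_length`.
#' @param config A [spectrometer_config()].
#' @param photon_budget Brillouin photons per order per row.
#' @param rng_seed Integer seed; `NULL` yields the noiseless frame.
#' @return A [spectral_frame()]; `metadata$truth` carries the ground truth,
#'   `metadata$noiseless` the expected counts.
#' @export
simulate_frame <- function(phantom_line, config, photon_budget,
                           rng_seed = NULL) {
  stopifnot(inherits(config, "spectrometer_config"))
  shift <- as.vector(phantom_line$shift)
  lw <- as.vector(phantom_line$linewidth)
  rf <- as.vector(phantom_line$reflectivity)
  n_rows <- length(shift)
  if (n_rows != config$line_length)
    stop(sprintf("phantom line length (%d) must equal configured line_length (%d)",
                 n_rows, config$line_length), call. = FALSE)
  key <- paste(shift, lw, rf)
  cache <- new.env(parent = emptyenv())
  noiseless <- matrix(0, n_rows, n_pixels_truth(config))
  for (i in seq_len(n_rows)) {
    if (is.null(cache[[key[i]]]))
      cache[[key[i]]] <- simulate_row_spectrum(
        list(shift = shift[i], linewidth = lw[i], reflectivity = rf[i]),
        config, photon_budget)$noiseless
    noiseless[i, ] <- cache[[key[i]]]
  }
  counts <- if (is.null(rng_seed)) noiseless else
    apply_camera_noise(noiseless / config$camera$gain, config$camera, rng_seed)
  spectral_frame(counts, exposure = config$camera$exposure,
                 metadata = list(truth = list(shift = shift, linewidth = lw),
                                 noiseless = noiseless,
                                 photon_budget = photon_budget,
                                 rng_seed = rng_seed))
}

#' Simulate a calibration frame with reference spectral lines
#'
#' Images narrow reference lines of known frequency (by default the
#' shipped Rb-87 D2 hyperfine set, see [rb87_reference_lines()]) through
#' the same dispersion law as the Brillouin signal.  The notch is disabled
#' so the elastic reference lines stay visible.
#'
#' @param config A [spectrometer_config()].
#' @param reference_lines Data frame with columns `frequency_ghz` and
#'   `relative_intensity` (or a numeric vector of frequencies), >= 2 lines.
#' @param photon_budget Peak photons of the strongest line (default 5000).
#' @param rng_seed Integer seed; `NULL` yields a noiseless frame.
#' @return A [spectral_frame()] with `metadata$reference_lines`.
#' @export
simulate_calibration_frame <- function(config,
                                       reference_lines = rb87_reference_lines(),
                                       photon_budget = 5000,
                                       rng_seed = NULL) {
  stopifnot(inherits(config, "spectrometer_config"))
  if (is.numeric(reference_lines))
    reference_lines <- data.frame(frequency_ghz = reference_lines,
                                  relative_intensity = 1)
  if (nrow(reference_lines) < 2)
    data_error("calibration requires at least 2 reference lines")
  comp <- data.frame(center = reference_lines$frequency_ghz %% config$fsr,
                     fwhm = rayleigh_intrinsic_fwhm,
                     amplitude = photon_budget *
                       reference_lines$relative_intensity,
                     shape = "gaussian")
  # map centres into the signed (-FSR/2, FSR/2] period
  comp$center <- ifelse(comp$center > config$fsr / 2,
                        comp$center - config$fsr, comp$center)
  photons <- row_expected_photons(comp, config, notch_on = FALSE)
  noiseless <- matrix(rep(config$camera$gain * photons,
                          each = config$line_length),
                      nrow = config$line_length, byrow = FALSE)
  counts <- if (is.null(rng_seed)) noiseless else
    apply_camera_noise(noiseless / config$camera$gain, config$camera, rng_seed)
  spectral_frame(counts, exposure = config$camera$exposure,
                 metadata = list(reference_lines = reference_lines,
                                 calibration = TRUE))
}

#' Rb-87 D2 hyperfine reference lines
#'
#' Reference line set used for spectrometer calibration, from standard
#' atomic-physics reference data for the Rb-87 D2 transition.  Frequencies
#' are offsets in GHz relative to the laser lock line; the main anchor is
#' the 6.834683 GHz ground-state hyperfine splitting.
#'
#' @return Data frame with columns `label`, `frequency_ghz`,
#'   `relative_intensity`.
#' @export
rb87_reference_lines <- function() {
  path <- system.file("extdata", "rb87_d2_lines.csv", package = "lsbrillouin",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
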