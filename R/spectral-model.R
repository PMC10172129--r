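#' Scattering geometry configuration
#'
#' Describes the Brillouin scattering geometry of a line-scan acquisition.
#' In the orthogonal-line geometry (O-LSBM) illumination and detection are
#' perpendicular, so the probed phonon wavevector bisects them and the
#' effective scattering angle is 90 degrees; in the epi-line geometry
#' (E-LSBM) light is collected in backscattering (180 degrees).
#'
#' @param scattering_angle Scattering angle in degrees, in (0, 180].
#'   180 for epi-detection, 90 for the orthogonal dual-objective geometry.
#' @param wavelength Laser vacuum wavelength in nm (default 780.24, the
#'   rubidium D2 line the laser is locked to).
#' @param refractive_index Refractive index of the probed material (>= 1).
#' @param sound_velocity Longitudinal sound velocity of the material in m/s.
#' @return An object of class `geometry_config`.
#' @examples
#' geom <- geometry_config(scattering_angle = 90, refractive_index = 1.33,
#'                         sound_velocity = 1490)
#' brillouin_shift_physics(geom)
#' @export
geometry_config <- function(scattering_angle = 90, wavelength = 780.24,
                            refractive_index = 1.33, sound_velocity = 1490) {
  stopifnot(is.numeric(scattering_angle), length(scattering_angle) == 1)
  if (scattering_angle <= 0 || scattering_angle > 180)
    stop("scattering_angle must be in (0, 180] degrees", call. = FALSE)
  if (wavelength <= 0) stop("wavelength must be > 0", call. = FALSE)
  if (refractive_index < 1) stop("refractive_index must be >= 1", call. = FALSE)
  if (sound_velocity <= 0) stop("sound_velocity must be > 0", call. = FALSE)
  structure(list(scattering_angle = scattering_angle, wavelength = wavelength,
                 refractive_index = refractive_index,
                 sound_velocity = sound_velocity),
            class = "geometry_config")
}

#' Closed-form Brillouin shift for a scattering geometry
#'
#' Computes the spontaneous Brillouin frequency shift
#' \deqn{\nu_B = 2 n V \sin(\theta/2) / \lambda}
#' for refractive index n, sound velocity V (m/s), scattering angle
#' \eqn{\theta} and vacuum wavelength \eqn{\lambda}.
#'
#' @param geometry A [geometry_config()].
#' @return Brillouin shift in GHz.
#' @export
brillouin_shift_physics <- function(geometry) {
  stopifnot(inherits(geometry, "geometry_config"))
  theta <- geometry$scattering_angle * pi / 180
  lambda_m <- geometry$wavelength * 1e-9
  2 * geometry$refractive_index * geometry$sound_velocity *
    sin(theta / 2) / lambda_m / 1e9
}

#' Lorentzian line profile
#'
#' Evaluates \eqn{A (\Gamma/2)^2 / ((\nu - \nu_0)^2 + (\Gamma/2)^2)}: peak
#' value `amplitude` at `center`, half maximum at `center +/- fwhm/2`.
#'
#' @param freq_grid Frequencies (GHz) at which to evaluate.
#' @param amplitude Peak amplitude (counts), >= 0.
#' @param center Peak centre (GHz).
#' @param fwhm Full width at half maximum (GHz), > 0.
#' @return Numeric vector of profile values.
#' @export
lorentzian_profile <- function(freq_grid, amplitude, center, fwhm) {
  if (!is.numeric(fwhm) || length(fwhm) != 1 || !is.finite(fwhm) || fwhm <= 0)
    stop("fwhm must be a positive number", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  hw2 <- (fwhm / 2)^2
  amplitude * hw2 / ((freq_grid - center)^2 + hw2)
}

# quadratic baseline used by the background-augmented fit models
quadratic_background <- function(freq_grid, b0, b1 = 0, b2 = 0) {
  b0 + b1 * freq_grid + b2 * freq_grid^2
}

#' Instrument-broadened Brillouin line profile
#'
#' Numerical convolution of a Lorentzian of intrinsic width `intrinsic_fwhm`
#' with a symmetric instrument broadening kernel.  The kernel models the
#' combined spectrometer and NA broadening; the default is a Gaussian of
#' configurable standard deviation.  Convolution is performed on an internal
#' fine grid and interpolated back onto `freq_grid`, preserving area, so the
#' result reduces exactly to [lorentzian_profile()] in the delta-kernel
#' limit.  `amplitude` is the amplitude of the underlying (unbroadened)
#' Lorentzian.
#'
#' @param freq_grid Frequencies (GHz); need not be uniform.
#' @param amplitude Amplitude of the intrinsic Lorentzian (counts).
#' @param center Peak centre (GHz).
#' @param intrinsic_fwhm Intrinsic Lorentzian FWHM (GHz), > 0.
#' @param kernel Either the string "delta", or a list
#'   `list(type = "gaussian", sigma = <GHz>)`.
#' @return Numeric vector of profile values on `freq_grid`.
#' @export
broadened_brillouin_profile <- function(freq_grid, amplitude, center,
                                        intrinsic_fwhm,
                                        kernel = list(type = "gaussian",
                                                      sigma = 0.3)) {
  if (intrinsic_fwhm <= 0) stop("intrinsic_fwhm must be > 0", call. = FALSE)
  if (identical(kernel, "delta") ||
      (is.list(kernel) && identical(kernel$type, "delta")))
    return(lorentzian_profile(freq_grid, amplitude, center, intrinsic_fwhm))
  if (!is.list(kernel) || !identical(kernel$type, "gaussian"))
    stop("kernel must be \"delta\" or list(type = \"gaussian\", sigma = )",
         call. = FALSE)
  sigma <- kernel$sigma
  if (!is.finite(sigma) || sigma < 0) stop("kernel sigma must be >= 0", call. = FALSE)
  if (sigma == 0)
    return(lorentzian_profile(freq_grid, amplitude, center, intrinsic_fwhm))
  span <- diff(range(freq_grid))
  if (span > 0 && 10 * sigma > span + 20 * intrinsic_fwhm)
    stop("instrument kernel is wider than the frequency grid span",
         call. = FALSE)
  df <- min(intrinsic_fwhm / 40, sigma / 10, 0.01)
  pad <- 6 * sigma + 10 * intrinsic_fwhm
  fine <- seq(min(freq_grid) - pad, max(freq_grid) + pad, by = df)
  y <- lorentzian_profile(fine, amplitude, center, intrinsic_fwhm)
  kern <- stats::dnorm(seq(-5 * sigma, 5 * sigma, by = df), 0, sigma)
  kern <- kern / sum(kern)
  yc <- stats::filter(y, kern, sides = 2)
  ok <- !is.na(yc)
  stats::approx(fine[ok], as.numeric(yc[ok]), xout = freq_grid, rule = 2)$y
}

#' Rubidium notch filter configuration
#'
#' Models the heated Rb-87 gas cell that rejects the elastically scattered
#' (Rayleigh) light before the VIPA.  Absorption lines are Doppler
#' (Gaussian) broadened; transmission at frequency nu is
#' \eqn{\exp(-OD \cdot \exp(-(\nu-c)^2 / 2\sigma_D^2))} per line.
#'
#' @param line_centers Absorption line centres in GHz relative to the laser
#'   line (default 0: the laser is locked to the absorption line).
#' @param optical_depth Peak optical depth (>= 0).  The default `log(1e8)`
#'   yields 80 dB suppression at line centre.
#' @param doppler_fwhm Doppler FWHM of the absorption line in GHz.
#' @return An object of class `notch_config`.
#' @export
notch_config <- function(line_centers = 0, optical_depth = log(1e8),
                         doppler_fwhm = 0.55) {
  if (optical_depth < 0) stop("optical_depth must be >= 0", call. = FALSE)
  if (doppler_fwhm <= 0) stop("doppler_fwhm must be > 0", call. = FALSE)
  structure(list(line_centers = line_centers, optical_depth = optical_depth,
                 doppler_fwhm = doppler_fwhm), class = "notch_config")
}

#' Camera configuration
#'
#' Detection model behind the shot-noise-limited operation of the
#' spectrometer: Poisson photon statistics scaled by `gain`, additive
#' Gaussian read noise, and clipping at `full_well`.
#'
#' @param read_noise Read noise in counts rms (>= 0).
#' @param gain Counts per detected photon (> 0).
#' @param full_well Saturation level in counts.
#' @param exposure Exposure time in seconds (default 0.1).
#' @return An object of class `camera_config`.
#' @export
camera_config <- function(read_noise = 2, gain = 1, full_well = 65535,
                          exposure = 0.1) {
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  if (read_noise < 0) stop("read_noise must be >= 0", call. = FALSE)
  if (full_well <= 0) stop("full_well must be > 0", call. = FALSE)
  if (exposure <= 0) stop("exposure must be > 0", call. = FALSE)
  structure(list(read_noise = read_noise, gain = gain, full_well = full_well,
                 exposure = exposure), class = "camera_config")
}

#' VIPA spectrometer configuration
#'
#' Geometry-independent description of the spectrometer: free spectral
#' range, number of visible diffraction orders, per-order dispersion law,
#' instrument spectral broadening, notch filter and camera.  The per-order
#' pixel-to-frequency law is linear with slope `spectral_sampling` plus an
#' optional quadratic term `dispersion_nonlinearity` (GHz/px^2); order
#' anchors repeat with a frequency pitch of exactly one FSR.
#'
#' @param fsr Free spectral range in GHz (default 15.15).
#' @param n_orders_visible Number of fully visible VIPA orders (>= 1,
#'   default 3: the pipeline sums at least three orders).
#' @param spectral_sampling Spectral sampling in GHz per pixel; must lie in
#'   \[0.1, 1\] and should be within the instrument's ~0.25-0.5 range.
#' @param spatial_sampling Spatial sampling along the illumination line in
#'   micrometres per pixel (default 0.7).
#' @param dispersion_nonlinearity Quadratic dispersion coefficient in
#'   GHz/px^2 (default 0: linear dispersion).
#' @param instrument_sigma Gaussian instrument-broadening sigma in GHz
#'   (default 0.3, i.e. ~0.7 GHz spectral resolution FWHM).
#' @param line_length Number of spatial rows per frame (default 48).
#' @param notch A [notch_config()].
#' @param camera A [camera_config()].
#' @return An object of class `spectrometer_config`.
#' @export
spectrometer_config <- function(fsr = 15.15, n_orders_visible = 3,
                                spectral_sampling = 0.25,
                                spatial_sampling = 0.7,
                                dispersion_nonlinearity = 0,
                                instrument_sigma = 0.3,
                                line_length = 48,
                                notch = notch_config(),
                                camera = camera_config()) {
  if (fsr <= 0) stop("fsr must be > 0", call. = FALSE)
  if (n_orders_visible < 1) stop("n_orders_visible must be >= 1", call. = FALSE)
  if (spectral_sampling < 0.1 || spectral_sampling > 1)
    stop("spectral_sampling must be in [0.1, 1] GHz/px", call. = FALSE)
  if (spatial_sampling <= 0) stop("spatial_sampling must be > 0", call. = FALSE)
  if (instrument_sigma < 0) stop("instrument_sigma must be >= 0", call. = FALSE)
  if (line_length < 1) stop("line_length must be >= 1", call. = FALSE)
  stopifnot(inherits(notch, "notch_config"), inherits(camera, "camera_config"))
  structure(list(fsr = fsr, n_orders_visible = n_orders_visible,
                 spectral_sampling = spectral_sampling,
                 spatial_sampling = spatial_sampling,
                 dispersion_nonlinearity = dispersion_nonlinearity,
                 instrument_sigma = instrument_sigma,
                 line_length = line_length,
                 notch = notch, camera = camera),
            class = "spectrometer_config")
}
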