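# Shift-map assembly and fluorescence-guided quantification: stacking
# per-line measurements into maps/volumes, bilinear rescaling to the
# fluorescence pixel grid, overlay registration, median re-slice
# projections, masked region statistics, relative time series and the
# bead-scan PSF analysis.

#' Shift map/volume container
#'
#' Congruent grids of shift, linewidth, SNR and validity, with voxel
#' geometry and acquisition metadata.  x runs along the illumination line,
#' y along the light-sheet scan, z in depth; an optional trailing time axis
#' is declared through `timepoints`.
#'
#' @param shift Shift array (GHz); NA marks invalid voxels.
#' @param linewidth,snr,valid Arrays congruent with `shift` (filled with
#'   NA/TRUE when omitted).
#' @param voxel_size Voxel size in micrometres per spatial axis.
#' @param geometry "O-LSBM" or "E-LSBM".
#' @param timepoints Optional timepoints in minutes.
#' @return An object of class `shift_volume`.
#' @export
shift_volume <- function(shift, linewidth = NULL, snr = NULL, valid = NULL,
                         voxel_size = c(0.7, 1.5, 1.5),
                         geometry = "O-LSBM", timepoints = NULL) {
  shift <- as.array(shift)
  fill <- function(x, default) {
    if (is.null(x)) return(array(default, dim = dim(shift)))
    x <- as.array(x)
    if (!identical(dim(x), dim(shift)))
      stop("all grids must be congruent", call. = FALSE)
    x
  }
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0", call. = FALSE)
  structure(list(shift = shift, linewidth = fill(linewidth, NA_real_),
                 snr = fill(snr, NA_real_),
                 valid = fill(valid, TRUE) & is.finite(shift),
                 voxel_size = voxel_size, geometry = geometry,
                 timepoints = timepoints),
            class = "shift_volume")
}

#' Assemble a shift map from per-line measurements
#'
#' Stacks the measurement tables of successive scan positions (one
#' [process_frame()] output per stage position) into a 2D map with x along
#' the illumination line and y along the scan.
#'
#' @param measurement_lines List of measurement data frames of equal length.
#' @param scan_positions Stage positions in micrometres (same length).
#' @param spatial_sampling Sampling along the line in micrometres per pixel.
#' @param geometry "O-LSBM" or "E-LSBM".
#' @return A [shift_volume()] of dimension `n_points x n_positions`.
#' @export
assemble_volume <- function(measurement_lines, scan_positions,
                            spatial_sampling = 0.7, geometry = "O-LSBM") {
  stopifnot(length(measurement_lines) == length(scan_positions))
  lens <- vapply(measurement_lines, nrow, integer(1))
  if (length(unique(lens)) != 1)
    stop("inconsistent line lengths", call. = FALSE)
  ord <- order(scan_positions)
  measurement_lines <- measurement_lines[ord]
  scan_positions <- scan_positions[ord]
  pull <- function(col) vapply(measurement_lines, function(m)
    as.numeric(m[[col]]), numeric(lens[1]))
  step <- if (length(scan_positions) > 1) mean(diff(scan_positions)) else
    spatial_sampling
  shift_volume(pull("shift"), pull("linewidth"), pull("snr_db"),
               matrix(vapply(measurement_lines, function(m)
                 as.logical(m$valid), logical(lens[1])), nrow = lens[1]),
               voxel_size = c(spatial_sampling, step), geometry = geometry)
}

#' Registration transform between Brillouin and fluorescence images
#'
#' @param xy_scale Isotropic x/y rescale factor from Brillouin to
#'   fluorescence pixels (default 2.5138).
#' @param y_offset Fluorescence row aligned with the centre of the
#'   Brillouin image in y (default 450: half the diameter of a 900-pixel
#'   fluorescence frame); `NULL` centres the crop in the frame.
#' @param x_offset Landmark-derived fluorescence column shift of the
#'   Brillouin origin in x (default 0; user-supplied, as the landmark is a
#'   manual choice).
#' @return An object of class `registration_transform`.
#' @export
registration_transform <- function(xy_scale = 2.5138, y_offset = 450,
                                   x_offset = 0) {
  if (xy_scale <= 0) stop("xy_scale must be > 0", call. = FALSE)
  structure(list(xy_scale = xy_scale, y_offset = y_offset,
                 x_offset = x_offset), class = "registration_transform")
}

# bilinear resampling with half-pixel-centre convention: output pixel i
# (1-based) has centre (i - 0.5) / scale in input pixel units
bilinear_resample <- function(mat, out_nx, out_ny) {
  nx <- nrow(mat); ny <- ncol(mat)
  xs <- (seq_len(out_nx) - 0.5) * nx / out_nx + 0.5
  ys <- (seq_len(out_ny) - 0.5) * ny / out_ny + 0.5
  x0 <- pmin(pmax(floor(xs), 1), nx); x1 <- pmin(x0 + 1, nx)
  y0 <- pmin(pmax(floor(ys), 1), ny); y1 <- pmin(y0 + 1, ny)
  wx <- pmin(pmax(xs - x0, 0), 1); wy <- pmin(pmax(ys - y0, 0), 1)
  m00 <- mat[x0, y0, drop = FALSE]; m10 <- mat[x1, y0, drop = FALSE]
  m01 <- mat[x0, y1, drop = FALSE]; m11 <- mat[x1, y1, drop = FALSE]
  WX <- matrix(wx, out_nx, out_ny); WY <- matrix(wy, out_nx, out_ny,
                                                 byrow = TRUE)
  m00 * (1 - WX) * (1 - WY) + m10 * WX * (1 - WY) +
    m01 * (1 - WX) * WY + m11 * WX * WY
}

nearest_resample <- function(mat, out_nx, out_ny) {
  nx <- nrow(mat); ny <- ncol(mat)
  xi <- pmin(pmax(round((seq_len(out_nx) - 0.5) * nx / out_nx + 0.5), 1), nx)
  yi <- pmin(pmax(round((seq_len(out_ny) - 0.5) * ny / out_ny + 0.5), 1), ny)
  mat[xi, yi, drop = FALSE]
}

#' Rescale a Brillouin map to the fluorescence pixel grid
#'
#' Bilinear interpolation in x and y by the transform's `xy_scale` (2.5138
#' by default) so the Brillouin map matches the dimensions of the
#' fluorescence images; output dimensions are `floor(input * scale)`.  The
#' validity mask is resampled by nearest neighbour.
#'
#' @param map2d Matrix (a shift map slice) or a 2D [shift_volume()].
#' @param transform A [registration_transform()].
#' @return Rescaled matrix, or list with `values` and `valid` for a
#'   `shift_volume` input.
#' @export
rescale_to_fluorescence <- function(map2d, transform) {
  stopifnot(inherits(transform, "registration_transform"))
  s <- transform$xy_scale
  if (inherits(map2d, "shift_volume")) {
    m <- map2d$shift
    out <- list(
      values = bilinear_resample(m, floor(nrow(m) * s), floor(ncol(m) * s)),
      valid = nearest_resample(map2d$valid, floor(nrow(m) * s),
                               floor(ncol(m) * s)) > 0.5)
    return(out)
  }
  m <- as.matrix(map2d)
  if (abs(s - 1) < 1e-12) return(m)
  bilinear_resample(m, floor(nrow(m) * s), floor(ncol(m) * s))
}

#' Overlay a fluorescence stack onto a Brillouin stack
#'
#' Crops the fluorescence image to the Brillouin dimensions after applying
#' the registration offsets, so both stacks share one coordinate frame.
#' `y_offset` names the fluorescence row aligned with the Brillouin centre
#' in y (the manual half-diameter alignment); `x_offset` shifts the
#' Brillouin origin along x (the manual landmark alignment).
#'
#' @param fluo Fluorescence matrix (x by y, fluorescence pixels).
#' @param brillouin Brillouin matrix already rescaled to fluorescence
#'   pixels (see [rescale_to_fluorescence()]).
#' @param transform A [registration_transform()].
#' @return List with `fluorescence` (cropped) and `brillouin`, same
#'   dimensions.
#' @export
register_overlay <- function(fluo, brillouin, transform) {
  stopifnot(inherits(transform, "registration_transform"))
  fluo <- as.matrix(fluo); brillouin <- as.matrix(brillouin)
  nxb <- nrow(brillouin); nyb <- ncol(brillouin)
  yc <- transform$y_offset %||% (ncol(fluo) / 2)
  y0 <- round(yc - nyb / 2)              # crop start - 1 in y
  x0 <- round(transform$x_offset)        # crop start - 1 in x
  xs <- x0 + seq_len(nxb); ys <- y0 + seq_len(nyb)
  if (min(xs) < 1 || max(xs) > nrow(fluo) || min(ys) < 1 ||
      max(ys) > ncol(fluo))
    data_error(sprintf(
      "offsets place the crop outside the fluorescence frame (x %d..%d of %d, y %d..%d of %d)",
      min(xs), max(xs), nrow(fluo), min(ys), max(ys), ncol(fluo)))
  list(fluorescence = fluo[xs, ys, drop = FALSE], brillouin = brillouin)
}

#' Re-slice a volume and compute slab median projections
#'
#' Voxel-wise median over groups of slices along one axis, ignoring
#' invalid (NA) voxels; the median of an even count is the mean of the
#' central pair.  A pixel whose slab is entirely invalid stays NA.
#'
#' @param volume 3D array (or `shift_volume` whose shift field is 3D);
#'   NA marks invalid voxels.
#' @param slabs List of slice-index vectors, e.g.
#'   `list(1:2, 3:4, 5:6)` for three projections of two slices each.
#' @param axis Axis to project over: 3 (default), 1 or 2.
#' @return List of 2D median maps, one per slab.
#' @export
reslice_and_median_project <- function(volume, slabs, axis = 3) {
  arr <- if (inherits(volume, "shift_volume")) {
    a <- volume$shift; a[!volume$valid] <- NA_real_; a
  } else as.array(volume)
  stopifnot(length(dim(arr)) == 3)
  nslice <- dim(arr)[axis]
  lapply(slabs, function(idx) {
    if (any(idx < 1 | idx > nslice)) stop("slab indices out of range",
                                          call. = FALSE)
    sub <- switch(axis,
                  `1` = arr[idx, , , drop = FALSE],
                  `2` = arr[, idx, , drop = FALSE],
                  `3` = arr[, , idx, drop = FALSE])
    apply(sub, setdiff(1:3, axis), function(v)
      if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
  })
}

#' Region-of-interest statistics of a shift map
#'
#' Central statistic and dispersion of the valid masked voxels: mean with
#' standard deviation, or median with interquartile range (linear
#' interpolation quantiles, `stats::quantile` type 7).
#'
#' @param map Numeric array (NA = invalid) or [shift_volume()].
#' @param mask Logical array congruent with the map.
#' @param statistic "mean_sd" or "median_iqr".
#' @return List with `stat`, `dispersion`, `q25`, `q75`, `n`.
#' @export
roi_quantify <- function(map, mask, statistic = c("mean_sd", "median_iqr")) {
  statistic <- match.arg(statistic)
  arr <- if (inherits(map, "shift_volume")) {
    a <- map$shift; a[!map$valid] <- NA_real_; a
  } else as.array(map)
  mask <- as.array(mask)
  if (!identical(dim(mask), dim(arr)))
    stop("mask must be congruent with the map", call. = FALSE)
  v <- arr[mask & is.finite(arr)]
  if (!length(v)) data_error("empty mask: no valid voxels to quantify")
  if (statistic == "mean_sd")
    list(stat = mean(v), dispersion = stats::sd(v),
         q25 = NA_real_, q75 = NA_real_, n = length(v))
  else {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(stat = q[2], dispersion = q[3] - q[1], q25 = q[1], q75 = q[3],
         n = length(v))
  }
}

#' Region time series from a sequence of maps
#'
#' Applies [roi_quantify()] per timepoint and collects the results.
#'
#' @param maps List of maps (one per timepoint) or a 3D array with time as
#'   the trailing axis.
#' @param mask Logical mask congruent with one map.
#' @param timepoints Timepoints in minutes.
#' @param statistic Passed to [roi_quantify()].
#' @return Data frame of class `roi_timeseries` with columns
#'   `timepoint_min`, `stat_ghz`, `dispersion_ghz`, `n_voxels`.
#' @export
roi_timeseries <- function(maps, mask, timepoints,
                           statistic = c("mean_sd", "median_iqr")) {
  statistic <- match.arg(statistic)
  if (is.array(maps) && length(dim(maps)) == 3)
    maps <- lapply(seq_len(dim(maps)[3]), function(t) maps[, , t])
  stopifnot(length(maps) == length(timepoints))
  rows <- lapply(seq_along(maps), function(i) {
    q <- roi_quantify(maps[[i]], mask, statistic)
    data.frame(timepoint_min = timepoints[i], stat_ghz = q$stat,
               dispersion_ghz = q$dispersion, n_voxels = q$n)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference_index") <- NA_integer_
  class(out) <- c("roi_timeseries", class(out))
  out
}

#' Express a region time series relative to a reference timepoint
#'
#' Subtracts the central statistic at the reference timepoint from every
#' timepoint (shift changes relative to t0); dispersions are untouched.
#'
#' @param series A [roi_timeseries()] data frame.
#' @param t0_index Index of the reference timepoint (default 1).
#' @return The series with `stat_ghz` replaced by differences to t0.
#' @export
relative_timeseries <- function(series, t0_index = 1) {
  stopifnot(t0_index >= 1, t0_index <= nrow(series))
  series$stat_ghz <- series$stat_ghz - series$stat_ghz[t0_index]
  attr(series, "reference_index") <- as.integer(t0_index)
  series
}

#' Bead-scan point-spread-function FWHM
#'
#' Gaussian least-squares fit of the Rayleigh-peak amplitude versus stage
#' position recorded while scanning a sub-resolution bead through the
#' focus; the spatial resolution is reported as
#' \eqn{FWHM = 2\sqrt{2\ln 2}\,\sigma}.
#'
#' @param scan_positions Stage positions in micrometres (>= 7 samples
#'   spanning the peak).
#' @param rayleigh_amplitudes Rayleigh peak amplitudes (counts).
#' @return List with `fwhm_um`, `sigma_um`, `center_um`.
#' @export
bead_psf_fwhm <- function(scan_positions, rayleigh_amplitudes) {
  x <- as.numeric(scan_positions); y <- as.numeric(rayleigh_amplitudes)
  stopifnot(length(x) == length(y))
  if (length(x) < 7) data_error("need at least 7 samples spanning the peak")
  if (max(y) - min(y) <= 1e-9 * max(abs(y), 1))
    data_error("flat profile: no peak to fit")
  imax <- which.max(y)
  if (imax <= 1 || imax >= length(y))
    data_error("peak not interior to the scan: monotone data")
  # start mu slightly off the argmax: an exactly centred start on a
  # symmetric grid yields a numerically singular initial gradient
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * sig^2)) + b,
    start = list(A = max(y) - min(y),
                 mu = x[imax] + 1e-3 * diff(range(x)),
                 sig = diff(range(x)) / 6, b = min(y)),
    lower = c(A = 0, mu = min(x), sig = 1e-6, b = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) data_error("Gaussian PSF fit failed"))
  cf <- stats::coef(fit)
  list(fwhm_um = 2 * sqrt(2 * log(2)) * cf[["sig"]],
       sigma_um = cf[["sig"]], center_um = cf[["mu"]])
}
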