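#' Digital phantom with per-voxel Brillouin ground truth
#'
#' A phantom holds the ground-truth fields the simulator images: Brillouin
#' shift and linewidth (GHz), Rayleigh reflectivity (relative units, the
#' pre-notch ratio between the elastic peak and the Stokes peak), and an
#' optional co-registered fluorescence field.  Fields may be 1D (a single
#' illumination line), 2D (line x scan), 3D or 4D (with a trailing time
#' axis declared through `timepoints`).
#'
#' @param shift Array of Brillouin shifts in GHz (> 0 everywhere).
#' @param linewidth Array (or scalar) of linewidths in GHz.
#' @param reflectivity Array (or scalar) of Rayleigh reflectivities.
#' @param voxel_size Voxel size in micrometres, one value per spatial axis.
#' @param fluorescence Optional fluorescence array (its own, finer grid).
#' @param fluorescence_scale Fluorescence pixels per Brillouin voxel in x/y.
#' @param timepoints Optional numeric vector of timepoints in minutes; when
#'   given, the trailing dimension of `shift` must have that length.
#' @return An object of class `brillouin_phantom`.
#' @export
brillouin_phantom <- function(shift, linewidth = 0.4, reflectivity = 1e4,
                              voxel_size = c(0.7, 1.5, 1.5),
                              fluorescence = NULL, fluorescence_scale = 1,
                              timepoints = NULL) {
  shift <- as.array(shift)
  if (any(!is.finite(shift)) || any(shift <= 0))
    stop("shift field must be positive everywhere", call. = FALSE)
  expand <- function(x) {
    x <- as.array(x)
    if (length(x) == 1) array(x, dim = dim(shift)) else x
  }
  linewidth <- expand(linewidth)
  reflectivity <- expand(reflectivity)
  if (!identical(dim(linewidth), dim(shift)) ||
      !identical(dim(reflectivity), dim(shift)))
    stop("all phantom fields must share one grid shape", call. = FALSE)
  if (any(linewidth <= 0)) stop("linewidth must be > 0", call. = FALSE)
  if (!is.null(timepoints)) {
    nd <- length(dim(shift))
    if (dim(shift)[nd] != length(timepoints))
      stop("trailing dimension must match timepoints", call. = FALSE)
  }
  structure(list(shift = shift, linewidth = linewidth,
                 reflectivity = reflectivity, voxel_size = voxel_size,
                 fluorescence = fluorescence,
                 fluorescence_scale = fluorescence_scale,
                 timepoints = timepoints),
            class = "brillouin_phantom")
}

#' Time-lapse folding phantom with an elevated-shift domain
#'
#' Builds a 4D phantom from a static base phantom by ramping the Brillouin
#' shift inside a masked domain linearly from 0 to `delta_shift` across the
#' timepoints, emulating a tissue-folding event in which the shift of the
#' folding domain rises by 10-20 MHz while the surround stays constant.  A
#' matched fluorescence channel carries the mask geometry at a finer pixel
#' size (`fluorescence_scale` pixels per voxel) for registration tests.
#'
#' @param base A static [brillouin_phantom()] (2D or 3D shift field).
#' @param folding_domain Logical mask with the base grid shape.
#' @param delta_shift Total shift increase in GHz (>= 0); e.g. 0.015 for
#'   a 15 MHz rise.
#' @param timepoints Numeric vector of timepoints (minutes).
#' @param fluorescence_scale Fluorescence pixels per Brillouin voxel
#'   (default 2.5138, the instrument's fluorescence/Brillouin pixel ratio).
#' @return A 4D `brillouin_phantom` whose `fluorescence` field holds the
#'   rescaled mask per timepoint.
#' @export
simulate_timelapse_phantom <- function(base, folding_domain, delta_shift,
                                       timepoints,
                                       fluorescence_scale = 2.5138) {
  stopifnot(inherits(base, "brillouin_phantom"))
  folding_domain <- as.array(folding_domain)
  if (!identical(dim(folding_domain), dim(base$shift)))
    stop("folding_domain mask must match the phantom grid", call. = FALSE)
  if (delta_shift < 0) stop("delta_shift must be >= 0", call. = FALSE)
  nt <- length(timepoints)
  if (nt < 1) stop("need at least one timepoint", call. = FALSE)
  ramp <- if (nt == 1) delta_shift else
    delta_shift * (seq_len(nt) - 1) / (nt - 1)
  dims <- dim(base$shift)
  shift4 <- array(NA_real_, c(dims, nt))
  for (t in seq_len(nt)) {
    st <- base$shift
    st[folding_domain] <- st[folding_domain] + ramp[t]
    shift4[slice.index(shift4, length(dims) + 1L) == t] <- st
  }
  lw4 <- array(rep(as.vector(base$linewidth), nt), c(dims, nt))
  rf4 <- array(rep(as.vector(base$reflectivity), nt), c(dims, nt))
  # fluorescence: the mask geometry at its own finer pixel size, constant in t
  mask2 <- if (length(dims) == 1) matrix(folding_domain, ncol = 1) else
    matrix(folding_domain, nrow = dims[1])
  fl_nx <- floor(nrow(mask2) * fluorescence_scale)
  fl_ny <- floor(ncol(mask2) * fluorescence_scale)
  xi <- pmin(nrow(mask2), floor((seq_len(fl_nx) - 0.5) / fluorescence_scale) + 1)
  yi <- pmin(ncol(mask2), floor((seq_len(fl_ny) - 0.5) / fluorescence_scale) + 1)
  fluo2 <- matrix(as.numeric(mask2[xi, yi, drop = FALSE]), fl_nx, fl_ny)
  fluo <- array(rep(fluo2, nt), c(fl_nx, fl_ny, nt))
  brillouin_phantom(shift4, lw4, rf4, voxel_size = base$voxel_size,
                    fluorescence = fluo,
                    fluorescence_scale = fluorescence_scale,
                    timepoints = timepoints)
}

#' Homogeneous water phantom line
#'
#' Convenience constructor for the reference sample used for precision
#' characterization: a homogeneous line of water-like material.
#'
#' @param n_rows Number of spatial points along the line.
#' @param shift Brillouin shift in GHz (default 5.05).
#' @param linewidth Linewidth in GHz (default 0.4).
#' @param reflectivity Rayleigh reflectivity (default 1e4).
#' @return A 1D `brillouin_phantom`.
#' @export
water_phantom_line <- function(n_rows = 48, shift = 5.05, linewidth = 0.4,
                               reflectivity = 1e4) {
  brillouin_phantom(array(shift, n_rows), array(linewidth, n_rows),
                    array(reflectivity, n_rows), voxel_size = 0.7)
}
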