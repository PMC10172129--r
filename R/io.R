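# Readers/writers and run configuration.  Frames travel as multi-page TIFF
# (16-bit integer counts, lossless) with a JSON sidecar for acquisition
# metadata; maps as 32-bit float TIFF pages with a documented scale factor;
# measurement tables as full-precision CSV; calibration models as JSON;
# run configuration as schema-validated YAML.

frame_sidecar_path <- function(path) paste0(path, ".json")

#' Write / read spectrometer frames as multi-page TIFF
#'
#' One TIFF page per frame, 16-bit unsigned counts (lossless for camera
#' data up to 65535); exposure and per-frame metadata go to a JSON sidecar
#' `<path>.json`, including any simulation ground truth under `truth` so
#' synthetic data keep their provenance.
#'
#' @param frames A [spectral_frame()] or list of them.
#' @param path Output TIFF path.
#' @return `path` invisibly (write); list of `spectral_frame` (read).
#' @export
write_frames <- function(frames, path) {
  if (inherits(frames, "spectral_frame")) frames <- list(frames)
  pages <- lapply(frames, function(f) {
    if (max(f$counts) > 65535)
      stop("counts exceed the 16-bit range", call. = FALSE)
    f$counts / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  meta <- lapply(frames, function(f)
    list(exposure = f$exposure,
         truth = f$metadata$truth,
         photon_budget = f$metadata$photon_budget,
         rng_seed = f$metadata$rng_seed))
  jsonlite::write_json(meta, frame_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) data_error(paste("no such file:", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      data_error(sprintf("malformed TIFF '%s': %s", path,
                                         conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  meta <- if (file.exists(frame_sidecar_path(path)))
    jsonlite::read_json(frame_sidecar_path(path), simplifyVector = TRUE,
                        simplifyDataFrame = FALSE) else NULL
  lapply(seq_along(pages), function(i) {
    counts <- round(pages[[i]] * 65535)
    m <- if (!is.null(meta) && length(meta) >= i) meta[[i]] else list()
    spectral_frame(counts, exposure = m$exposure %||% NA_real_,
                   metadata = m)
  })
}

#' Write / read a shift volume as float TIFF plus JSON sidecar
#'
#' Stores the shift, linewidth, snr and validity grids as 32-bit float
#' TIFF pages (values divided by a fixed scale of 16 to fit the TIFF
#' float [0,1] convention; the scale and grid layout are recorded in the
#' sidecar).  Geometry, voxel size and timepoints live in `<path>.json`.
#'
#' @param volume A [shift_volume()].
#' @param path Output TIFF path.
#' @return `path` invisibly (write); a `shift_volume` (read).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "shift_volume"))
  dims <- dim(volume$shift)
  offs <- numeric(0); scales <- numeric(0)
  as_page <- function(a) {
    m <- matrix(as.vector(a), nrow = dims[1])
    fin <- m[is.finite(m)]
    off <- min(fin, 0)
    sc <- max(max(fin, 0) - off, 1e-9)
    offs <<- c(offs, off); scales <<- c(scales, sc)
    m[!is.finite(m)] <- off             # placeholder; NA restored via valid
    (m - off) / sc
  }
  pages <- list(as_page(volume$shift), as_page(volume$linewidth),
                as_page(volume$snr), as_page(volume$valid * 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(offsets = offs, scales = scales, dims = dims,
         voxel_size = volume$voxel_size,
         geometry = volume$geometry, timepoints = volume$timepoints,
         pages = c("shift", "linewidth", "snr", "valid")),
    frame_sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(frame_sidecar_path(path),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  restore <- function(i)
    array(as.vector(pages[[i]]) * meta$scales[i] + meta$offsets[i],
          dim = meta$dims)
  valid <- array(restore(4) > 0.5, dim = meta$dims)
  na_fix <- function(a) { a[!valid] <- NA_real_; a }
  shift_volume(na_fix(restore(1)), na_fix(restore(2)), na_fix(restore(3)),
               valid,
               voxel_size = meta$voxel_size, geometry = meta$geometry,
               timepoints = meta$timepoints)
}

#' Write / read measurement tables as full-precision CSV
#'
#' GHz fields survive the round trip losslessly (17 significant digits).
#'
#' @param measurements Data frame (e.g. from [process_frame()]).
#' @param path CSV path.
#' @return `path` invisibly (write); a data frame (read).
#' @export
write_measurements <- function(measurements, path) {
  num <- vapply(measurements, is.numeric, logical(1))
  out <- measurements
  out[num] <- lapply(measurements[num], function(x)
    vapply(x, function(v)
      if (is.na(v)) "NA" else sprintf("%.17g", v), character(1)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) data_error(paste("no such file:", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# ---- run configuration -----------------------------------------------------

config_schema <- list(
  spectrometer = c("fsr", "n_orders_visible", "spectral_sampling",
                   "spatial_sampling", "dispersion_nonlinearity",
                   "instrument_sigma", "line_length"),
  notch = c("line_centers", "optical_depth", "doppler_fwhm"),
  camera = c("read_noise", "gain", "full_well", "exposure"),
  geometry = c("scattering_angle", "wavelength", "refractive_index",
               "sound_velocity"),
  fit = c("model_kind", "target_df", "min_orders", "r2_threshold",
          "weighted", "stokes_range", "antistokes_range"),
  registration = c("xy_scale", "y_offset", "x_offset"),
  simulation = c("photon_budget", "n_frames", "shift", "linewidth",
                 "reflectivity"),
  run = c("seed", "log_level"))

#' Read and validate a run configuration
#'
#' Parses the YAML run configuration shared by all pipeline stages and
#' validates it against the schema before any stage runs: unknown sections
#' or keys are rejected, and the spectrometer/geometry/camera sections are
#' instantiated through their typed constructors (which enforce the
#' physical invariants).
#'
#' @param path YAML file path.
#' @return List with `spectrometer` ([spectrometer_config()]), `geometry`
#'   ([geometry_config()]), `fit`, `registration`
#'   ([registration_transform()]), `simulation` and `run` entries.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) data_error(paste("no such config file:", path))
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(config_schema))
  if (length(unknown))
    data_error(paste("unknown config section(s):",
                     paste(unknown, collapse = ", ")))
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), config_schema[[sec]])
    if (length(bad))
      data_error(sprintf("unknown key(s) in '%s': %s", sec,
                         paste(bad, collapse = ", ")))
  }
  notch <- do.call(notch_config, raw$notch %||% list())
  camera <- do.call(camera_config, raw$camera %||% list())
  spectro <- do.call(spectrometer_config,
                     c(raw$spectrometer %||% list(),
                       list(notch = notch, camera = camera)))
  geom <- do.call(geometry_config, raw$geometry %||% list())
  reg <- do.call(registration_transform, raw$registration %||% list())
  fit <- utils::modifyList(
    list(model_kind = "lorentzian", target_df = 0.1, min_orders = 3,
         r2_threshold = 0.5, weighted = FALSE), raw$fit %||% list())
  if (!is.null(fit$stokes_range) || !is.null(fit$antistokes_range))
    fit$fit_ranges <- list(stokes = fit$stokes_range,
                           antistokes = fit$antistokes_range)
  sim <- utils::modifyList(
    list(photon_budget = 500, n_frames = 10, shift = 5.05, linewidth = 0.4,
         reflectivity = 1e4), raw$simulation %||% list())
  run <- utils::modifyList(list(seed = 1L, log_level = "info"),
                           raw$run %||% list())
  list(spectrometer = spectro, geometry = geom, fit = fit,
       registration = reg, simulation = sim, run = run)
}

#' Write a run configuration skeleton
#'
#' @param config Nested list of raw (YAML-level) settings.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# stable md5 hash of a config file, logged with every run for provenance
config_hash <- function(path) unname(tools::md5sum(path))
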