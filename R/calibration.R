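# Spectrometer calibration: locate the per-order Rayleigh anchors, fit the
# pixel-to-frequency dispersion law against reference lines of known
# frequency, and expose the pixel <-> GHz mapping used by the remapper.

# local maxima with a simple prominence measure (height above the higher of
# the two bounding valleys towards taller neighbours)
find_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(data.frame(pixel = integer(0), height = numeric(0),
                               prominence = numeric(0)))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(idx)) return(data.frame(pixel = integer(0), height = numeric(0),
                                      prominence = numeric(0)))
  # prominence = height minus the higher of the two key valleys (the lowest
  # point between the peak and the nearest taller sample on each side; the
  # whole-side minimum when no taller sample exists)
  prom <- vapply(idx, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1)]
    right <- y[seq(i + 1, n)]
    higher_l <- which(left >= h)
    higher_r <- which(right >= h)
    vl <- if (length(higher_l)) min(left[seq(max(higher_l), i - 1)]) else min(left)
    vr <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else min(right)
    h - max(vl, vr)
  }, numeric(1))
  data.frame(pixel = idx, height = y[idx], prominence = prom)
}

# 3-point parabolic sub-pixel refinement on log-intensity
refine_subpixel <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(as.numeric(i))
  eps <- max(y) * 1e-12 + 1e-12
  la <- log(y[i - 1] + eps); lb <- log(y[i] + eps); lc <- log(y[i + 1] + eps)
  denom <- la - 2 * lb + lc
  if (!is.finite(denom) || denom >= 0) return(as.numeric(i))
  d <- 0.5 * (la - lc) / denom
  as.numeric(i) + max(-0.5, min(0.5, d))
}

#' Detect the Rayleigh order anchors in a spectral row
#'
#' Finds the elastic (Rayleigh) peak of each visible VIPA order by
#' prominence-ranked local maxima constrained to a consistent inter-order
#' periodicity, and refines each position to sub-pixel accuracy with a
#' 3-point parabolic interpolation of log-intensity.  Brillouin peaks and
#' other non-periodic features are rejected by the periodicity constraint.
#'
#' @param frame_row Counts of one spectral row (vector).
#' @param expected_orders Number of anchors to find (>= 1).
#' @param min_prominence Minimum prominence as a fraction of the largest
#'   peak prominence (default 0.2).
#' @param pitch_tol Relative tolerance on the inter-anchor pitch (default 0.05).
#' @return Sorted sub-pixel anchor positions (length `expected_orders`).
#' @export
detect_order_anchors <- function(frame_row, expected_orders,
                                 min_prominence = 0.2, pitch_tol = 0.05) {
  y <- as.numeric(frame_row)
  pk <- find_peaks(y)
  pk <- pk[order(-pk$prominence), , drop = FALSE]
  pk <- pk[pk$prominence >= min_prominence * max(pk$prominence, 0), , drop = FALSE]
  if (nrow(pk) < expected_orders)
    data_error(sprintf(
      "anchor detection found %d candidate peak(s), expected %d (candidates at: %s)",
      nrow(pk), expected_orders,
      paste(utils::head(pk$pixel, 10), collapse = ", ")))
  if (expected_orders == 1) {
    best <- pk$pixel[1]
    return(refine_subpixel(y, best))
  }
  pk <- utils::head(pk, 12)                    # cap the combinatorial search
  pos <- sort(pk$pixel)
  prom <- pk$prominence[match(pos, pk$pixel)]
  best <- NULL; best_score <- -Inf
  # hypothesise the pitch from every candidate pair; anchors must occupy
  # CONSECUTIVE progression indices (adjacent orders), one peak per index;
  # among all such windows keep the one with the largest total prominence
  for (i in seq_along(pos)) for (j in seq_along(pos)) {
    if (j <= i) next
    for (m in seq_len(expected_orders - 1)) {
      pitch <- (pos[j] - pos[i]) / m
      if (pitch < 4) next
      tol <- max(2, pitch * pitch_tol)
      kk <- round((pos - pos[i]) / pitch)
      resid <- abs(pos - (pos[i] + kk * pitch))
      ok <- resid <= tol
      if (sum(ok) < expected_orders) next
      # one peak per progression index: the most prominent
      by_k <- split(which(ok), kk[ok])
      k_idx <- as.integer(names(by_k))
      pick <- vapply(by_k, function(w) w[which.max(prom[w])], integer(1))
      for (k0 in k_idx) {
        win <- match(k0 + seq_len(expected_orders) - 1L, k_idx)
        if (any(is.na(win))) next
        sel <- pick[win]
        score <- sum(prom[sel])
        if (score > best_score) {
          best_score <- score
          best <- pos[sel]
        }
      }
    }
  }
  if (is.null(best))
    data_error(sprintf(
      "no set of %d periodically spaced anchors found (candidates at: %s)",
      expected_orders, paste(pos, collapse = ", ")))
  sort(vapply(best, function(i) refine_subpixel(y, i), numeric(1)))
}

#' Calibration model: per-order pixel-to-frequency mapping
#'
#' @param order_anchors Sub-pixel Rayleigh anchor positions, strictly
#'   increasing, one per order.
#' @param fsr Free spectral range in GHz.
#' @param slope Linear dispersion coefficient in GHz/px.
#' @param quad Quadratic dispersion coefficient in GHz/px^2 (default 0).
#' @param n_pixels Width of the calibrated frame in pixels.
#' @param residual_rms Calibration residual rms in GHz.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(order_anchors, fsr, slope, quad = 0,
                              n_pixels = NULL, residual_rms = NA_real_) {
  if (is.unsorted(order_anchors, strictly = TRUE))
    stop("order anchors must be strictly increasing", call. = FALSE)
  if (fsr <= 0) stop("fsr must be > 0", call. = FALSE)
  if (slope <= 0) stop("dispersion slope must be > 0", call. = FALSE)
  pitch <- if (length(order_anchors) > 1) mean(diff(order_anchors)) else
    fsr / slope
  if (is.null(n_pixels)) n_pixels <- ceiling(max(order_anchors) + pitch / 2)
  structure(list(order_anchors = order_anchors, fsr = fsr, slope = slope,
                 quad = quad, pitch = pitch, n_pixels = n_pixels,
                 residual_rms = residual_rms),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("VIPA calibration: %d orders, FSR %.4f GHz, %.4f GHz/px%s\n",
              length(x$order_anchors), x$fsr, x$slope,
              if (x$quad != 0) sprintf(" (+%.2e GHz/px^2)", x$quad) else ""))
  cat(sprintf("  anchors (px): %s\n",
              paste(sprintf("%.2f", x$order_anchors), collapse = ", ")))
  cat(sprintf("  residual rms: %.4g GHz\n", x$residual_rms))
  invisible(x)
}

#' Fit the dispersion law from anchors and reference lines
#'
#' Least-squares estimate of the per-order pixel-to-frequency mapping and
#' of the free spectral range.  Each order's Rayleigh anchor defines 0 GHz
#' for that order; reference-line observations `(pixel, frequency_ghz)`
#' constrain the dispersion slope (and, optionally, a quadratic term), and
#' the FSR follows as the frequency spanned by one inter-anchor pitch.
#'
#' @param anchor_positions Sub-pixel anchor positions (>= 2 orders).
#' @param reference_lines Data frame with columns `pixel` and
#'   `frequency_ghz` (signed GHz relative to the laser line, reduced to the
#'   order each pixel sits in); >= 1 non-zero line.
#' @param nonlinear Fit a quadratic dispersion term (default FALSE).
#' @param n_pixels Optional frame width for the valid pixel ranges.
#' @return A [calibration_model()].
#' @export
fit_dispersion <- function(anchor_positions, reference_lines,
                           nonlinear = FALSE, n_pixels = NULL) {
  if (length(anchor_positions) < 2)
    data_error("need >= 2 order anchors to estimate the FSR")
  pitch <- mean(diff(anchor_positions))
  ref <- reference_lines[reference_lines$frequency_ghz != 0, , drop = FALSE]
  if (nrow(ref) < 1)
    data_error("need at least one non-zero reference line")
  # pixel offset from the nearest anchor
  near <- vapply(ref$pixel, function(p)
    which.min(abs(anchor_positions - p)), integer(1))
  dp <- ref$pixel - anchor_positions[near]
  f <- ref$frequency_ghz
  if (length(unique(dp)) < (1 + nonlinear))
    data_error("degenerate reference-line geometry: dispersion fit is rank-deficient")
  fit <- if (nonlinear) stats::lm(f ~ 0 + dp + I(dp^2)) else
    stats::lm(f ~ 0 + dp)
  cf <- stats::coef(fit)
  slope <- cf[[1]]
  quad <- if (nonlinear) cf[[2]] else 0
  if (!is.finite(slope) || slope <= 0)
    data_error("dispersion fit produced a non-positive slope")
  fsr <- slope * pitch + quad * pitch^2
  rms <- sqrt(mean(stats::resid(fit)^2))
  calibration_model(anchor_positions, fsr = fsr, slope = slope, quad = quad,
                    n_pixels = n_pixels, residual_rms = rms)
}

#' Calibrate from a calibration frame
#'
#' Full calibration driver: detects the order anchors (the brightest
#' periodic line set, i.e. the 0 GHz laser-lock line), locates the other
#' reference lines in every order, associates them with the supplied
#' frequency table by rank, and fits the dispersion law.
#'
#' @param frame A [spectral_frame()] (its row-average spectrum is used).
#' @param reference_lines Data frame with `frequency_ghz` (and optionally
#'   `relative_intensity`); defaults to the shipped Rb-87 D2 set.
#' @param expected_orders Number of visible orders (default 3).
#' @param nonlinear Fit a quadratic dispersion term (default FALSE).
#' @return A [calibration_model()].
#' @export
calibrate_frame <- function(frame, reference_lines = rb87_reference_lines(),
                            expected_orders = 3, nonlinear = FALSE) {
  stopifnot(inherits(frame, "spectral_frame"))
  if (is.numeric(reference_lines))
    reference_lines <- data.frame(frequency_ghz = reference_lines)
  if (nrow(reference_lines) < 2)
    data_error("calibration requires at least 2 reference lines")
  y <- colMeans(frame$counts)
  anchors <- detect_order_anchors(y, expected_orders)
  pitch <- mean(diff(anchors))
  # reference lines other than the anchor line, reduced to one period
  fsr0 <- reference_lines$frequency_ghz
  other <- sort(fsr0[fsr0 != 0])
  obs <- data.frame(pixel = numeric(0), frequency_ghz = numeric(0))
  pk <- find_peaks(y)
  pk <- pk[pk$prominence > 0.02 * max(pk$prominence), , drop = FALSE]
  for (k in seq_along(anchors)) {
    lo <- anchors[k] - pitch / 2
    hi <- anchors[k] + pitch / 2
    inord <- pk$pixel[pk$pixel > lo & pk$pixel < hi &
                        abs(pk$pixel - anchors[k]) > 2]
    if (!length(inord)) next
    inord <- sort(inord)
    # rank-match: non-anchor peaks in pixel order against the reference
    # lines sorted by frequency (lines must be resolvable and within half
    # an FSR of the lock line for this association to be unambiguous)
    cand <- utils::head(inord, length(other))
    if (length(cand) != length(other)) next
    subpx <- vapply(cand, function(i) refine_subpixel(y, i), numeric(1))
    obs <- rbind(obs, data.frame(pixel = subpx, frequency_ghz = other))
  }
  if (!nrow(obs))
    data_error("no reference lines found besides the order anchors")
  fit_dispersion(anchors, obs, nonlinear = nonlinear,
                 n_pixels = ncol(frame$counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# valid pixel range of one order: half a pitch either side of its anchor,
# clipped to the frame
order_pixel_range <- function(calib, order) {
  a <- calib$order_anchors[order]
  c(max(1, a - calib$pitch / 2), min(calib$n_pixels, a + calib$pitch / 2))
}

#' Convert a pixel position to signed frequency
#'
#' Signed GHz relative to the laser line, using the order's Rayleigh anchor
#' as the 0 GHz origin: exactly 0 at the anchor, +/- FSR/2 at the
#' midpoints to the neighbouring orders (linear model).
#'
#' @param calib A [calibration_model()].
#' @param order Order index (1-based).
#' @param pixel Fractional pixel position(s) within the order's valid range.
#' @return Frequency in GHz.
#' @export
pixel_to_frequency <- function(calib, order, pixel) {
  stopifnot(inherits(calib, "calibration_model"))
  if (order < 1 || order > length(calib$order_anchors))
    stop("order out of range", call. = FALSE)
  rng <- order_pixel_range(calib, order)
  if (any(pixel < rng[1] - 1e-9 | pixel > rng[2] + 1e-9))
    stop(sprintf("pixel outside order %d valid range [%.2f, %.2f]",
                 order, rng[1], rng[2]), call. = FALSE)
  dp <- pixel - calib$order_anchors[order]
  calib$slope * dp + calib$quad * dp^2
}

#' Convert a signed frequency to a pixel position
#'
#' Inverse of [pixel_to_frequency()] within one order.
#'
#' @inheritParams pixel_to_frequency
#' @param freq Signed frequency (GHz) within (-FSR/2, FSR/2).
#' @return Fractional pixel position.
#' @export
frequency_to_pixel <- function(calib, order, freq) {
  stopifnot(inherits(calib, "calibration_model"))
  a <- calib$order_anchors[order]
  if (calib$quad == 0) return(a + freq / calib$slope)
  # smaller-magnitude root of quad*dp^2 + slope*dp - freq = 0
  disc <- calib$slope^2 + 4 * calib$quad * freq
  a + (-calib$slope + sqrt(disc)) / (2 * calib$quad)
}

#' Write / read a calibration model as JSON
#'
#' @param calib A [calibration_model()].
#' @param path Output file path.
#' @return `path`, invisibly (write) or a `calibration_model` (read).
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_model"))
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(x$order_anchors, x$fsr, x$slope, x$quad %||% 0,
                    n_pixels = x$n_pixels, residual_rms = x$residual_rms)
}
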