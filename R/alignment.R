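# Windowed-FFT orientation analysis of fibrous images, alignment
# statistics, and intensity-threshold area coverage.
#
# Each window is mean-subtracted, Hann-tapered and Fourier transformed;
# the dominant spectral orientation is the principal axis of the angular
# (doubled-angle) first moment of spectral energy on an annular frequency
# band -- equivalent to the structure-tensor axis but computed in the
# spectral domain, and free of the angular quantization that a discrete
# 1-degree energy histogram suffers at low spectral radius. The
# real-space fiber angle is the spectral angle rotated by 90 degrees (a
# fiber's energy concentrates perpendicular to its axis). The window's
# anisotropy weight is the resultant length of the doubled-angle energy
# distribution, so bright but isotropic windows carry little weight in
# image-level statistics.

#' Orientation-analysis configuration
#'
#' The two legacy scan parameters of windowed orientation tools map here
#' to an explicit window edge and scan step: `window_px` is the FFT window
#' (a "pattern size" multiplier of a 32-px base window) and `step_px` the
#' scan resolution.
#'
#' @param window_px FFT window edge in pixels (>= 8; power of two
#'   recommended).
#' @param step_px scan step between window origins (>= 1).
#' @param um_per_px physical calibration (optional, metadata only).
#' @param energy_floor windows whose spectral energy falls below this
#'   fraction of the median window energy are flagged invalid.
#' @param band_px fiber-scale band as wavelengths in pixels,
#'   `c(min, max)`: spectral radii outside `[window_px/max, window_px/min]`
#'   cycles/window are ignored.
#' @return an `orientation_config` list.
#' @export
orientation_config <- function(window_px = 64L, step_px = 16L,
                               um_per_px = NULL, energy_floor = 0.05,
                               band_px = c(3, 32)) {
  if (window_px < 8L) stop_bad_arg("`window_px` must be >= 8")
  if (step_px < 1L) stop_bad_arg("`step_px` must be >= 1")
  if (energy_floor < 0) stop_bad_arg("`energy_floor` must be >= 0")
  structure(list(window_px = as.integer(window_px),
                 step_px = as.integer(step_px), um_per_px = um_per_px,
                 energy_floor = energy_floor, band_px = band_px),
            class = "orientation_config")
}

# per-window spectral geometry, computed once per window size: Hann
# taper, annular band mask, and the doubled-angle direction components of
# every FFT bin (angle only; radius enters only through the band mask)
spectral_geometry <- function(n, band_px) {
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  taper <- outer(hann, hann)
  fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n  # cycles/px along rows
  FR <- matrix(rep(fr, times = n), n, n)
  FC <- matrix(rep(fr, each = n), n, n)
  radius <- sqrt(FR^2 + FC^2)
  # spatial frame: x = +col, y = -row; wave-vector components
  FX <- FC; FY <- -FR
  band <- radius >= 1 / band_px[2L] & radius <= pmin(1 / band_px[1L], 0.45)
  band[1L, 1L] <- FALSE  # DC
  ux <- FX / radius; uy <- FY / radius
  ux[1L, 1L] <- 0; uy[1L, 1L] <- 0
  list(taper = taper, band = band,
       cos2 = (ux^2 - uy^2)[band], sin2 = (2 * ux * uy)[band])
}

#' Per-window dominant orientation field of an image
#'
#' @param image numeric matrix (grayscale, any range).
#' @param config an [orientation_config()].
#' @return an `orientation_field` tibble: window centers (`row`, `col`,
#'   pixels), `angle_deg` (dominant fiber orientation in `[0, 180)`),
#'   `weight` (spectral anisotropy in `[0, 1]`), `energy`, `valid`.
#' @export
orientation_field <- function(image, config = orientation_config()) {
  stopifnot(is.matrix(image), inherits(config, "orientation_config"))
  n <- config$window_px
  H <- nrow(image); W <- ncol(image)
  if (H < n || W < n) stop_bad_arg("image smaller than one analysis window")
  geom <- spectral_geometry(n, config$band_px)
  r0s <- seq(1L, H - n + 1L, by = config$step_px)
  c0s <- seq(1L, W - n + 1L, by = config$step_px)
  grid <- tidyr::expand_grid(r0 = r0s, c0 = c0s)
  one <- function(r0, c0) {
    win <- image[r0:(r0 + n - 1L), c0:(c0 + n - 1L)]
    win <- (win - mean(win)) * geom$taper
    P <- Mod(fft(win))^2
    E <- P[geom$band]
    tot <- sum(E)
    if (tot <= 0) return(c(NA_real_, NA_real_, 0))
    C2 <- sum(E * geom$cos2) / tot
    S2 <- sum(E * geom$sin2) / tot
    spec_deg <- 0.5 * atan2(S2, C2) * 180 / pi
    fiber_deg <- (spec_deg + 90) %% 180
    c(fiber_deg, sqrt(C2^2 + S2^2), tot)
  }
  m <- t(mapply(one, grid$r0, grid$c0))
  energy <- m[, 3L]
  floor_e <- config$energy_floor * median(energy)
  valid <- is.finite(m[, 1L]) & energy >= floor_e
  out <- tibble::tibble(row = grid$r0 + (n - 1) / 2,
                        col = grid$c0 + (n - 1) / 2,
                        angle_deg = ifelse(valid, m[, 1L], NA_real_),
                        weight = ifelse(valid, m[, 2L], NA_real_),
                        energy = energy, valid = valid)
  structure(out, config = config,
            class = c("orientation_field", class(out)))
}

#' Weighted aligned fraction of an orientation field
#'
#' Weight-weighted fraction of valid windows whose axial angular distance
#' to the reference orientation is at most `tolerance_deg`.
#'
#' @param field an [orientation_field()] result.
#' @param reference_angle_deg reference orientation (e.g. the pattern or
#'   superior angle), degrees.
#' @param tolerance_deg alignment half-window (default 10 degrees).
#' @return an `alignment_result` one-row tibble: `reference_angle_deg`,
#'   `tolerance_deg`, `aligned_fraction`, `n_windows`.
#' @export
aligned_fraction <- function(field, reference_angle_deg,
                             tolerance_deg = 10) {
  stopifnot(inherits(field, "orientation_field"))
  v <- field[field$valid, ]
  if (nrow(v) == 0L) stop_bad_arg("no valid orientation windows")
  hit <- axial_diff_deg(v$angle_deg, reference_angle_deg) <= tolerance_deg
  frac <- sum(v$weight * hit) / sum(v$weight)
  structure(tibble::tibble(reference_angle_deg = reference_angle_deg,
                           tolerance_deg = tolerance_deg,
                           aligned_fraction = frac,
                           n_windows = nrow(v)),
            class = c("alignment_result", class(tibble::tibble())))
}

#' Dominant global ("superior") orientation of a field
#'
#' Weight-weighted axial circular mean of the window orientations.
#'
#' @param field an [orientation_field()] result.
#' @param min_resultant minimum doubled-angle resultant length; below it
#'   (e.g. a balanced bimodal field) there is no meaningful dominant
#'   orientation and an error is raised.
#' @return angle in degrees, `[0, 180)`.
#' @export
superior_angle <- function(field, min_resultant = 0.05) {
  stopifnot(inherits(field, "orientation_field"))
  v <- field[field$valid, ]
  if (nrow(v) == 0L) stop_bad_arg("no valid orientation windows")
  am <- axial_mean_deg(v$angle_deg, v$weight)
  if (!is.finite(am$resultant) || am$resultant < min_resultant)
    stop_bad_arg("orientation distribution has no dominant axis; supply a reference angle explicitly")
  am$mean_deg
}

#' Area coverage of a region by bright signal
#'
#' Percent of region pixels whose intensity exceeds a threshold chosen by
#' Otsu's method (default) or given as a fixed value.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param region_mask logical matrix of the same shape (`NULL` = whole
#'   frame).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold when `threshold_method = "fixed"`.
#' @return coverage percent (0-100) with the applied threshold attached as
#'   attribute `"threshold"`.
#' @export
area_coverage <- function(image, region_mask = NULL,
                          threshold_method = c("otsu", "fixed"),
                          fixed_value = 0.5) {
  threshold_method <- match.arg(threshold_method)
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(all(dim(image) == dim(region_mask)))
  if (!any(region_mask)) stop_bad_arg("empty region mask")
  px <- image[region_mask]
  thr <- if (threshold_method == "otsu") otsu_threshold(px) else fixed_value
  structure(100 * mean(px > thr), threshold = thr)
}

# Otsu's threshold on intensities in [0, 1] (256-bin histogram);
# degenerate (single-level) inputs return the level itself so nothing
# exceeds the threshold
otsu_threshold <- function(px, levels = 256L) {
  if (diff(range(px)) <= .Machine$double.eps) return(px[1L])
  if (requireNamespace("EBImage", quietly = TRUE)) {
    return(EBImage::otsu(matrix(pmin(pmax(px, 0), 1), nrow = 1L),
                         range = c(0, 1), levels = levels))
  }
  breaks <- seq(0, 1, length.out = levels + 1L)
  h <- tabulate(findInterval(pmin(pmax(px, 0), 1), breaks,
                             rightmost.closed = TRUE), nbins = levels)
  w <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w1 <- cumsum(w)
  mu1 <- cumsum(w * mids)
  mu_t <- mu1[levels]
  sigma_b <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Change in area coverage between two co-registered images
#'
#' @param image_start,image_end numeric matrices of identical shape.
#' @param field_mask optional logical region mask applied to both.
#' @param ... passed to [area_coverage()].
#' @return change in percentage points (`end - start`), with both
#'   coverages attached as attributes.
#' @export
cell_coverage_change <- function(image_start, image_end, field_mask = NULL,
                                 ...) {
  if (!all(dim(image_start) == dim(image_end)))
    stop_bad_arg("images must have identical shapes")
  a <- area_coverage(image_start, field_mask, ...)
  b <- area_coverage(image_end, field_mask, ...)
  structure(as.numeric(b) - as.numeric(a),
            coverage_start_pct = as.numeric(a),
            coverage_end_pct = as.numeric(b))
}
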