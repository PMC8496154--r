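# Optical-mapping analysis of calcium-transient movies.
#
# Per-pixel fluorescence traces are spatially binned, temporally smoothed
# and normalized per beat; activation is the time of maximum upstroke
# derivative (with parabolic sub-sample refinement, and a plateau-midpoint
# tie-break for upstrokes whose derivative is constant); rise-up time is
# the 10-90% upstroke duration; the transient duration (CaTD80) runs from
# activation to 80% relaxation. Conduction velocity comes from local plane
# fits to the activation map.

# centered moving average down the columns of a matrix, shrinking windows
# at the ends
moving_average_mat <- function(F, width) {
  if (width <= 1L) return(F)
  n <- nrow(F)
  half <- (width - 1L) %/% 2L
  cs <- rbind(0, apply(F, 2L, cumsum))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

#' Extract per-pixel calcium traces from a movie
#'
#' Bins the movie `bin_px x bin_px` by averaging, smooths each trace with
#' a centered moving average, flags flat or saturated traces invalid, and
#' segments the recording into beats (by the pacing period when stated,
#' else by detecting upstroke crossings of the mean trace).
#'
#' @param movie an [image_stack()].
#' @param bin_px spatial binning factor (>= 1).
#' @param smooth_width moving-average width in samples (default 5).
#' @param pacing_hz pacing rate if the recording was paced; `NULL` means
#'   unpaced (beats are auto-detected from the field-mean trace).
#' @param min_amplitude minimum raw peak-to-baseline range for a trace to
#'   be considered a real transient (intensity units).
#' @param saturation_frac traces spending more than this fraction of
#'   samples at >= 0.999 intensity are flagged saturated (invalid).
#' @return a `calcium_traces` object: `t_ms`, smoothed trace matrix `f`
#'   (`T x N`), `map` tibble (`trace_id`, `row`, `col`, binned-grid
#'   coordinates plus original-pixel centers, `baseline`, `amplitude`,
#'   `valid`), and `beats` tibble (`beat`, `t_start_ms`, `t_end_ms`).
#' @export
extract_traces <- function(movie, bin_px = 1L, smooth_width = 5L,
                           pacing_hz = NULL, min_amplitude = 0.1,
                           saturation_frac = 0.2) {
  stopifnot(inherits(movie, "image_stack"))
  H <- dim(movie)[1L]; W <- dim(movie)[2L]; T_ <- dim(movie)[3L]
  bin_px <- as.integer(bin_px)
  if (bin_px < 1L) stop_bad_arg("`bin_px` must be >= 1")
  Hb <- H %/% bin_px; Wb <- W %/% bin_px
  if (Hb < 1L || Wb < 1L) stop_bad_arg("`bin_px` larger than the frame")
  fps <- 1 / attr(movie, "frame_interval_s")
  t_ms <- (seq_len(T_) - 1L) * 1000 / fps

  # block-average by accumulating the bin offsets (bin_px^2 array adds)
  acc <- array(0, c(Hb, Wb, T_))
  sub <- unclass(movie)[seq_len(Hb * bin_px), seq_len(Wb * bin_px), ,
                        drop = FALSE]
  for (i in seq_len(bin_px)) {
    for (j in seq_len(bin_px)) {
      acc <- acc + sub[seq(i, by = bin_px, length.out = Hb),
                       seq(j, by = bin_px, length.out = Wb), ,
                       drop = FALSE]
    }
  }
  binned <- acc / bin_px^2
  Fraw <- matrix(aperm(binned, c(3L, 1L, 2L)), nrow = T_)  # T x (Hb*Wb)
  # trace_id runs row-major over the binned grid
  map <- tidyr::expand_grid(row = seq_len(Hb), col = seq_len(Wb))
  Fraw <- Fraw[, (map$col - 1L) * Hb + map$row, drop = FALSE]
  Fs <- moving_average_mat(Fraw, smooth_width)

  rng_lo <- apply(Fraw, 2L, min); rng_hi <- apply(Fraw, 2L, max)
  sat <- colMeans(Fraw >= 0.999)
  valid <- (rng_hi - rng_lo) >= min_amplitude & sat <= saturation_frac
  map$trace_id <- seq_len(nrow(map))
  map$row_px <- (map$row - 0.5) * bin_px + 0.5
  map$col_px <- (map$col - 0.5) * bin_px + 0.5
  map$baseline <- rng_lo
  map$amplitude <- rng_hi - rng_lo
  map$valid <- valid
  map <- map[, c("trace_id", "row", "col", "row_px", "col_px",
                 "baseline", "amplitude", "valid")]

  beats <- segment_beats(t_ms, Fs, valid, pacing_hz)
  structure(list(t_ms = t_ms, f = Fs, map = map, beats = beats),
            pixel_um = attr(movie, "pixel_um"),
            pixel_um_eff = attr(movie, "pixel_um") * bin_px,
            fps = fps, bin_px = bin_px,
            class = "calcium_traces")
}

# beat windows: pacing period when given, else rising 50%-crossings of
# the field-mean trace with window boundaries midway between onsets
segment_beats <- function(t_ms, Fs, valid, pacing_hz) {
  T_end <- max(t_ms) + (t_ms[2L] - t_ms[1L])
  if (!is.null(pacing_hz)) {
    period <- 1000 / pacing_hz
    n <- max(1L, ceiling(T_end / period))
    return(tibble::tibble(beat = seq_len(n),
                          t_start_ms = (seq_len(n) - 1) * period,
                          t_end_ms = pmin(seq_len(n) * period, T_end)))
  }
  if (!any(valid)) return(tibble::tibble(beat = 1L, t_start_ms = 0,
                                         t_end_ms = T_end))
  mt <- rowMeans(Fs[, valid, drop = FALSE])
  level <- (min(mt) + max(mt)) / 2
  up <- which(mt[-length(mt)] < level & mt[-1L] >= level)
  if (length(up) <= 1L) return(tibble::tibble(beat = 1L, t_start_ms = 0,
                                              t_end_ms = T_end))
  onset <- t_ms[up]
  cuts <- c(0, (onset[-1L] + onset[-length(onset)]) / 2, T_end)
  tibble::tibble(beat = seq_along(onset), t_start_ms = cuts[-length(cuts)],
                 t_end_ms = cuts[-1L])
}

#' Detected beat rate of a recording
#'
#' @param traces an [extract_traces()] result (use `pacing_hz = NULL` for
#'   spontaneous recordings).
#' @return beats per minute implied by the detected beat count over the
#'   recording duration.
#' @export
beat_rate_bpm <- function(traces) {
  stopifnot(inherits(traces, "calcium_traces"))
  dur_ms <- max(traces$beats$t_end_ms)
  nrow(traces$beats) / dur_ms * 60000
}

# normalize a windowed trace to [0, 1]; returns NULL if flat
normalize_window <- function(f) {
  lo <- min(f); hi <- max(f)
  if (hi - lo <= 0) return(NULL)
  (f - lo) / (hi - lo)
}

#' Activation time of one calcium transient
#'
#' Time of maximum upstroke derivative. A parabolic fit to the derivative
#' samples around the discrete maximum gives sub-sample precision; when
#' the derivative is constant over the upstroke (an exactly linear rise)
#' the plateau midpoint is returned.
#'
#' @param t_ms sample times (ms), strictly increasing.
#' @param f normalized fluorescence samples for one beat.
#' @param noise_floor minimum derivative peak (per ms) for the trace to be
#'   accepted.
#' @return activation time in ms, or `NA` if the upstroke is not resolved.
#' @export
activation_time <- function(t_ms, f, noise_floor = 0) {
  n <- length(f)
  if (n < 3L) return(NA_real_)
  dt <- diff(t_ms)
  df <- diff(f) / dt
  t_mid <- (t_ms[-n] + t_ms[-1L]) / 2
  i <- which.max(df)
  dmax <- df[i]
  if (!is.finite(dmax) || dmax <= noise_floor) return(NA_real_)
  plateau <- abs(df - dmax) <= 1e-9 * max(abs(dmax), 1)
  runs <- rle(plateau)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- which(runs$values & starts <= i & ends >= i)
  if (length(k) == 1L && runs$lengths[k] > 1L) {
    return((t_mid[starts[k]] + t_mid[ends[k]]) / 2)
  }
  if (i > 1L && i < length(df)) {
    dm <- df[i - 1L]; dp <- df[i + 1L]
    den <- dm - 2 * dmax + dp
    if (den < 0) {
      delta <- 0.5 * (dm - dp) / den
      delta <- max(min(delta, 0.5), -0.5)
      return(t_mid[i] + delta * mean(dt))
    }
  }
  t_mid[i]
}

#' Rise-up time (10-90% upstroke duration) of one transient
#'
#' @param t_ms,f as in [activation_time()]; `f` need not be normalized
#'   (thresholds are relative to the beat's own range).
#' @param lo,hi fractional thresholds (defaults 0.1 and 0.9).
#' @return duration in ms, or `NA` if either crossing is missing.
#' @export
rise_up_time <- function(t_ms, f, lo = 0.1, hi = 0.9) {
  fz <- normalize_window(f)
  if (is.null(fz)) return(NA_real_)
  p <- which.max(fz)
  if (p < 2L) return(NA_real_)
  t10 <- first_crossing(t_ms[1:p], fz[1:p], lo, rising = TRUE)
  t90 <- first_crossing(t_ms[1:p], fz[1:p], hi, rising = TRUE)
  if (is.na(t10) || is.na(t90)) return(NA_real_)
  t90 - t10
}

#' Transient duration at 80% relaxation (CaTD80)
#'
#' Duration from the activation time (maximum upstroke derivative, the
#' default) or from the 50%-upstroke crossing, to the first post-peak
#' return to 20% of peak amplitude (80% relaxation), with linear
#' interpolation at the crossing.
#'
#' @param t_ms,f as in [activation_time()].
#' @param start `"activation"` or `"half_upstroke"`.
#' @param level relaxation crossing level as a fraction of peak (default
#'   0.2, i.e. 80% recovered).
#' @return duration in ms, or `NA` when the trace never recovers.
#' @export
catd80 <- function(t_ms, f, start = c("activation", "half_upstroke"),
                   level = 0.2) {
  start <- match.arg(start)
  fz <- normalize_window(f)
  if (is.null(fz)) return(NA_real_)
  p <- which.max(fz)
  t0 <- if (start == "activation") activation_time(t_ms, fz)
        else first_crossing(t_ms[1:p], fz[1:p], 0.5, rising = TRUE)
  if (is.na(t0)) return(NA_real_)
  t_rec <- first_crossing(t_ms[p:length(fz)], fz[p:length(fz)], level,
                          rising = FALSE)
  if (is.na(t_rec)) return(NA_real_)
  t_rec - t0
}

#' Per-trace transient metrics over one beat
#'
#' Applies [activation_time()], [rise_up_time()] and [catd80()] to every
#' valid trace within the chosen beat window (each trace min-max
#' normalized within the window).
#'
#' @param traces an [extract_traces()] result.
#' @param beat beat number (row of `traces$beats`).
#' @param catd_start passed to [catd80()] as `start`.
#' @return a `cat_metrics` tibble: `trace_id`, `row`, `col`,
#'   `activation_time_ms` (absolute, recording clock), `rise_up_time_ms`,
#'   `catd80_ms`, `valid`.
#' @export
cat_metrics <- function(traces, beat = 1L, catd_start = "activation") {
  stopifnot(inherits(traces, "calcium_traces"))
  bw <- traces$beats[traces$beats$beat == beat, ]
  if (nrow(bw) != 1L) stop_bad_arg("no such beat window")
  sel <- traces$t_ms >= bw$t_start_ms & traces$t_ms < bw$t_end_ms
  tw <- traces$t_ms[sel]
  res <- purrr::map(seq_len(nrow(traces$map)), function(j) {
    if (!traces$map$valid[j])
      return(c(NA_real_, NA_real_, NA_real_))
    fw <- normalize_window(traces$f[sel, j])
    if (is.null(fw)) return(c(NA_real_, NA_real_, NA_real_))
    c(activation_time(tw, fw),
      rise_up_time(tw, fw),
      catd80(tw, fw, start = catd_start))
  })
  m <- do.call(rbind, res)
  out <- tibble::tibble(trace_id = traces$map$trace_id,
                        row = traces$map$row, col = traces$map$col,
                        activation_time_ms = m[, 1L],
                        rise_up_time_ms = m[, 2L], catd80_ms = m[, 3L])
  out$valid <- is.finite(out$activation_time_ms)
  structure(out, pixel_um_eff = attr(traces, "pixel_um_eff"),
            fps = attr(traces, "fps"),
            grid_dim = c(max(out$row), max(out$col)),
            class = c("cat_metrics", class(out)))
}

#' Build an activation map from per-trace metrics
#'
#' Re-zeroes activation times to the earliest valid activation.
#'
#' @param metrics a [cat_metrics()] tibble (>= 10 valid traces required).
#' @param median_filter apply a 3x3 median filter to the map (off by
#'   default; flagged in the attributes when used).
#' @return an `activation_map` tibble: `row`, `col`, `x_um`, `y_um`
#'   (y up), `t_act_ms` (min over valid pixels = 0), `valid`.
#' @export
build_activation_map <- function(metrics, median_filter = FALSE) {
  stopifnot(inherits(metrics, "cat_metrics"))
  if (sum(metrics$valid) < 10L)
    stop_bad_arg("fewer than 10 valid activation times")
  gd <- attr(metrics, "grid_dim")
  h <- attr(metrics, "pixel_um_eff")
  t_act <- metrics$activation_time_ms - min(
    metrics$activation_time_ms[metrics$valid])
  if (median_filter) {
    M <- matrix(NA_real_, gd[1L], gd[2L])
    M[cbind(metrics$row, metrics$col)] <- t_act
    Mf <- M
    for (r in seq_len(gd[1L])) {
      for (cc in seq_len(gd[2L])) {
        rr <- max(1L, r - 1L):min(gd[1L], r + 1L)
        ccs <- max(1L, cc - 1L):min(gd[2L], cc + 1L)
        v <- M[rr, ccs]
        if (any(is.finite(v))) Mf[r, cc] <- median(v, na.rm = TRUE)
      }
    }
    t_act <- Mf[cbind(metrics$row, metrics$col)]
  }
  out <- tibble::tibble(row = metrics$row, col = metrics$col,
                        x_um = metrics$col * h, y_um = -metrics$row * h,
                        t_act_ms = t_act,
                        valid = metrics$valid & is.finite(t_act))
  structure(out, pixel_um_eff = h, fps = attr(metrics, "fps"),
            grid_dim = gd, median_filter = median_filter,
            class = c("activation_map", class(out)))
}

#' Conduction-velocity field from an activation map
#'
#' Fits a plane to the activation time over sliding `k x k` windows; the
#' local velocity is `grad(t) / |grad(t)|^2`, reported in cm/s with the
#' propagation direction in the 90-degrees-up angle convention. Windows
#' with too few valid pixels, a fit residual above `residual_max_ms`, or a
#' gradient below `grad_floor_ms_um` (speed unresolvably high) are
#' excluded.
#'
#' @param map a [build_activation_map()] result.
#' @param k window edge length in map pixels (default 5).
#' @param residual_max_ms maximum RMS plane-fit residual (default: one
#'   frame interval).
#' @param grad_floor_ms_um minimum `|grad t|`; the default `1e-3` ms/um
#'   caps resolvable speed at 100 cm/s.
#' @param min_frac minimum fraction of valid pixels per window.
#' @return a `velocity_field` object: `windows` tibble (`x_um`, `y_um`,
#'   `gx`, `gy`, `speed_cm_s`, `angle_deg`, `resid_rms_ms`, `valid`) plus
#'   `mean_cv_cm_s` and `n_valid`.
#' @export
conduction_velocity <- function(map, k = 5L, residual_max_ms = NULL,
                                grad_floor_ms_um = 1e-3, min_frac = 0.8) {
  stopifnot(inherits(map, "activation_map"))
  gd <- attr(map, "grid_dim")
  h <- attr(map, "pixel_um_eff")
  if (is.null(residual_max_ms)) residual_max_ms <- 1000 / attr(map, "fps")
  M <- matrix(NA_real_, gd[1L], gd[2L])
  M[cbind(map$row, map$col)] <- ifelse(map$valid, map$t_act_ms, NA_real_)
  if (gd[1L] < k || gd[2L] < k)
    stop_bad_arg("activation map smaller than the fitting window")
  wins <- tidyr::expand_grid(r0 = seq_len(gd[1L] - k + 1L),
                             c0 = seq_len(gd[2L] - k + 1L))
  offs <- tidyr::expand_grid(dr = 0:(k - 1L), dc = 0:(k - 1L))
  fit_one <- function(r0, c0) {
    rows <- r0 + offs$dr; cols <- c0 + offs$dc
    tv <- M[cbind(rows, cols)]
    ok <- is.finite(tv)
    if (mean(ok) < min_frac)
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    x <- cols[ok] * h; y <- -rows[ok] * h
    X <- cbind(1, x, y)
    ft <- stats::.lm.fit(X, tv[ok])
    res <- sqrt(mean(ft$residuals^2))
    c(ft$coefficients[2L], ft$coefficients[3L], res,
      mean(ok))
  }
  m <- t(mapply(fit_one, wins$r0, wins$c0))
  gx <- m[, 1L]; gy <- m[, 2L]; resid <- m[, 3L]
  gmag <- sqrt(gx^2 + gy^2)
  speed <- (1 / gmag) / 10  # um/ms -> cm/s
  angle <- (atan2(gy, gx) * 180 / pi) %% 360
  valid <- is.finite(gmag) & gmag >= grad_floor_ms_um &
    resid <= residual_max_ms
  if (!any(valid))
    stop_bad_arg("no window resolved a propagating wavefront (activation may be uniform)")
  windows <- tibble::tibble(
    x_um = (wins$c0 + (k - 1) / 2) * h,
    y_um = -(wins$r0 + (k - 1) / 2) * h,
    gx = gx, gy = gy,
    speed_cm_s = ifelse(valid, speed, NA_real_),
    angle_deg = ifelse(valid, angle, NA_real_),
    resid_rms_ms = resid, valid = valid)
  structure(list(windows = windows,
                 mean_cv_cm_s = mean(speed[valid]),
                 n_valid = sum(valid),
                 pixel_um_eff = h, k = k),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d/%d valid windows; mean CV %.2f cm/s\n",
              x$n_valid, nrow(x$windows), x$mean_cv_cm_s))
  invisible(x)
}

#' Conduction-velocity anisotropy about a pattern axis
#'
#' Longitudinal speed is the mean over windows whose propagation direction
#' lies within `half_width_deg` of the axis (axially, mod 180); transverse
#' likewise about the perpendicular.
#'
#' @param vf a [conduction_velocity()] result.
#' @param axis_angle_deg pattern axis, degrees CCW from +x.
#' @param half_width_deg sector half-width (default 22.5).
#' @param min_windows minimum valid windows required per sector.
#' @return one-row tibble: `cv_long_cm_s`, `cv_trans_cm_s`,
#'   `anisotropy_ratio`, `n_long`, `n_trans`.
#' @export
anisotropy <- function(vf, axis_angle_deg, half_width_deg = 22.5,
                       min_windows = 5L) {
  stopifnot(inherits(vf, "velocity_field"))
  w <- vf$windows[vf$windows$valid, ]
  d_long <- axial_diff_deg(w$angle_deg, axis_angle_deg)
  d_trans <- axial_diff_deg(w$angle_deg, axis_angle_deg + 90)
  long <- w$speed_cm_s[d_long <= half_width_deg]
  trans <- w$speed_cm_s[d_trans <= half_width_deg]
  if (length(long) < min_windows || length(trans) < min_windows)
    stop_bad_arg(sprintf(
      "too few windows in a sector (longitudinal %d, transverse %d; need >= %d)",
      length(long), length(trans), min_windows))
  tibble::tibble(cv_long_cm_s = mean(long), cv_trans_cm_s = mean(trans),
                 anisotropy_ratio = mean(long) / mean(trans),
                 n_long = length(long), n_trans = length(trans))
}
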