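# Synthetic calcium-transient movies with closed-form metric truth.
#
# Each pixel's fluorescence follows a piecewise template: flat baseline,
# linear upstroke of duration `rise_time_ms` starting at the pixel's
# activation time, then single-exponential decay with time constant
# `decay_tau_ms`. The template is chosen so every optical-mapping metric
# has a closed form: with activation defined at the upstroke-derivative
# plateau midpoint (t_a + R/2), the 10-90% rise-up time is 0.8 R and the
# duration to 80% relaxation is R/2 + tau * ln 5. Activation times come
# from elliptical wavefront geometry (planar as the degenerate case), so
# conduction velocity and its anisotropy are also known exactly.

#' Ground-truth calcium wave description
#'
#' @param cv_long_cm_s,cv_trans_cm_s wavefront speeds (cm/s) along and
#'   across the pattern axis; `cv_long >= cv_trans > 0`.
#' @param axis_angle_deg pattern (longitudinal) axis, degrees CCW from +x,
#'   image-up = 90.
#' @param origin_px wave origin as `c(row, col)` in pixels (elliptical
#'   geometry); ignored for planar geometry.
#' @param geometry `"elliptical"` (point source, elliptical isochrones) or
#'   `"planar"` (plane wave traveling along the axis).
#' @param rise_time_ms full linear upstroke duration R (> 0).
#' @param decay_tau_ms exponential decay constant tau (> 0).
#' @param pacing_hz pacing rate; beats repeat at `1000 / pacing_hz` ms
#'   (default 1 Hz pacing).
#' @param pixel_um,fps acquisition geometry; defaults match a high-speed
#'   optical-mapping camera (60 um/pixel, 1000 fps).
#' @param height_px,width_px mapped field size in pixels.
#' @param baseline,amplitude raw-intensity baseline and transient
#'   amplitude.
#' @param t_start_ms quiescent time before the earliest activation.
#' @param noise_sd Gaussian noise sd as a fraction of `amplitude`.
#' @param seed integer seed for the noise.
#' @return a `wave_truth` list.
#' @export
wave_truth <- function(cv_long_cm_s = 12, cv_trans_cm_s = 12,
                       axis_angle_deg = 0, origin_px = NULL,
                       geometry = c("planar", "elliptical"),
                       rise_time_ms = 50, decay_tau_ms = 150,
                       pacing_hz = 1, pixel_um = 60, fps = 1000,
                       height_px = 100L, width_px = 100L,
                       baseline = 0.1, amplitude = 0.8,
                       t_start_ms = 20, noise_sd = 0, seed = 1L) {
  geometry <- match.arg(geometry)
  if (!(cv_long_cm_s >= cv_trans_cm_s && cv_trans_cm_s > 0))
    stop_bad_arg("need cv_long_cm_s >= cv_trans_cm_s > 0")
  if (rise_time_ms <= 0) stop_bad_arg("`rise_time_ms` must be > 0")
  if (decay_tau_ms <= 0) stop_bad_arg("`decay_tau_ms` must be > 0")
  if (pixel_um <= 0 || fps <= 0) stop_bad_arg("invalid acquisition geometry")
  if (is.null(origin_px)) origin_px <- c((height_px + 1) / 2, (width_px + 1) / 2)
  structure(list(cv_long_cm_s = cv_long_cm_s, cv_trans_cm_s = cv_trans_cm_s,
                 axis_angle_deg = axis_angle_deg, origin_px = origin_px,
                 geometry = geometry, rise_time_ms = rise_time_ms,
                 decay_tau_ms = decay_tau_ms, pacing_hz = pacing_hz,
                 pixel_um = pixel_um, fps = fps,
                 height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 baseline = baseline, amplitude = amplitude,
                 t_start_ms = t_start_ms, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "wave_truth")
}

# analytic activation-time map (ms, earliest = t_start_ms) for a truth;
# returns H x W matrix
activation_truth_map <- function(truth) {
  H <- truth$height_px; W <- truth$width_px
  cols <- matrix(rep(seq_len(W), each = H), H, W)
  rows <- matrix(rep(seq_len(H), times = W), H, W)
  # user frame: x = col, y = up
  dx <- (cols - truth$origin_px[2L]) * truth$pixel_um
  dy <- (truth$origin_px[1L] - rows) * truth$pixel_um
  th <- truth$axis_angle_deg * pi / 180
  l <- dx * cos(th) + dy * sin(th)    # um along the axis
  tr <- -dx * sin(th) + dy * cos(th)  # um across
  vl <- truth$cv_long_cm_s * 10       # um/ms
  vt <- truth$cv_trans_cm_s * 10
  t_a <- if (truth$geometry == "planar") l / vl
         else sqrt((l / vl)^2 + (tr / vt)^2)
  t_a - min(t_a) + truth$t_start_ms
}

# transient template value at times t (ms) after activation start
cat_template <- function(t, R, tau) {
  up <- t / R
  up[t < 0] <- 0
  up[t > R] <- 0
  dn <- exp(-(t - R) / tau)
  dn[t <= R] <- 0
  pmin(up, 1) * (t >= 0 & t <= R) + dn
}

#' Generate a calcium-transient movie with analytic metric truth
#'
#' @param truth a [wave_truth()].
#' @param n_frames number of frames at `truth$fps`.
#' @return a `calcium_movie` list: `stack` ([image_stack()]),
#'   `activation_ms` (H x W analytic activation-time map, ms, relative to
#'   recording start, using the upstroke-midpoint activation convention),
#'   `rise_up_ms` (analytic 10-90% rise-up time, `0.8 R`), `catd80_ms`
#'   (analytic duration to 80% relaxation, `R/2 + tau ln 5`), and `truth`.
#' @export
gen_calcium_movie <- function(truth, n_frames = 1200L) {
  stopifnot(inherits(truth, "wave_truth"))
  R <- truth$rise_time_ms; tau <- truth$decay_tau_ms
  if (R * truth$fps / 1000 < 3)
    stop_bad_arg("fps too low: fewer than 3 samples on the upstroke")
  t_ms <- (seq_len(n_frames) - 1L) * 1000 / truth$fps
  t_a <- activation_truth_map(truth)
  if (max(t_a) + R >= max(t_ms))
    stop_bad_arg("wave does not cross the field within `n_frames`")
  H <- truth$height_px; W <- truth$width_px
  period_ms <- 1000 / truth$pacing_hz
  n_beats <- 1L + max(0L, floor((max(t_ms) - max(t_a) - R) / period_ms))
  frames <- array(0, c(H, W, n_frames))
  tavec <- as.vector(t_a)
  for (k in seq_len(n_frames)) {
    tk <- t_ms[k]
    f <- rep(0, H * W)
    for (b in seq_len(n_beats) - 1L) {
      f <- pmax(f, cat_template(tk - (tavec + b * period_ms), R, tau))
    }
    frames[, , k] <- matrix(truth$baseline + truth$amplitude * f, H, W)
  }
  if (truth$noise_sd > 0) {
    old <- .Random.seed_guard(truth$seed)
    on.exit(old(), add = TRUE)
    frames <- frames + rnorm(length(frames),
                             sd = truth$noise_sd * truth$amplitude)
  }
  frames <- pmin(pmax(frames, 0), 1)
  stack <- image_stack(frames, pixel_um = truth$pixel_um,
                       frame_interval_s = 1 / truth$fps)
  structure(list(stack = stack,
                 activation_ms = t_a + R / 2,
                 rise_up_ms = 0.8 * R,
                 catd80_ms = R / 2 + tau * log(5),
                 n_beats = n_beats, truth = truth),
            class = "calcium_movie")
}
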