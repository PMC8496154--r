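# Synthetic speckle texture and ground-truth contraction movies.
#
# The speckle frame stands in for bright-field cell texture: random
# Gaussian dots on a dim background give every correlation subset a
# distinctive pattern, which is what subset matching needs. Movies are
# produced by pushing the frame through an affine, time-scaled uniform
# strain field whose second principal strain is the prescribed peak
# contractile strain, so the analytic displacement and strain fields are
# known at every pixel and frame.

#' Speckle texture specification
#'
#' @param height_px,width_px frame size in pixels (>= 64).
#' @param dot_density dots per 100 square pixels (>= 0; 0 gives a uniform
#'   background frame).
#' @param dot_radius_px Gaussian radius (sigma) of one dot, pixels.
#' @param noise_sd additive Gaussian intensity noise, as a fraction of the
#'   full intensity range, baked into the texture (>= 0).
#' @param seed integer seed; generation is bitwise-reproducible.
#' @return a `speckle_spec` list.
#' @export
speckle_spec <- function(height_px = 256L, width_px = 256L, dot_density = 5,
                         dot_radius_px = 1.5, noise_sd = 0, seed = 1L) {
  if (height_px < 64 || width_px < 64)
    stop_bad_arg("speckle frames must be at least 64 x 64 px")
  if (dot_density < 0) stop_bad_arg("`dot_density` must be >= 0")
  if (dot_radius_px <= 0) stop_bad_arg("`dot_radius_px` must be > 0")
  if (noise_sd < 0) stop_bad_arg("`noise_sd` must be >= 0")
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 dot_density = dot_density, dot_radius_px = dot_radius_px,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "speckle_spec")
}

# rasterize Gaussian dots at fractional (row, col) centers onto an
# H x W canvas; returns the accumulated dot field (no background)
render_dots <- function(centers, H, W, sigma) {
  canvas <- matrix(0, H, W)
  if (nrow(centers) == 0L) return(canvas)
  reach <- ceiling(3 * sigma)
  for (k in seq_len(nrow(centers))) {
    r <- centers[k, 1L]; c <- centers[k, 2L]
    rr <- max(1L, floor(r - reach)):min(H, ceiling(r + reach))
    cc <- max(1L, floor(c - reach)):min(W, ceiling(c + reach))
    if (length(rr) == 0L || length(cc) == 0L) next
    g <- exp(-outer((rr - r)^2, (cc - c)^2, "+") / (2 * sigma^2))
    canvas[rr, cc] <- canvas[rr, cc] + g
  }
  canvas
}

#' Generate a speckle reference frame
#'
#' Dot count is `round(dot_density * H * W / 100)`; centers are uniform over
#' the frame and are attached as attribute `"centers"` (a matrix of
#' fractional `row, col` positions) so downstream code can re-render the
#' same texture at displaced positions (band-limited subpixel shifts).
#'
#' @param spec a [speckle_spec()].
#' @return numeric `H x W` matrix in `[0, 1]` with attribute `"centers"`.
#' @export
gen_speckle <- function(spec) {
  stopifnot(inherits(spec, "speckle_spec"))
  old <- .Random.seed_guard(spec$seed)
  on.exit(old(), add = TRUE)
  H <- spec$height_px; W <- spec$width_px
  n_dots <- round(spec$dot_density * H * W / 100)
  centers <- cbind(row = runif(n_dots, 0.5, H + 0.5),
                   col = runif(n_dots, 0.5, W + 0.5))
  frame <- speckle_from_centers(centers, spec)
  if (spec$noise_sd > 0)
    frame <- frame + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
  frame <- pmin(pmax(frame, 0), 1)
  attr(frame, "centers") <- centers
  frame
}

# render background + dots for given centers (shared by gen_speckle and
# analytically shifted variants)
speckle_from_centers <- function(centers, spec) {
  dots <- render_dots(centers, spec$height_px, spec$width_px,
                      spec$dot_radius_px)
  0.15 + 0.8 * pmin(dots, 1)
}

# run `expr`-free seed scoping: set the RNG to `seed`, return a restorer
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Ground-truth contraction event description
#'
#' Describes the affine strain event imposed by [warp_movie()]: a uniform
#' strain tensor whose second principal strain equals
#' `peak_contractile_strain` along `axis_angle_deg` (the other principal
#' strain is zero), scaled through time by `event_profile`.
#'
#' @param peak_contractile_strain dimensionless; negative means shortening;
#'   magnitude must be below 0.2.
#' @param axis_angle_deg contraction axis, degrees CCW from image +x
#'   (image-up = 90).
#' @param event_profile function mapping normalized time in `[0, 1]` to a
#'   scale factor; it is renormalized so the sampled profile starts at 0 and
#'   attains 1 exactly once. Default: raised-cosine pulse.
#' @param frame_rate_fps video frame rate (default the bright-field
#'   acquisition rate 18.9 fps).
#' @return a `contraction_truth` list.
#' @export
contraction_truth <- function(peak_contractile_strain = -0.03,
                              axis_angle_deg = 0,
                              event_profile = function(t) 0.5 * (1 - cos(2 * pi * t)),
                              frame_rate_fps = 18.9) {
  if (abs(peak_contractile_strain) >= 0.2)
    stop_bad_arg("|peak_contractile_strain| must be < 0.2")
  if (frame_rate_fps <= 0) stop_bad_arg("`frame_rate_fps` must be > 0")
  structure(list(peak_contractile_strain = peak_contractile_strain,
                 axis_angle_deg = axis_angle_deg,
                 event_profile = event_profile,
                 frame_rate_fps = frame_rate_fps),
            class = "contraction_truth")
}

# uniform strain tensor with principal strains (0, s) where the s-axis is
# at `angle_deg` CCW from +x in the user (y-up) frame
strain_tensor_along <- function(s, angle_deg) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  R %*% diag(c(s, 0)) %*% t(R)
}

#' Warp a reference frame through a prescribed contraction event
#'
#' Frame `k` is the reference resampled through the displacement field
#' `u(x) = scale_k * E (x - x0)` where `E` is the uniform strain tensor of
#' `truth` and `x0` the frame center; the analytic displacement and strain
#' fields are returned alongside the movie.
#'
#' @param ref reference frame (matrix from [gen_speckle()]).
#' @param truth a [contraction_truth()].
#' @param n_frames number of frames (>= 2).
#' @param pixel_um microns per pixel for the resulting stack.
#' @return a `warp_movie` list: `stack` ([image_stack()]), `scale`
#'   (per-frame profile values), `peak_frame`, `tensor` (peak strain
#'   tensor, x-y frame), `truth`, and `displacement(row_px, col_px, frame)`
#'   returning analytic `u_x`, `u_y` in pixels (y up).
#' @export
warp_movie <- function(ref, truth, n_frames = 41L, pixel_um = 1) {
  stopifnot(inherits(truth, "contraction_truth"))
  if (n_frames < 2L) stop_bad_arg("`n_frames` must be >= 2")
  H <- nrow(ref); W <- ncol(ref)
  t01 <- seq(0, 1, length.out = n_frames)
  scale <- truth$event_profile(t01)
  if (!all(is.finite(scale)) || max(scale) <= 0)
    stop_bad_arg("event profile must be finite with a positive maximum")
  scale <- scale / max(scale)
  scale[1L] <- 0
  E <- strain_tensor_along(truth$peak_contractile_strain,
                           truth$axis_angle_deg)
  # margin check: neither the forward map (material points leaving the
  # frame) nor the inverse sampling map may overshoot the border by more
  # than a small fraction of the frame
  x0 <- c((W + 1) / 2, (H + 1) / 2)  # (x, y_up) center, y_up = H + 1 - row
  corners <- rbind(c(1, 1), c(W, 1), c(1, H), c(W, H))
  Ainv <- solve(diag(2) + E)
  umax <- max(apply(corners, 1L, function(p) {
    max(sqrt(sum((E %*% (p - x0))^2)),
        sqrt(sum(((Ainv - diag(2)) %*% (p - x0))^2)))
  }))
  if (umax > min(H, W) / 16)
    stop_bad_arg("peak displacement exceeds the image margin")

  cols <- matrix(rep(seq_len(W), each = H), H, W)
  rows <- matrix(rep(seq_len(H), times = W), H, W)
  x <- cols - x0[1L]
  y <- (H + 1 - rows) - x0[2L]
  frames <- array(0, c(H, W, n_frames))
  for (k in seq_len(n_frames)) {
    if (scale[k] == 0) { frames[, , k] <- ref; next }
    # deformed(p) = ref(q) with q = (I + sE)^{-1} (p - x0) + x0
    A <- solve(diag(2) + scale[k] * E)
    qx <- A[1, 1] * x + A[1, 2] * y
    qy <- A[2, 1] * x + A[2, 2] * y
    src_col <- qx + x0[1L]
    src_row <- H + 1 - (qy + x0[2L])
    frames[, , k] <- matrix(bilinear_sample(ref, as.vector(src_row),
                                            as.vector(src_col)), H, W)
  }
  stack <- image_stack(frames, pixel_um = pixel_um,
                       frame_interval_s = 1 / truth$frame_rate_fps)
  displacement <- function(row_px, col_px, frame) {
    s <- scale[frame]
    xx <- col_px - x0[1L]; yy <- (H + 1 - row_px) - x0[2L]
    list(u_x = s * (E[1, 1] * xx + E[1, 2] * yy),
         u_y = s * (E[2, 1] * xx + E[2, 2] * yy))
  }
  structure(list(stack = stack, scale = scale,
                 peak_frame = which.max(scale), tensor = E, truth = truth,
                 displacement = displacement),
            class = "warp_movie")
}
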