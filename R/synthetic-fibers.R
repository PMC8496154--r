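# Synthetic fibrous images with known orientation statistics.
#
# Fibers are anti-aliased straight segments whose orientations are drawn
# from an axial von Mises distribution (kappa = 0 gives uniform
# orientations). Because all fibers share one length, the ground-truth
# aligned fraction is a direct tally over the sampled angles.

#' Fiber field specification
#'
#' @param mean_angle_deg mean fiber orientation, degrees CCW from +x
#'   (axial, period 180).
#' @param kappa von Mises concentration of the axial orientation
#'   distribution; 0 means uniform; values above 700 are treated as a
#'   point mass at the mean.
#' @param n_fibers number of fibers (>= 1).
#' @param fiber_length_px,fiber_width_px segment geometry in pixels.
#' @param height_px,width_px image size.
#' @param seed integer seed.
#' @return a `fiber_field_spec` list.
#' @export
fiber_field_spec <- function(mean_angle_deg = 15, kappa = 4, n_fibers = 340L,
                             fiber_length_px = 40, fiber_width_px = 2.5,
                             height_px = 768L, width_px = 768L, seed = 1L) {
  if (kappa < 0) stop_bad_arg("`kappa` must be >= 0")
  if (n_fibers < 1) stop_bad_arg("`n_fibers` must be >= 1")
  if (fiber_length_px <= 0 || fiber_width_px <= 0)
    stop_bad_arg("fiber geometry must be positive")
  structure(list(mean_angle_deg = mean_angle_deg, kappa = kappa,
                 n_fibers = as.integer(n_fibers),
                 fiber_length_px = fiber_length_px,
                 fiber_width_px = fiber_width_px,
                 height_px = as.integer(height_px),
                 width_px = as.integer(width_px), seed = as.integer(seed)),
            class = "fiber_field_spec")
}

# splat a unit-intensity anti-aliased segment onto canvas (in place-ish);
# center (row, col), angle deg CCW from +x with image-up positive
draw_fiber <- function(canvas, center, angle_deg, length_px, width_px) {
  th <- angle_deg * pi / 180
  # direction in (row, col) indices: +x = +col, +y = -row
  d <- c(-sin(th), cos(th))
  perp <- c(-d[2L], d[1L])
  along <- seq(-length_px / 2, length_px / 2, by = 0.5)
  across <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, by = 0.5)
  H <- nrow(canvas); W <- ncol(canvas)
  for (a in across) {
    rr <- center[1L] + along * d[1L] + a * perp[1L]
    cc <- center[2L] + along * d[2L] + a * perp[2L]
    r0 <- floor(rr); c0 <- floor(cc)
    fr <- rr - r0; fc <- cc - c0
    for (corner in 1:4) {
      ri <- r0 + (corner > 2)
      ci <- c0 + (corner %% 2 == 0)
      wgt <- (if (corner > 2) fr else 1 - fr) *
             (if (corner %% 2 == 0) fc else 1 - fc)
      keep <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
      if (any(keep)) {
        idx <- cbind(ri[keep], ci[keep])
        canvas[idx] <- canvas[idx] + 0.25 * wgt[keep]
      }
    }
  }
  canvas
}

#' Generate a fibrous image with ground-truth aligned fraction
#'
#' @param spec a [fiber_field_spec()].
#' @param tolerance_deg half-width of the alignment window used for the
#'   truth tally (default 10 degrees, axial).
#' @return list with `image` (matrix in `[0, 1]`), `angles_deg` (sampled
#'   fiber orientations in `[0, 180)`), and `aligned_fraction_truth`
#'   (fraction of fibers within `tolerance_deg` of the mean, axially;
#'   all fibers share one length so fiber count equals fiber length).
#' @export
gen_fiber_image <- function(spec, tolerance_deg = 10) {
  stopifnot(inherits(spec, "fiber_field_spec"))
  old <- .Random.seed_guard(spec$seed)
  on.exit(old(), add = TRUE)
  H <- spec$height_px; W <- spec$width_px
  n <- spec$n_fibers
  if (spec$kappa > 700) {
    angles <- rep(spec$mean_angle_deg %% 180, n)
  } else {
    # axial von Mises: sample the doubled angle, halve
    dbl <- rvonmises(n, 2 * spec$mean_angle_deg * pi / 180, spec$kappa)
    angles <- ((dbl / 2) * 180 / pi) %% 180
  }
  centers <- cbind(runif(n, 1, H), runif(n, 1, W))
  canvas <- matrix(0, H, W)
  for (k in seq_len(n)) {
    canvas <- draw_fiber(canvas, centers[k, ], angles[k],
                         spec$fiber_length_px, spec$fiber_width_px)
  }
  img <- pmin(canvas / stats::quantile(canvas[canvas > 0], 0.95), 1)
  truth <- mean(axial_diff_deg(angles, spec$mean_angle_deg) <= tolerance_deg)
  list(image = img, angles_deg = angles, aligned_fraction_truth = truth)
}

#' Painted-fraction coverage image
#'
#' Paints a prescribed fraction of the frame at high intensity over a dim
#' background (clearly bimodal contrast), emulating area-density
#' quantification targets such as ECM density or cell-coverage images.
#' Painting uses randomly placed axis-aligned rectangles trimmed to hit
#' the requested pixel fraction exactly.
#'
#' @param fraction target painted fraction in `[0, 1]`.
#' @param height_px,width_px image size.
#' @param fg,bg painted and background mean intensities.
#' @param noise_sd Gaussian noise sd added to both classes.
#' @param seed integer seed.
#' @return list with `image` (matrix in `[0, 1]`), `mask` (logical painted
#'   mask), and `fraction_truth` (exact painted pixel fraction).
#' @export
gen_coverage_image <- function(fraction, height_px = 256L, width_px = 256L,
                               fg = 0.8, bg = 0.2, noise_sd = 0.03,
                               seed = 1L) {
  if (fraction < 0 || fraction > 1)
    stop_bad_arg("`fraction` must be in [0, 1]")
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  H <- height_px; W <- width_px
  target <- round(fraction * H * W)
  mask <- matrix(FALSE, H, W)
  while (sum(mask) < target) {
    h <- sample(8:max(9, H %/% 4), 1L)
    w <- sample(8:max(9, W %/% 4), 1L)
    r <- sample(seq_len(max(1L, H - h)), 1L)
    c <- sample(seq_len(max(1L, W - w)), 1L)
    mask[r:(r + h - 1L), c:(c + w - 1L)] <- TRUE
  }
  excess <- sum(mask) - target
  if (excess > 0) {
    on_idx <- which(mask)
    mask[sample(on_idx, excess)] <- FALSE
  }
  img <- matrix(bg, H, W)
  img[mask] <- fg
  img <- img + matrix(rnorm(H * W, 0, noise_sd), H, W)
  list(image = pmin(pmax(img, 0), 1), mask = mask,
       fraction_truth = sum(mask) / (H * W))
}
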