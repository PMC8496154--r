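# Strain fields from displacement fields, and the masked contractile
# summary used to score contraction videos.
#
# The infinitesimal (small-strain) tensor is used: measured contractile
# strains in these preparations are a few percent, where the quadratic
# Green-Lagrange term is negligible. Gradients are centered finite
# differences on the regular subset grid (one-sided at grid edges);
# invalid displacement points propagate invalidity to every strain that
# would use them.

# centered differences along columns of M with spacing h (one-sided at
# the two edge columns); NA inputs propagate
grad_cols <- function(M, h) {
  n <- ncol(M)
  G <- matrix(NA_real_, nrow(M), n)
  if (n >= 3) G[, 2:(n - 1)] <- (M[, 3:n] - M[, 1:(n - 2)]) / (2 * h)
  G[, 1] <- (M[, 2] - M[, 1]) / h
  G[, n] <- (M[, n] - M[, n - 1]) / h
  G
}

grad_rows <- function(M, h) t(grad_cols(t(M), h))

#' Strain tensor field from a displacement field
#'
#' @param field a [track_stack()] result.
#' @param smooth_sigma_pts optional Gaussian pre-smoothing of the
#'   displacement grids, in grid points (0 = off, the default).
#' @return a `strain_field` tibble: per frame and grid point `eps_xx`,
#'   `eps_yy`, `eps_xy`, principal strains `eps_1 >= eps_2`, and `valid`.
#' @export
strain_from_displacements <- function(field, smooth_sigma_pts = 0) {
  stopifnot(inherits(field, "displacement_field"))
  gd <- attr(field, "grid_dim")
  if (any(gd < 2L)) stop_bad_arg("need >= 2 grid points along each axis")
  h_um <- attr(field, "spacing_px") * attr(field, "pixel_um")
  frames <- unique(field$frame)
  res <- purrr::map(frames, function(k) {
    sl <- field[field$frame == k, ]
    Ux <- matrix(sl$u_x_um, gd[1L], gd[2L], byrow = TRUE)
    Uy <- matrix(sl$u_y_um, gd[1L], gd[2L], byrow = TRUE)
    if (smooth_sigma_pts > 0) {
      Ux <- gauss_smooth_mat(Ux, smooth_sigma_pts)
      Uy <- gauss_smooth_mat(Uy, smooth_sigma_pts)
    }
    # y points up while grid rows count down, hence the sign flips
    exx <- grad_cols(Ux, h_um)
    eyy <- -grad_rows(Uy, h_um)
    exy <- 0.5 * (-grad_rows(Ux, h_um) + grad_cols(Uy, h_um))
    pr <- principal_strains(as.vector(t(exx)), as.vector(t(eyy)),
                            as.vector(t(exy)))
    tibble::tibble(frame = k, point_id = sl$point_id,
                   row = sl$row, col = sl$col,
                   eps_xx = as.vector(t(exx)), eps_yy = as.vector(t(eyy)),
                   eps_xy = as.vector(t(exy)),
                   eps_1 = pr$eps_1, eps_2 = pr$eps_2,
                   input_valid = sl$valid)
  })
  out <- dplyr::bind_rows(res)
  out$valid <- is.finite(out$eps_xx) & is.finite(out$eps_yy) &
    is.finite(out$eps_xy) & out$input_valid
  out$input_valid <- NULL
  structure(out,
            grid_dim = gd, spacing_um = h_um,
            frame_interval_s = attr(field, "frame_interval_s"),
            class = c("strain_field", class(out)))
}

# separable Gaussian smoothing with NA-aware normalized convolution
gauss_smooth_mat <- function(M, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  ok <- is.finite(M)
  M0 <- ifelse(ok, M, 0)
  sm <- function(A) {
    A2 <- apply(A, 2L, function(col) stats::filter(col, k, sides = 2L))
    t(apply(t(A2), 2L, function(col) stats::filter(col, k, sides = 2L)))
  }
  num <- sm(M0); den <- sm(ok * 1)
  out <- num / den
  out[!ok] <- NA_real_
  out
}

#' Principal strains of a 2-D strain tensor
#'
#' `eps_{1,2} = (eps_xx + eps_yy)/2 +/- sqrt(((eps_xx - eps_yy)/2)^2 +
#' eps_xy^2)` with `eps_1 >= eps_2`.
#'
#' @param eps_xx,eps_yy,eps_xy tensor components (vectorized).
#' @return list with `eps_1` and `eps_2`.
#' @export
principal_strains <- function(eps_xx, eps_yy, eps_xy) {
  m <- (eps_xx + eps_yy) / 2
  r <- sqrt(((eps_xx - eps_yy) / 2)^2 + eps_xy^2)
  list(eps_1 = m + r, eps_2 = m - r)
}

#' Automatic cell mask from a displacement field
#'
#' Keeps grid points that actually move: peak displacement magnitude over
#' the recording above `disp_frac` of the field's robust maximum (95th
#' percentile of peak magnitudes) and median correlation quality above
#' `quality_floor`.
#'
#' @param field a [track_stack()] result.
#' @param disp_frac fraction of the robust maximum displacement below
#'   which points are excluded.
#' @param quality_floor minimum median correlation quality.
#' @return logical matrix of grid dimension (`TRUE` = keep), with the
#'   applied thresholds attached as attributes.
#' @export
auto_mask <- function(field, disp_frac = 0.2, quality_floor = 0.8) {
  stopifnot(inherits(field, "displacement_field"))
  gd <- attr(field, "grid_dim")
  per_point <- dplyr::summarise(
    dplyr::group_by(field, .data$point_id),
    peak_u = ifelse(any(.data$valid),
                    max(sqrt(.data$u_x^2 + .data$u_y^2)[.data$valid]), NA_real_),
    med_q = median(.data$quality, na.rm = TRUE),
    .groups = "drop")
  robust_max <- stats::quantile(per_point$peak_u, 0.95, na.rm = TRUE,
                                names = FALSE)
  keep <- !is.na(per_point$peak_u) &
    per_point$peak_u >= disp_frac * robust_max &
    !is.na(per_point$med_q) & per_point$med_q >= quality_floor
  if (!any(keep))
    stop_bad_arg(sprintf(
      "auto_mask excluded every point (robust max displacement %.3g px, quality floor %.2f); is there any real motion?",
      robust_max, quality_floor))
  mask <- matrix(keep[order(per_point$point_id)], gd[1L], gd[2L],
                 byrow = TRUE)
  structure(mask, disp_frac = disp_frac, quality_floor = quality_floor,
            disp_threshold_px = disp_frac * robust_max)
}

#' Masked contractile-strain trace and its maximum
#'
#' Averages the second principal strain (the contractile strain) over the
#' masked, valid grid points for each frame; the maximum contractile
#' strain is the magnitude of the most negative per-frame mean, reported
#' as a positive percentage.
#'
#' @param strains a [strain_from_displacements()] result.
#' @param mask logical matrix of grid dimension (e.g. [auto_mask()]), or a
#'   logical vector ordered by `point_id`.
#' @return a `contraction_trace` object: `trace` tibble (`frame`, `t_s`,
#'   `mean_eps2`, `n_points`), `max_contractile_strain_pct`, `peak_frame`.
#' @export
contractile_trace <- function(strains, mask) {
  stopifnot(inherits(strains, "strain_field"))
  gd <- attr(strains, "grid_dim")
  if (is.matrix(mask)) mask <- as.vector(t(mask))
  n_pts <- max(strains$point_id)
  if (length(mask) != n_pts)
    stop_bad_arg("mask shape does not match the strain grid")
  if (!any(mask)) stop_bad_arg("empty mask")
  dt <- attr(strains, "frame_interval_s")
  sel <- strains[mask[strains$point_id] & strains$valid, ]
  if (nrow(sel) == 0L) stop_bad_arg("mask selects no valid strain points")
  trace <- dplyr::summarise(dplyr::group_by(sel, .data$frame),
                            mean_eps2 = mean(.data$eps_2),
                            n_points = dplyr::n(), .groups = "drop")
  trace$t_s <- (trace$frame - 1L) * dt
  peak_frame <- trace$frame[which.min(trace$mean_eps2)]
  structure(list(trace = trace[, c("frame", "t_s", "mean_eps2", "n_points")],
                 max_contractile_strain_pct =
                   -min(trace$mean_eps2) * 100,
                 peak_frame = peak_frame),
            class = "contraction_trace")
}

#' @export
print.contraction_trace <- function(x, ...) {
  cat(sprintf(
    "<contraction_trace> %d frames; max contractile strain %.3f%% at frame %d\n",
    nrow(x$trace), x$max_contractile_strain_pct, x$peak_frame))
  invisible(x)
}

#' Per-event contractile peaks within a trace
#'
#' Secondary summary for recordings with several contraction events: local
#' minima of the mean contractile-strain trace separated by at least
#' `min_separation_frames` and deeper than `min_depth_frac` of the global
#' extremum.
#'
#' @param ct a [contractile_trace()] result.
#' @param min_separation_frames minimum frames between reported peaks.
#' @param min_depth_frac minimum depth relative to the global extremum.
#' @return tibble `frame`, `t_s`, `contractile_strain_pct`.
#' @export
event_peaks <- function(ct, min_separation_frames = 5L,
                        min_depth_frac = 0.5) {
  stopifnot(inherits(ct, "contraction_trace"))
  x <- -ct$trace$mean_eps2
  thr <- min_depth_frac * max(x)
  cand <- which(x >= thr &
                  x >= dplyr::lag(x, default = -Inf) &
                  x > dplyr::lead(x, default = -Inf))
  keep <- integer(0)
  for (i in cand[order(-x[cand])]) {
    if (all(abs(i - keep) >= min_separation_frames)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  tibble::tibble(frame = ct$trace$frame[keep], t_s = ct$trace$t_s[keep],
                 contractile_strain_pct = 100 * x[keep])
}
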