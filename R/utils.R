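# Shared numeric helpers: angle conventions and interpolation.
#
# Coordinate convention used throughout the package: matrices are indexed
# [row, col] with row increasing downward (image convention), but every
# user-facing coordinate and angle lives in a right-handed frame with
# x = +col, y = image-up, angles CCW from +x so that 90 deg points up.
# Conversions happen at module boundaries, never inside numerics.

#' Minimal axial angular distance
#'
#' Distance between two orientations treated as axial data (period 180
#' degrees): the result is in `[0, 90]`.
#'
#' @param a,b angles in degrees.
#' @return numeric vector of axial distances in degrees.
#' @export
axial_diff_deg <- function(a, b) {
  d <- (a - b) %% 180
  pmin(d, 180 - d)
}

# circular distance on the full circle, result in [0, 180]
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Axial circular mean of orientations
#'
#' Mean orientation of axial data (period 180 degrees) by the doubled-angle
#' method, optionally weighted. Also returns the resultant length of the
#' doubled-angle distribution, a concentration measure in `[0, 1]`.
#'
#' @param angles_deg orientations in degrees.
#' @param w non-negative weights (default equal).
#' @return list with `mean_deg` in `[0, 180)` and `resultant` in `[0, 1]`.
#' @export
axial_mean_deg <- function(angles_deg, w = NULL) {
  if (is.null(w)) w <- rep(1, length(angles_deg))
  stopifnot(length(w) == length(angles_deg))
  ok <- is.finite(angles_deg) & is.finite(w)
  angles_deg <- angles_deg[ok]; w <- w[ok]
  if (length(angles_deg) == 0L || sum(w) <= 0)
    return(list(mean_deg = NA_real_, resultant = NA_real_))
  th <- 2 * angles_deg * pi / 180
  z <- sum(w * exp(1i * th)) / sum(w)
  list(mean_deg = (Arg(z) * 180 / pi / 2) %% 180, resultant = Mod(z))
}

# vectorized bilinear sampling of matrix `img` at fractional (row, col);
# coordinates are clamped to the image border (replicate padding)
bilinear_sample <- function(img, row, col) {
  H <- nrow(img); W <- ncol(img)
  row <- pmin(pmax(row, 1), H)
  col <- pmin(pmax(col, 1), W)
  r0 <- pmin(floor(row), H - 1L); c0 <- pmin(floor(col), W - 1L)
  fr <- row - r0; fc <- col - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  (1 - fr) * (1 - fc) * img[i00] + fr * (1 - fc) * img[i10] +
    (1 - fr) * fc * img[i01] + fr * fc * img[i11]
}

# centered moving average, ends handled by shrinking the window
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# first linear-interpolated crossing of `level` by `x` (increasing if
# rising, decreasing otherwise) over sample times `t`; NA when absent
first_crossing <- function(t, x, level, rising = TRUE) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  if (rising) hit <- which(x[-n] < level & x[-1] >= level)
  else hit <- which(x[-n] > level & x[-1] <= level)
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1L]
  frac <- (level - x[i]) / (x[i + 1L] - x[i])
  t[i] + frac * (t[i + 1L] - t[i])
}

# von Mises sampler (Best & Fisher rejection method); kappa = 0 is uniform
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out + mu
}

stop_bad_arg <- function(msg) abort(msg, class = "cardiofunc_bad_arg")
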