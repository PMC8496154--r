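# Synthetic cell-migration trajectories.
#
# Two regimes: isotropic random walks (cells on an unpatterned monolayer
# pick a fresh uniform heading each step) and lane-confined walks (cells
# on micropatterned lanes move predominantly up/down the lane, heading 90
# or 270 degrees with a small jitter, reflecting off the lane walls).
# Step length is exactly speed x interval, so per-step speed equals the
# prescribed speed and the cohort-mean truth is exact.

#' Random-walk specification
#'
#' @param mode `"isotropic"` or `"lane"`.
#' @param lane_width_um lane width (lane mode only, > 0); the walk starts
#'   mid-lane and reflects off walls at `x = 0` and `x = lane_width_um`.
#' @param speed_um_min migration speed in microns per minute (> 0); every
#'   step has exactly this speed.
#' @param step_interval_min sampling interval in minutes.
#' @param n_steps steps per cell.
#' @param n_cells number of cells.
#' @param heading_sd_deg lane mode: sd of the Gaussian jitter around the
#'   90/270-degree lane direction.
#' @param seed integer seed.
#' @return a `walk_spec` list.
#' @export
walk_spec <- function(mode = c("isotropic", "lane"), lane_width_um = 30,
                      speed_um_min = 0.33, step_interval_min = 10,
                      n_steps = 60L, n_cells = 40L, heading_sd_deg = 8,
                      seed = 1L) {
  mode <- match.arg(mode)
  if (speed_um_min <= 0) stop_bad_arg("`speed_um_min` must be > 0")
  if (mode == "lane" && !(lane_width_um > 0))
    stop_bad_arg("lane mode requires `lane_width_um` > 0")
  if (step_interval_min <= 0) stop_bad_arg("`step_interval_min` must be > 0")
  structure(list(mode = mode, lane_width_um = lane_width_um,
                 speed_um_min = speed_um_min,
                 step_interval_min = step_interval_min,
                 n_steps = as.integer(n_steps), n_cells = as.integer(n_cells),
                 heading_sd_deg = heading_sd_deg, seed = as.integer(seed)),
            class = "walk_spec")
}

#' Generate migration trajectories with known truth
#'
#' @param spec a [walk_spec()].
#' @return tibble `cell_id, t_min, x_um, y_um` (y up, so step angles read
#'   90 degrees = up downstream), with attribute `"speed_truth_um_min"`.
#'   Lane-mode reflections can shorten the net displacement of the rare
#'   wall-hitting steps, so measured cohort speed sits marginally below
#'   the truth attribute.
#' @export
gen_walks <- function(spec) {
  stopifnot(inherits(spec, "walk_spec"))
  old <- .Random.seed_guard(spec$seed)
  on.exit(old(), add = TRUE)
  step_len <- spec$speed_um_min * spec$step_interval_min
  cells <- purrr::map(seq_len(spec$n_cells), function(id) {
    if (spec$mode == "isotropic") {
      heading <- runif(spec$n_steps, 0, 360)
      x <- cumsum(c(0, step_len * cos(heading * pi / 180)))
      y <- cumsum(c(0, step_len * sin(heading * pi / 180)))
    } else {
      updown <- sample(c(90, 270), spec$n_steps, replace = TRUE)
      heading <- updown + rnorm(spec$n_steps, 0, spec$heading_sd_deg)
      dx <- step_len * cos(heading * pi / 180)
      dy <- step_len * sin(heading * pi / 180)
      x <- numeric(spec$n_steps + 1L)
      y <- cumsum(c(0, dy))
      x[1L] <- spec$lane_width_um / 2
      for (k in seq_len(spec$n_steps)) {
        xn <- x[k] + dx[k]
        # reflect at the lane walls (possibly repeatedly for narrow lanes)
        repeat {
          if (xn < 0) xn <- -xn
          else if (xn > spec$lane_width_um) xn <- 2 * spec$lane_width_um - xn
          else break
        }
        x[k + 1L] <- xn
      }
    }
    tibble::tibble(cell_id = sprintf("cell%03d", id),
                   t_min = (0:spec$n_steps) * spec$step_interval_min,
                   x_um = x, y_um = y)
  })
  out <- dplyr::bind_rows(cells)
  attr(out, "speed_truth_um_min") <- spec$speed_um_min
  out
}
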