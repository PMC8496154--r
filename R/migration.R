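# Trajectory statistics for single-cell migration.
#
# Angles use the rose-plot convention of time-lapse tracking figures:
# degrees CCW from +x with 90 = upward movement, 270 = downward, each
# step's direction taken from the displacement since the last
# measurement. Speeds are in microns per minute. Cohort statistics
# aggregate per cell first, then across cells, so long tracks do not
# dominate.

#' Read a trajectory table
#'
#' Expects the common cell-tracking export `cell_id,t_min,x_um,y_um`.
#' Image-origin handling: tracking tools that report pixel-derived y
#' growing downward (`image_origin = "upper"`, the default for most
#' trackers) have y negated on import so that upward movement reads 90
#' degrees.
#'
#' @param path CSV path.
#' @param image_origin `"upper"` (y grows downward in the file, flipped on
#'   import) or `"lower"` (y already grows upward).
#' @return tibble `cell_id, t_min, x_um, y_um` (y up).
#' @export
read_trajectories <- function(path, image_origin = c("upper", "lower")) {
  image_origin <- match.arg(image_origin)
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("cell_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop_bad_arg(paste0("trajectory CSV must have columns ",
                        paste(need, collapse = ",")))
  df <- df[need]
  if (image_origin == "upper") df$y_um <- -df$y_um
  df
}

#' Write a trajectory table
#'
#' Inverse of [read_trajectories()] (y negated back when
#' `image_origin = "upper"`).
#'
#' @param traj tibble `cell_id, t_min, x_um, y_um` (y up).
#' @param path output CSV path.
#' @param image_origin as in [read_trajectories()].
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path, image_origin = c("upper", "lower")) {
  image_origin <- match.arg(image_origin)
  out <- traj[c("cell_id", "t_min", "x_um", "y_um")]
  if (image_origin == "upper") out$y_um <- -out$y_um
  readr::write_csv(out, path)
  invisible(path)
}

#' Per-step migration statistics
#'
#' @param traj trajectory tibble `cell_id, t_min, x_um, y_um` (one or many
#'   cells; y up). Times must be strictly increasing within each cell.
#' @return a `migration_steps` tibble: per consecutive sample pair
#'   `cell_id`, `t0_min`, `t1_min`, `dt_min`, `step_um`,
#'   `speed_um_min`, `angle_deg` in `[0, 360)` (90 = up; `NA` with
#'   `angle_defined = FALSE` for zero-length steps).
#' @export
step_stats <- function(traj) {
  need <- c("cell_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(traj)))
    stop_bad_arg(paste0("trajectory table must have columns ",
                        paste(need, collapse = ",")))
  steps <- traj |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$t_min, .by_group = TRUE) |>
    dplyr::mutate(dt_min = dplyr::lead(.data$t_min) - .data$t_min,
                  dx = dplyr::lead(.data$x_um) - .data$x_um,
                  dy = dplyr::lead(.data$y_um) - .data$y_um) |>
    dplyr::filter(!is.na(.data$dt_min)) |>
    dplyr::ungroup()
  if (any(steps$dt_min <= 0))
    stop_bad_arg("times must be strictly increasing within each cell")
  if (any(table(traj$cell_id) < 2L))
    stop_bad_arg("every trajectory needs >= 2 samples")
  step_um <- sqrt(steps$dx^2 + steps$dy^2)
  angle <- (atan2(steps$dy, steps$dx) * 180 / pi) %% 360
  defined <- step_um > 0
  out <- tibble::tibble(cell_id = steps$cell_id,
                        t0_min = steps$t_min,
                        t1_min = steps$t_min + steps$dt_min,
                        dt_min = steps$dt_min,
                        step_um = step_um,
                        speed_um_min = step_um / steps$dt_min,
                        angle_deg = ifelse(defined, angle, NA_real_),
                        angle_defined = defined)
  structure(out, class = c("migration_steps", class(out)))
}

#' Angular histogram of step directions
#'
#' @param steps a [step_stats()] result.
#' @param bin_deg bin width in degrees (must divide 360).
#' @return tibble `bin_start_deg`, `bin_end_deg`, `count` (undefined
#'   angles excluded).
#' @export
angular_histogram <- function(steps, bin_deg = 20) {
  stopifnot(inherits(steps, "migration_steps"))
  if (360 %% bin_deg != 0) stop_bad_arg("`bin_deg` must divide 360")
  a <- steps$angle_deg[steps$angle_defined]
  edges <- seq(0, 360, by = bin_deg)
  counts <- tabulate(findInterval(a %% 360, edges,
                                  rightmost.closed = FALSE),
                     nbins = length(edges) - 1L)
  tibble::tibble(bin_start_deg = edges[-length(edges)],
                 bin_end_deg = edges[-1L], count = counts)
}

#' Fraction of steps directed along an axis
#'
#' Fraction of defined-angle steps whose direction lies within
#' `tolerance_deg` of the axis or its opposite (axial comparison), e.g.
#' along a micropatterned lane.
#'
#' @param steps a [step_stats()] result.
#' @param axis_angle_deg lane axis (90 = vertical lanes).
#' @param tolerance_deg half-width of each sector (default 15).
#' @return fraction in `[0, 1]`.
#' @export
directionality_index <- function(steps, axis_angle_deg = 90,
                                 tolerance_deg = 15) {
  stopifnot(inherits(steps, "migration_steps"))
  a <- steps$angle_deg[steps$angle_defined]
  if (length(a) == 0L) stop_bad_arg("no defined step angles")
  mean(axial_diff_deg(a, axis_angle_deg) <= tolerance_deg)
}

#' Cohort speed summary
#'
#' Per-cell time-weighted mean speed (total path length over total time),
#' then a cohort mean and SD across cells. With a single cell the SD is
#' `NA` (documented convention).
#'
#' @param steps a [step_stats()] result (pass all cells together).
#' @return list with `per_cell` tibble (`cell_id`, `mean_speed_um_min`,
#'   `n_steps`) and `summary` one-row tibble (`n_cells`,
#'   `mean_speed_um_min`, `sd_speed_um_min`).
#' @export
cohort_speeds <- function(steps) {
  stopifnot(inherits(steps, "migration_steps"))
  per_cell <- steps |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(mean_speed_um_min = sum(.data$step_um) / sum(.data$dt_min),
                     n_steps = dplyr::n(), .groups = "drop")
  summary <- tibble::tibble(
    n_cells = nrow(per_cell),
    mean_speed_um_min = mean(per_cell$mean_speed_um_min),
    sd_speed_um_min = if (nrow(per_cell) > 1L)
      stats::sd(per_cell$mean_speed_um_min) else NA_real_)
  list(per_cell = per_cell, summary = summary)
}
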