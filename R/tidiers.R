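# broom-style tidiers for the result objects that are not already tibbles.

#' @describeIn contractile_trace tidy(): the per-frame trace as a tibble.
#' @param x a `contraction_trace`.
#' @param ... unused.
#' @method tidy contraction_trace
#' @export
tidy.contraction_trace <- function(x, ...) x$trace

#' @describeIn contractile_trace glance(): one-row summary.
#' @method glance contraction_trace
#' @export
glance.contraction_trace <- function(x, ...) {
  tibble::tibble(max_contractile_strain_pct = x$max_contractile_strain_pct,
                 peak_frame = x$peak_frame,
                 peak_t_s = x$trace$t_s[x$trace$frame == x$peak_frame],
                 n_frames = nrow(x$trace))
}

#' @describeIn conduction_velocity tidy(): the per-window table.
#' @param x a `velocity_field`.
#' @param ... unused.
#' @method tidy velocity_field
#' @export
tidy.velocity_field <- function(x, ...) x$windows

#' @describeIn conduction_velocity glance(): one-row summary.
#' @method glance velocity_field
#' @export
glance.velocity_field <- function(x, ...) {
  tibble::tibble(mean_cv_cm_s = x$mean_cv_cm_s, n_valid = x$n_valid,
                 n_windows = nrow(x$windows))
}

#' @describeIn extract_traces tidy(): traces in long form
#'   (`trace_id`, `t_ms`, `f`), valid traces only.
#' @param x a `calcium_traces` object.
#' @param ... unused.
#' @method tidy calcium_traces
#' @export
tidy.calcium_traces <- function(x, ...) {
  keep <- which(x$map$valid)
  purrr::map_dfr(keep, function(j) {
    tibble::tibble(trace_id = x$map$trace_id[j], t_ms = x$t_ms,
                   f = x$f[, j])
  })
}

#' @describeIn extract_traces glance(): one-row summary of the recording.
#' @method glance calcium_traces
#' @export
glance.calcium_traces <- function(x, ...) {
  tibble::tibble(n_traces = nrow(x$map), n_valid = sum(x$map$valid),
                 n_beats = nrow(x$beats),
                 duration_ms = max(x$beats$t_end_ms),
                 beat_rate_bpm = beat_rate_bpm(x))
}

#' @describeIn orientation_field glance(): dominant axis and weighted
#'   concentration of a field.
#' @param x an `orientation_field`.
#' @param ... unused.
#' @method glance orientation_field
#' @export
glance.orientation_field <- function(x, ...) {
  v <- x[x$valid, ]
  am <- axial_mean_deg(v$angle_deg, v$weight)
  tibble::tibble(n_windows = nrow(x), n_valid = nrow(v),
                 dominant_angle_deg = am$mean_deg,
                 concentration = am$resultant)
}

#' @describeIn cohort_speeds glance-style accessor on the full list
#'   result is `$summary`; this tidier flattens per-cell speeds.
#' @param x a `migration_steps` tibble.
#' @param ... unused.
#' @method glance migration_steps
#' @export
glance.migration_steps <- function(x, ...) {
  cs <- cohort_speeds(x)
  dplyr::bind_cols(cs$summary,
                   tibble::tibble(n_steps = nrow(x),
                                  n_defined_angles = sum(x$angle_defined)))
}
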