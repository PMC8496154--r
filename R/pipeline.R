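# Reproducible end-to-end runs: a config (YAML or list) names a modality
# and its parameters; every resolved parameter is logged next to the
# outputs, metrics land in machine-readable JSON with units in the key
# names, and reruns with the same config and seed are bitwise identical
# at the metrics level.

default_params <- function(modality) {
  switch(modality,
    contraction = list(input = NULL, pixel_um = 1, frame_interval_s = 1 / 18.9,
                       subset_size_px = 32L, spacing_px = 8L,
                       search_radius_px = 10L, reference_frame_index = 1L,
                       mask = "auto", disp_frac = 0.2, quality_floor = 0.8),
    calcium = list(input = NULL, pixel_um = 60, fps = 1000, bin_px = 2L,
                   smooth_width = 5L, pacing_hz = 1, beat = 1L,
                   axis_angle_deg = 0, cv_window = 5L,
                   sector_half_width_deg = 22.5),
    alignment = list(input = NULL, window_px = 64L, step_px = 16L,
                     energy_floor = 0.05, reference_angle_deg = NULL,
                     tolerance_deg = 10),
    migration = list(input = NULL, image_origin = "upper",
                     axis_angle_deg = 90, tolerance_deg = 15),
    simulate = list(what = "contraction", n_frames = NULL),
    stop_bad_arg(paste0("unknown modality: ", modality)))
}

resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_bad_arg("config must be a list or a YAML path")
  top_known <- c("modality", "seed", "out_dir", "params")
  bad <- setdiff(names(config), top_known)
  if (length(bad) > 0)
    stop_bad_arg(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  if (is.null(config$modality)) stop_bad_arg("config needs a `modality`")
  defaults <- default_params(config$modality)
  params <- config$params %||% list()
  bad <- setdiff(names(params), names(defaults))
  if (length(bad) > 0 && config$modality != "simulate")
    stop_bad_arg(paste0("unknown parameter keys for ", config$modality,
                        ": ", paste(bad, collapse = ", ")))
  config$params <- modifyList(defaults, params)
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% "cardiofunc_out"
  config
}

write_metrics <- function(metrics, out_dir) {
  path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run a configured analysis end to end
#'
#' `config` names one modality (`contraction`, `calcium`, `alignment`,
#' `migration`, or `simulate`) with a parameter block; unknown keys are
#' rejected. Outputs go to `out_dir`: `metrics.json` (units in key
#' names, percent on the 0-100 scale), per-point CSV tables, a figure per
#' result type, and `resolved_config.yaml` capturing every parameter
#' actually used.
#'
#' @param config list or path to a YAML file with fields `modality`,
#'   `seed`, `out_dir`, `params`.
#' @param write_figures write PNG figures (default TRUE).
#' @return the metrics list, invisibly; side effects in `out_dir`.
#' @export
run_pipeline <- function(config, write_figures = TRUE) {
  config <- resolve_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(config$out_dir, "resolved_config.yaml"))
  p <- config$params
  metrics <- switch(config$modality,
    contraction = run_contraction(p, config, write_figures),
    calcium = run_calcium(p, config, write_figures),
    alignment = run_alignment(p, config, write_figures),
    migration = run_migration(p, config, write_figures),
    simulate = run_simulate(p, config))
  write_metrics(metrics, config$out_dir)
  invisible(metrics)
}

run_contraction <- function(p, config, write_figures) {
  if (is.null(p$input)) stop_bad_arg("contraction: `input` TIFF required")
  stack <- read_stack(p$input, pixel_um = p$pixel_um,
                      frame_interval_s = p$frame_interval_s)
  grid <- build_grid(dim(stack)[1:2], p$subset_size_px, p$spacing_px)
  field <- track_stack(stack, grid, p$reference_frame_index,
                       p$search_radius_px)
  strains <- strain_from_displacements(field)
  mask <- if (identical(p$mask, "auto")) {
    auto_mask(field, p$disp_frac, p$quality_floor)
  } else {
    m <- read_image(p$mask) > 0.5
    # sample the mask at the subset centers
    matrix(m[cbind(grid$row, grid$col)], attr(grid, "grid_dim")[1L],
           attr(grid, "grid_dim")[2L], byrow = TRUE)
  }
  ct <- contractile_trace(strains, mask)
  readr::write_csv(ct$trace, file.path(config$out_dir, "strain_trace.csv"))
  readr::write_csv(strains[strains$frame == ct$peak_frame, ],
                   file.path(config$out_dir, "strain_field_peak.csv"))
  if (write_figures)
    ggplot2::ggsave(file.path(config$out_dir, "strain_trace.png"),
                    autoplot(ct), width = 6, height = 4, dpi = 150)
  list(max_contractile_strain_pct = ct$max_contractile_strain_pct,
       peak_frame = ct$peak_frame,
       n_masked_points = sum(mask),
       n_frames = n_frames(stack))
}

run_calcium <- function(p, config, write_figures) {
  if (is.null(p$input)) stop_bad_arg("calcium: `input` TIFF required")
  stack <- read_stack(p$input, pixel_um = p$pixel_um,
                      frame_interval_s = 1 / p$fps)
  traces <- extract_traces(stack, bin_px = p$bin_px,
                           smooth_width = p$smooth_width,
                           pacing_hz = p$pacing_hz)
  met <- cat_metrics(traces, beat = p$beat)
  amap <- build_activation_map(met)
  vf <- conduction_velocity(amap, k = p$cv_window)
  aniso <- tryCatch(
    anisotropy(vf, p$axis_angle_deg,
               half_width_deg = p$sector_half_width_deg),
    error = function(e) NULL)
  readr::write_csv(met, file.path(config$out_dir, "cat_metrics.csv"))
  readr::write_csv(vf$windows, file.path(config$out_dir, "cv_windows.csv"))
  if (write_figures) {
    ggplot2::ggsave(file.path(config$out_dir, "activation_map.png"),
                    autoplot(amap), width = 5, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(config$out_dir, "velocity_field.png"),
                    autoplot(vf), width = 5, height = 4, dpi = 150)
  }
  v <- met[met$valid, ]
  out <- list(catd80_ms = median(v$catd80_ms, na.rm = TRUE),
              rise_up_time_ms = median(v$rise_up_time_ms, na.rm = TRUE),
              mean_cv_cm_s = vf$mean_cv_cm_s,
              beat_rate_bpm = beat_rate_bpm(traces),
              n_valid_traces = nrow(v))
  if (!is.null(aniso)) {
    out$cv_long_cm_s <- aniso$cv_long_cm_s
    out$cv_trans_cm_s <- aniso$cv_trans_cm_s
    out$anisotropy_ratio <- aniso$anisotropy_ratio
  }
  out
}

run_alignment <- function(p, config, write_figures) {
  if (is.null(p$input)) stop_bad_arg("alignment: `input` image required")
  img <- read_image(p$input)
  cfg <- orientation_config(window_px = p$window_px, step_px = p$step_px,
                            energy_floor = p$energy_floor)
  field <- orientation_field(img, cfg)
  ref <- p$reference_angle_deg %||% superior_angle(field)
  al <- aligned_fraction(field, ref, p$tolerance_deg)
  readr::write_csv(field, file.path(config$out_dir, "orientation_windows.csv"))
  if (write_figures)
    ggplot2::ggsave(file.path(config$out_dir, "orientation_field.png"),
                    autoplot(field), width = 5, height = 4, dpi = 150)
  list(superior_angle_deg = ref,
       aligned_fraction_pct = 100 * al$aligned_fraction,
       tolerance_deg = p$tolerance_deg, n_windows = al$n_windows)
}

run_migration <- function(p, config, write_figures) {
  if (is.null(p$input)) stop_bad_arg("migration: `input` CSV required")
  traj <- read_trajectories(p$input, image_origin = p$image_origin)
  steps <- step_stats(traj)
  cs <- cohort_speeds(steps)
  di <- directionality_index(steps, p$axis_angle_deg, p$tolerance_deg)
  readr::write_csv(steps, file.path(config$out_dir, "migration_steps.csv"))
  if (write_figures)
    ggplot2::ggsave(file.path(config$out_dir, "rose.png"),
                    plot_rose(steps), width = 4, height = 4, dpi = 150)
  list(mean_speed_um_min = cs$summary$mean_speed_um_min,
       sd_speed_um_min = cs$summary$sd_speed_um_min,
       directionality_index = di,
       axis_angle_deg = p$axis_angle_deg,
       n_cells = cs$summary$n_cells, n_steps = nrow(steps))
}

run_simulate <- function(p, config) {
  what <- p$what %||% "contraction"
  seed <- config$seed
  out <- config$out_dir
  if (what == "contraction") {
    spec <- speckle_spec(seed = seed)
    truth <- contraction_truth()
    wm <- warp_movie(gen_speckle(spec), truth,
                     n_frames = p$n_frames %||% 41L)
    write_stack(wm$stack, file.path(out, "contraction.tif"))
    truth_json <- list(peak_contractile_strain = truth$peak_contractile_strain,
                       axis_angle_deg = truth$axis_angle_deg,
                       frame_rate_fps = truth$frame_rate_fps,
                       peak_frame = wm$peak_frame)
  } else if (what == "calcium") {
    truth <- wave_truth(seed = seed)
    cm <- gen_calcium_movie(truth, n_frames = p$n_frames %||% 900L)
    write_stack(cm$stack, file.path(out, "calcium.tif"))
    truth_json <- list(cv_long_cm_s = truth$cv_long_cm_s,
                       cv_trans_cm_s = truth$cv_trans_cm_s,
                       rise_up_ms = cm$rise_up_ms, catd80_ms = cm$catd80_ms,
                       pixel_um = truth$pixel_um, fps = truth$fps)
  } else if (what == "alignment") {
    spec <- fiber_field_spec(seed = seed)
    fi <- gen_fiber_image(spec)
    write_stack(fi$image, file.path(out, "fibers.tif"))
    truth_json <- list(mean_angle_deg = spec$mean_angle_deg,
                       kappa = spec$kappa,
                       aligned_fraction_truth = fi$aligned_fraction_truth)
  } else if (what == "migration") {
    spec <- walk_spec(seed = seed)
    walks <- gen_walks(spec)
    write_trajectories(walks, file.path(out, "walks.csv"))
    truth_json <- list(mode = spec$mode,
                       speed_um_min = spec$speed_um_min)
  } else {
    stop_bad_arg(paste0("unknown simulate target: ", what))
  }
  jsonlite::write_json(truth_json, file.path(out, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(simulated = what, seed = seed)
}
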