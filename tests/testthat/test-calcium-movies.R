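# Movie-level calcium analysis: trace extraction, activation maps,
# conduction velocity and anisotropy on truth-known synthetic waves.

activation_truth_map_for_test <- function(truth)
  cardiofunc:::activation_truth_map(truth)

circ_diff_deg_for_test <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

planar_movie <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      wt <- wave_truth(cv_long_cm_s = 12, cv_trans_cm_s = 12,
                       geometry = "planar", rise_time_ms = 30,
                       decay_tau_ms = 100, height_px = 60, width_px = 60)
      cm <- gen_calcium_movie(wt, n_frames = 620)
      tr <- extract_traces(cm$stack, bin_px = 2, pacing_hz = 1)
      cache <<- list(cm = cm, tr = tr, met = cat_metrics(tr))
    }
    cache
  }
})

test_that("planar activation times follow the analytic geometry exactly", {
  wt <- wave_truth(cv_long_cm_s = 10, cv_trans_cm_s = 10,
                   geometry = "planar", axis_angle_deg = 0,
                   rise_time_ms = 20, decay_tau_ms = 80,
                   height_px = 20, width_px = 40)
  cm <- gen_calcium_movie(wt, n_frames = 500)
  # t_a grows along +x at pixel_um / (10 * v) ms per pixel, constant in y
  ta <- cm$truth |> activation_truth_map_for_test()
  expect_equal(ta[1, ] - ta[1, 1], (0:39) * 60 / (10 * 10), tolerance = 1e-9)
  expect_true(all(abs(ta - rep(ta[1, ], each = 20)) < 1e-9))
})

test_that("noiseless traces peak exactly at activation + rise time", {
  wt <- wave_truth(geometry = "planar", rise_time_ms = 30,
                   decay_tau_ms = 100, height_px = 16, width_px = 16)
  cm <- gen_calcium_movie(wt, n_frames = 400)
  k <- which(cm$stack[4, 9, ] == max(cm$stack[4, 9, ]))[1]
  t_peak <- (k - 1) * 1000 / wt$fps
  ta_start <- cm$activation_ms[4, 9] - 15  # template upstroke start
  expect_equal(t_peak, ta_start + 30, tolerance = 1.0001)
})

test_that("elliptical isochrones have the prescribed axis ratio", {
  wt <- wave_truth(cv_long_cm_s = 16, cv_trans_cm_s = 8,
                   geometry = "elliptical", axis_angle_deg = 0,
                   rise_time_ms = 20, decay_tau_ms = 80)
  ta <- activation_truth_map_for_test(wt)
  t0 <- min(ta)
  # on-axis pixels reaching t0 + dt lie twice as far along x as along y
  ctr <- wt$origin_px
  row_c <- ta[, ctr[2]] - t0   # along y
  col_c <- ta[ctr[1], ] - t0   # along x
  d_for <- function(v, dt) {
    i <- which(abs(v - dt) == min(abs(v - dt)))[1]
    abs(i - (length(v) + 1) / 2)
  }
  expect_equal(d_for(col_c, 8) / d_for(row_c, 8), 2, tolerance = 0.15)
})

test_that("too-coarse sampling of the upstroke is rejected", {
  wt <- wave_truth(rise_time_ms = 2, fps = 1000, decay_tau_ms = 50,
                   height_px = 16, width_px = 16)
  expect_error(gen_calcium_movie(wt, n_frames = 400),
               class = "cardiofunc_bad_arg")
  wt2 <- wave_truth(rise_time_ms = 30, decay_tau_ms = 5000,
                    height_px = 16, width_px = 16)
  expect_error(gen_calcium_movie(wt2, n_frames = 40),
               class = "cardiofunc_bad_arg")
})

test_that("binning leaves activation times nearly unchanged on smooth waves", {
  pm <- planar_movie()
  tr1 <- extract_traces(pm$cm$stack, bin_px = 1, pacing_hz = 1)
  m1 <- cat_metrics(tr1)
  m4 <- pm$met  # bin_px = 2
  # compare medians: both should sit mid-recording with < 1 frame skew
  expect_lt(abs(median(m1$activation_time_ms[m1$valid]) -
                  median(m4$activation_time_ms[m4$valid])), 1)
})

test_that("constant movies yield no valid traces", {
  flat <- image_stack(array(0.4, c(16, 16, 50)), 60, 0.001)
  tr <- extract_traces(flat, bin_px = 2)
  expect_true(all(!tr$map$valid))
  expect_error(cat_metrics(tr) |> build_activation_map(),
               class = "cardiofunc_bad_arg")
})

test_that("activation map of a planar wave is planar with zero minimum", {
  pm <- planar_movie()
  am <- build_activation_map(pm$met)
  expect_equal(min(am$t_act_ms[am$valid]), 0)
  v <- am[am$valid, ]
  fit <- lm(t_act_ms ~ x_um + y_um, data = v)
  expect_lt(sqrt(mean(residuals(fit)^2)), 1)  # < one frame (ms)
})

test_that("recovered conduction velocity and direction match the truth", {
  pm <- planar_movie()
  vf <- conduction_velocity(build_activation_map(pm$met))
  expect_equal(vf$mean_cv_cm_s, 12, tolerance = 0.05 * 12)
  w <- vf$windows[vf$windows$valid, ]
  expect_lt(max(circ_diff_deg_for_test(w$angle_deg, 0)), 5)
})

test_that("halving spatial sampling doubles the reported speed", {
  pm <- planar_movie()
  am <- build_activation_map(pm$met)
  am2 <- am
  attr(am2, "pixel_um_eff") <- 2 * attr(am, "pixel_um_eff")
  am2$x_um <- 2 * am2$x_um; am2$y_um <- 2 * am2$y_um
  vf <- conduction_velocity(am)
  vf2 <- conduction_velocity(am2)
  expect_equal(vf2$mean_cv_cm_s, 2 * vf$mean_cv_cm_s, tolerance = 1e-6)
})

test_that("uniform activation is rejected as unresolvable", {
  m <- tibble::tibble(trace_id = 1:100,
                      row = rep(1:10, each = 10), col = rep(1:10, 10),
                      activation_time_ms = 5, rise_up_time_ms = 10,
                      catd80_ms = 100, valid = TRUE)
  m <- structure(m, pixel_um_eff = 60, fps = 1000, grid_dim = c(10L, 10L),
                 class = c("cat_metrics", class(m)))
  am <- build_activation_map(m)
  expect_error(conduction_velocity(am), class = "cardiofunc_bad_arg")
})

test_that("anisotropy ratio reflects elliptical truth and axis swaps", {
  wt <- wave_truth(cv_long_cm_s = 16, cv_trans_cm_s = 8,
                   geometry = "elliptical", axis_angle_deg = 0,
                   rise_time_ms = 30, decay_tau_ms = 100,
                   height_px = 60, width_px = 60)
  cm <- gen_calcium_movie(wt, n_frames = 620)
  vf <- conduction_velocity(build_activation_map(
    cat_metrics(extract_traces(cm$stack, bin_px = 2, pacing_hz = 1))))
  a0 <- anisotropy(vf, 0)
  expect_equal(a0$anisotropy_ratio, 2, tolerance = 0.15)
  a90 <- anisotropy(vf, 90)
  expect_equal(a90$cv_long_cm_s, a0$cv_trans_cm_s)
  expect_equal(a90$cv_trans_cm_s, a0$cv_long_cm_s)
})

test_that("spontaneous beat detection recovers the generator rate", {
  # 30 bpm = 0.5 Hz pacing left undeclared to the analysis
  wt <- wave_truth(pacing_hz = 0.5, geometry = "planar", rise_time_ms = 30,
                   decay_tau_ms = 100, height_px = 16, width_px = 16)
  cm <- gen_calcium_movie(wt, n_frames = 4000)
  tr <- extract_traces(cm$stack, bin_px = 2, pacing_hz = NULL)
  expect_equal(beat_rate_bpm(tr), 30, tolerance = 1)
  expect_equal(nrow(tr$beats), 2L)
})
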