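# Shared fixture builders (everything generated in code, nothing on disk).

# sinusoidal grating whose stripes (fibers) run at `angle_deg`
make_grating <- function(n = 256, angle_deg = 15, freq = 0.08,
                         contrast = 0.4) {
  x <- matrix(rep(seq_len(n), each = n), n, n)
  yup <- matrix(rep(n:1, times = n), n, n)
  th <- (angle_deg + 90) * pi / 180  # wave vector perpendicular to stripes
  0.5 + contrast * cos(2 * pi * freq * (x * cos(th) + yup * sin(th)))
}

# single-trace transient sampled at `fps`: linear rise of duration R from
# t_a, exponential decay tau, over total duration `dur_ms`
make_transient <- function(t_a = 50, R = 30, tau = 150, fps = 1000,
                           dur_ms = 900, baseline = 0, amplitude = 1) {
  t_ms <- seq(0, dur_ms, by = 1000 / fps)
  f <- ifelse(t_ms < t_a, 0,
              ifelse(t_ms <= t_a + R, (t_ms - t_a) / R,
                     exp(-(t_ms - t_a - R) / tau)))
  list(t_ms = t_ms, f = baseline + amplitude * f)
}

# speckle frame plus the same texture re-rendered with all dot centers
# displaced by (dx_px, dy_px_up): an exactly band-limited subpixel shift
shifted_speckle_pair <- function(spec, dx_px, dy_px_up) {
  ref <- gen_speckle(spec)
  centers <- attr(ref, "centers")
  moved <- centers
  moved[, "col"] <- moved[, "col"] + dx_px
  moved[, "row"] <- moved[, "row"] - dy_px_up
  cur <- cardiofunc:::speckle_from_centers(moved, spec)
  list(ref = ref, cur = cur)
}

# small contraction movie chain shared by several tests (built lazily once)
small_warp_chain <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- gen_speckle(speckle_spec(128, 128, dot_density = 5, seed = 7))
      truth <- contraction_truth(peak_contractile_strain = -0.03,
                                 axis_angle_deg = 0)
      wm <- warp_movie(ref, truth, n_frames = 15)
      grid <- build_grid(c(128, 128), 32, 8)
      field <- track_stack(wm$stack, grid, 1, search_radius_px = 5)
      cache <<- list(wm = wm, grid = grid, field = field)
    }
    cache
  }
})

expect_angle_close <- function(a, b, tol) {
  expect_lt(max(axial_diff_deg(a, b)), tol)
}
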