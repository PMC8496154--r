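# Generators: determinism, degenerate cases, and truth bookkeeping.

test_that("speckle generation is seed-deterministic and normalized", {
  spec <- speckle_spec(128, 128, dot_density = 5, seed = 7)
  a <- gen_speckle(spec)
  b <- gen_speckle(spec)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  # independent oracle: the number of rasterized dots is the number of
  # generated centers, which the density law fixes exactly
  expect_equal(nrow(attr(a, "centers")), round(5 * 128 * 128 / 100))
})

test_that("zero dot density gives a uniform background frame", {
  f <- gen_speckle(speckle_spec(64, 64, dot_density = 0, seed = 1))
  expect_equal(length(unique(as.vector(f))), 1L)
})

test_that("speckle spec validation rejects bad geometry", {
  expect_error(speckle_spec(32, 128), class = "cardiofunc_bad_arg")
  expect_error(speckle_spec(128, 128, dot_density = -1),
               class = "cardiofunc_bad_arg")
})

test_that("zero-scale event profile reproduces the reference everywhere", {
  ref <- gen_speckle(speckle_spec(64, 64, dot_density = 4, seed = 2))
  tr0 <- contraction_truth(peak_contractile_strain = -1e-9)
  wm <- warp_movie(ref, tr0, n_frames = 5)
  for (k in 1:5)
    expect_equal(wm$stack[, , k], unclass(ref), ignore_attr = TRUE,
                 tolerance = 1e-6)
})

test_that("imposed strain tensor matches its definition and rotation", {
  tr <- contraction_truth(-0.03, axis_angle_deg = 0)
  ref <- gen_speckle(speckle_spec(96, 96, dot_density = 4, seed = 3))
  wm <- warp_movie(ref, tr, n_frames = 5)
  expect_equal(wm$tensor, matrix(c(-0.03, 0, 0, 0), 2), tolerance = 1e-12)
  th <- 15 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  wm15 <- warp_movie(ref, contraction_truth(-0.03, 15), n_frames = 5)
  expect_equal(wm15$tensor, R %*% diag(c(-0.03, 0)) %*% t(R),
               tolerance = 1e-12)
})

test_that("analytic displacement field matches brute-force finite differences", {
  ref <- gen_speckle(speckle_spec(96, 96, dot_density = 4, seed = 3))
  wm <- warp_movie(ref, contraction_truth(-0.03, 15), n_frames = 5)
  k <- wm$peak_frame
  h <- 2
  rows <- seq(20, 76, by = 8); cols <- seq(20, 76, by = 8)
  pts <- expand.grid(row = rows, col = cols)
  u0 <- wm$displacement(pts$row, pts$col, k)
  ux_xp <- wm$displacement(pts$row, pts$col + h, k)$u_x
  ux_xm <- wm$displacement(pts$row, pts$col - h, k)$u_x
  uy_yp <- wm$displacement(pts$row - h, pts$col, k)$u_y  # y up = row down
  uy_ym <- wm$displacement(pts$row + h, pts$col, k)$u_y
  ux_yp <- wm$displacement(pts$row - h, pts$col, k)$u_x
  ux_ym <- wm$displacement(pts$row + h, pts$col, k)$u_x
  uy_xp <- wm$displacement(pts$row, pts$col + h, k)$u_y
  uy_xm <- wm$displacement(pts$row, pts$col - h, k)$u_y
  exx <- (ux_xp - ux_xm) / (2 * h)
  eyy <- (uy_yp - uy_ym) / (2 * h)
  exy <- 0.5 * ((ux_yp - ux_ym) / (2 * h) + (uy_xp - uy_xm) / (2 * h))
  E <- wm$tensor * wm$scale[k]
  expect_lt(max(abs(exx - E[1, 1])), 1e-6)
  expect_lt(max(abs(eyy - E[2, 2])), 1e-6)
  expect_lt(max(abs(exy - E[1, 2])), 1e-6)
})

test_that("excessive imposed displacement is rejected", {
  ref <- gen_speckle(speckle_spec(256, 256, dot_density = 2, seed = 1))
  expect_error(warp_movie(ref, contraction_truth(-0.19), n_frames = 5),
               class = "cardiofunc_bad_arg")
})

test_that("event profile starts at zero and attains its peak once", {
  ref <- gen_speckle(speckle_spec(64, 64, dot_density = 4, seed = 2))
  wm <- warp_movie(ref, contraction_truth(-0.02), n_frames = 15)
  expect_identical(wm$scale[1], 0)
  expect_equal(sum(wm$scale == 1), 1L)
})

test_that("fiber truth tally covers the degenerate and seeded cases", {
  # point mass: everything aligned
  fi <- gen_fiber_image(fiber_field_spec(30, kappa = 1e9, n_fibers = 50,
                                         height_px = 128, width_px = 128,
                                         seed = 1))
  expect_equal(fi$aligned_fraction_truth, 1.0)
  # uniform orientations: expected aligned fraction = 20/180
  fracs <- vapply(1:6, function(s) {
    gen_fiber_image(fiber_field_spec(15, kappa = 0, n_fibers = 400,
                                     height_px = 64, width_px = 64,
                                     fiber_length_px = 10, seed = s)
    )$aligned_fraction_truth
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 20 / 180), 0.03)
  # truth equals a direct tally of the sampled angles
  fi2 <- gen_fiber_image(fiber_field_spec(15, kappa = 4, n_fibers = 500,
                                          height_px = 128, width_px = 128,
                                          fiber_length_px = 10, seed = 9))
  tally <- mean(axial_diff_deg(fi2$angles_deg, 15) <= 10)
  expect_equal(fi2$aligned_fraction_truth, tally)
})

test_that("walk generators respect lane bounds and circular symmetry", {
  w <- gen_walks(walk_spec(mode = "lane", lane_width_um = 30,
                           speed_um_min = 0.3, n_cells = 10, n_steps = 50,
                           seed = 4))
  expect_true(all(w$x_um >= 0 & w$x_um <= 30))
  # isotropic headings: mean resultant length near zero
  wi <- gen_walks(walk_spec(mode = "isotropic", speed_um_min = 0.3,
                            n_cells = 40, n_steps = 60, seed = 5))
  st <- step_stats(wi)
  a <- st$angle_deg[st$angle_defined] * pi / 180
  r <- Mod(mean(exp(1i * a)))
  expect_lt(r, 3 / sqrt(length(a)))  # ~99% bound for uniform headings
})

test_that("generators are bitwise-deterministic under a fixed seed", {
  expect_identical(gen_walks(walk_spec(seed = 3)), gen_walks(walk_spec(seed = 3)))
  fs <- fiber_field_spec(seed = 8, n_fibers = 40, height_px = 96,
                         width_px = 96)
  expect_identical(gen_fiber_image(fs), gen_fiber_image(fs))
  wt <- wave_truth(noise_sd = 0.05, seed = 6, height_px = 24, width_px = 24,
                   rise_time_ms = 20, decay_tau_ms = 50)
  a <- gen_calcium_movie(wt, n_frames = 320)
  b <- gen_calcium_movie(wt, n_frames = 320)
  expect_identical(a$stack, b$stack)
})
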