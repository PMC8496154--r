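# Strain tensors, principal strains, masks, and the contractile trace.

# build a displacement_field tibble directly from analytic u(x, y)
synthetic_field <- function(fun, n = 9, spacing = 8, pixel_um = 1,
                            frames = 1L) {
  g <- build_grid(c(n * spacing + 32, n * spacing + 32), 32, spacing)
  purrr::map_dfr(seq_len(frames), function(k) {
    x <- g$col * pixel_um
    y <- -g$row * pixel_um
    u <- fun(x, y, k)
    tibble::tibble(frame = k, point_id = g$point_id, row = g$row,
                   col = g$col, u_x = u$u_x, u_y = u$u_y, quality = 1,
                   valid = TRUE, u_x_um = u$u_x * pixel_um,
                   u_y_um = u$u_y * pixel_um)
  }) |>
    structure(subset_size_px = 32L, spacing_px = as.integer(spacing),
              grid_dim = attr(g, "grid_dim"),
              image_shape = attr(g, "image_shape"), pixel_um = pixel_um,
              frame_interval_s = 0.05, reference_frame_index = 1L,
              class = c("displacement_field", "tbl_df", "tbl", "data.frame"))
}

test_that("rigid translation produces a zero tensor", {
  f <- synthetic_field(function(x, y, k) list(u_x = rep(3, length(x)),
                                              u_y = rep(-2, length(x))))
  s <- strain_from_displacements(f)
  expect_true(all(abs(s$eps_xx) < 1e-12))
  expect_true(all(abs(s$eps_yy) < 1e-12))
  expect_true(all(abs(s$eps_xy) < 1e-12))
})

test_that("affine displacements give exact tensors, including shear", {
  a <- 0.01
  f <- synthetic_field(function(x, y, k) list(u_x = a * x, u_y = 0 * y))
  s <- strain_from_displacements(f)
  expect_equal(s$eps_xx, rep(a, nrow(s)), tolerance = 1e-10)
  expect_true(all(abs(s$eps_yy) < 1e-12))
  fs <- synthetic_field(function(x, y, k) list(u_x = a * y, u_y = a * x))
  ss <- strain_from_displacements(fs)
  expect_equal(ss$eps_xy, rep(a, nrow(ss)), tolerance = 1e-10)
  expect_equal(ss$eps_1, rep(a, nrow(ss)), tolerance = 1e-10)
  expect_equal(ss$eps_2, rep(-a, nrow(ss)), tolerance = 1e-10)
})

test_that("principal strains match an eigen oracle and preserve the trace", {
  set.seed(42)
  for (i in 1:20) {
    e <- rnorm(3, sd = 0.02)
    pr <- principal_strains(e[1], e[2], e[3])
    ev <- sort(eigen(matrix(c(e[1], e[3], e[3], e[2]), 2),
                     symmetric = TRUE)$values, decreasing = TRUE)
    expect_equal(c(pr$eps_1, pr$eps_2), ev, tolerance = 1e-12)
    expect_gte(pr$eps_1, pr$eps_2)
    expect_equal(pr$eps_1 + pr$eps_2, e[1] + e[2], tolerance = 1e-12)
  }
  pr <- principal_strains(0.02, -0.01, 0)
  expect_equal(pr$eps_1, 0.02)
  expect_equal(pr$eps_2, -0.01)
})

test_that("principal strains are invariant under field rotation", {
  set.seed(7)
  a <- matrix(rnorm(4, sd = 0.01), 2)  # random displacement gradient
  E <- (a + t(a)) / 2
  for (th_deg in c(20, 55, 110)) {
    th <- th_deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    Er <- R %*% E %*% t(R)
    p0 <- principal_strains(E[1, 1], E[2, 2], E[1, 2])
    pr <- principal_strains(Er[1, 1], Er[2, 2], Er[1, 2])
    expect_equal(pr$eps_1, p0$eps_1, tolerance = 1e-12)
    expect_equal(pr$eps_2, p0$eps_2, tolerance = 1e-12)
  }
})

test_that("invalid displacement points poison only their neighborhood", {
  f <- synthetic_field(function(x, y, k) list(u_x = 0.01 * x, u_y = 0 * y))
  mid <- f$point_id[f$row == sort(unique(f$row))[5] &
                      f$col == sort(unique(f$col))[5]]
  f$u_x[f$point_id == mid] <- NA
  f$u_x_um[f$point_id == mid] <- NA
  f$valid[f$point_id == mid] <- FALSE
  s <- strain_from_displacements(f)
  bad <- s[!s$valid, ]
  expect_gt(nrow(bad), 0)
  expect_lte(nrow(bad), 5)  # the point and its 4-neighborhood
  good <- s[s$valid, ]
  expect_equal(good$eps_xx, rep(0.01, nrow(good)), tolerance = 1e-10)
})

test_that("tiny grids are rejected", {
  f <- synthetic_field(function(x, y, k) list(u_x = 0 * x, u_y = 0 * y))
  attr(f, "grid_dim") <- c(1L, 9L)
  expect_error(strain_from_displacements(f), class = "cardiofunc_bad_arg")
})

test_that("contractile trace of a zero field is zero, mask-independent", {
  f <- synthetic_field(function(x, y, k) list(u_x = 0 * x, u_y = 0 * y),
                       frames = 4)
  s <- strain_from_displacements(f)
  gd <- attr(s, "grid_dim")
  full <- matrix(TRUE, gd[1], gd[2])
  ct <- contractile_trace(s, full)
  expect_true(all(ct$trace$mean_eps2 == 0))
  expect_equal(ct$max_contractile_strain_pct, 0)
  # uniform field: half mask gives the same trace as the full mask
  fu <- synthetic_field(function(x, y, k) list(u_x = -0.01 * x, u_y = 0 * y),
                        frames = 2)
  su <- strain_from_displacements(fu)
  half <- full; half[, 1:4] <- FALSE
  expect_equal(contractile_trace(su, full)$trace$mean_eps2,
               contractile_trace(su, half)$trace$mean_eps2,
               tolerance = 1e-10)
  expect_error(contractile_trace(su, full & FALSE),
               class = "cardiofunc_bad_arg")
})

test_that("auto mask keeps uniformly moving tissue and rejects pure noise", {
  pair <- shifted_speckle_pair(speckle_spec(96, 96, dot_density = 6,
                                            seed = 18), 1.5, -1.5)
  stack <- image_stack(array(c(pair$ref, pair$cur), c(96, 96, 2)), 1, 0.05)
  fld <- track_stack(stack, build_grid(c(96, 96), 32, 16), 1, 4)
  m <- auto_mask(fld)
  expect_true(mean(m) > 0.95)
  set.seed(11)
  noise <- array(runif(64 * 64 * 4), c(64, 64, 4))
  nf <- track_stack(image_stack(noise, 1, 0.05),
                    build_grid(c(64, 64), 32, 16), 1, 4)
  expect_error(auto_mask(nf), class = "cardiofunc_bad_arg")
})

test_that("pipeline recovers the imposed peak contractile strain", {
  ch <- small_warp_chain()
  s <- strain_from_displacements(ch$field)
  ct <- contractile_trace(s, auto_mask(ch$field))
  expect_equal(ct$max_contractile_strain_pct, 3.0, tolerance = 0.1)
  expect_equal(ct$peak_frame, ch$wm$peak_frame)
})

test_that("tidy/glance/autoplot work on contraction traces", {
  ch <- small_warp_chain()
  ct <- contractile_trace(strain_from_displacements(ch$field),
                          auto_mask(ch$field))
  expect_s3_class(tidy(ct), "tbl_df")
  g <- glance(ct)
  expect_equal(g$max_contractile_strain_pct, ct$max_contractile_strain_pct)
  expect_s3_class(autoplot(ct), "ggplot")
})
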