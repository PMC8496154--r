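# Subset grids and image correlation.

test_that("subset grids keep every subset inside the image", {
  g <- build_grid(c(128, 128), 32, 8)
  expect_true(all(g$row >= 17 & g$row <= 112))
  expect_true(all(g$col >= 17 & g$col <= 112))
  # brute-force enumeration oracle for the 256^2 default geometry
  valid_centers <- function(n, size, sp) {
    half <- size %/% 2
    sum(vapply(seq_len(n), function(c) c - half >= 1 && c + half <= n,
               logical(1)) & ((seq_len(n) - (half + 1)) %% sp == 0) &
          seq_len(n) >= half + 1)
  }
  g2 <- build_grid(c(256, 256), 32, 8)
  expect_equal(nrow(g2), valid_centers(256, 32, 8)^2)
})

test_that("degenerate spacing yields a single center; bad subsets rejected", {
  g <- build_grid(c(64, 64), 32, 64)
  expect_equal(nrow(g), 1L)
  expect_error(build_grid(c(16, 16), 32, 8), class = "cardiofunc_bad_arg")
})

test_that("identical frames match at zero displacement with quality one", {
  ref <- gen_speckle(speckle_spec(64, 64, dot_density = 6, seed = 1))
  m <- match_subset(ref, ref, c(32, 32), 32, 5)
  expect_equal(m$u_x, 0)
  expect_equal(m$u_y, 0)
  expect_equal(m$quality, 1, tolerance = 1e-12)
})

test_that("integer shifts are recovered exactly at interior subsets", {
  ref <- gen_speckle(speckle_spec(96, 96, dot_density = 6, seed = 2))
  # shift content by dx=+3 (right), dy=-2 (down two rows in image terms)
  cur <- matrix(0, 96, 96)
  cur[3:96, 4:96] <- ref[1:94, 1:93]
  for (ctr in list(c(48, 48), c(40, 56), c(60, 44))) {
    m <- match_subset(ref, cur, ctr, 32, 6)
    expect_equal(m$u_x, 3)
    expect_equal(m$u_y, -2)
    expect_gt(m$quality, 0.999)
  }
})

test_that("band-limited half-pixel shifts are recovered within 0.1 px", {
  pair <- shifted_speckle_pair(speckle_spec(96, 96, dot_density = 6,
                                            seed = 3), 0.5, 0)
  errs <- vapply(list(c(48, 48), c(40, 40), c(56, 56)), function(ctr) {
    m <- match_subset(pair$ref, pair$cur, ctr, 32, 5)
    abs(m$u_x - 0.5)
  }, numeric(1))
  expect_lt(max(errs), 0.1)
})

test_that("flat texture is flagged invalid, not zero", {
  flat <- matrix(0.5, 64, 64)
  m <- match_subset(flat, flat, c(32, 32), 32, 5)
  expect_false(m$valid)
  expect_true(is.na(m$u_x))
})

test_that("translation equivariance: common integer shifts cancel", {
  ref <- gen_speckle(speckle_spec(96, 96, dot_density = 6, seed = 4))
  cur <- gen_speckle(speckle_spec(96, 96, dot_density = 6, seed = 5))
  shift_img <- function(img, dr, dc) {
    out <- matrix(mean(img), nrow(img), ncol(img))
    out[(1 + dr):nrow(img), (1 + dc):ncol(img)] <-
      img[1:(nrow(img) - dr), 1:(ncol(img) - dc)]
    out
  }
  m0 <- match_subset(ref, cur, c(40, 40), 24, 5)
  m1 <- match_subset(shift_img(ref, 4, 4), shift_img(cur, 4, 4),
                     c(44, 44), 24, 5)
  expect_equal(m1$u_x, m0$u_x, tolerance = 1e-9)
  expect_equal(m1$u_y, m0$u_y, tolerance = 1e-9)
})

test_that("tracking a constant stack yields an all-zero field", {
  ref <- gen_speckle(speckle_spec(64, 64, dot_density = 6, seed = 6))
  stack <- image_stack(array(rep(ref, 3), c(64, 64, 3)), 1, 0.05)
  g <- build_grid(c(64, 64), 32, 16)
  f <- track_stack(stack, g, 1, 4)
  expect_true(all(f$u_x == 0 & f$u_y == 0))
  expect_true(all(f$valid))
})

test_that("tracking recovers the imposed affine field at the strain peak", {
  ch <- small_warp_chain()
  pk <- ch$field[ch$field$frame == ch$wm$peak_frame & ch$field$valid, ]
  an <- ch$wm$displacement(pk$row, pk$col, ch$wm$peak_frame)
  rms <- sqrt(mean((pk$u_x - an$u_x)^2 + (pk$u_y - an$u_y)^2))
  expect_lt(rms, 0.15)
  expect_gt(min(pk$quality), 0.9)  # interpolated warp blurs the texture a bit
})

test_that("a correct match on noiseless data has near-perfect quality", {
  # integer-aligned content: exact correlation
  ref <- gen_speckle(speckle_spec(96, 96, dot_density = 6, seed = 19))
  cur <- matrix(mean(ref), 96, 96)
  cur[3:96, 1:96] <- ref[1:94, 1:96]
  expect_gt(match_subset(ref, cur, c(48, 48), 32, 5)$quality, 0.99)
  # at a half-pixel offset the integer-lag correlation peak is bounded by
  # the texture autocorrelation, still close to 1
  pair <- shifted_speckle_pair(speckle_spec(96, 96, dot_density = 6,
                                            seed = 19), 0.5, 0.25)
  expect_gt(match_subset(pair$ref, pair$cur, c(48, 48), 32, 5)$quality, 0.9)
})

test_that("reversing the imposed event negates the recovered field", {
  ref <- gen_speckle(speckle_spec(96, 96, dot_density = 6, seed = 8))
  # two frames: rest and peak of opposite-sign strains
  wp <- warp_movie(ref, contraction_truth(-0.02, 0), n_frames = 3)
  wn <- warp_movie(ref, contraction_truth(0.02, 0), n_frames = 3)
  g <- build_grid(c(96, 96), 32, 16)
  fp <- track_stack(image_stack(wp$stack[, , c(1, 2)], 1, 1), g, 1, 4)
  fn <- track_stack(image_stack(wn$stack[, , c(1, 2)], 1, 1), g, 1, 4)
  p2 <- fp[fp$frame == 2, ]; n2 <- fn[fn$frame == 2, ]
  ok <- p2$valid & n2$valid
  expect_gt(mean(ok), 0.5)
  expect_lt(sqrt(mean((p2$u_x[ok] + n2$u_x[ok])^2)), 0.1)
  expect_lt(sqrt(mean((p2$u_y[ok] + n2$u_y[ok])^2)), 0.1)
})
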