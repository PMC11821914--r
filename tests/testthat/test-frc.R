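test_that("FRC of an image with itself is 1 on every ring", {
  set.seed(1)
  img <- matrix(runif(64 * 64), 64, 64)
  cu <- frc_curve(img, img, bio_pixel_nm = 25)
  expect_true(all(abs(cu$correlations - 1) < 1e-9))
  expect_true(all(diff(cu$frequencies) > 0))
  expect_equal(max(cu$frequencies), 1 / (2 * 25))  # Nyquist
  expect_error(frc_curve(matrix(0, 16, 16), matrix(0, 16, 16), 25),
               "degenerate-input")
  expect_error(frc_curve(img, img[, 1:32], 25), "shapes differ|square")
})

test_that("FRC is symmetric and invariant to intensity scaling", {
  set.seed(2)
  sp <- crossing_tubes_spec(n = 64)
  pair <- render_image(make_tube_phantom(sp), 2, seed = 2)
  a <- get_plane(pair[[1]])
  b <- get_plane(pair[[2]])
  c1 <- frc_curve(a, b, 25)
  c2 <- frc_curve(b, a, 25)
  expect_equal(c1$correlations, c2$correlations, tolerance = 1e-12)
  c3 <- frc_curve(3.7 * a, 0.2 * b, 25)
  expect_equal(c1$correlations, c3$correlations, tolerance = 1e-9)
})

test_that("independent pure-noise images decorrelate beyond the first ring", {
  set.seed(3)
  a <- matrix(rpois(64 * 64, 100), 64, 64)
  b <- matrix(rpois(64 * 64, 100), 64, 64)
  cu <- frc_curve(a, b, 25)
  # rings with enough pixels for the statistic to stabilize stay below 0.2,
  # and the curve carries no correlation on average
  big <- cu$n_pixels_per_ring >= 100
  expect_true(all(abs(cu$correlations[big]) < 0.2))
  expect_lt(abs(mean(cu$correlations)), 0.05)
})

test_that("FFT ring sums equal direct DFT ring summation to 1e-10", {
  set.seed(4)
  for (win in c(TRUE, FALSE)) {
    a <- matrix(runif(32 * 32), 32, 32)
    b <- a + matrix(rnorm(32 * 32, sd = 0.2), 32, 32)
    b <- b - min(b)
    fast <- frc_curve(a, b, 20, window = win)
    slow <- frc_curve_direct(a, b, 20, window = win)
    expect_equal(fast$correlations, slow$correlations, tolerance = 1e-10)
    expect_equal(fast$frequencies, slow$frequencies, tolerance = 1e-12)
  }
})

test_that("threshold crossing interpolates linearly and handles limits", {
  mk_curve <- function(corrs, pix = 25) {
    structure(list(frequencies = seq_along(corrs) / (64 * pix),
                   correlations = corrs,
                   n_pixels_per_ring = rep(8L, length(corrs)),
                   bio_pixel_nm = pix), class = "frc_curve")
  }
  # drops from 0.5 to 0.05 between rings 3 and 4; 1/7 lies 0.3571/0.45 of the way
  cu <- mk_curve(c(0.9, 0.8, 0.5, 0.05, 0.01))
  res <- frc_resolution(cu, threshold = 1 / 7)
  f_star <- (3 + (0.5 - 1 / 7) / (0.5 - 0.05)) / (64 * 25)
  expect_equal(res$resolution_nm, 1 / f_star, tolerance = 1e-9)
  expect_equal(res$flag, "crossing")

  # curve == 1 everywhere: Nyquist-limited
  res1 <- frc_resolution(mk_curve(rep(1, 32)))
  expect_equal(res1$resolution_nm, 50)
  expect_equal(res1$flag, "limit")

  # below threshold already at the first ring: no-signal error
  expect_error(frc_resolution(mk_curve(c(0.05, 0.01))), "no-signal")
})

test_that("phantom-pair resolution is recovered and degrades monotonically with noise", {
  resolutions <- vapply(c(2000, 100, 10), function(ph_scale) {
    sp <- crossing_tubes_spec(n = 128, seed = 10L, photon_scale = ph_scale,
                              background_level = 2)
    pair <- render_image(make_tube_phantom(sp), 2, seed = 10)
    cu <- frc_curve(get_plane(pair[[1]]), get_plane(pair[[2]]),
                    bio_pixel_size(pair[[1]])[2])
    frc_resolution(cu)$resolution_nm
  }, numeric(1))
  # more photons -> finer (or equal) resolution, never better with less light
  expect_true(all(diff(resolutions) >= 0))
  # at high SNR the estimate sits near the PSF scale (FWHM 62.5 nm biological)
  expect_gt(resolutions[1], 40)
  expect_lt(resolutions[1], 150)
})

test_that("blockwise FRC reduces to full-image FRC for a one-block image", {
  sp <- crossing_tubes_spec(n = 64, seed = 6L)
  pair <- render_image(make_tube_phantom(sp), 2, seed = 6)
  a <- get_plane(pair[[1]])
  b <- get_plane(pair[[2]])
  blk <- blockwise_frc(a, b, 25, block_size_px = 64L)
  full <- frc_resolution(frc_curve(a, b, 25))$resolution_nm
  expect_equal(blk$best_resolution_nm, full, tolerance = 1e-12)
  expect_equal(nrow(blk$per_block), 1)
})

test_that("blocks without content are left unscored and best is the minimum", {
  set.seed(7)
  sp <- phantom_spec(c(1, 64, 64), 25, tubes = list(
    list(control_points_px = rbind(c(0, 8, 4), c(0, 24, 28)),
         radius_nm = 200, shell_nm = 40)), seed = 7L)  # signal in one quadrant
  pair <- render_image(make_tube_phantom(sp), 2, seed = 7)
  blk <- blockwise_frc(get_plane(pair[[1]]), get_plane(pair[[2]]), 25,
                       block_size_px = 32L, min_block_content = 0.2)
  expect_equal(nrow(blk$per_block), 4)
  expect_true(any(!blk$per_block$scored))
  scored <- blk$per_block$resolution_nm[blk$per_block$scored]
  expect_equal(blk$best_resolution_nm, min(scored))
  expect_lte(blk$best_resolution_nm, median(scored))

  # sparse bright dots nowhere reaching the content fraction: no scoreable block
  sp1 <- matrix(rpois(64 * 64, 2), 64, 64)
  sp1[sample(64 * 64, 150)] <- 1000
  expect_error(blockwise_frc(sp1, sp1 + 1, 25, block_size_px = 32L),
               "no scoreable block")
})

test_that("odd-even frame splitting preserves order and validates length", {
  arr <- array(0, dim = c(40, 4, 4))
  for (f in 1:40) arr[f, , ] <- f
  ser <- image_stack(list(arr), pixel_size_nm = 100, axes = "tyx")
  halves <- split_frames(ser)
  expect_equal(dim(get_channel(halves$a))[1], 20)
  expect_equal(dim(get_channel(halves$b))[1], 20)
  expect_equal(get_channel(halves$a)[, 1, 1], seq(1, 39, by = 2))
  expect_equal(get_channel(halves$b)[, 1, 1], seq(2, 40, by = 2))

  two <- image_stack(list(arr[1:2, , , drop = FALSE]), 100, axes = "tyx")
  h2 <- split_frames(two)
  expect_equal(get_channel(h2$a)[1, 1, 1], 1)
  expect_equal(get_channel(h2$b)[1, 1, 1], 2)

  odd <- image_stack(list(arr[1:3, , , drop = FALSE]), 100, axes = "tyx")
  expect_error(split_frames(odd), "even")

  # concatenating a series with itself interleaves the duplicates
  cat2 <- array(0, dim = c(8, 4, 4))
  for (f in 1:8) cat2[f, , ] <- c(1, 2, 3, 4, 1, 2, 3, 4)[f]
  serc <- image_stack(list(cat2), 100, axes = "tyx")
  hc <- split_frames(serc)
  expect_equal(get_channel(hc$a)[, 1, 1], c(1, 3, 1, 3))
  expect_equal(get_channel(hc$b)[, 1, 1], c(2, 4, 2, 4))
})
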