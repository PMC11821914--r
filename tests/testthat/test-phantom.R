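test_that("tube rendering is deterministic and geometrically correct", {
  sp <- phantom_spec(c(1, 32, 64), 25, tubes = list(
    list(control_points_px = rbind(c(0, 16, 4), c(0, 16, 60)),
         radius_nm = 150, shell_nm = 40)))
  ph1 <- make_tube_phantom(sp)
  ph2 <- make_tube_phantom(sp)
  expect_identical(ph1$geometry, ph2$geometry)

  # pre-PSF transverse cut shows two wall maxima ~300 nm apart
  cut <- ph1$geometry$membrane[1, , 32]
  peaks <- which(diff(sign(diff(cut))) == -2) + 1
  expect_length(peaks, 2)
  expect_equal(abs(diff(peaks)) * 25, 300, tolerance = 25)  # within one voxel

  # shell voxels sit at |distance - radius| <= shell/2 of the centerline
  shell_y <- which(ph1$shell_mask[1, , 32])
  d_nm <- abs(shell_y - 1 - 16) * 25
  expect_true(all(abs(d_nm - 150) <= 20 + 25))

  # zero tubes: all-zero volume
  empty <- make_tube_phantom(phantom_spec(c(1, 8, 8), 25))
  expect_true(all(empty$geometry$membrane == 0))

  # invalid spec: radius must exceed half shell thickness
  expect_error(phantom_spec(c(1, 8, 8), 25, tubes = list(
    list(control_points_px = rbind(c(0, 4, 0), c(0, 4, 7)),
         radius_nm = 15, shell_nm = 40))), "radius")
})

test_that("noisy rendering is reproducible and follows the noise model", {
  sp <- cilium_phantom(length_px = 100, seed = 7L)
  ph <- make_tube_phantom(sp)
  a <- render_image(ph, seed = 7)
  b <- render_image(ph, seed = 7)
  expect_identical(get_channel(a), get_channel(b))

  # photon_scale = 0: image is background + read noise only
  sp0 <- phantom_spec(c(1, 24, 24), 25, tubes = list(
    list(control_points_px = rbind(c(0, 12, 2), c(0, 12, 22)),
         radius_nm = 150, shell_nm = 40)),
    photon_scale = 0, background_level = 5, gauss_read_noise = 1, seed = 2L)
  img0 <- render_image(make_tube_phantom(sp0))
  expect_equal(mean(get_channel(img0)), 5, tolerance = 0.2)

  # Poisson statistics: mean of constant-signal pixels within 3 SE
  spc <- phantom_spec(c(1, 40, 40), 25, photon_scale = 0, background_level = 50,
                      gauss_read_noise = 0, seed = 3L)
  imgc <- render_image(make_tube_phantom(spc))
  v <- as.vector(get_channel(imgc))
  se <- sqrt(50 / length(v))
  expect_lt(abs(mean(v) - 50), 3 * se)
})

test_that("two realizations share signal but have independent noise", {
  sp <- crossing_tubes_spec(n = 196, seed = 5L)
  ph <- make_tube_phantom(sp)
  pair <- render_image(ph, n_realizations = 2, seed = 5)
  a <- get_plane(pair[[1]])
  b <- get_plane(pair[[2]])
  expect_false(identical(a, b))
  # noise residuals (image minus expected signal) are uncorrelated
  sigma_px <- memquant:::psf_sigma_bio_nm(sp) / sp$bio_pixel_nm
  signal <- sp$photon_scale *
    memquant:::gaussian_blur_nd(ph$geometry$membrane, sigma_px)[1, , ] +
    sp$background_level
  r <- cor(as.vector(a - signal), as.vector(b - signal))
  expect_lt(abs(r), 0.02)
})

test_that("gap insertion hits the target fraction within one interval quantum", {
  sp <- cilium_phantom(length_px = 400)  # 10 um path
  ph <- make_tube_phantom(sp)

  ph0 <- insert_gaps(ph, 0, 100)
  expect_identical(ph0$geometry, ph$geometry)
  expect_equal(nrow(ph0$gaps_truth[[1]]), 0)

  ph3 <- insert_gaps(ph, 0.03, min_gap_len_nm = 100, seed = 11)
  total <- sum(ph3$gaps_truth[[1]][, 2] - ph3$gaps_truth[[1]][, 1])
  expect_gte(total, 300 - 1e-6)
  expect_lt(total, 300 + 100)  # overshoot bounded by one minimum interval
  # intervals lie within the path and are disjoint
  g <- ph3$gaps_truth[[1]]
  L <- path_length_nm(ph3$paths_truth[[1]])
  expect_true(all(g[, 1] >= 0 & g[, 2] <= L))
  if (nrow(g) > 1) expect_true(all(g[-1, 1] >= g[-nrow(g), 2]))

  expect_error(insert_gaps(ph, 1.0, 100), "parameter error")
  expect_error(insert_gaps(ph, 0.5, min_gap_len_nm = 1e6), "parameter error")
})

test_that("ground truth stays consistent after gap insertion", {
  sp <- cilium_phantom(length_px = 400)
  ph <- insert_gaps(make_tube_phantom(sp), 0.05, 200, seed = 4)
  vox <- ph$shell_voxels
  g <- ph$gaps_truth[[1]]
  in_gap <- rep(FALSE, nrow(vox))
  for (i in seq_len(nrow(g))) in_gap <- in_gap | (vox$s_nm >= g[i, 1] & vox$s_nm <= g[i, 2])
  # every gap-interval voxel was zeroed in both geometry and mask
  expect_true(all(ph$geometry$membrane[vox$idx[in_gap]] == 0))
  expect_true(all(!ph$shell_mask[vox$idx[in_gap]]))
  # away from gaps every hard-shell voxel survives
  margin <- 100
  clear <- rep(TRUE, nrow(vox))
  for (i in seq_len(nrow(g))) {
    clear <- clear & (vox$s_nm < g[i, 1] - margin | vox$s_nm > g[i, 2] + margin)
  }
  expect_true(all(ph$shell_mask[vox$idx[clear & vox$hard]]))
})

test_that("fluctuation series blink per emitter and keep noise where expected", {
  sp <- phantom_spec(c(1, 24, 48), 25, tubes = list(
    list(control_points_px = rbind(c(0, 12, 4), c(0, 12, 44)),
         radius_nm = 150, shell_nm = 40)),
    fill_channel = FALSE, photon_scale = 300, background_level = 2,
    gauss_read_noise = 1, seed = 9L)
  ph <- make_tube_phantom(sp)
  ser <- make_fluctuation_series(ph, n_frames = 20, blink_on_prob = 0.5, seed = 9)
  expect_equal(ser$axes, "tyx")
  arr <- get_channel(ser)
  expect_equal(dim(arr)[1], 20)
  v <- apply(arr, c(2, 3), stats::var)
  on_shell <- ph$shell_mask[1, , ]
  # blinking variance on the shell far exceeds the noise floor off it
  expect_gt(median(v[on_shell]), 10 * median(v[!on_shell]))

  # blink_on_prob = 1: static signal, variance at the shot-noise level only
  ser1 <- make_fluctuation_series(ph, n_frames = 20, blink_on_prob = 1, seed = 9)
  v1 <- apply(get_channel(ser1), c(2, 3), stats::var)
  expect_lt(median(v1[on_shell]), median(v[on_shell]) / 5)

  expect_error(make_fluctuation_series(ph, 20, 0), "parameter error")
  expect_error(make_fluctuation_series(ph, 20, 1.5), "parameter error")
  expect_error(make_fluctuation_series(ph, 1, 0.5), "n_frames >= 2")
})

test_that("distorted pairs have exact scaling, landmarks and field statistics", {
  sp <- crossing_tubes_spec(n = 128)
  ph <- make_tube_phantom(sp)

  # amplitude 0, factor 4: landmark distance ratios are exactly 4
  pair <- make_distorted_pair(ph, 4, deformation_amp_nm = 0, seed = 1)
  est <- estimate_expansion_factor(pair$landmarks, pair$pre$pixel_size_nm,
                                   pair$post$pixel_size_nm)
  expect_equal(est$factor, 4, tolerance = 1e-12)
  expect_equal(est$sd, 0, tolerance = 1e-12)

  # the truth field has the requested RMS magnitude
  pair50 <- make_distorted_pair(ph, 4, deformation_amp_nm = 50,
                                deformation_scale_px = 24, seed = 2)
  f <- pair50$deformation_truth
  expect_equal(sqrt(mean(f$dy^2 + f$dx^2)), 50, tolerance = 1e-9)

  # factor 1, amplitude 0: pre == post up to interpolation epsilon
  pair1 <- make_distorted_pair(ph, 1, deformation_amp_nm = 0, seed = 3)
  expect_equal(get_plane(pair1$pre), get_plane(pair1$post), tolerance = 1e-9)
})
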