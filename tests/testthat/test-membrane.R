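test_that("path sampling interpolates correctly and counts samples", {
  # constant image: every sample equals the constant, sd 0
  arr <- array(7, dim = c(1, 16, 60))
  st <- image_stack(arr, pixel_size_nm = 25)
  p <- membrane_path(rbind(c(0, 8, 2), c(0, 8, 42)), bio_pixel_size(st))
  prof <- sample_path_intensity(st, p, sampling_step_nm = 30)
  expect_true(all(prof$intensity == 7))
  expect_equal(prof$sd, 0)

  # 1200 nm path at 30 nm steps: 41 samples
  p2 <- membrane_path(rbind(c(0, 8, 2), c(0, 8, 50)), bio_pixel_size(st))
  expect_equal(path_length_nm(p2), 1200)
  prof2 <- sample_path_intensity(st, p2, sampling_step_nm = 30)
  expect_length(prof2$intensity, 41)

  # linear ramp: samples match the analytic interpolation
  ramp <- array(0, dim = c(1, 16, 60))
  for (x in 1:60) ramp[1, , x] <- x - 1
  str <- image_stack(ramp, pixel_size_nm = 25)
  profr <- sample_path_intensity(str, p2, sampling_step_nm = 30)
  expect_equal(profr$intensity, 2 + profr$arclength_nm / 25, tolerance = 1e-9)

  # out-of-bounds vertex is reported by index
  bad <- membrane_path(rbind(c(0, 8, 2), c(0, 99, 10)), bio_pixel_size(st))
  expect_error(sample_path_intensity(st, bad), "vertex 2")
})

test_that("gap detection applies the 2-SD rule with the minimum-extent filter", {
  # hand-built profile with path statistics fixed at mean 100, sd 10
  # (threshold = 100 - 2*10 = 80): one 3-sample low run spanning 90 nm and
  # one single-sample low run spanning 30 nm, both at value 60
  step <- 30
  vals <- rep(100, 100)
  vals[40:42] <- 60   # 90 nm extent
  vals[70] <- 60      # 30 nm extent
  prof <- structure(list(
    arclength_nm = (seq_along(vals) - 1) * step,
    intensity = vals, mean = 100, sd = 10,
    step_nm = step, path_length_nm = (length(vals) - 1) * step,
    source = "hand"), class = "intensity_profile")
  gaps <- detect_gaps(prof, k_sd = 2, min_gap_len_nm = 60)
  # the 3-sample (90 nm) low run is a gap; the single-sample (30 nm) one is not
  expect_equal(gaps$n_gaps, 1)
  expect_equal(unname(gaps$gaps[1, 2] - gaps$gaps[1, 1]), 90)

  # constant profile: degenerate SD, no gaps
  cprof <- prof
  cprof$intensity <- rep(5, length(vals)); cprof$sd <- 0; cprof$mean <- 5
  g0 <- detect_gaps(cprof)
  expect_equal(g0$n_gaps, 0)
  expect_true(g0$degenerate_sd)

  # k_sd -> Inf or min_gap_len -> Inf: no gaps
  expect_equal(detect_gaps(prof, k_sd = 1e6)$n_gaps, 0)
  expect_equal(detect_gaps(prof, min_gap_len_nm = 1e9)$n_gaps, 0)
})

test_that("percent continuity is the length fraction outside gaps", {
  step <- 30
  vals <- rep(100, 335)
  prof <- structure(list(
    arclength_nm = (seq_along(vals) - 1) * step, intensity = vals,
    mean = 100, sd = 10, step_nm = step,
    path_length_nm = 10000, source = "hand"), class = "intensity_profile")
  empty <- structure(list(gaps = matrix(numeric(0), ncol = 2), n_gaps = 0L,
                          total_gap_nm = 0, threshold = 80,
                          degenerate_sd = FALSE), class = "gap_set")
  expect_equal(percent_continuity(prof, empty)$percent_continuity, 100)
  g300 <- empty
  g300$gaps <- rbind(c(1000, 1200), c(5000, 5100))
  g300$n_gaps <- 2L
  g300$total_gap_nm <- 300
  expect_equal(percent_continuity(prof, g300)$percent_continuity, 97.0)
})

test_that("adding a gap never increases continuity and bounds hold", {
  vals <- c(rep(100, 200), rep(0, 10), rep(100, 200))
  prof <- structure(list(
    arclength_nm = (seq_along(vals) - 1) * 30, intensity = vals,
    mean = mean(vals), sd = sd(vals), step_nm = 30,
    path_length_nm = (length(vals) - 1) * 30, source = "hand"),
    class = "intensity_profile")
  g1 <- detect_gaps(prof)
  c1 <- percent_continuity(prof, g1)$percent_continuity
  expect_gte(c1, 0); expect_lte(c1, 100)
  vals2 <- vals; vals2[300:320] <- 0
  prof2 <- prof
  prof2$intensity <- vals2; prof2$mean <- mean(vals2); prof2$sd <- sd(vals2)
  c2 <- percent_continuity(prof2, detect_gaps(prof2))$percent_continuity
  expect_lte(c2, c1)
})

test_that("an inserted phantom gap is found where the truth says it is", {
  sp <- cilium_phantom(length_px = 400, seed = 21L)
  ph <- make_tube_phantom(sp)
  ph <- insert_gaps(ph, 0.02, min_gap_len_nm = 150, seed = 21)
  truth <- ph$gaps_truth[[1]]
  img <- render_image(ph, seed = 22)
  bio <- bio_pixel_size(img)
  tr <- membrane_path(rbind(c(0, 8 + 6, 5), c(0, 8 + 6, 405)), bio, source = "wall")
  prof <- sample_path_intensity(img, tr, channel = "membrane")
  gaps <- detect_gaps(prof, k_sd = 2, min_gap_len_nm = 60)
  expect_gte(gaps$n_gaps, 1)
  jaccard <- function(a, b) {
    inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
    inter / (max(a[2], b[2]) - min(a[1], b[1]))
  }
  best <- max(apply(gaps$gaps, 1, function(g)
    max(apply(truth, 1, function(tg) jaccard(g, tg)))))
  expect_gt(best, 0.5)
})

test_that("transverse profiles are normalized, symmetric and flag degeneracy", {
  sp <- phantom_spec(c(1, 64, 64), 25, tubes = list(
    list(control_points_px = rbind(c(0, 32, 4), c(0, 32, 60)),
         radius_nm = 150, shell_nm = 40)), fill_channel = FALSE, seed = 23L)
  ph <- make_tube_phantom(sp)
  img <- image_stack(memquant:::gaussian_blur_nd(ph$geometry$membrane,
                                                 c(0, 1, 1)),
                     pixel_size_nm = 100, expansion_factor = 4)
  tp <- transverse_profile(img, center = c(32, 32), angle_deg = 0,
                           length_nm = 500, width_nm = 800)
  expect_equal(max(tp$normalized), 1)
  expect_false(tp$degenerate)
  # twin wall peaks
  v <- tp$intensity
  n <- length(v)
  peaks <- which(c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE))
  expect_gte(length(peaks), 2)

  # rotating the box 180 degrees reverses the profile
  tp2 <- transverse_profile(img, c(32, 32), 180, 500, 800)
  expect_equal(tp2$intensity, rev(tp$intensity), tolerance = 1e-9)

  flat <- image_stack(array(3, dim = c(1, 32, 32)), 100)
  tpf <- transverse_profile(flat, c(16, 16), 0, 300, 300)
  expect_true(tpf$degenerate)
  expect_error(transverse_profile(img, c(32, 32), 0, 0, 300), "degenerate box")
})

test_that("diameters come from parabolic-refined wall peaks", {
  # analytic two-Gaussian profile with peaks at +/-150 nm
  off <- seq(-400, 400, by = 10)
  v <- exp(-(off - 150)^2 / (2 * 50^2)) + exp(-(off + 150)^2 / (2 * 50^2))
  tp <- structure(list(offset_nm = off, intensity = v, normalized = v / max(v),
                       degenerate = FALSE), class = "transverse_profile")
  d <- diameter_from_profile(tp)
  expect_equal(d$diameter_nm, 300, tolerance = 10)

  # intensity scaling leaves the diameter unchanged
  tp5 <- tp; tp5$intensity <- 5 * tp5$intensity
  expect_equal(diameter_from_profile(tp5)$diameter_nm, d$diameter_nm)

  # flat or single-peaked profiles have unresolved walls
  flat <- tp; flat$intensity <- rep(1, length(off)); flat$degenerate <- TRUE
  expect_error(diameter_from_profile(flat), "unresolved-walls")
  single <- tp; single$intensity <- exp(-off^2 / (2 * 80^2)); single$degenerate <- FALSE
  expect_error(diameter_from_profile(single), "unresolved-walls")
})

test_that("a rendered phantom tube measures ~300 nm across after PSF blur", {
  sp <- phantom_spec(c(1, 64, 64), 12.5, tubes = list(
    list(control_points_px = rbind(c(0, 32, 4), c(0, 32, 60)),
         radius_nm = 150, shell_nm = 40)),
    fill_channel = FALSE, psf_fwhm_nm = c(240, 500), photon_scale = 5000,
    background_level = 2, seed = 24L)  # FWHM 60 nm biological
  img <- render_image(make_tube_phantom(sp), seed = 24)
  tp <- transverse_profile(img, c(32, 32), 0, length_nm = 500, width_nm = 700,
                           channel = "membrane")
  d <- diameter_from_profile(tp)
  expect_lt(abs(d$diameter_nm - 300) / 300, 0.15)
})
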