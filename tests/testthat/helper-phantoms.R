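# Shared phantom constructors for the test suite. Conditions mirror the
# structures the analyses target: a straight cilium-like tube for continuity,
# a puncta-rich field (mitochondria-marker-like texture) for registration,
# and blinking emitters for fluctuation imaging.

# Single straight cilium-like tube (radius 150 nm, 40 nm shell) along x.
cilium_phantom <- function(length_px = 800, bio_nm = 25, seed = 0L, ...) {
  phantom_spec(
    c(1, 16, length_px + 10), bio_nm,
    tubes = list(list(
      control_points_px = rbind(c(0, 8, 5), c(0, 8, 5 + length_px)),
      radius_nm = 150, shell_nm = 40)),
    fill_channel = FALSE, photon_scale = 200, background_level = 5,
    seed = seed, ...)
}

# Two crossing curved tubes in a 2-D plane; texture for FRC / registration.
crossing_tubes_spec <- function(n = 256, bio_nm = 25, seed = 0L, ...) {
  phantom_spec(
    c(1, n, n), bio_nm,
    tubes = list(
      list(control_points_px = rbind(c(0, 0.12 * n, 0.04 * n),
                                     c(0, 0.47 * n, 0.47 * n),
                                     c(0, 0.78 * n, 0.94 * n)),
           radius_nm = 200, shell_nm = 40),
      list(control_points_px = rbind(c(0, 0.78 * n, 0.08 * n),
                                     c(0, 0.39 * n, 0.51 * n),
                                     c(0, 0.23 * n, 0.9 * n)),
           radius_nm = 150, shell_nm = 40)),
    seed = seed, ...)
}

# Blinking two-point-emitter series: emitters separated by sep_fwhm PSF
# widths, independent Bernoulli on/off, Poisson noise. Returns the (t, y, x)
# array plus geometry for reference.
two_emitter_series <- function(n_frames = 200, n = 32, sigma_px = 2, sep_fwhm = 0.7,
                               photons = 300, p_on = 0.5, background = 2,
                               seed = 1) {
  set.seed(seed)
  fwhm <- 2 * sqrt(2 * log(2)) * sigma_px
  sep <- sep_fwhm * fwhm
  c0 <- (n + 1) / 2
  p1 <- c(c0, c0 - sep / 2)
  p2 <- c(c0, c0 + sep / 2)
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  spot <- function(p) exp(-((yy - p[1])^2 + (xx - p[2])^2) / (2 * sigma_px^2))
  s1 <- spot(p1)
  s2 <- spot(p2)
  series <- array(0, dim = c(n_frames, n, n))
  for (f in seq_len(n_frames)) {
    lam <- photons * (s1 * stats::rbinom(1, 1, p_on) + s2 * stats::rbinom(1, 1, p_on)) +
      background
    series[f, , ] <- stats::rpois(n * n, lam)
  }
  list(series = series, sigma_px = sigma_px, emitters = rbind(p1, p2))
}

# Count strict 2-D local maxima above a fraction of the image maximum.
count_local_maxima <- function(img, frac = 0.2) {
  ny <- nrow(img); nx <- ncol(img)
  thr <- frac * max(img)
  cnt <- 0
  for (i in 2:(ny - 1)) {
    for (j in 2:(nx - 1)) {
      v <- img[i, j]
      nb <- img[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (v > thr && v == max(nb) && sum(nb == v) == 1) cnt <- cnt + 1
    }
  }
  cnt
}

# Measured continuity of one seeded cilium phantom with inserted gap fraction g.
measure_continuity <- function(g, seed, min_insert_nm = 200) {
  sp <- cilium_phantom(seed = seed)
  ph <- make_tube_phantom(sp)
  if (g > 0) ph <- insert_gaps(ph, g, min_gap_len_nm = min_insert_nm, seed = seed)
  img <- render_image(ph, seed = seed + 1000L)
  bio <- bio_pixel_size(img)
  yw <- 8 + 150 / bio[2]  # trace along the upper membrane wall
  tr <- membrane_path(rbind(c(0, yw, 5), c(0, yw, 805)), bio, source = "wall")
  prof <- sample_path_intensity(img, tr, channel = "membrane")
  gaps <- detect_gaps(prof, k_sd = 2, min_gap_len_nm = 60)
  percent_continuity(prof, gaps)$percent_continuity
}
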