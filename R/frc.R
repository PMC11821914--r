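#' Fourier ring correlation curve between two independent acquisitions
#'
#' Computes, per integer-radius frequency ring, the normalized cross-
#' correlation of the two images' Fourier transforms:
#' `FRC(f) = Re sum_ring F_a conj(F_b) / sqrt(sum_ring |F_a|^2 sum_ring |F_b|^2)`,
#' after optional 2-D Hann apodization (on by default, suppressing edge
#' leakage). Frequencies are reported in 1/nm of *biological* units — pixel
#' sizes are normalized by the expansion factor so resolution reads in
#' original-tissue terms. Values are clipped to `[-1, 1]`.
#'
#' @param img_a,img_b Equal-sized square numeric matrices: the same field
#'   imaged twice with independent noise.
#' @param bio_pixel_nm Biological pixel size (nm) of the plane (isotropic
#'   lateral sampling assumed).
#' @param window Apply a Hann window (default `TRUE`).
#' @return Object of class `frc_curve` with `frequencies` (1/nm, strictly
#'   increasing, up to Nyquist), `correlations`, `n_pixels_per_ring`, and
#'   `bio_pixel_nm`.
#' @export
frc_curve <- function(img_a, img_b, bio_pixel_nm, window = TRUE) {
  if (!is.matrix(img_a) || !is.matrix(img_b)) stopf("frc_curve expects 2-D matrices")
  if (!all(dim(img_a) == dim(img_b))) stopf("image shapes differ: %s vs %s",
                                            paste(dim(img_a), collapse = "x"),
                                            paste(dim(img_b), collapse = "x"))
  if (nrow(img_a) != ncol(img_a)) stopf("frc_curve expects square planes")
  if (all(img_a == img_a[1]) || all(img_b == img_b[1])) {
    stopf("degenerate-input error: constant image")
  }
  n <- nrow(img_a)
  # remove the DC component before apodization: the window otherwise leaks
  # the (large) mean intensity into the lowest-frequency rings
  img_a <- img_a - mean(img_a)
  img_b <- img_b - mean(img_b)
  if (window) {
    w <- hann_window_2d(n, n)
    img_a <- img_a * w
    img_b <- img_b * w
  }
  fa <- stats::fft(img_a)
  fb <- stats::fft(img_b)
  k <- fft_freq_index(n)
  rad <- sqrt(outer(k^2, k^2, `+`))
  ring <- round(rad)
  kmax <- floor(n / 2)
  num <- Re(fa * Conj(fb))
  pa <- Mod(fa)^2
  pb <- Mod(fb)^2
  sel <- ring >= 1 & ring <= kmax
  rf <- factor(ring[sel], levels = seq_len(kmax))
  s_num <- as.numeric(tapply(num[sel], rf, sum, default = 0))
  s_pa <- as.numeric(tapply(pa[sel], rf, sum, default = 0))
  s_pb <- as.numeric(tapply(pb[sel], rf, sum, default = 0))
  npix <- as.integer(table(rf))
  den <- sqrt(s_pa * s_pb)
  corr <- ifelse(den > 0, s_num / den, 0)
  corr <- clamp(corr, -1, 1)
  structure(list(
    frequencies = seq_len(kmax) / (n * bio_pixel_nm),
    correlations = corr,
    n_pixels_per_ring = npix,
    bio_pixel_nm = bio_pixel_nm
  ), class = "frc_curve")
}

#' Resolution from an FRC curve by fixed-threshold crossing
#'
#' Resolution is `1/f*` where `f*` is the first frequency at which the curve
#' falls below the threshold (default 1/7, the fixed-threshold criterion
#' standard in the FRC ecosystem), with linear interpolation between the
#' adjacent rings. A curve that never crosses returns the Nyquist-limited
#' value `2 * bio_pixel_nm`, flagged `"limit"`; a curve already below the
#' threshold at the first ring is a no-signal error.
#'
#' @param curve An `frc_curve`.
#' @param threshold Correlation cutoff in (0, 1) (default `1/7`).
#' @return List of class `frc_resolution` with `resolution_nm` and `flag`
#'   (`"crossing"` or `"limit"`).
#' @export
frc_resolution <- function(curve, threshold = 1 / 7) {
  stopifnot(inherits(curve, "frc_curve"))
  stopifnot(threshold > 0, threshold < 1)
  co <- curve$correlations
  fr <- curve$frequencies
  if (co[1] < threshold) {
    stopf("no-signal error: FRC below threshold at the first ring (%.3f < %.3f)",
          co[1], threshold)
  }
  below <- which(co < threshold)
  if (!length(below)) {
    return(structure(list(resolution_nm = 2 * curve$bio_pixel_nm, flag = "limit"),
                     class = "frc_resolution"))
  }
  i <- below[1]
  f_star <- fr[i - 1] + (co[i - 1] - threshold) / (co[i - 1] - co[i]) * (fr[i] - fr[i - 1])
  res <- max(1 / f_star, 2 * curve$bio_pixel_nm)
  structure(list(resolution_nm = res, flag = "crossing"), class = "frc_resolution")
}

#' Blockwise FRC resolution map
#'
#' Tiles the image pair into `block_size_px` square tiles, scores tiles whose
#' above-background content fraction reaches `min_block_content` (a pixel
#' counts as content when it exceeds a global Otsu threshold computed on the
#' average of the two acquisitions), computes an FRC resolution per scored
#' tile, and reports the per-block map together with the best value. "Best"
#' is the minimum (finest) resolution across scored blocks — the value used
#' to quantify an image pair's resolution.
#'
#' @param img_a,img_b Equal-sized matrices (the two acquisitions).
#' @param bio_pixel_nm Biological pixel size (nm).
#' @param block_size_px Tile edge length (default 128, minimum 32).
#' @param threshold FRC threshold (default `1/7`).
#' @param min_block_content Minimum content fraction per tile (default 0.2).
#' @param window Hann window flag passed to [frc_curve()].
#' @return Object of class `frc_result` with `best_resolution_nm`, `per_block`
#'   (data.frame: row, col, content fraction, resolution, scored flag), and
#'   `best_rule = "min_resolution"`.
#' @export
blockwise_frc <- function(img_a, img_b, bio_pixel_nm, block_size_px = 128L,
                          threshold = 1 / 7, min_block_content = 0.2,
                          window = TRUE) {
  if (block_size_px < 32L) stopf("block_size_px must be >= 32")
  if (!all(dim(img_a) == dim(img_b))) stopf("image shapes differ")
  nby <- nrow(img_a) %/% block_size_px
  nbx <- ncol(img_a) %/% block_size_px
  if (nby < 1 || nbx < 1) stopf("images smaller than one block")
  avg <- (img_a + img_b) / 2
  rng <- range(avg)
  if (rng[1] == rng[2]) stopf("no scoreable block: images are constant")
  norm <- (avg - rng[1]) / (rng[2] - rng[1])
  t01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bg_thr <- rng[1] + t01 * (rng[2] - rng[1])
  rows <- integer(0); cols <- integer(0); content <- numeric(0)
  res <- numeric(0); scored <- logical(0)
  for (by in seq_len(nby)) {
    for (bx in seq_len(nbx)) {
      ys <- ((by - 1) * block_size_px + 1):(by * block_size_px)
      xs <- ((bx - 1) * block_size_px + 1):(bx * block_size_px)
      frac <- mean(avg[ys, xs] > bg_thr)
      r <- NA_real_
      sc <- FALSE
      if (frac >= min_block_content) {
        r <- tryCatch({
          cu <- frc_curve(img_a[ys, xs], img_b[ys, xs], bio_pixel_nm, window = window)
          frc_resolution(cu, threshold)$resolution_nm
        }, error = function(e) NA_real_)
        sc <- !is.na(r)
      }
      rows <- c(rows, by); cols <- c(cols, bx)
      content <- c(content, frac); res <- c(res, r); scored <- c(scored, sc)
    }
  }
  if (!any(scored)) {
    stopf("no scoreable block: content fractions were %s (need >= %g)",
          paste(sprintf("%.2f", content), collapse = ", "), min_block_content)
  }
  structure(list(
    best_resolution_nm = min(res[scored]),
    per_block = data.frame(row = rows, col = cols, content = content,
                           resolution_nm = res, scored = scored),
    best_rule = "min_resolution",
    threshold = threshold,
    block_size_px = as.integer(block_size_px)
  ), class = "frc_result")
}

#' Split a frame series into odd and even halves
#'
#' Divides a `(t, y, x)` series into the odd-indexed and even-indexed frames
#' (order preserved within each half) — the scheme used to build two
#' independent inputs for FRC from a single fluctuation acquisition (e.g. 40
#' frames into two sets of 20).
#'
#' @param series An [image_stack] with axes `"tyx"`.
#' @param scheme Only `"odd-even"` is defined.
#' @param channel Channel to split.
#' @return List with `a` (odd frames) and `b` (even frames), both
#'   [image_stack]s with axes `"tyx"`.
#' @export
split_frames <- function(series, scheme = "odd-even", channel = 1L) {
  stopifnot(inherits(series, "image_stack"))
  if (!identical(scheme, "odd-even")) stopf("unknown split scheme '%s'", scheme)
  arr <- get_channel(series, channel)
  t <- dim(arr)[1]
  if (t < 2 || t %% 2 != 0) stopf("series length must be even and >= 2, got %d", t)
  odd <- arr[seq(1, t, by = 2), , , drop = FALSE]
  even <- arr[seq(2, t, by = 2), , , drop = FALSE]
  mk <- function(a) image_stack(list(a), pixel_size_nm = series$pixel_size_nm,
                                expansion_factor = series$expansion_factor,
                                channel_names = series$channel_names[1], axes = "tyx")
  list(a = mk(odd), b = mk(even))
}

#' Average a frame series into a single plane
#'
#' @param series An [image_stack] with axes `"tyx"`.
#' @param channel Channel to average.
#' @return Numeric `(y, x)` matrix.
#' @export
frame_average <- function(series, channel = 1L) {
  arr <- get_channel(series, channel)
  apply(arr, c(2, 3), mean)
}
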