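#' Gaussian PSF model for deconvolution
#'
#' Diffraction-limited lateral PSF approximated as a 2-D Gaussian with
#' `sigma = 0.21 * lambda / NA / pixel_size` pixels, truncated at 4 sigma and
#' normalized to sum 1.
#'
#' @param na Numerical aperture, in (0, 1.7).
#' @param wavelength_nm Emission wavelength in nm.
#' @param pixel_size_nm Pixel size in nm (same length scale as the image the
#'   PSF will be applied to).
#' @return Object of class `psf_model`: `sigma_px`, `kernel` (odd-sized
#'   matrix summing to 1).
#' @export
gaussian_psf <- function(na, wavelength_nm, pixel_size_nm) {
  if (!(na > 0 && na < 1.7)) stopf("NA out of range (0, 1.7): %g", na)
  if (wavelength_nm <= 0 || pixel_size_nm <= 0) {
    stopf("wavelength and pixel size must be positive")
  }
  sigma_px <- 0.21 * wavelength_nm / na / pixel_size_nm
  psf_from_sigma(sigma_px)
}

psf_from_sigma <- function(sigma_px) {
  k1 <- gauss_kernel_1d(sigma_px, trunc = 4)
  kernel <- outer(k1, k1)
  kernel <- kernel / sum(kernel)
  structure(list(sigma_px = sigma_px, kernel = kernel), class = "psf_model")
}

# Circular (FFT) convolution of an image with a centered kernel.
fft_convolve <- function(img, kernel) {
  ny <- nrow(img); nx <- ncol(img)
  kf <- matrix(0, ny, nx)
  kh <- (dim(kernel) - 1) %/% 2
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      yi <- ((i - 1 - kh[1]) %% ny) + 1
      xi <- ((j - 1 - kh[2]) %% nx) + 1
      kf[yi, xi] <- kf[yi, xi] + kernel[i, j]
    }
  }
  Re(stats::fft(stats::fft(img) * stats::fft(kf), inverse = TRUE)) / (ny * nx)
}

#' Fourier (sinc) upsampling of an image
#'
#' Zero-padded Fourier interpolation: the spectrum is embedded in a larger
#' frequency grid (Nyquist bins split symmetrically for even sizes) and
#' inverse-transformed, preserving mean intensity. Output dimensions are
#' `scale` times the input.
#'
#' @param image Numeric matrix.
#' @param scale Integer upsampling factor in `{1, 2, 4}`.
#' @return Upsampled matrix.
#' @export
fourier_upsample <- function(image, scale) {
  if (!scale %in% c(1L, 2L, 4L)) stopf("scale must be 1, 2 or 4")
  scale <- as.integer(scale)
  if (scale == 1L) return(image)
  ny <- nrow(image); nx <- ncol(image)
  pad <- pad_spectrum_axis(stats::fft(image), scale, 1L)
  pad <- pad_spectrum_axis(pad, scale, 2L)
  # unnormalized inverse FFT / original pixel count: preserves mean intensity
  Re(stats::fft(pad, inverse = TRUE)) / (ny * nx)
}

# Zero-pad an FFT spectrum along one axis, splitting the Nyquist bin in half
# between +/- frequencies for even sizes (keeps Hermitian symmetry, so the
# inverse transform of real input stays real).
pad_spectrum_axis <- function(F, scale, axis) {
  if (axis == 2L) return(t(pad_spectrum_axis(t(F), scale, 1L)))
  n <- nrow(F)
  N <- n * scale
  out <- matrix(0 + 0i, N, ncol(F))
  if (n %% 2 == 0) {
    half <- n %/% 2
    out[1:half, ] <- F[1:half, , drop = FALSE]
    out[half + 1, ] <- F[half + 1, , drop = FALSE] / 2
    out[N - half + 1, ] <- F[half + 1, , drop = FALSE] / 2
    if (half >= 2) out[(N - half + 2):N, ] <- F[(half + 2):n, , drop = FALSE]
  } else {
    half <- (n + 1) %/% 2
    out[1:half, ] <- F[1:half, , drop = FALSE]
    out[(N - half + 2):N, ] <- F[(half + 1):n, , drop = FALSE]
  }
  out
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative RL updates with a symmetric Gaussian PSF (FFT
#' convolutions, circular boundary). Zero iterations returns the input;
#' output stays non-negative for non-negative input.
#'
#' @param image Non-negative numeric matrix.
#' @param psf A `psf_model` from [gaussian_psf()].
#' @param n_iters Number of iterations, `>= 0`.
#' @return Deconvolved matrix.
#' @export
richardson_lucy <- function(image, psf, n_iters) {
  stopifnot(inherits(psf, "psf_model"), n_iters >= 0)
  if (any(image < 0)) stopf("negative input pixels: clip before deconvolution")
  if (n_iters == 0) return(image)
  est <- image
  eps <- .Machine$double.eps
  for (i in seq_len(n_iters)) {
    conv <- fft_convolve(est, psf$kernel)
    ratio <- image / pmax(conv, eps)
    est <- est * fft_convolve(ratio, psf$kernel)  # Gaussian PSF is symmetric
    est[est < 0] <- 0
  }
  est
}

#' Per-pixel temporal cumulant of a fluctuation series
#'
#' Order-2: the lag-0 variance of each pixel's mean-subtracted time course
#' (population denominator `t`), the quantity whose PSF is the square of the
#' imaging PSF — hence a sqrt(2) resolution gain before deconvolution.
#' Negative rounding noise is clipped at 0.
#'
#' @param series An [image_stack] with axes `"tyx"`, or a `(t, y, x)` array.
#' @param order Cumulant order; only 2 is implemented.
#' @param channel Channel for stack input.
#' @return Numeric `(y, x)` matrix.
#' @export
temporal_cumulant <- function(series, order = 2L, channel = 1L) {
  if (order != 2L) stopf("unsupported cumulant order %d (only 2 is implemented)", order)
  arr <- if (inherits(series, "image_stack")) get_channel(series, channel) else series
  if (length(dim(arr)) != 3L || dim(arr)[1] < 2) stopf("need a (t, y, x) series with t >= 2")
  t <- dim(arr)[1]
  mu <- apply(arr, c(2, 3), mean)
  v <- apply(arr, c(2, 3), function(x) mean((x - mean(x))^2))
  v[v < 0] <- 0
  v
}

#' SACD parameter set
#'
#' Defaults follow the standard fluctuation-reconstruction recipe: 10
#' pre-deconvolution iterations, 2x Fourier upsampling, 10 post-deconvolution
#' iterations, cumulant order 2 (the second deconvolution uses the PSF
#' narrowed by `1/sqrt(order)`).
#'
#' @param n1 Pre-deconvolution RL iterations (default 10).
#' @param fourier_scale Upsampling factor in `{1, 2, 4}` (default 2).
#' @param n2 Post-deconvolution RL iterations (default 10).
#' @param order Cumulant order (only 2).
#' @param psf A `psf_model` on the native pixel grid.
#' @return List of class `sacd_params`.
#' @export
sacd_params <- function(psf, n1 = 10L, fourier_scale = 2L, n2 = 10L, order = 2L) {
  stopifnot(inherits(psf, "psf_model"), n1 >= 0, n2 >= 0, order >= 2)
  if (!fourier_scale %in% c(1L, 2L, 4L)) stopf("fourier_scale must be 1, 2 or 4")
  structure(list(psf = psf, n1 = as.integer(n1),
                 fourier_scale = as.integer(fourier_scale),
                 n2 = as.integer(n2), order = as.integer(order)),
            class = "sacd_params")
}

#' Fluctuation super-resolution reconstruction (simplified SACD)
#'
#' Pipeline: per-frame Richardson-Lucy deconvolution (`n1` iterations, native
#' grid) — per-frame Fourier upsampling (`fourier_scale`) — per-pixel
#' temporal cumulant (`order`) — clip at 0 — Richardson-Lucy (`n2`
#' iterations) with the PSF rescaled to the upsampled grid and narrowed by
#' `1/sqrt(order)`. The result is a non-negative image on the
#' `fourier_scale`-times finer grid; a temporally constant series yields a
#' near-zero reconstruction since the cumulant removes static signal.
#'
#' @param series An [image_stack] with axes `"tyx"` (t >= 2), or `(t, y, x)`
#'   array.
#' @param params An [sacd_params()] object.
#' @param channel Channel for stack input.
#' @return Reconstructed `(y, x)` matrix at the upsampled grid.
#' @export
sacd_reconstruct <- function(series, params, channel = 1L) {
  stopifnot(inherits(params, "sacd_params"))
  arr <- if (inherits(series, "image_stack")) get_channel(series, channel) else series
  if (length(dim(arr)) != 3L || dim(arr)[1] < 2) stopf("need a (t, y, x) series with t >= 2")
  t <- dim(arr)[1]
  up <- NULL
  for (f in seq_len(t)) {
    frame <- arr[f, , ]
    frame <- richardson_lucy(frame, params$psf, params$n1)
    frame <- fourier_upsample(frame, params$fourier_scale)
    if (is.null(up)) up <- array(0, dim = c(t, dim(frame)))
    up[f, , ] <- frame
  }
  cum <- temporal_cumulant(up, order = params$order)
  cum[cum < 0] <- 0
  psf2 <- psf_from_sigma(params$psf$sigma_px * params$fourier_scale / sqrt(params$order))
  richardson_lucy(cum, psf2, params$n2)
}
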