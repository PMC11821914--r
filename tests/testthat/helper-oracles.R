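# Independent oracles: brute-force / direct-summation implementations kept
# deliberately separate from the package's optimized code paths.

# Direct-DFT Fourier ring correlation: the 2-D transform is computed by
# explicit DFT matrix multiplication (no fft), rings summed directly.
frc_curve_direct <- function(img_a, img_b, bio_pixel_nm, window = TRUE) {
  n <- nrow(img_a)
  img_a <- img_a - mean(img_a)
  img_b <- img_b - mean(img_b)
  if (window) {
    wy <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
    w <- outer(wy, wy)
    img_a <- img_a * w
    img_b <- img_b * w
  }
  idx <- 0:(n - 1)
  W <- exp(-2i * pi * outer(idx, idx) / n)   # DFT matrix
  Fa <- W %*% img_a %*% W
  Fb <- W %*% img_b %*% W
  k <- idx
  k[k > n / 2] <- k[k > n / 2] - n
  rad <- sqrt(outer(k^2, k^2, `+`))
  ring <- round(rad)
  kmax <- floor(n / 2)
  corr <- numeric(kmax)
  for (r in seq_len(kmax)) {
    sel <- ring == r
    num <- sum(Re(Fa[sel] * Conj(Fb[sel])))
    den <- sqrt(sum(Mod(Fa[sel])^2) * sum(Mod(Fb[sel])^2))
    corr[r] <- if (den > 0) num / den else 0
  }
  list(frequencies = seq_len(kmax) / (n * bio_pixel_nm),
       correlations = pmin(pmax(corr, -1), 1))
}

# Exhaustive pair-enumeration Rand index over all C(n, 2) element pairs.
rand_brute_force <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1
    }
  }
  agree / (n * (n - 1) / 2)
}

# Trigonometric interpolation of a real image evaluated on the scale-times
# finer grid by direct summation over frequency components (split Nyquist).
fourier_upsample_direct <- function(img, scale) {
  n <- nrow(img)
  stopifnot(n == ncol(img), n %% 2 == 0)
  grid <- 0:(n - 1)
  F <- matrix(0 + 0i, n, n)
  for (u in grid) {
    for (v in grid) {
      ph <- exp(-2i * pi * (u * grid %o% rep(1, n) + rep(1, n) %o% (v * grid)) / n)
      F[u + 1, v + 1] <- sum(img * ph)
    }
  }
  # two-sided spectrum: k in -n/2..n/2 with the (shared) Nyquist bin halved
  ks <- (-n / 2):(n / 2)
  wt <- rep(1, length(ks))
  wt[c(1, length(ks))] <- 0.5
  Fk <- vapply(ks, function(k) (k %% n) + 1L, integer(1))  # bin index per signed freq
  N <- n * scale
  out <- matrix(0, N, N)
  for (yi in 0:(N - 1)) {
    y <- yi / scale
    ey <- wt * exp(2i * pi * ks * y / n)
    for (xi in 0:(N - 1)) {
      x <- xi / scale
      ex <- wt * exp(2i * pi * ks * x / n)
      s <- 0 + 0i
      for (a in seq_along(ks)) {
        s <- s + ey[a] * sum(F[Fk[a], Fk] * ex)
      }
      out[yi + 1, xi + 1] <- Re(s) / n^2
    }
  }
  out
}

# Analytic minimum distance from grid voxels to a segment, for rasterization
# checks (anisotropic pixel sizes handled by the caller via nm coordinates).
min_dist_to_segment <- function(p, a, b) {
  v <- b - a
  t <- sum((p - a) * v) / sum(v^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * v))^2))
}
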