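# Internal numerics shared across modules. All public coordinates are 0-based and
# pixel-centered, axis order (z, y, x); conversion to R's 1-based indexing happens
# only inside the samplers below.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
gauss_kernel_1d <- function(sigma_px, trunc = 4) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, ceiling(trunc * sigma_px))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Convolve `arr` along one axis with an odd-length kernel, replicate padding at
# the edges. Uses stats::filter column-wise for C speed.
convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  r <- (length(kernel) - 1L) %/% 2L
  idx <- c(rep(1L, r), seq_len(n), rep(n, r))
  mp <- m[idx, , drop = FALSE]
  out <- stats::filter(mp, kernel, sides = 2)
  out <- matrix(as.numeric(out), nrow = n + 2L * r)[(r + 1L):(r + n), , drop = FALSE]
  res <- array(out, dim = d[perm])
  aperm(res, order(perm))
}

# Separable Gaussian blur; sigma_px is one value per axis (0 skips an axis).
gaussian_blur_nd <- function(arr, sigma_px, trunc = 4) {
  d <- dim(arr)
  stopifnot(length(sigma_px) == length(d))
  for (ax in seq_along(d)) {
    if (sigma_px[ax] > 0 && d[ax] > 1L) {
      arr <- convolve_axis(arr, gauss_kernel_1d(sigma_px[ax], trunc), ax)
    }
  }
  arr
}

# Trilinear interpolation of a (z, y, x) array at 0-based pixel-centered points
# (n x 3 matrix). Coordinates are clamped to the valid domain (edge extension).
interp_trilinear <- function(arr, pts) {
  d <- dim(arr)
  pts <- matrix(pts, ncol = 3)
  z <- clamp(pts[, 1], 0, d[1] - 1)
  y <- clamp(pts[, 2], 0, d[2] - 1)
  x <- clamp(pts[, 3], 0, d[3] - 1)
  z0 <- pmin(floor(z), d[1] - 1); z1 <- pmin(z0 + 1, d[1] - 1)
  y0 <- pmin(floor(y), d[2] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  x0 <- pmin(floor(x), d[3] - 1); x1 <- pmin(x0 + 1, d[3] - 1)
  fz <- z - z0; fy <- y - y0; fx <- x - x0
  ix <- function(zz, yy, xx) arr[cbind(zz + 1, yy + 1, xx + 1)]
  v000 <- ix(z0, y0, x0); v001 <- ix(z0, y0, x1)
  v010 <- ix(z0, y1, x0); v011 <- ix(z0, y1, x1)
  v100 <- ix(z1, y0, x0); v101 <- ix(z1, y0, x1)
  v110 <- ix(z1, y1, x0); v111 <- ix(z1, y1, x1)
  v00 <- v000 * (1 - fx) + v001 * fx
  v01 <- v010 * (1 - fx) + v011 * fx
  v10 <- v100 * (1 - fx) + v101 * fx
  v11 <- v110 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v01 * fy
  v1 <- v10 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}

# Bilinear interpolation of a (y, x) matrix at 0-based coordinates. Points
# outside the domain return `fill` (default: edge extension).
interp_bilinear <- function(mat, y, x, fill = NULL) {
  d <- dim(mat)
  outside <- y < 0 | y > d[1] - 1 | x < 0 | x > d[2] - 1
  yc <- clamp(y, 0, d[1] - 1)
  xc <- clamp(x, 0, d[2] - 1)
  y0 <- pmin(floor(yc), d[1] - 1); y1 <- pmin(y0 + 1, d[1] - 1)
  x0 <- pmin(floor(xc), d[2] - 1); x1 <- pmin(x0 + 1, d[2] - 1)
  fy <- yc - y0; fx <- xc - x0
  v00 <- mat[cbind(y0 + 1, x0 + 1)]; v01 <- mat[cbind(y0 + 1, x1 + 1)]
  v10 <- mat[cbind(y1 + 1, x0 + 1)]; v11 <- mat[cbind(y1 + 1, x1 + 1)]
  v <- (v00 * (1 - fx) + v01 * fx) * (1 - fy) + (v10 * (1 - fx) + v11 * fx) * fy
  if (!is.null(fill)) v[outside] <- fill
  v
}

# Integer frequency index per FFT bin (0, 1, ..., n/2, -(n/2-1), ..., -1).
fft_freq_index <- function(n) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

hann_window_2d <- function(ny, nx) {
  wy <- if (ny > 1) 0.5 * (1 - cos(2 * pi * (seq_len(ny) - 1) / (ny - 1))) else 1
  wx <- if (nx > 1) 0.5 * (1 - cos(2 * pi * (seq_len(nx) - 1) / (nx - 1))) else 1
  outer(wy, wx)
}

# Block-average downsample of a matrix by integer factor f (trims remainder).
block_average <- function(mat, f) {
  f <- as.integer(f)
  if (f == 1L) return(mat)
  ny <- (nrow(mat) %/% f) * f
  nx <- (ncol(mat) %/% f) * f
  m <- mat[seq_len(ny), seq_len(nx), drop = FALSE]
  a <- array(m, dim = c(f, ny %/% f, f, nx %/% f))
  apply(a, c(2, 4), mean)
}

# Distance from points to a 3D segment, plus the arclength parameter of the
# nearest point. All inputs in physical (nm) coordinates; pts is n x 3.
point_segment_distance <- function(pts, p0, p1) {
  v <- p1 - p0
  L2 <- sum(v^2)
  dp <- sweep(pts, 2, p0)
  t <- if (L2 > 0) clamp(as.vector(dp %*% v) / L2, 0, 1) else rep(0, nrow(pts))
  proj <- outer(t, v)
  dd <- dp - proj
  list(dist = sqrt(rowSums(dd^2)), t = t)
}

seeded <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
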