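#' Expansion factor from paired landmark distances
#'
#' For every pair of landmarks (all `C(n, 2)` combinations) the physical
#' distance is computed in the pre- and in the post-expansion image; the
#' expansion factor is the mean of the post/pre distance ratios, reported with
#' SD and a 95% t-interval.
#'
#' @param landmarks A [landmark_set].
#' @param pre_pixel_size_nm Physical pixel size `(z, y, x)` (or scalar) of the
#'   pre-expansion image, nm.
#' @param post_pixel_size_nm Same for the post-expansion image.
#' @return Object of class `expansion_estimate`: `factor`, `per_pair_ratios`,
#'   `sd`, `ci95`.
#' @export
estimate_expansion_factor <- function(landmarks, pre_pixel_size_nm,
                                      post_pixel_size_nm) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (length(pre_pixel_size_nm) == 1L) pre_pixel_size_nm <- rep(pre_pixel_size_nm, 3)
  if (length(post_pixel_size_nm) == 1L) post_pixel_size_nm <- rep(post_pixel_size_nm, 3)
  pre_nm <- sweep(landmarks$pre, 2, pre_pixel_size_nm, `*`)
  post_nm <- sweep(landmarks$post, 2, post_pixel_size_nm, `*`)
  n <- landmarks$n_pairs
  idx <- utils::combn(n, 2)
  dpre <- sqrt(rowSums((pre_nm[idx[1, ], , drop = FALSE] - pre_nm[idx[2, ], , drop = FALSE])^2))
  dpost <- sqrt(rowSums((post_nm[idx[1, ], , drop = FALSE] - post_nm[idx[2, ], , drop = FALSE])^2))
  if (any(dpre == 0)) stopf("coincident landmarks: zero pre-expansion distance")
  ratios <- dpost / dpre
  m <- mean(ratios)
  s <- stats::sd(ratios)
  ci <- if (length(ratios) > 1 && s > 0) {
    m + stats::qt(c(0.025, 0.975), df = length(ratios) - 1) * s / sqrt(length(ratios))
  } else c(m, m)
  structure(list(factor = m, per_pair_ratios = ratios, sd = s, ci95 = ci),
            class = "expansion_estimate")
}

#' @export
print.expansion_estimate <- function(x, ...) {
  cat(sprintf("<expansion_estimate> factor %.4g (SD %.3g, 95%% CI %.4g-%.4g, %d ratios)\n",
              x$factor, x$sd, x$ci95[1], x$ci95[2], length(x$per_pair_ratios)))
  invisible(x)
}

# Rotate a matrix by `angle_deg` (CCW) about its center, bilinear, zero fill.
rotate_plane <- function(mat, angle_deg) {
  if (angle_deg == 0) return(mat)
  ny <- nrow(mat); nx <- ncol(mat)
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  th <- angle_deg * pi / 180
  yy <- matrix(0:(ny - 1), ny, nx) - cy
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE) - cx
  ys <- cos(th) * yy + sin(th) * xx + cy
  xs <- -sin(th) * yy + cos(th) * xx + cx
  matrix(interp_bilinear(mat, as.vector(ys), as.vector(xs), fill = 0), ny, nx)
}

# Shift a matrix by subpixel (dy, dx): out(y, x) = mat(y - dy, x - dx).
shift_plane <- function(mat, dy, dx, fill = 0) {
  ny <- nrow(mat); nx <- ncol(mat)
  yy <- matrix(0:(ny - 1), ny, nx) - dy
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE) - dx
  matrix(interp_bilinear(mat, as.vector(yy), as.vector(xx), fill = fill), ny, nx)
}

ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

# Translation (dy, dx) of b relative to a by phase correlation with 3-point
# parabolic subpixel refinement. Positive shift means b(y - dy, x - dx) ~ a.
phase_correlation <- function(a, b) {
  fa <- stats::fft(a - mean(a))
  fb <- stats::fft(b - mean(b))
  cp <- fa * Conj(fb)
  mag <- Mod(cp)
  cp <- cp / pmax(mag, .Machine$double.eps)
  corr <- Re(stats::fft(cp, inverse = TRUE)) / length(a)
  pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  n <- dim(a)
  refine <- function(i, axis_n, get) {
    im <- ((i - 2) %% axis_n) + 1
    ip <- (i %% axis_n) + 1
    c0 <- get(i); cm <- get(im); cp_ <- get(ip)
    den <- cm - 2 * c0 + cp_
    if (den == 0) 0 else clamp(0.5 * (cm - cp_) / den, -0.5, 0.5)
  }
  dy <- refine(pk[1], n[1], function(i) corr[i, pk[2]])
  dx <- refine(pk[2], n[2], function(i) corr[pk[1], i])
  to_signed <- function(i, axis_n) {
    s <- i - 1
    if (s > axis_n / 2) s - axis_n else s
  }
  list(dy = -(to_signed(pk[1], n[1]) + dy),
       dx = -(to_signed(pk[2], n[2]) + dx),
       peak = max(corr))
}

#' Rigid registration of a pre-/post-expansion plane pair
#'
#' The post image is first rescaled into pre coordinates by `1/factor`
#' (bilinear), then a rotation grid (default +/-10 deg in 0.25 deg steps) is
#' searched; translation per angle comes from phase correlation with subpixel
#' refinement, and the transform maximizing the normalized cross-correlation
#' of the aligned pair wins.
#'
#' @param pre Numeric matrix (pre-expansion plane).
#' @param post Numeric matrix (post-expansion plane, `factor`-times finer).
#' @param factor Linear expansion factor relating the two.
#' @param rotation_range_deg,rotation_step_deg Search grid for the rotation.
#' @return List of class `rigid_transform`: `angle_deg`, `dy`, `dx` (pre-grid
#'   pixels), `correlation`, and `aligned` (post resampled onto the pre grid).
#' @export
register_rigid <- function(pre, post, factor,
                           rotation_range_deg = 10, rotation_step_deg = 0.25) {
  post_ds <- rescale_plane(post, 1 / factor, dim(pre))
  # scoring uses mildly prefiltered images and the central region, which
  # removes the bias toward angles whose resampling smooths the candidate
  pre_s <- gaussian_blur_nd(pre, c(0.75, 0.75))
  post_s <- gaussian_blur_nd(post_ds, c(0.75, 0.75))
  n <- dim(pre)
  cy <- max(1, n[1] %/% 8):(n[1] - max(1, n[1] %/% 8) + 1)
  cx <- max(1, n[2] %/% 8):(n[2] - max(1, n[2] %/% 8) + 1)
  angles <- seq(-rotation_range_deg, rotation_range_deg, by = rotation_step_deg)
  best <- list(correlation = -Inf)
  for (th in angles) {
    cand <- rotate_plane(post_s, th)
    pc <- phase_correlation(pre_s, cand)
    aligned <- shift_plane(cand, pc$dy, pc$dx)
    sc <- ncc(pre_s[cy, cx], aligned[cy, cx])
    if (sc > best$correlation) {
      best <- list(angle_deg = th, dy = pc$dy, dx = pc$dx, correlation = sc)
    }
  }
  if (best$correlation < 0.2) {
    stopf("registration-failure error: best correlation %.3f < 0.2", best$correlation)
  }
  best$aligned <- shift_plane(rotate_plane(post_ds, best$angle_deg), best$dy, best$dx)
  class(best) <- "rigid_transform"
  best
}

# Bilinear rescale of a plane by `scale`, into an output of dims `out_dim`
# (pixel-centered mapping). Block-averages first when downscaling by an
# integer factor, to avoid aliasing.
rescale_plane <- function(mat, scale, out_dim) {
  inv <- 1 / scale
  if (scale < 1 && abs(inv - round(inv)) < 1e-9) {
    m <- block_average(mat, round(inv))
    # pad/crop to out_dim
    out <- matrix(0, out_dim[1], out_dim[2])
    ry <- seq_len(min(nrow(m), out_dim[1]))
    rx <- seq_len(min(ncol(m), out_dim[2]))
    out[ry, rx] <- m[ry, rx]
    return(out)
  }
  yy <- matrix(0:(out_dim[1] - 1), out_dim[1], out_dim[2])
  xx <- matrix(0:(out_dim[2] - 1), out_dim[1], out_dim[2], byrow = TRUE)
  ys <- (yy + 0.5) * inv - 0.5
  xs <- (xx + 0.5) * inv - 0.5
  matrix(interp_bilinear(mat, as.vector(ys), as.vector(xs), fill = 0),
         out_dim[1], out_dim[2])
}

#' Non-rigid deformation field between aligned planes
#'
#' Estimates a smooth 2-D displacement field by multiresolution (2-level)
#' local normalized-cross-correlation block matching on a regular node grid,
#' with 3-point parabolic subpixel refinement and bilinear interpolation of
#' the node displacements to the full grid. Low-confidence nodes (NCC below
#' 0.3 or structureless windows) are filled from their neighbors. The field
#' maps pre-grid points to their matching post positions, in *biological* nm.
#'
#' @param pre_aligned,post_aligned Equal-sized matrices after rigid alignment
#'   (e.g. `register_rigid()$aligned`).
#' @param bio_pixel_nm Biological pixel size (nm) of the pre grid.
#' @param grid_spacing_px Node spacing (default 16 px).
#' @param block_half_px Half-size of the matching window (default 12 px).
#' @param search_px Integer search radius per level (default 5 px).
#' @return Object of class `deformation_field`: `dy_nm`, `dx_nm` (full-grid
#'   matrices), `mask` (where the match was direct), `bio_pixel_nm`.
#' @export
register_nonrigid <- function(pre_aligned, post_aligned, bio_pixel_nm,
                              grid_spacing_px = 16L, block_half_px = 12L,
                              search_px = 5L) {
  stopifnot(all(dim(pre_aligned) == dim(post_aligned)))
  levels <- list(
    list(f = 2L, img_a = block_average(pre_aligned, 2), img_b = block_average(post_aligned, 2)),
    list(f = 1L, img_a = pre_aligned, img_b = post_aligned)
  )
  init_dy <- NULL; init_dx <- NULL
  for (lv in levels) {
    f <- lv$f
    a <- lv$img_a; b <- lv$img_b
    sp <- max(4L, as.integer(round(grid_spacing_px / f)))
    hw <- max(3L, as.integer(round(block_half_px / f)))
    ny <- nrow(a); nx <- ncol(a)
    if (ny < 2 * hw + 2 || nx < 2 * hw + 2) stopf("images too small for the matching grid")
    gy <- unique(c(seq(hw + 1L, ny - hw, by = sp), ny - hw))
    gx <- unique(c(seq(hw + 1L, nx - hw, by = sp), nx - hw))
    dyg <- matrix(NA_real_, length(gy), length(gx))
    dxg <- matrix(NA_real_, length(gy), length(gx))
    okg <- matrix(FALSE, length(gy), length(gx))
    for (i in seq_along(gy)) {
      for (j in seq_along(gx)) {
        y0 <- gy[i]; x0 <- gx[j]
        init <- c(0, 0)
        if (!is.null(init_dy)) {
          init <- c(round(interp_bilinear(init_dy, (y0 - 1) / 1, (x0 - 1) / 1) / f),
                    round(interp_bilinear(init_dx, (y0 - 1) / 1, (x0 - 1) / 1) / f))
          init[!is.finite(init)] <- 0
        }
        win_a <- a[(y0 - hw):(y0 + hw), (x0 - hw):(x0 + hw)]
        if (stats::sd(win_a) == 0) next
        offs <- (-search_px):search_px
        scores <- matrix(-Inf, length(offs), length(offs))
        for (oi in seq_along(offs)) {
          for (oj in seq_along(offs)) {
            yy <- y0 + init[1] + offs[oi]
            xx <- x0 + init[2] + offs[oj]
            if (yy - hw < 1 || yy + hw > ny || xx - hw < 1 || xx + hw > nx) next
            win_b <- b[(yy - hw):(yy + hw), (xx - hw):(xx + hw)]
            scores[oi, oj] <- ncc(win_a, win_b)
          }
        }
        if (!any(is.finite(scores))) next
        pk <- which(scores == max(scores), arr.ind = TRUE)[1, ]
        if (scores[pk[1], pk[2]] < 0.3) next
        sub <- function(k, get) {
          if (k <= 1 || k >= length(offs)) return(0)
          c0 <- get(k); cm <- get(k - 1); cp <- get(k + 1)
          if (!is.finite(cm) || !is.finite(cp)) return(0)
          den <- cm - 2 * c0 + cp
          if (den == 0) 0 else clamp(0.5 * (cm - cp) / den, -0.5, 0.5)
        }
        ry <- sub(pk[1], function(k) scores[k, pk[2]])
        rx <- sub(pk[2], function(k) scores[pk[1], k])
        dyg[i, j] <- init[1] + offs[pk[1]] + ry
        dxg[i, j] <- init[2] + offs[pk[2]] + rx
        okg[i, j] <- TRUE
      }
    }
    if (!any(okg)) stopf("divergent optimization: no confident matches at level %d", f)
    dyg <- fill_nodes(dyg); dxg <- fill_nodes(dxg)
    # light smoothing of the node lattice regularizes the field
    dyg <- gaussian_blur_nd(dyg, c(0.7, 0.7))
    dxg <- gaussian_blur_nd(dxg, c(0.7, 0.7))
    full_dy <- nodes_to_grid(dyg, gy, gx, ny, nx)
    full_dx <- nodes_to_grid(dxg, gy, gx, ny, nx)
    if (f > 1L) {
      init_dy <- rescale_plane(full_dy * f, f, dim(pre_aligned))
      init_dx <- rescale_plane(full_dx * f, f, dim(pre_aligned))
    } else {
      # field is trusted only over the matched node hull (the registered
      # overlap); outside it the interpolation is constant extrapolation
      hull <- matrix(FALSE, ny, nx)
      hull[min(gy):max(gy), min(gx):max(gx)] <- TRUE
      conf <- nodes_to_grid((okg * 1), gy, gx, ny, nx) > 0.5
      return(structure(list(
        dy_nm = full_dy * bio_pixel_nm,
        dx_nm = full_dx * bio_pixel_nm,
        mask = hull & conf,
        bio_pixel_nm = bio_pixel_nm
      ), class = "deformation_field"))
    }
  }
}

# Replace NA nodes by the mean of available neighbors (iterative dilation).
fill_nodes <- function(m) {
  while (anyNA(m)) {
    nas <- which(is.na(m), arr.ind = TRUE)
    filled <- FALSE
    for (r in seq_len(nrow(nas))) {
      i <- nas[r, 1]; j <- nas[r, 2]
      ni <- max(1, i - 1):min(nrow(m), i + 1)
      nj <- max(1, j - 1):min(ncol(m), j + 1)
      nb <- m[ni, nj]
      if (any(!is.na(nb))) {
        m[i, j] <- mean(nb, na.rm = TRUE)
        filled <- TRUE
      }
    }
    if (!filled) { m[is.na(m)] <- 0; break }
  }
  m
}

# Bilinear interpolation of node values (at 1-based positions gy, gx) to the
# full pixel grid, constant extrapolation beyond the node hull.
nodes_to_grid <- function(nodes, gy, gx, ny, nx) {
  if (length(gy) == 1L && length(gx) == 1L) return(matrix(nodes[1, 1], ny, nx))
  ax <- function(g, n) {
    if (length(g) == 1L) rep(1, n)
    else clamp(stats::approx(g, seq_along(g), xout = seq_len(n), rule = 2)$y, 1, length(g))
  }
  yi <- ax(gy, ny)
  xi <- ax(gx, nx)
  yy <- matrix(yi - 1, ny, nx)
  xx <- matrix(xi - 1, ny, nx, byrow = TRUE)
  matrix(interp_bilinear(nodes, as.vector(yy), as.vector(xx)), ny, nx)
}

#' RMS length-measurement-error curve from a deformation field
#'
#' The isotropy statistic for expansion distortion: for each measurement
#' length `L`, point pairs at separation `L` are sampled inside the mask, each
#' pair's length error is the difference between the separation after adding
#' the local displacements and `L`, and the per-bin RMS (and SD) of those
#' unsigned errors is reported. A zero or spatially constant field gives zero
#' error at all lengths (shifts preserve distances); a uniform relative
#' misscaling `u(x) = eps * x` gives `rms(L) = eps * L` exactly.
#'
#' @param field A `deformation_field` (truth or estimated).
#' @param n_pairs_per_bin Pairs sampled per length bin (default 1000).
#' @param n_bins Number of log-spaced bins (default 10) from `min_length_um`
#'   to half the masked field extent.
#' @param min_length_um Shortest measurement length (default 1).
#' @param mask Optional logical matrix restricting sampling (default: field
#'   mask).
#' @param seed RNG seed (default 0).
#' @return Object of class `rms_curve`: `length_um`, `rms_um`, `sd_um`,
#'   `n_pairs` per bin (bins with no feasible pairs report `n_pairs = 0`).
#' @export
rms_error_curve <- function(field, n_pairs_per_bin = 1000L, n_bins = 10L,
                            min_length_um = 1, mask = NULL, seed = 0L) {
  stopifnot(inherits(field, "deformation_field"))
  mask <- mask %||% field$mask %||% matrix(TRUE, nrow(field$dy_nm), ncol(field$dy_nm))
  ny <- nrow(field$dy_nm); nx <- ncol(field$dy_nm)
  pix_nm <- field$bio_pixel_nm
  extent_um <- min(ny, nx) * pix_nm / 1000
  max_len <- extent_um / 2
  if (max_len <= min_length_um) {
    lengths_um <- max_len
  } else {
    lengths_um <- exp(seq(log(min_length_um), log(max_len), length.out = n_bins))
  }
  cand <- which(mask, arr.ind = TRUE)
  if (!nrow(cand)) stopf("mask contains no pixels")
  rms <- sd_ <- numeric(length(lengths_um))
  npair <- integer(length(lengths_um))
  seeded(seed, {
    for (bi in seq_along(lengths_um)) {
      L_px <- lengths_um[bi] * 1000 / pix_nm
      errs <- numeric(0)
      attempts <- 0
      while (length(errs) < n_pairs_per_bin && attempts < 20 * n_pairs_per_bin) {
        m <- n_pairs_per_bin
        attempts <- attempts + m
        pi_ <- cand[sample.int(nrow(cand), m, replace = TRUE), , drop = FALSE]
        th <- stats::runif(m, 0, 2 * pi)
        qy <- pi_[, 1] + L_px * sin(th)
        qx <- pi_[, 2] + L_px * cos(th)
        ok <- qy >= 1 & qy <= ny & qx >= 1 & qx <= nx
        ok[ok] <- mask[cbind(pmax(1, pmin(ny, round(qy[ok]))),
                             pmax(1, pmin(nx, round(qx[ok]))))]
        if (!any(ok)) next
        py <- pi_[ok, 1]; px_ <- pi_[ok, 2]; qy <- qy[ok]; qx <- qx[ok]
        uy_p <- interp_bilinear(field$dy_nm, py - 1, px_ - 1)
        ux_p <- interp_bilinear(field$dx_nm, py - 1, px_ - 1)
        uy_q <- interp_bilinear(field$dy_nm, qy - 1, qx - 1)
        ux_q <- interp_bilinear(field$dx_nm, qy - 1, qx - 1)
        dy_nm <- (qy - py) * pix_nm + uy_q - uy_p
        dx_nm <- (qx - px_) * pix_nm + ux_q - ux_p
        errs <- c(errs, abs(sqrt(dy_nm^2 + dx_nm^2) - lengths_um[bi] * 1000))
      }
      errs <- utils::head(errs, n_pairs_per_bin)
      if (length(errs)) {
        rms[bi] <- sqrt(mean((errs / 1000)^2))
        sd_[bi] <- stats::sd(errs / 1000)
        npair[bi] <- length(errs)
      } else {
        rms[bi] <- NA_real_; sd_[bi] <- NA_real_; npair[bi] <- 0L
      }
    }
  })
  structure(list(length_um = lengths_um, rms_um = rms, sd_um = sd_,
                 n_pairs = npair), class = "rms_curve")
}

#' Compose rigid and non-rigid transforms into one displacement field
#'
#' [register_rigid()] absorbs rotation and mean translation before
#' [register_nonrigid()] estimates the residual field; to compare against a
#' ground-truth deformation (or to report total distortion) the two must be
#' composed. For a pre-grid point `p`, the matched post position is
#' `R(p + u_nr(p) - t - c) + c` (rotation `R` about the image center `c`,
#' translation `t`, non-rigid displacement `u_nr`); the composed field is that
#' position minus `p`, in biological nm.
#'
#' @param rigid A `rigid_transform` from [register_rigid()].
#' @param field A `deformation_field` from [register_nonrigid()] computed on
#'   `rigid$aligned`.
#' @return A `deformation_field` holding the total pre-to-post displacement.
#' @export
compose_rigid_nonrigid <- function(rigid, field) {
  stopifnot(inherits(rigid, "rigid_transform"), inherits(field, "deformation_field"))
  ny <- nrow(field$dy_nm); nx <- ncol(field$dy_nm)
  pix <- field$bio_pixel_nm
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  th <- rigid$angle_deg * pi / 180
  py <- yy + field$dy_nm / pix - rigid$dy - cy
  px_ <- xx + field$dx_nm / pix - rigid$dx - cx
  dy <- (cos(th) * py + sin(th) * px_ + cy - yy) * pix
  dx <- (-sin(th) * py + cos(th) * px_ + cx - xx) * pix
  deformation_field(dy, dx, pix, mask = field$mask)
}

#' Build a deformation field object directly from displacement matrices
#'
#' Convenience constructor used for truth fields and analytic cases.
#'
#' @param dy_nm,dx_nm Displacement matrices in biological nm.
#' @param bio_pixel_nm Grid pixel size in biological nm.
#' @param mask Optional logical matrix.
#' @return A `deformation_field`.
#' @export
deformation_field <- function(dy_nm, dx_nm, bio_pixel_nm, mask = NULL) {
  stopifnot(all(dim(dy_nm) == dim(dx_nm)))
  if (any(!is.finite(dy_nm)) || any(!is.finite(dx_nm))) {
    stopf("deformation field must be finite everywhere")
  }
  structure(list(dy_nm = dy_nm, dx_nm = dx_nm,
                 mask = mask %||% matrix(TRUE, nrow(dy_nm), ncol(dy_nm)),
                 bio_pixel_nm = bio_pixel_nm),
            class = "deformation_field")
}
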