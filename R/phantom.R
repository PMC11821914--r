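#' Specification of a synthetic membrane phantom
#'
#' Describes tube-shaped membrane structures (axons, cilia: thin shells around
#' a lumen, 100-1500 nm diameter) rendered into a voxel grid, plus the imaging
#' model: anisotropic Gaussian PSF, photon (Poisson) noise, Gaussian read
#' noise, and constant background. The grid is defined in biological units;
#' the physical (expanded-sample) pixel size is `bio_pixel_nm *
#' expansion_factor`.
#'
#' @param shape_px Volume shape `(z, y, x)` in pixels.
#' @param bio_pixel_nm Biological pixel size in nm (scalar or `(z, y, x)`).
#' @param tubes List of tubes, each a list with `control_points_px` (`n x 3`
#'   matrix of `(z, y, x)` pixel coordinates), `radius_nm`, `shell_nm`
#'   (shell thickness), and optional `myelinated` flag (thicker/brighter
#'   shell: intensity doubled).
#' @param expansion_factor Linear expansion factor emulated (default 4).
#' @param fill_channel Render a lumen "fill" channel (anti-GFP-like) in
#'   addition to the membrane shell channel (default `TRUE`).
#' @param psf_fwhm_nm PSF full width at half maximum in *physical* nm,
#'   `c(lateral, axial)`; defaults to a confocal-like 250 nm lateral / 500 nm
#'   axial. Divided by the expansion factor these set the blur in biological
#'   units.
#' @param photon_scale Expected photons at unit geometry intensity (default
#'   200).
#' @param gauss_read_noise Read-noise SD in photon units (default 2).
#' @param background_level Mean background level in photon units (default 5).
#' @param seed Default RNG seed for operations on this phantom (default 0).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_px, bio_pixel_nm, tubes = list(),
                         expansion_factor = 4, fill_channel = TRUE,
                         psf_fwhm_nm = c(250, 500), photon_scale = 200,
                         gauss_read_noise = 2, background_level = 5,
                         seed = 0L) {
  stopifnot(length(shape_px) == 3L, all(shape_px >= 1))
  if (length(bio_pixel_nm) == 1L) bio_pixel_nm <- rep(bio_pixel_nm, 3)
  stopifnot(length(bio_pixel_nm) == 3L, all(bio_pixel_nm > 0))
  stopifnot(length(psf_fwhm_nm) == 2L, all(psf_fwhm_nm > 0))
  stopifnot(expansion_factor >= 1, photon_scale >= 0,
            gauss_read_noise >= 0, background_level >= 0)
  for (tb in tubes) {
    stopifnot(!is.null(tb$control_points_px), !is.null(tb$radius_nm), !is.null(tb$shell_nm))
    if (tb$radius_nm <= tb$shell_nm / 2) {
      stopf("tube radius (%g nm) must exceed half the shell thickness (%g nm)",
            tb$radius_nm, tb$shell_nm / 2)
    }
  }
  structure(list(
    shape_px = as.integer(shape_px),
    bio_pixel_nm = as.numeric(bio_pixel_nm),
    tubes = tubes,
    expansion_factor = expansion_factor,
    fill_channel = isTRUE(fill_channel),
    psf_fwhm_nm = as.numeric(psf_fwhm_nm),
    photon_scale = photon_scale,
    gauss_read_noise = gauss_read_noise,
    background_level = background_level,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# PSF sigma per axis (z, y, x) in *biological* nm.
psf_sigma_bio_nm <- function(spec) {
  s <- spec$psf_fwhm_nm / (2 * sqrt(2 * log(2))) / spec$expansion_factor
  c(s[2], s[1], s[1])
}

#' Render noiseless tube geometry with ground truth
#'
#' Rasterizes each tube's membrane as a thin shell (annulus in cross-section):
#' signed distance `d` to the centerline is computed per voxel and the shell is
#' `|d - r| <= shell/2`, antialiased by a linear falloff over one voxel. The
#' optional fill channel covers the lumen interior. Centerlines are stored as
#' ground-truth [membrane_path]s; per-voxel nearest-centerline arclengths are
#' kept so that [insert_gaps()] can carve gaps consistently in both the
#' geometry and the truth mask. Tubes extending beyond the volume are clipped
#' with a warning.
#'
#' @param spec A [phantom_spec].
#' @return Object of class `phantom_volume` with fields `geometry` (named list
#'   of noiseless channel arrays), `shell_mask`, `paths_truth`, `gaps_truth`,
#'   `shell_voxels`, and `spec`.
#' @export
make_tube_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape_px
  px <- spec$bio_pixel_nm
  membrane <- array(0, dim = d)
  fill <- if (spec$fill_channel) array(0, dim = d) else NULL
  shell_mask <- array(FALSE, dim = d)
  paths <- list()
  voxel_tabs <- list()
  h <- min(px[2], px[3])  # antialiasing falloff scale: one lateral voxel
  for (ti in seq_along(spec$tubes)) {
    tb <- spec$tubes[[ti]]
    cp <- matrix(as.numeric(tb$control_points_px), ncol = 3)
    r <- tb$radius_nm
    t2 <- tb$shell_nm / 2
    bright <- if (isTRUE(tb$myelinated)) 2 else 1
    path <- membrane_path(cp, px, source = sprintf("truth_tube_%d", ti))
    paths[[ti]] <- path
    cp_nm <- sweep(cp, 2, px, `*`)
    margin_nm <- r + t2 + 2 * h
    lo <- pmax(floor((apply(cp_nm, 2, min) - margin_nm) / px), 0)
    hi <- pmin(ceiling((apply(cp_nm, 2, max) + margin_nm) / px), d - 1)
    if (any(apply(cp, 2, min) < 0) || any(apply(cp, 2, max) > d - 1)) {
      warning(sprintf("tube %d extends beyond the volume; clipping", ti))
    }
    if (any(hi < lo)) next
    nz <- lo[1]:hi[1]; ny <- lo[2]:hi[2]; nx <- lo[3]:hi[3]
    nb <- length(nz) * length(ny) * length(nx)
    pts <- cbind(
      rep(nz, times = length(ny) * length(nx)) * px[1],
      rep(rep(ny, each = length(nz)), times = length(nx)) * px[2],
      rep(nx, each = length(nz) * length(ny)) * px[3]
    )
    best_d <- rep(Inf, nb)
    best_s <- rep(0, nb)
    cum <- path$arclength_nm
    for (si in seq_len(nrow(cp) - 1)) {
      ps <- point_segment_distance(pts, cp_nm[si, ], cp_nm[si + 1, ])
      upd <- ps$dist < best_d
      best_d[upd] <- ps$dist[upd]
      best_s[upd] <- cum[si] + ps$t[upd] * (cum[si + 1] - cum[si])
    }
    w_shell <- clamp((t2 + h - abs(best_d - r)) / h, 0, 1) * bright
    w_fill <- clamp((r - t2 - best_d) / h + 1, 0, 1)
    hard <- abs(best_d - r) <= t2
    # linear indices of the box voxels in the full array
    iz <- rep(nz, times = length(ny) * length(nx))
    iy <- rep(rep(ny, each = length(nz)), times = length(nx))
    ix <- rep(nx, each = length(nz) * length(ny))
    lin <- 1 + iz + d[1] * (iy + d[2] * ix)
    sel <- w_shell > 0
    membrane[lin[sel]] <- pmax(membrane[lin[sel]], w_shell[sel])
    if (!is.null(fill)) {
      self <- w_fill > 0
      fill[lin[self]] <- pmax(fill[lin[self]], w_fill[self])
    }
    shell_mask[lin[hard]] <- TRUE
    keep <- w_shell > 0 | hard
    voxel_tabs[[ti]] <- data.frame(idx = lin[keep], tube = ti,
                                   s_nm = best_s[keep], hard = hard[keep])
  }
  geometry <- list(membrane = membrane)
  if (!is.null(fill)) geometry$fill <- fill
  structure(list(
    geometry = geometry,
    shell_mask = shell_mask,
    paths_truth = paths,
    gaps_truth = rep(list(matrix(numeric(0), ncol = 2,
                                 dimnames = list(NULL, c("start_nm", "end_nm")))),
                     length(paths)),
    shell_voxels = if (length(voxel_tabs)) do.call(rbind, voxel_tabs) else
      data.frame(idx = integer(0), tube = integer(0), s_nm = numeric(0),
                 hard = logical(0)),
    spec = spec
  ), class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  d <- x$spec$shape_px
  cat(sprintf("<phantom_volume> %d x %d x %d px, %d tube(s), %d gap interval(s)\n",
              d[1], d[2], d[3], length(x$paths_truth),
              sum(vapply(x$gaps_truth, nrow, integer(1)))))
  invisible(x)
}

#' Carve labeling gaps of known total fraction into a phantom
#'
#' Removes shell voxels along randomly placed, non-overlapping arclength
#' intervals on each truth path so that the removed fraction of each path's
#' length equals `gap_fraction` (up to one interval quantum: the final
#' interval is trimmed to hit the target exactly when the remainder is at
#' least `min_gap_len_nm`, otherwise it overshoots by less than one minimum
#' length). Interval lengths are drawn uniformly in
#' `[min_gap_len_nm, 3 * min_gap_len_nm]`.
#'
#' @param phantom A `phantom_volume` from [make_tube_phantom()].
#' @param gap_fraction Target gap fraction `g` in `[0, 1)` of each path.
#' @param min_gap_len_nm Minimum gap length in biological nm.
#' @param seed RNG seed (default: the phantom spec's seed).
#' @return The modified `phantom_volume` (geometry, shell mask and
#'   `gaps_truth` updated).
#' @export
insert_gaps <- function(phantom, gap_fraction, min_gap_len_nm, seed = NULL) {
  stopifnot(inherits(phantom, "phantom_volume"))
  if (gap_fraction < 0 || gap_fraction >= 1) {
    stopf("parameter error: gap_fraction must be in [0, 1), got %g", gap_fraction)
  }
  if (gap_fraction == 0) return(phantom)
  stopifnot(min_gap_len_nm > 0)
  seed <- seed %||% phantom$spec$seed
  seeded(seed, {
    for (pi in seq_along(phantom$paths_truth)) {
      L <- path_length_nm(phantom$paths_truth[[pi]])
      target <- gap_fraction * L
      if (min_gap_len_nm > L) {
        stopf("parameter error: min_gap_len_nm (%g) exceeds path length (%g nm)",
              min_gap_len_nm, L)
      }
      intervals <- matrix(numeric(0), ncol = 2)
      total <- 0
      tries <- 0
      while (total < target) {
        len <- stats::runif(1, min_gap_len_nm, 3 * min_gap_len_nm)
        remainder <- target - total
        if (remainder < min_gap_len_nm) len <- min_gap_len_nm
        else if (remainder < len) len <- remainder
        if (len > L) len <- L * 0.9
        start <- stats::runif(1, 0, L - len)
        overlaps <- nrow(intervals) > 0 &&
          any(start < intervals[, 2] + min_gap_len_nm &
              start + len > intervals[, 1] - min_gap_len_nm)
        tries <- tries + 1
        if (tries > 2000) {
          stopf("parameter error: cannot place gap fraction %g with min length %g nm on a %g nm path",
                gap_fraction, min_gap_len_nm, L)
        }
        if (overlaps) next
        intervals <- rbind(intervals, c(start, start + len))
        total <- total + len
      }
      intervals <- intervals[order(intervals[, 1]), , drop = FALSE]
      colnames(intervals) <- c("start_nm", "end_nm")
      phantom$gaps_truth[[pi]] <- intervals
      vox <- phantom$shell_voxels
      vsel <- vox$tube == pi
      if (any(vsel)) {
        s <- vox$s_nm[vsel]
        ingap <- rep(FALSE, length(s))
        for (gi in seq_len(nrow(intervals))) {
          ingap <- ingap | (s >= intervals[gi, 1] & s <= intervals[gi, 2])
        }
        idx <- vox$idx[vsel][ingap]
        phantom$geometry$membrane[idx] <- 0
        phantom$shell_mask[idx] <- FALSE
      }
    }
  })
  phantom
}

#' Render a phantom into noisy image stack(s)
#'
#' The noiseless geometry is convolved with the separable anisotropic Gaussian
#' PSF, scaled to expected photons, Poisson sampled, and Gaussian read noise
#' plus the constant background are added (negative values clipped at 0). With
#' `n_realizations = 2`, the identical blurred signal receives two independent
#' noise draws — the acquisition scheme used for FRC resolution analysis.
#'
#' @param phantom A `phantom_volume`.
#' @param n_realizations 1 or 2.
#' @param seed RNG seed (default: spec seed).
#' @return An [image_stack], or a list of two for `n_realizations = 2`.
#' @export
render_image <- function(phantom, n_realizations = 1, seed = NULL) {
  stopifnot(inherits(phantom, "phantom_volume"), n_realizations %in% c(1, 2))
  spec <- phantom$spec
  seed <- seed %||% spec$seed
  sigma_px <- psf_sigma_bio_nm(spec) / spec$bio_pixel_nm
  blurred <- lapply(phantom$geometry, gaussian_blur_nd, sigma_px = sigma_px)
  one <- function() {
    chans <- lapply(blurred, function(b) {
      lambda <- spec$photon_scale * b + spec$background_level
      img <- stats::rpois(length(lambda), lambda) +
        stats::rnorm(length(lambda), 0, spec$gauss_read_noise)
      img[img < 0] <- 0
      array(img, dim = dim(b))
    })
    image_stack(chans, pixel_size_nm = spec$bio_pixel_nm * spec$expansion_factor,
                expansion_factor = spec$expansion_factor)
  }
  seeded(seed, {
    if (n_realizations == 1) one() else list(one(), one())
  })
}

#' Render a blinking-fluorophore time series from a phantom
#'
#' Each geometry voxel acts as an independent two-state emitter: per frame it
#' is on with probability `blink_on_prob`, and frames are rendered with the
#' same PSF/noise model as [render_image()]. The phantom must be a single
#' z-plane (fluctuation imaging is 2-D here).
#'
#' @param phantom A `phantom_volume` with `shape_px[1] == 1`.
#' @param n_frames Number of frames, `>= 2` (20 is the typical acquisition).
#' @param blink_on_prob On-probability per frame, in `(0, 1]`.
#' @param seed RNG seed (default: spec seed).
#' @param channel Geometry channel rendered (default `"membrane"`).
#' @return An [image_stack] with axes `"tyx"`.
#' @export
make_fluctuation_series <- function(phantom, n_frames, blink_on_prob,
                                    seed = NULL, channel = "membrane") {
  stopifnot(inherits(phantom, "phantom_volume"), n_frames >= 2)
  if (blink_on_prob <= 0 || blink_on_prob > 1) {
    stopf("parameter error: blink_on_prob must be in (0, 1], got %g", blink_on_prob)
  }
  spec <- phantom$spec
  if (spec$shape_px[1] != 1L) stopf("fluctuation series require a single-z phantom")
  seed <- seed %||% spec$seed
  geom <- phantom$geometry[[channel]][1, , ]
  emitters <- which(geom > 0)
  sigma_px <- (psf_sigma_bio_nm(spec) / spec$bio_pixel_nm)[2:3]
  frames <- array(0, dim = c(n_frames, dim(geom)))
  seeded(seed, {
    for (f in seq_len(n_frames)) {
      g <- geom
      if (length(emitters)) {
        on <- stats::runif(length(emitters)) <= blink_on_prob
        g[emitters[!on]] <- 0
      }
      b <- gaussian_blur_nd(g, sigma_px)
      lambda <- spec$photon_scale * b + spec$background_level
      img <- stats::rpois(length(lambda), lambda) +
        stats::rnorm(length(lambda), 0, spec$gauss_read_noise)
      img[img < 0] <- 0
      frames[f, , ] <- img
    }
  })
  image_stack(list(membrane = frames),
              pixel_size_nm = spec$bio_pixel_nm * spec$expansion_factor,
              expansion_factor = spec$expansion_factor, axes = "tyx")
}

# Band-limited random 2-D displacement field with exact RMS magnitude amp_nm.
random_smooth_field <- function(ny, nx, scale_px, amp_nm) {
  comp <- function() gaussian_blur_nd(matrix(stats::rnorm(ny * nx), ny, nx),
                                      c(scale_px, scale_px))
  dy <- comp(); dx <- comp()
  rms <- sqrt(mean(dy^2 + dx^2))
  if (rms == 0 || amp_nm == 0) return(list(dy = dy * 0, dx = dx * 0))
  list(dy = dy * amp_nm / rms, dx = dx * amp_nm / rms)
}

#' Simulate a pre-/post-expansion image pair with known distortion
#'
#' The phantom's (noiseless, PSF-blurred) membrane geometry is projected to a
#' 2-D plane; bright bead-like puncta are added as landmarks. The
#' post-expansion image lives on the fine grid and is warped by a smooth
#' band-limited random displacement field with exact RMS magnitude
#' `deformation_amp_nm` (biological nm); the pre-expansion image is the
#' block-average downsampling of the unwarped fine image by the (integer)
#' expansion factor. Landmark truth gives matched puncta coordinates in each
#' image's own pixel units.
#'
#' @param phantom A `phantom_volume`.
#' @param expansion_factor Integer linear factor `>= 1` (default: spec value).
#' @param deformation_amp_nm RMS displacement magnitude in biological nm.
#' @param deformation_scale_px Correlation length of the field in fine-grid
#'   pixels (default 24).
#' @param n_landmarks Number of bead puncta (default 6).
#' @param seed RNG seed (default: spec seed).
#' @return List with `pre` and `post` [image_stack]s, `landmarks`
#'   ([landmark_set]), and `deformation_truth` (list of `dy`/`dx` matrices in
#'   biological nm on the post grid).
#' @export
make_distorted_pair <- function(phantom, expansion_factor = NULL,
                                deformation_amp_nm = 0,
                                deformation_scale_px = 24,
                                n_landmarks = 6, seed = NULL) {
  stopifnot(inherits(phantom, "phantom_volume"), deformation_amp_nm >= 0)
  spec <- phantom$spec
  factor <- expansion_factor %||% spec$expansion_factor
  if (factor < 1 || factor != round(factor)) {
    stopf("expansion_factor must be a positive integer for the simulated pair")
  }
  factor <- as.integer(factor)
  seed <- seed %||% spec$seed
  bio_px <- spec$bio_pixel_nm[2:3]
  sigma_px <- (psf_sigma_bio_nm(spec) / spec$bio_pixel_nm)[2:3]
  geom <- apply(phantom$geometry$membrane, c(2, 3), max)
  ny <- nrow(geom); nx <- ncol(geom)
  seeded(seed, {
    lm_y <- stats::runif(n_landmarks, 0.15 * ny, 0.85 * ny)
    lm_x <- stats::runif(n_landmarks, 0.15 * nx, 0.85 * nx)
    amp <- max(geom, 1)
    yy <- matrix(0:(ny - 1), ny, nx)
    xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
    for (i in seq_len(n_landmarks)) {
      geom <- geom + 2 * amp * exp(-((yy - lm_y[i])^2 + (xx - lm_x[i])^2) / (2 * 2^2))
    }
    fine <- gaussian_blur_nd(geom, sigma_px)
    field <- random_smooth_field(ny, nx, deformation_scale_px, deformation_amp_nm)
    uy_px <- field$dy / bio_px[1]
    ux_px <- field$dx / bio_px[2]
    post_img <- interp_bilinear(fine, as.vector(yy - uy_px), as.vector(xx - ux_px))
    post_img <- matrix(post_img, ny, nx)
    pre_img <- block_average(fine, factor)
    # landmark positions: forward-displaced on the post grid, scaled on pre
    lm_uy <- interp_bilinear(uy_px, lm_y, lm_x)
    lm_ux <- interp_bilinear(ux_px, lm_y, lm_x)
    post_lm <- cbind(0, lm_y + lm_uy, lm_x + lm_ux)
    pre_lm <- cbind(0, (lm_y + 0.5) / factor - 0.5, (lm_x + 0.5) / factor - 0.5)
    phys_px <- bio_px * factor  # same physical pixel pitch pre and post
    pre_stack <- image_stack(list(membrane = pre_img),
                             pixel_size_nm = c(spec$bio_pixel_nm[1] * factor, phys_px),
                             expansion_factor = 1)
    post_stack <- image_stack(list(membrane = post_img),
                              pixel_size_nm = c(spec$bio_pixel_nm[1] * factor, phys_px),
                              expansion_factor = factor)
    list(pre = pre_stack, post = post_stack,
         landmarks = landmark_set(pre_lm, post_lm),
         deformation_truth = field)
  })
}
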