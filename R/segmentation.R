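#' Rand score between two segmentations
#'
#' Pair-counting Rand index over voxel pairs, computed from label-contingency
#' sums (never enumerating pairs): the fraction of voxel pairs on which the
#' two labelings agree (same label in both, or different in both). A score of
#' 1 means the two labelings induce identical partitions of the evaluated
#' voxel set; 0 means no similarity. With `foreground_restricted = TRUE`
#' (the default use when `seg_b` is the designated ground truth) only voxels
#' labeled foreground (`> 0`) in `seg_b` are evaluated. The adapted-Rand
#' F-score used in connectomics is available as `variant = "adapted"`.
#'
#' @param seg_a,seg_b Integer label arrays of equal shape (0 = background).
#' @param foreground_restricted Restrict evaluation to `seg_b > 0`.
#' @param variant `"plain"` (pair-counting Rand index) or `"adapted"`
#'   (adapted-Rand F-score).
#' @return Object of class `rand_result`: `score`, `variant`, `pair_counts`
#'   (agree_same, agree_diff, disagree), `restricted_to_foreground`.
#' @export
rand_score <- function(seg_a, seg_b, foreground_restricted = FALSE,
                       variant = c("plain", "adapted")) {
  variant <- match.arg(variant)
  a <- as.integer(seg_a)
  b <- as.integer(seg_b)
  if (length(a) != length(b)) stopf("shape mismatch: %d vs %d voxels", length(a), length(b))
  if (any(a < 0) || any(b < 0)) stopf("labels must be non-negative integers")
  if (foreground_restricted) {
    keep <- b > 0
    a <- a[keep]
    b <- b[keep]
  }
  n <- length(a)
  if (n == 0) stopf("empty evaluated voxel set")
  fa <- factor(a); fb <- factor(b)
  ia <- as.integer(fa); ib <- as.integer(fb)
  nb <- nlevels(fb)
  code <- (ia - 1L) * nb + ib
  nij <- tabulate(code, nbins = nlevels(fa) * nb)
  nij <- nij[nij > 0]
  ai <- tabulate(ia)
  bj <- tabulate(ib)
  c2 <- function(x) sum(x * (x - 1)) / 2
  total <- n * (n - 1) / 2
  same_same <- c2(nij)                       # same label in both
  same_a <- c2(ai); same_b <- c2(bj)
  agree_diff <- total - same_a - same_b + same_same
  disagree <- total - same_same - agree_diff
  score <- if (variant == "plain") {
    if (total == 0) 1 else (same_same + agree_diff) / total
  } else {
    # adapted-Rand F-score: harmonic mean of pair precision and recall
    s2 <- sum(nij^2)
    sa <- sum(ai^2); sb <- sum(bj^2)
    if (sa + sb == 0) 1 else 2 * s2 / (sa + sb)
  }
  structure(list(
    score = score,
    variant = variant,
    pair_counts = c(agree_same = same_same, agree_diff = agree_diff,
                    disagree = disagree, total = total),
    restricted_to_foreground = foreground_restricted,
    n_voxels = n
  ), class = "rand_result")
}

#' @export
print.rand_result <- function(x, ...) {
  cat(sprintf("<rand_result> %s Rand score %.4f over %d voxels%s\n",
              x$variant, x$score, x$n_voxels,
              if (x$restricted_to_foreground) " (foreground-restricted)" else ""))
  invisible(x)
}

#' Rasterize centroid tracings into a label volume
#'
#' Each trace is drawn as a tube of the given brush radius around its
#' polyline (the annotation style used for axon tracing: centroid annotation
#' with a fixed brush size), one label per trace, so that two tracings can be
#' compared with [rand_score()]. Where traces overlap, the later label wins
#' and the overlap fraction is reported.
#'
#' @param traces List of [membrane_path]s (pixel coordinates).
#' @param shape Output volume shape `(z, y, x)`.
#' @param brush_radius_px Tube radius in pixels (default 4, i.e. brush size 8).
#' @return List of class `label_volume`: `labels` (integer array),
#'   `overlap_fraction`.
#' @export
trace_to_labels <- function(traces, shape, brush_radius_px = 4) {
  if (inherits(traces, "membrane_path")) traces <- list(traces)
  labels <- array(0L, dim = shape)
  painted <- array(0L, dim = shape)
  r <- brush_radius_px
  for (ti in seq_along(traces)) {
    cp <- traces[[ti]]$points
    margin <- ceiling(r) + 1
    lo <- pmax(floor(apply(cp, 2, min)) - margin, 0)
    hi <- pmin(ceiling(apply(cp, 2, max)) + margin, shape - 1)
    if (any(hi < lo)) next
    nz <- lo[1]:hi[1]; ny <- lo[2]:hi[2]; nx <- lo[3]:hi[3]
    pts <- cbind(
      rep(nz, times = length(ny) * length(nx)),
      rep(rep(ny, each = length(nz)), times = length(nx)),
      rep(nx, each = length(nz) * length(ny))
    )
    best <- rep(Inf, nrow(pts))
    for (si in seq_len(nrow(cp) - 1)) {
      ps <- point_segment_distance(pts, cp[si, ], cp[si + 1, ])
      best <- pmin(best, ps$dist)
    }
    sel <- best <= r
    iz <- pts[sel, 1]; iy <- pts[sel, 2]; ix <- pts[sel, 3]
    lin <- 1 + iz + shape[1] * (iy + shape[2] * ix)
    labels[lin] <- ti
    painted[lin] <- painted[lin] + 1L
  }
  total_painted <- sum(painted > 0)
  overlap <- if (total_painted) sum(painted > 1) / total_painted else 0
  structure(list(labels = labels, overlap_fraction = overlap),
            class = "label_volume")
}

#' Fraction of reference-positive pixels that are probe-positive
#'
#' Thresholds the probe channel (Otsu by default, or a fixed intensity
#' percentile) and returns `|reference AND probe+| / |reference|` — the
#' colocalization statistic asking how much of a reference marker's footprint
#' carries probe signal.
#'
#' @param reference_mask Logical/0-1 array marking reference-indicator pixels.
#' @param probe Numeric array (probe channel) of the same shape, or an
#'   [image_stack].
#' @param threshold_method `"otsu"` or a number in (0, 100): the percentile of
#'   probe intensities used as the cutoff.
#' @param channel Channel for `image_stack` probes.
#' @return List of class `coloc_result`: `fraction`, `threshold`, `method`.
#' @export
colocalization_fraction <- function(reference_mask, probe,
                                    threshold_method = "otsu", channel = 1L) {
  if (inherits(probe, "image_stack")) probe <- get_channel(probe, channel)
  if (!is.null(dim(reference_mask)) && !is.null(dim(probe)) &&
      !identical(dim(reference_mask), dim(probe))) {
    stopf("shape mismatch between reference mask and probe image")
  }
  if (length(reference_mask) != length(probe)) stopf("shape mismatch")
  reference_mask <- reference_mask > 0
  n_ref <- sum(reference_mask)
  if (n_ref == 0) stopf("empty reference mask")
  if (identical(threshold_method, "otsu")) {
    rng <- range(probe)
    if (rng[1] == rng[2]) {
      thr <- rng[1]  # degenerate constant probe: everything at the value is positive
    } else {
      norm <- (probe - rng[1]) / (rng[2] - rng[1])
      t01 <- EBImage::otsu(EBImage::Image(as.numeric(norm), dim = c(length(norm), 1)),
                           range = c(0, 1))
      thr <- rng[1] + t01 * (rng[2] - rng[1])
    }
    method <- "otsu"
  } else if (is.numeric(threshold_method) && threshold_method > 0 && threshold_method < 100) {
    thr <- stats::quantile(probe, threshold_method / 100)
    method <- sprintf("percentile_%g", threshold_method)
  } else {
    stopf("threshold_method must be 'otsu' or a percentile in (0, 100)")
  }
  positive <- probe >= thr
  structure(list(
    fraction = sum(reference_mask & positive) / n_ref,
    threshold = as.numeric(thr),
    method = method
  ), class = "coloc_result")
}
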