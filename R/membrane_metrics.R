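#' Sample image intensity along a traced membrane path
#'
#' Trilinear interpolation of one channel at uniform arclength steps along the
#' path; the mean and SD over the path's samples (the reference statistics for
#' gap detection) are stored with the profile.
#'
#' @param stack An [image_stack].
#' @param path A [membrane_path] (within image bounds).
#' @param channel Channel name or index.
#' @param sampling_step_nm Arclength step in biological nm; default half the
#'   smallest lateral biological pixel.
#' @return Object of class `intensity_profile`: `arclength_nm`, `intensity`,
#'   `mean`, `sd`, `step_nm`, `path_length_nm`.
#' @export
sample_path_intensity <- function(stack, path, channel = 1L,
                                  sampling_step_nm = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(path, "membrane_path"))
  arr <- get_channel(stack, channel)
  d <- dim(arr)
  outb <- path$points[, 1] < 0 | path$points[, 1] > d[1] - 1 |
    path$points[, 2] < 0 | path$points[, 2] > d[2] - 1 |
    path$points[, 3] < 0 | path$points[, 3] > d[3] - 1
  if (any(outb)) {
    v <- which(outb)[1]
    stopf("path vertex %d at (%.1f, %.1f, %.1f) lies outside the image bounds",
          v, path$points[v, 1], path$points[v, 2], path$points[v, 3])
  }
  bp <- bio_pixel_size(stack)
  step <- sampling_step_nm %||% (min(bp[2], bp[3]) / 2)
  L <- path_length_nm(path)
  s <- seq(0, L, by = step)
  if (s[length(s)] < L - 1e-9 && (L - s[length(s)]) > step / 2) s <- c(s, L)
  pts <- path_point_at(path, s)
  vals <- interp_trilinear(arr, pts)
  structure(list(
    arclength_nm = s,
    intensity = vals,
    mean = mean(vals),
    sd = stats::sd(vals),
    step_nm = step,
    path_length_nm = L,
    source = path$source
  ), class = "intensity_profile")
}

#' Detect labeling gaps along an intensity profile
#'
#' A gap is a maximal run of consecutive samples whose intensity falls below
#' `mean - k_sd * SD` of the profile (statistics computed along the same
#' traced path) whose arclength extent — first to last sub-threshold sample
#' plus one sampling step — exceeds `min_gap_len_nm`. The default minimum (60
#' nm, biological) ties the gap definition to the effective image resolution;
#' callers should pass their own measured resolution.
#'
#' @param profile An `intensity_profile` from [sample_path_intensity()].
#' @param k_sd Threshold multiplier (default 2).
#' @param min_gap_len_nm Minimum gap extent in biological nm (default 60).
#' @return Object of class `gap_set`: `gaps` (matrix of start/end nm),
#'   `n_gaps`, `total_gap_nm`, `threshold`, `degenerate_sd` flag.
#' @export
detect_gaps <- function(profile, k_sd = 2, min_gap_len_nm = 60) {
  stopifnot(inherits(profile, "intensity_profile"))
  stopifnot(k_sd > 0, min_gap_len_nm > 0)
  if (length(profile$intensity) < 2) stopf("profile needs >= 2 samples")
  empty <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start_nm", "end_nm")))
  if (!is.finite(profile$sd) || profile$sd == 0) {
    return(structure(list(gaps = empty, n_gaps = 0L, total_gap_nm = 0,
                          threshold = NA_real_, degenerate_sd = TRUE),
                     class = "gap_set"))
  }
  thr <- profile$mean - k_sd * profile$sd
  below <- profile$intensity < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  gaps <- empty
  step <- profile$step_nm
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    s0 <- profile$arclength_nm[starts[i]]
    s1 <- profile$arclength_nm[ends[i]]
    extent <- (s1 - s0) + step
    if (extent > min_gap_len_nm) gaps <- rbind(gaps, c(s0, s1 + step))
  }
  colnames(gaps) <- c("start_nm", "end_nm")
  structure(list(
    gaps = gaps,
    n_gaps = nrow(gaps),
    total_gap_nm = if (nrow(gaps)) sum(gaps[, 2] - gaps[, 1]) else 0,
    threshold = thr,
    degenerate_sd = FALSE
  ), class = "gap_set")
}

#' Percent continuity of the membrane label along a path
#'
#' `100 * (1 - total gap arclength / path arclength)`: the percentage of the
#' traced length lying outside detected gaps.
#'
#' @param profile The `intensity_profile` the gaps were detected on.
#' @param gaps A `gap_set` from [detect_gaps()].
#' @return Object of class `continuity_result`: `percent_continuity`,
#'   `n_gaps`, `total_gap_nm`, `path_length_nm`, `gaps`.
#' @export
percent_continuity <- function(profile, gaps) {
  stopifnot(inherits(profile, "intensity_profile"), inherits(gaps, "gap_set"))
  L <- profile$path_length_nm
  total <- min(gaps$total_gap_nm, L)
  structure(list(
    percent_continuity = 100 * (1 - total / L),
    n_gaps = gaps$n_gaps,
    total_gap_nm = total,
    path_length_nm = L,
    gaps = gaps$gaps
  ), class = "continuity_result")
}

#' @export
print.continuity_result <- function(x, ...) {
  cat(sprintf("<continuity_result> %.2f%% continuous (%d gap(s), %.0f of %.0f nm)\n",
              x$percent_continuity, x$n_gaps, x$total_gap_nm, x$path_length_nm))
  invisible(x)
}

#' Transverse intensity profile across a tubular structure
#'
#' Samples an oriented box on a regular sub-pixel grid (bilinear), averages
#' down the box's long axis, and normalizes the averaged profile to its peak —
#' the standard presentation for membrane cross-sections (twin wall peaks for
#' a tube).
#'
#' @param stack An [image_stack].
#' @param center `(y, x)` box center in pixels (0-based).
#' @param angle_deg Direction of the box's long axis, degrees CCW from +x.
#' @param length_nm,width_nm Box dimensions in biological nm (length along the
#'   structure, width across it).
#' @param plane 1-based z-plane index.
#' @param channel Channel name or index.
#' @param step_nm Sampling step (default half the lateral biological pixel).
#' @return Object of class `transverse_profile`: `offset_nm` (across-axis,
#'   centered on 0), `intensity` (averaged), `normalized` (peak = 1),
#'   `degenerate` flag.
#' @export
transverse_profile <- function(stack, center, angle_deg, length_nm, width_nm,
                               plane = 1L, channel = 1L, step_nm = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (length_nm <= 0 || width_nm <= 0) stopf("degenerate box: length and width must be > 0")
  img <- get_plane(stack, plane, channel)
  bp <- bio_pixel_size(stack)
  pix <- c(bp[2], bp[3])
  step <- step_nm %||% (min(pix) / 2)
  th <- angle_deg * pi / 180
  ulong <- c(sin(th), cos(th))   # (y, x) unit vector along the long axis
  uperp <- c(cos(th), -sin(th))  # across the structure
  l_off <- seq(-length_nm / 2, length_nm / 2, by = step)
  w_off <- seq(-width_nm / 2, width_nm / 2, by = step)
  ys <- center[1] + outer(l_off * ulong[1], w_off * uperp[1], `+`) / pix[1]
  xs <- center[2] + outer(l_off * ulong[2], w_off * uperp[2], `+`) / pix[2]
  d <- dim(img)
  if (min(ys) < 0 || max(ys) > d[1] - 1 || min(xs) < 0 || max(xs) > d[2] - 1) {
    stopf("box extends outside the image bounds")
  }
  grid <- matrix(interp_bilinear(img, as.vector(ys), as.vector(xs)),
                 length(l_off), length(w_off))
  prof <- colMeans(grid)
  rng <- max(prof) - min(prof)
  degenerate <- rng == 0
  normalized <- if (degenerate) rep(1, length(prof)) else prof / max(prof)
  structure(list(
    offset_nm = w_off,
    intensity = prof,
    normalized = normalized,
    degenerate = degenerate
  ), class = "transverse_profile")
}

#' Tube diameter from a twin-peaked transverse profile
#'
#' The diameter is the distance between the two membrane-wall peaks, each
#' refined by a 3-point parabolic sub-sample fit. The profile must show two
#' local maxima separated by a local minimum; single-peaked profiles (walls
#' unresolved at the image resolution) are an error.
#'
#' @param profile A `transverse_profile`.
#' @return List of class `diameter_result`: `diameter_nm`, `peak_offsets_nm`.
#' @export
diameter_from_profile <- function(profile) {
  stopifnot(inherits(profile, "transverse_profile"))
  if (isTRUE(profile$degenerate)) {
    stopf("unresolved-walls error: flat profile")
  }
  v <- profile$intensity
  n <- length(v)
  if (n < 5) stopf("profile too short for peak detection")
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2) {
    stopf("unresolved-walls error: fewer than two wall peaks (structure thinner than the resolution)")
  }
  # the two highest peaks, required to bracket a local minimum
  ord <- peaks[order(v[peaks], decreasing = TRUE)]
  p1 <- ord[1]
  p2 <- ord[which(abs(ord - p1) > 1)[1]]
  if (is.na(p2)) stopf("unresolved-walls error: wall peaks not separated")
  lo <- min(p1, p2); hi <- max(p1, p2)
  if (min(v[lo:hi]) >= min(v[lo], v[hi])) {
    stopf("unresolved-walls error: no valley between candidate wall peaks")
  }
  refine <- function(k) {
    if (k <= 1 || k >= n) return(profile$offset_nm[k])
    den <- v[k - 1] - 2 * v[k] + v[k + 1]
    delta <- if (den == 0) 0 else clamp(0.5 * (v[k - 1] - v[k + 1]) / den, -0.5, 0.5)
    dstep <- profile$offset_nm[2] - profile$offset_nm[1]
    profile$offset_nm[k] + delta * dstep
  }
  o1 <- refine(lo); o2 <- refine(hi)
  structure(list(diameter_nm = abs(o2 - o1), peak_offsets_nm = c(o1, o2)),
            class = "diameter_result")
}
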