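#' Traced membrane path
#'
#' An ordered polyline of sub-pixel `(z, y, x)` coordinates along a traced
#' membrane, with cumulative arclength in biological nm. Coordinates are
#' 0-based and pixel-centered in the pixel grid of the image the path was
#' traced on; arclength uses the per-axis biological pixel size, so anisotropic
#' sampling is handled correctly.
#'
#' @param points Numeric `n x 3` matrix of `(z, y, x)` pixel coordinates,
#'   `n >= 2`; consecutive points must be distinct.
#' @param bio_pixel_size_nm Biological pixel size per axis `(z, y, x)` in nm
#'   (scalar allowed for isotropic grids).
#' @param source Free-text provenance (e.g. trace file name, `"synthetic"`).
#' @return Object of class `membrane_path` with fields `points`,
#'   `arclength_nm` (cumulative, starting at 0) and `source`.
#' @export
membrane_path <- function(points, bio_pixel_size_nm, source = "unknown") {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 2L) stopf("a membrane path needs at least 2 points")
  if (any(!is.finite(points))) stopf("path coordinates must be finite")
  if (length(bio_pixel_size_nm) == 1L) bio_pixel_size_nm <- rep(bio_pixel_size_nm, 3)
  stopifnot(length(bio_pixel_size_nm) == 3L, all(bio_pixel_size_nm > 0))
  steps_nm <- sweep(diff(points), 2, bio_pixel_size_nm, `*`)
  seglen <- sqrt(rowSums(steps_nm^2))
  if (any(seglen == 0)) stopf("consecutive path points must be distinct")
  structure(list(
    points = points,
    bio_pixel_size_nm = as.numeric(bio_pixel_size_nm),
    arclength_nm = c(0, cumsum(seglen)),
    source = source
  ), class = "membrane_path")
}

#' Total arclength of a path in biological nm
#' @param path A [membrane_path].
#' @return Scalar length in nm.
#' @export
path_length_nm <- function(path) {
  stopifnot(inherits(path, "membrane_path"))
  path$arclength_nm[length(path$arclength_nm)]
}

# Resample a path at given arclength positions (nm); returns n x 3 pixel coords.
path_point_at <- function(path, s_nm) {
  s_nm <- clamp(s_nm, 0, path_length_nm(path))
  seg <- findInterval(s_nm, path$arclength_nm, rightmost.closed = TRUE)
  seg <- clamp(seg, 1, nrow(path$points) - 1)
  s0 <- path$arclength_nm[seg]
  s1 <- path$arclength_nm[seg + 1]
  f <- (s_nm - s0) / (s1 - s0)
  path$points[seg, , drop = FALSE] * (1 - f) + path$points[seg + 1, , drop = FALSE] * f
}

#' @export
print.membrane_path <- function(x, ...) {
  cat(sprintf("<membrane_path> %d points, %.1f nm (biological), source: %s\n",
              nrow(x$points), path_length_nm(x), x$source))
  invisible(x)
}

#' Paired pre-/post-expansion landmark coordinates
#'
#' @param pre Numeric `n x 3` matrix of `(z, y, x)` pixel coordinates in the
#'   pre-expansion image.
#' @param post Numeric `n x 3` matrix of corresponding coordinates in the
#'   post-expansion image.
#' @return Object of class `landmark_set` with fields `pre`, `post`, `n_pairs`.
#' @export
landmark_set <- function(pre, post) {
  pre <- matrix(as.numeric(pre), ncol = 3)
  post <- matrix(as.numeric(post), ncol = 3)
  if (nrow(pre) != nrow(post)) stopf("pre and post must have the same number of landmarks")
  if (nrow(pre) < 2L) stopf("need at least 2 landmark pairs for distance-ratio estimation")
  if (any(!is.finite(pre)) || any(!is.finite(post))) {
    stopf("validation error: landmark coordinates must be finite")
  }
  structure(list(pre = pre, post = post, n_pairs = nrow(pre)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d pairs\n", x$n_pairs))
  invisible(x)
}
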