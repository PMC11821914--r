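#' Multi-channel image stack with physical units
#'
#' The shared data container for all analyses. Intensity data are stored as a
#' named list of 3-D arrays indexed `(z, y, x)` (or `(t, y, x)` for time
#' series), one array per channel. Physical pixel sizes refer to the *expanded*
#' sample; dividing by the expansion factor gives sizes in biological units,
#' i.e. lengths referred to the original tissue.
#'
#' @param data A numeric array (2-D `(y, x)` or 3-D `(z, y, x)`), or a named
#'   list of such arrays, one per channel.
#' @param pixel_size_nm Physical pixel size of the expanded sample in nm;
#'   either a scalar (isotropic) or a length-3 vector `(z, y, x)`.
#' @param expansion_factor Dimensionless linear expansion factor, `>= 1`.
#' @param channel_names Optional character vector of channel names; defaults to
#'   names of `data` or `"ch1"`, `"ch2"`, ...
#' @param axes Axis order string, `"zyx"` for spatial stacks or `"tyx"` for
#'   time series.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_nm, expansion_factor = 1,
                        channel_names = NULL, axes = "zyx") {
  if (!is.list(data)) data <- list(data)
  data <- lapply(data, function(a) {
    if (is.null(dim(a))) stopf("channel data must be a matrix or 3-D array")
    if (length(dim(a)) == 2L) dim(a) <- c(1L, dim(a))
    if (length(dim(a)) != 3L) stopf("channel data must be 2-D or 3-D")
    storage.mode(a) <- "double"
    a
  })
  if (is.null(channel_names)) {
    channel_names <- names(data) %||% paste0("ch", seq_along(data))
    if (any(!nzchar(channel_names))) channel_names <- paste0("ch", seq_along(data))
  }
  names(data) <- channel_names
  d1 <- dim(data[[1]])
  for (a in data) {
    if (!all(dim(a) == d1)) stopf("all channels must share the same dimensions")
    if (any(!is.finite(a))) stopf("image data must be finite")
    if (any(a < 0)) stopf("image data must be non-negative")
  }
  if (length(pixel_size_nm) == 1L) pixel_size_nm <- rep(pixel_size_nm, 3)
  if (length(pixel_size_nm) != 3L) stopf("pixel_size_nm must have length 1 or 3 (z, y, x)")
  if (any(!is.finite(pixel_size_nm)) || any(pixel_size_nm <= 0)) {
    stopf("unit error: pixel sizes must be positive and finite")
  }
  if (!is.finite(expansion_factor) || expansion_factor < 1) {
    stopf("unit error: expansion_factor must be >= 1")
  }
  if (!axes %in% c("zyx", "tyx")) stopf("axes must be 'zyx' or 'tyx'")
  structure(list(
    data = data,
    pixel_size_nm = as.numeric(pixel_size_nm),
    expansion_factor = as.numeric(expansion_factor),
    channel_names = channel_names,
    axes = axes
  ), class = "image_stack")
}

#' Biological pixel size of a stack
#'
#' Physical pixel size divided by the expansion factor, per axis `(z, y, x)`,
#' in nm of the original (pre-expansion) tissue.
#'
#' @param stack An [image_stack].
#' @return Numeric length-3 vector, nm per pixel in biological units.
#' @export
bio_pixel_size <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  stack$pixel_size_nm / stack$expansion_factor
}

#' Extract one channel of a stack as a 3-D array
#'
#' @param stack An [image_stack].
#' @param channel Channel name or index (default first channel).
#' @return 3-D numeric array `(z|t, y, x)`.
#' @export
get_channel <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel) && !channel %in% names(stack$data)) {
    stopf("unknown channel '%s'; available: %s", channel,
          paste(names(stack$data), collapse = ", "))
  }
  stack$data[[channel]]
}

#' Extract one z- (or t-) plane as a matrix
#'
#' @param stack An [image_stack].
#' @param plane 1-based plane index along the first axis.
#' @param channel Channel name or index.
#' @return Numeric `(y, x)` matrix.
#' @export
get_plane <- function(stack, plane = 1L, channel = 1L) {
  a <- get_channel(stack, channel)
  if (plane < 1 || plane > dim(a)[1]) stopf("plane %d out of range", plane)
  a[plane, , ]
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf("<image_stack> %s %d x %d x %d, %d channel(s): %s\n",
              x$axes, d[1], d[2], d[3], length(x$data),
              paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  pixel size (nm, expanded): %s; expansion factor %.3g\n",
              paste(signif(x$pixel_size_nm, 4), collapse = " x "),
              x$expansion_factor))
  cat(sprintf("  pixel size (nm, biological): %s\n",
              paste(signif(bio_pixel_size(x), 4), collapse = " x ")))
  invisible(x)
}

#' Convert a physical length to biological units
#'
#' Lengths measured in the expanded gel divided by the linear expansion factor.
#' The same arithmetic gives the effective biological-unit resolution of an
#' instrument: e.g. a confocal axial resolution of ~500 nm at 4x expansion
#' corresponds to ~125 nm in biological units.
#'
#' @param length_nm Physical length(s) in nm (expanded sample).
#' @param expansion_factor Linear expansion factor, `>= 1`.
#' @return Length(s) in biological-unit nm.
#' @export
to_bio_units <- function(length_nm, expansion_factor) {
  if (any(expansion_factor < 1)) stopf("expansion_factor must be >= 1")
  length_nm / expansion_factor
}
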