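#' Mean background level from empty-gel reference images
#'
#' Grand mean intensity across all pixels of all images (pixel-weighted when
#' image sizes differ). The references must share acquisition settings with
#' the signal volume — that contract is the caller's to assert.
#'
#' @param empty_gel_images List of [image_stack]s (or numeric arrays).
#' @param channel Channel used for `image_stack` inputs.
#' @return Scalar mean background intensity.
#' @export
background_level <- function(empty_gel_images, channel = 1L) {
  if (inherits(empty_gel_images, "image_stack") || is.numeric(empty_gel_images)) {
    empty_gel_images <- list(empty_gel_images)
  }
  if (!length(empty_gel_images)) stopf("need at least one empty-gel image")
  total <- 0
  npix <- 0
  for (im in empty_gel_images) {
    a <- if (inherits(im, "image_stack")) get_channel(im, channel) else im
    total <- total + sum(a)
    npix <- npix + length(a)
  }
  total / npix
}

#' Signal-to-background ratio per z-plane
#'
#' For each XY plane of the volume, the mean over *all* pixels divided by the
#' scalar background — the depth profile used to assess labeling uniformity
#' through a tissue volume. Depths are reported in biological micrometers.
#'
#' @param volume An [image_stack] (axes `"zyx"`).
#' @param background Scalar background from [background_level()]; must be
#'   positive.
#' @param channel Channel name or index.
#' @return Object of class `sbr_profile`: `z_um` (biological), `mean_signal`,
#'   `background_mean`, `sbr` per plane.
#' @export
sbr_depth_profile <- function(volume, background, channel = 1L) {
  stopifnot(inherits(volume, "image_stack"))
  if (!is.finite(background) || background <= 0) {
    stopf("background must be a positive scalar, got %g", background)
  }
  arr <- get_channel(volume, channel)
  means <- apply(arr, 1, mean)
  z_um <- (seq_len(dim(arr)[1]) - 1) * bio_pixel_size(volume)[1] / 1000
  structure(list(
    z_um = z_um,
    mean_signal = means,
    background_mean = background,
    sbr = means / background
  ), class = "sbr_profile")
}

#' @export
print.sbr_profile <- function(x, ...) {
  cat(sprintf("<sbr_profile> %d planes, S/B min %.3g / median %.3g / max %.3g\n",
              length(x$sbr), min(x$sbr), stats::median(x$sbr), max(x$sbr)))
  invisible(x)
}
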