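#' Read a TIFF / OME-TIFF stack
#'
#' Reads a (multi-page) TIFF into an [image_stack]. Unit metadata is resolved
#' with the precedence: explicit arguments win over OME-XML
#' `PhysicalSizeX/Y/Z` attributes in the ImageDescription, which win over a
#' JSON sidecar (`<path>.json`, as written by [write_stack]) — deposited data
#' may carry incomplete metadata. Pages are stacked along the first axis.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm Optional override: physical pixel size in nm (scalar or
#'   `(z, y, x)`).
#' @param expansion_factor Optional override: linear expansion factor
#'   (default 1 when absent from metadata).
#' @param channel_name Channel name for the loaded data (default `"ch1"`).
#' @param axes `"zyx"` (default) or `"tyx"` for time series.
#' @return An [image_stack].
#' @export
read_stack <- function(path, pixel_size_nm = NULL, expansion_factor = NULL,
                       channel_name = "ch1", axes = "zyx") {
  if (!file.exists(path)) stopf("I/O error: cannot read '%s'", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stopf("I/O error reading '%s': %s", path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  desc <- attr(pages[[1]], "description")
  bits <- attr(pages[[1]], "bits.per.sample") %||% 8L
  meta <- parse_ome_description(desc)
  sidecar <- read_stack_sidecar(path)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first sample of RGB-style pages
    p
  })
  # readTIFF rescales integer samples to [0, 1]; restore raw counts, then
  # apply any recorded sidecar intensity scale (floats are stored as-is)
  scale <- sidecar$intensity_scale %||% if (bits <= 16L) 2^bits - 1 else 1
  if (is.null(pixel_size_nm)) pixel_size_nm <- meta$pixel_size_nm %||% sidecar$pixel_size_nm
  if (is.null(expansion_factor)) {
    expansion_factor <- meta$expansion_factor %||% sidecar$expansion_factor %||% 1
  }
  if (is.null(pixel_size_nm)) {
    stopf("unit error: '%s' carries no pixel-size metadata and no override was given", path)
  }
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * scale
  arr[arr < 0] <- 0
  image_stack(stats::setNames(list(arr), channel_name),
              pixel_size_nm = pixel_size_nm,
              expansion_factor = expansion_factor,
              axes = axes)
}

# Pull PhysicalSize{X,Y,Z} (+unit) and an optional ExpansionFactor annotation
# out of an OME ImageDescription string. Returns nm.
parse_ome_description <- function(desc) {
  out <- list(pixel_size_nm = NULL, expansion_factor = NULL)
  if (is.null(desc) || !nzchar(desc)) return(out)
  grab <- function(attrname) {
    m <- regmatches(desc, regexpr(sprintf('%s="[^"]*"', attrname), desc))
    if (!length(m)) return(NULL)
    as.numeric(sub('.*="([^"]*)"', "\\1", m))
  }
  unit_of <- function(attrname) {
    m <- regmatches(desc, regexpr(sprintf('%sUnit="[^"]*"', attrname), desc))
    if (!length(m)) return("µm")
    sub('.*="([^"]*)"', "\\1", m)
  }
  to_nm <- function(v, unit) {
    if (is.null(v)) return(NULL)
    switch(unit,
           "nm" = v,
           "µm" = v * 1000, "um" = v * 1000, "micron" = v * 1000,
           "mm" = v * 1e6,
           v * 1000)
  }
  px <- to_nm(grab("PhysicalSizeX"), unit_of("PhysicalSizeX"))
  py <- to_nm(grab("PhysicalSizeY"), unit_of("PhysicalSizeY"))
  pz <- to_nm(grab("PhysicalSizeZ"), unit_of("PhysicalSizeZ"))
  if (!is.null(px)) {
    if (is.null(py)) py <- px
    if (is.null(pz)) pz <- px
    out$pixel_size_nm <- c(pz, py, px)
  }
  ef <- grab("ExpansionFactor")
  if (!is.null(ef)) out$expansion_factor <- ef
  out
}

sidecar_path <- function(path) paste0(path, ".json")

read_stack_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(list())
  jsonlite::fromJSON(sp)
}

#' Write an image stack to TIFF (+ unit sidecar)
#'
#' One channel per file; pages along the first axis; samples stored as 32-bit
#' values scaled into `[0, 1]`. Pixel sizes, expansion factor and the intensity
#' scale are recorded in a JSON sidecar (`<path>.json`) so that [read_stack]
#' round-trips both units and intensities.
#'
#' @param stack An [image_stack].
#' @param path Output file path.
#' @param channel Channel name or index to write.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  arr <- get_channel(stack, channel)
  scale <- max(arr)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(dim(arr)[1]), function(i) arr[i, , ] / scale)
  tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE),
           error = function(e) stopf("I/O error writing '%s': %s", path, conditionMessage(e)))
  jsonlite::write_json(
    list(pixel_size_nm = stack$pixel_size_nm,
         expansion_factor = stack$expansion_factor,
         intensity_scale = scale,
         axes = stack$axes,
         channel = if (is.character(channel)) channel else stack$channel_names[channel]),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
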