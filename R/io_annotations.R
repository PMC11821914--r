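#' Read polyline annotations (JSON or ImageJ ROI)
#'
#' The canonical annotation format is a JSON document with schema
#' `{"coordinate_order": "zyx", "polylines": [{"name": ..., "points": [[z, y, x], ...]}]}`
#' (coordinates 0-based, pixel-centered). ImageJ `.roi` files and `.zip`
#' archives of them are supported as a convenience for manual traces; only
#' line-type ROIs (line, freeline, polyline) are accepted.
#'
#' @param path `.json`, `.roi` or `.zip` file.
#' @param bio_pixel_size_nm Biological pixel size `(z, y, x)` (or scalar) of
#'   the image the traces refer to, used to compute arclengths. An
#'   [image_stack] may be passed instead.
#' @return List of [membrane_path] objects.
#' @export
read_polylines <- function(path, bio_pixel_size_nm) {
  if (inherits(bio_pixel_size_nm, "image_stack")) {
    bio_pixel_size_nm <- bio_pixel_size(bio_pixel_size_nm)
  }
  if (!file.exists(path)) stopf("I/O error: cannot read '%s'", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    read_polylines_json(path, bio_pixel_size_nm)
  } else if (ext == "roi") {
    list(read_imagej_roi(path, bio_pixel_size_nm))
  } else if (ext == "zip") {
    dir <- tempfile("roizip")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    files <- utils::unzip(path, exdir = dir)
    files <- sort(files[tolower(tools::file_ext(files)) == "roi"])
    lapply(files, read_imagej_roi, bio_pixel_size_nm = bio_pixel_size_nm)
  } else {
    stopf("unsupported annotation format '%s' (expected .json, .roi or .zip)", ext)
  }
}

read_polylines_json <- function(path, bio_pixel_size_nm) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  if (is.null(doc$polylines)) stopf("JSON polyline file lacks a 'polylines' field")
  ord <- doc$coordinate_order %||% "zyx"
  if (!identical(ord, "zyx")) stopf("unsupported coordinate_order '%s'", ord)
  lapply(seq_along(doc$polylines), function(i) {
    pl <- doc$polylines[[i]]
    pts <- pl$points
    if (is.list(pts)) pts <- do.call(rbind, pts)
    pts <- matrix(as.numeric(pts), ncol = 3)
    membrane_path(pts, bio_pixel_size_nm,
                  source = pl$name %||% sprintf("%s#%d", basename(path), i))
  })
}

#' Write polylines to the canonical JSON schema
#'
#' @param paths A [membrane_path] or list of them.
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
write_polylines <- function(paths, path) {
  if (inherits(paths, "membrane_path")) paths <- list(paths)
  doc <- list(
    coordinate_order = "zyx",
    polylines = lapply(paths, function(p) {
      list(name = p$source, points = unname(apply(p$points, 1, as.numeric, simplify = FALSE)))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Minimal ImageJ .roi decoder for line-type ROIs. Big-endian layout:
# "Iout", version(2), type(1), pad(1), top/left/bottom/right (4 shorts),
# nCoordinates(2), x1,y1,x2,y2 (4 floats), ..., options at byte 50,
# position (slice) at byte 56; integer coords (x then y, relative to
# left/top) from byte 64, followed by float coords when the sub-pixel
# resolution option bit (128) is set.
read_imagej_roi <- function(path, bio_pixel_size_nm) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout") {
    stopf("'%s' is not an ImageJ ROI file", path)
  }
  be_short <- function(off, signed = TRUE) {
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big", signed = signed)
  }
  be_int <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = "big")
  be_floats <- function(off, n) readBin(raw[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4, endian = "big")
  type <- as.integer(raw[7])
  # 3 = line, 4 = freeline, 5 = polyline
  if (!type %in% c(3L, 4L, 5L)) {
    stopf("unsupported-ROI error: ROI type %d in '%s' is not a polyline", type, path)
  }
  top <- be_short(8); left <- be_short(10)
  n <- be_short(16, signed = FALSE)
  options <- be_short(50, signed = FALSE)
  position <- be_int(56)
  z <- max(position - 1, 0)
  if (type == 3L) {  # straight line: endpoints stored as floats at bytes 18..33
    xy <- be_floats(18, 4)
    pts <- cbind(z, c(xy[2], xy[4]), c(xy[1], xy[3]))
  } else {
    if (n < 2) stopf("ROI in '%s' has fewer than 2 points", path)
    xi <- vapply(seq_len(n), function(i) be_short(64 + 2 * (i - 1)), numeric(1))
    yi <- vapply(seq_len(n), function(i) be_short(64 + 2 * n + 2 * (i - 1)), numeric(1))
    if (bitwAnd(options, 128L) != 0L) {  # sub-pixel float coordinates
      xf <- be_floats(64 + 4 * n, n)
      yf <- be_floats(64 + 8 * n, n)
      pts <- cbind(z, yf, xf)
    } else {
      pts <- cbind(z, top + yi, left + xi)
    }
  }
  membrane_path(pts, bio_pixel_size_nm, source = basename(path))
}

#' Read pre/post-expansion landmark pairs from a delimited table
#'
#' Expects columns `pre_z, pre_y, pre_x, post_z, post_y, post_x` (the `*_z`
#' columns may be omitted for 2-D landmarks; zeros are filled in). Coordinates
#' are pixel units of the respective images.
#'
#' @param path CSV file path.
#' @return A [landmark_set].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stopf("I/O error: cannot read '%s'", path)
  tab <- utils::read.csv(path)
  need2d <- c("pre_y", "pre_x", "post_y", "post_x")
  if (!all(need2d %in% names(tab))) {
    stopf("schema error: landmark table must have columns %s (optionally pre_z/post_z)",
          paste(need2d, collapse = ", "))
  }
  if (!"pre_z" %in% names(tab)) tab$pre_z <- 0
  if (!"post_z" %in% names(tab)) tab$post_z <- 0
  if (nrow(tab) < 2L) stopf("schema error: need at least 2 landmark pairs, got %d", nrow(tab))
  pre <- as.matrix(tab[, c("pre_z", "pre_y", "pre_x")])
  post <- as.matrix(tab[, c("post_z", "post_y", "post_x")])
  if (any(!is.finite(pre)) || any(!is.finite(post))) {
    stopf("validation error: landmark table contains non-finite coordinates")
  }
  landmark_set(pre, post)
}
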