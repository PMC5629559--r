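#' Load a sequence-logo raster image
#'
#' Reads a PNG, JPEG or GIF file into a common three-channel RGB pixel
#' grid. Grayscale images are promoted to RGB by channel replication;
#' only the first frame of an animated GIF is used. A PNG carrying an
#' alpha (transparency) channel is rejected unless `flatten_alpha = TRUE`,
#' in which case it is composited over a white background.
#'
#' @param path Path to a `.png`, `.jpg`, `.jpeg` or `.gif` file.
#' @param flatten_alpha Composite an alpha channel over white instead of
#'   rejecting the file.
#' @return A `logo_image`: list with `pixels` (H x W x 3 integer array,
#'   0-255), `source_format`, `height_px`, `width_px`.
#' @export
read_logo <- function(path, flatten_alpha = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "jpg", "jpeg", "gif")) {
    stop("unsupported image format '", ext,
         "' (supported: png, jpg, jpeg, gif)", call. = FALSE)
  }
  arr <- switch(ext,
    png = {
      a <- png::readPNG(path)
      round(to_rgb01(a, flatten_alpha) * 255)
    },
    jpg = ,
    jpeg = {
      a <- jpeg::readJPEG(path)
      round(to_rgb01(a, flatten_alpha) * 255)
    },
    gif = read_gif(path)
  )
  storage.mode(arr) <- "integer"
  new_logo_image(arr, source_format = ext)
}

# normalise a decoded raster (matrix or H x W x {1,2,3,4} array in [0,1])
# to an H x W x 3 array in [0,1]
to_rgb01 <- function(a, flatten_alpha) {
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  nc <- dim(a)[3]
  if (nc == 2L) {                       # gray + alpha
    a <- array(c(a[, , 1], a[, , 1], a[, , 1], a[, , 2]),
               dim = c(dim(a)[1:2], 4L))
    nc <- 4L
  }
  if (nc == 1L) {
    return(array(a[, , 1], dim = c(dim(a)[1:2], 3L))[, , c(1, 1, 1)])
  }
  if (nc == 4L) {
    if (!flatten_alpha) {
      stop("image has an alpha (transparency) channel, which is not ",
           "supported; re-save without transparency or use ",
           "`flatten_alpha = TRUE` to composite over white", call. = FALSE)
    }
    al <- a[, , 4]
    out <- array(0, dim = c(dim(a)[1:2], 3L))
    for (ch in 1:3) out[, , ch] <- a[, , ch] * al + (1 - al)
    return(out)
  }
  a[, , 1:3, drop = FALSE]
}

new_logo_image <- function(pixels, source_format = "png") {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (any(pixels < 0L) || any(pixels > 255L)) {
    stop("pixel channels must be in [0, 255]", call. = FALSE)
  }
  structure(list(pixels = pixels,
                 source_format = source_format,
                 height_px = dim(pixels)[1],
                 width_px = dim(pixels)[2]),
            class = "logo_image")
}

#' @export
print.logo_image <- function(x, ...) {
  cat(sprintf("<logo_image> %d x %d px (%s)\n",
              x$height_px, x$width_px, x$source_format))
  invisible(x)
}

#' Crop a logo image
#'
#' Extracts a rectangular sub-image. Cropping to the pure logo area
#' (ideally with no left or right margin) is the standard rescue when a
#' figure contains more than the logo, e.g. surrounding panels or long
#' internal gaps.
#'
#' @param img A [read_logo()] image.
#' @param rect Rectangle `c(x, y, w, h)`: 0-based left/top corner plus
#'   width and height in pixels.
#' @return The cropped `logo_image`.
#' @export
crop_logo <- function(img, rect) {
  if (!inherits(img, "logo_image")) stop("`img` must be a logo_image",
                                         call. = FALSE)
  if (length(rect) != 4L || anyNA(rect)) {
    stop("`rect` must be c(x, y, w, h)", call. = FALSE)
  }
  x <- rect[1]; y <- rect[2]; w <- rect[3]; h <- rect[4]
  if (x < 0 || y < 0 || w < 1 || h < 1 ||
      x + w > img$width_px || y + h > img$height_px) {
    stop("crop rectangle out of image bounds", call. = FALSE)
  }
  new_logo_image(img$pixels[(y + 1):(y + h), (x + 1):(x + w), , drop = FALSE],
                 source_format = img$source_format)
}

# write an H x W x 3 integer array (0-255) in the format implied by the
# file extension; JPEG quality is kept high so flat-color glyphs survive
write_image <- function(pixels, path, quality = 0.95) {
  ext <- tolower(tools::file_ext(path))
  a01 <- array(pixels / 255, dim = dim(pixels))
  switch(ext,
    png = png::writePNG(a01, path),
    jpg = ,
    jpeg = jpeg::writeJPEG(a01, path, quality = quality),
    gif = write_gif(pixels, path),
    stop("unsupported output image format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}
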