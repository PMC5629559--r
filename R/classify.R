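# The six reference colors. Everything in a standard DNA logo is assumed
# to be one of these: white background, black axes/labels, and the four
# letter colors green = A, blue = C, yellow = G, red = T.
COLOR_CENTROIDS <- rbind(
  black  = c(0, 0, 0),
  white  = c(255, 255, 255),
  red    = c(200, 25, 32),
  green  = c(57, 178, 65),
  blue   = c(43, 60, 147),
  yellow = c(240, 173, 10)
)

#' Color classes recognised in logo images
#' @return Character vector of the six class names in fixed order.
#' @export
color_classes <- function() rownames(COLOR_CENTROIDS)

# class index of a nucleotide's letter color
BASE_COLOR_CLASS <- c(A = "green", C = "blue", G = "yellow", T = "red")

#' Classify one RGB value into a reference color class
#'
#' Nearest-centroid ("nearest neighbor") classification under Euclidean
#' distance in RGB space. Ties are broken by the fixed class order
#' black, white, red, green, blue, yellow.
#'
#' @param rgb Numeric 3-vector, channels in \[0, 255\].
#' @return One of [color_classes()].
#' @examples
#' classify_pixel(c(0, 0, 0))      # "black"
#' classify_pixel(c(255, 0, 0))    # "red"
#' @export
classify_pixel <- function(rgb) {
  if (length(rgb) != 3L || anyNA(rgb) || any(rgb < 0) || any(rgb > 255)) {
    stop("`rgb` must be a 3-vector with channels in [0, 255]", call. = FALSE)
  }
  d2 <- rowSums(sweep(COLOR_CENTROIDS, 2, rgb)^2)
  rownames(COLOR_CENTROIDS)[which.min(d2)]
}

#' Classify every pixel of a logo image
#'
#' Applies nearest-centroid color classification to the whole pixel grid.
#'
#' @param img A [read_logo()] image.
#' @return A `color_map`: integer H x W matrix of class codes, with the
#'   class names in `attr(, "classes")`; use [color_class_of()] for a
#'   character view.
#' @export
classify_colors <- function(img) {
  if (!inherits(img, "logo_image")) stop("`img` must be a logo_image",
                                         call. = FALSE)
  px <- img$pixels
  n <- prod(dim(px)[1:2])
  flat <- matrix(as.numeric(px), nrow = n)          # n x 3
  # squared distance to each centroid, vectorized over pixels
  d2 <- matrix(0, nrow = n, ncol = nrow(COLOR_CENTROIDS))
  for (k in seq_len(nrow(COLOR_CENTROIDS))) {
    d2[, k] <- (flat[, 1] - COLOR_CENTROIDS[k, 1])^2 +
               (flat[, 2] - COLOR_CENTROIDS[k, 2])^2 +
               (flat[, 3] - COLOR_CENTROIDS[k, 3])^2
  }
  code <- max.col(-d2, ties.method = "first")
  cmap <- matrix(as.integer(code), nrow = dim(px)[1])
  new_color_map(cmap)
}

new_color_map <- function(cmap) {
  structure(cmap, classes = rownames(COLOR_CENTROIDS),
            class = c("color_map", "matrix", "array"))
}

#' @export
print.color_map <- function(x, ...) {
  tab <- table(factor(attr(x, "classes")[x], levels = attr(x, "classes")))
  cat(sprintf("<color_map> %d x %d px\n", nrow(x), ncol(x)))
  print(tab)
  invisible(x)
}

#' Character view of a color map
#' @param cmap A [classify_colors()] map.
#' @return Character matrix of class names.
#' @export
color_class_of <- function(cmap) {
  m <- matrix(attr(cmap, "classes")[cmap], nrow = nrow(cmap))
  m
}

# integer codes for frequently tested classes
class_code <- function(name) match(name, rownames(COLOR_CENTROIDS))

#' Remove background noise from a classified logo image
#'
#' Reclassifies as white (background) all non-white connected components
#' smaller than `min_component_px` pixels -- stray marks, anti-aliasing
#' specks, and the dashes of dashed background rules -- plus any
#' 1-pixel-tall black component spanning at least half the image width
#' that has colored content both above and below it (a solid horizontal
#' background rule running through the logo; the X axis, which has no
#' letters beneath it, is never touched). Letter glyphs are connected
#' components far above the threshold and pass through unchanged. The
#' operation is idempotent.
#'
#' @param cmap A [classify_colors()] map.
#' @param min_component_px Components smaller than this many pixels are
#'   treated as noise (default 4).
#' @return The cleaned `color_map`.
#' @export
remove_noise <- function(cmap, min_component_px = 4) {
  white <- class_code("white")
  black <- class_code("black")
  fg <- unclass(cmap) != white
  if (!any(fg)) return(cmap)
  lab <- EBImage::bwlabel(fg * 1L)
  sz <- tabulate(lab[lab > 0L])
  small <- which(sz > 0L & sz < min_component_px)
  out <- unclass(cmap)
  if (length(small)) out[lab %in% small] <- white

  # solid 1-px horizontal black rules strictly inside the colored content
  colored <- out != white & out != black
  if (any(colored)) {
    rows_colored <- which(rowSums(colored) > 0)
    top <- min(rows_colored); bottom <- max(rows_colored)
    black_rows <- which(rowSums(out == black) >= ncol(out) * 0.5)
    for (r in black_rows) {
      if (r <= top || r >= bottom) next
      above <- (r > 1 && any(out[r - 1, ] == black))
      below <- (r < nrow(out) && any(out[r + 1, ] == black))
      if (!above && !below) out[r, out[r, ] == black] <- white
    }
  }
  new_color_map(out)
}
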