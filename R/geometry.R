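# All rectangles and intervals in this package are 0-based and half-open:
# a region [top, bottom) x [left, right) with row 0 at the top of the
# image and column 0 at the left. Conversion to R's 1-based matrix
# indices happens only at the point of subsetting.

new_logo_region <- function(top, bottom, left, right,
                            has_x_axis = FALSE, has_y_axis = FALSE,
                            y_axis_height_px = NULL) {
  stopifnot(bottom > top, right > left)
  structure(list(top = as.integer(top), bottom = as.integer(bottom),
                 left = as.integer(left), right = as.integer(right),
                 has_x_axis = has_x_axis, has_y_axis = has_y_axis,
                 y_axis_height_px = if (has_y_axis) as.integer(y_axis_height_px)),
            class = "logo_region")
}

#' @export
print.logo_region <- function(x, ...) {
  cat(sprintf("<logo_region> rows [%d, %d) x cols [%d, %d); x axis: %s, y axis: %s\n",
              x$top, x$bottom, x$left, x$right,
              x$has_x_axis, x$has_y_axis))
  invisible(x)
}

# longest TRUE run in a logical vector: length, 0-based start of that run
longest_run <- function(v) {
  r <- rle(v)
  if (!any(r$values)) return(c(len = 0L, start = 0L))
  ends <- cumsum(r$lengths)
  idx <- which(r$values)
  best <- idx[which.max(r$lengths[idx])]
  c(len = r$lengths[best], start = ends[best] - r$lengths[best])
}

#' Detect logo axes and the pure logo region
#'
#' Coordinate axes are assumed to be drawn in black: a vertical black run
#' spanning at least half the image height near the left is the Y axis, a
#' horizontal black run spanning at least half the image width near the
#' bottom is the X axis. When both are present the pure logo area is the
#' box they frame (which keeps zero-height columns inside the region);
#' otherwise it falls back to the bounding box of colored (letter)
#' pixels, which automatically excludes tick marks and black label text.
#'
#' @param cmap A [classify_colors()] map, ideally after [remove_noise()].
#' @param min_run_frac Minimum axis length as a fraction of the image
#'   dimension (default 0.5).
#' @return A `logo_region` with fields `top`, `bottom`, `left`, `right`
#'   (0-based, half-open), `has_x_axis`, `has_y_axis`, and
#'   `y_axis_height_px` (the pixel length of the Y axis, used as the
#'   2-bit scale).
#' @export
detect_axes <- function(cmap, min_run_frac = 0.5) {
  m <- unclass(cmap)
  H <- nrow(m); W <- ncol(m)
  black <- m == class_code("black")
  white <- class_code("white")
  colored <- m != white & !black

  if (!any(m != white)) stop("blank image: no non-white pixels", call. = FALSE)

  # vertical axis: leftmost group of adjacent columns whose longest black
  # run covers >= min_run_frac of the height
  vruns <- vapply(seq_len(W), function(j) longest_run(black[, j]),
                  c(len = 0L, start = 0L))
  vcand <- which(vruns["len", ] >= min_run_frac * H)
  has_y <- length(vcand) > 0L
  y_col_last <- NA_integer_; y_top <- NA_integer_; y_len <- NA_integer_
  if (has_y) {
    grp <- vcand[cumsum(c(1L, diff(vcand) != 1L)) == 1L]  # leftmost group
    y_col_last <- max(grp)                                # 1-based
    j <- grp[1L]
    y_len <- vruns["len", j]
    y_top <- vruns["start", j]                            # 0-based row
  }

  # horizontal axis: bottom-most group of adjacent rows
  hruns <- vapply(seq_len(H), function(i) longest_run(black[i, ]),
                  c(len = 0L, start = 0L))
  hcand <- which(hruns["len", ] >= min_run_frac * W)
  has_x <- length(hcand) > 0L
  x_row_first <- NA_integer_; x_left <- NA_integer_; x_len <- NA_integer_
  if (has_x) {
    g <- cumsum(c(1L, diff(hcand) != 1L))
    grp <- hcand[g == max(g)]                             # bottom-most group
    x_row_first <- min(grp)                               # 1-based
    i <- grp[1L]
    x_len <- hruns["len", i]
    x_left <- hruns["start", i]                           # 0-based col
  }

  # where the axes cross, the vertical run continues through the X-axis
  # line; the Y axis proper ends at the X axis
  if (has_x && has_y && y_top + y_len > x_row_first - 1L) {
    y_len <- x_row_first - 1L - y_top
  }

  have_colored <- any(colored)
  if (have_colored) {
    rows <- which(rowSums(colored) > 0L)
    cols <- which(colSums(colored) > 0L)
    ctop <- rows[1L] - 1L; cbot <- rows[length(rows)]     # half-open
    cleft <- cols[1L] - 1L; cright <- cols[length(cols)]
  }

  if (has_x && has_y) {
    top <- y_top
    bottom <- x_row_first - 1L                            # 0-based axis row
    left <- y_col_last                                    # col after axis
    right <- x_left + x_len
  } else if (has_y && have_colored) {
    top <- y_top; bottom <- y_top + y_len
    left <- y_col_last; right <- cright
  } else if (has_x && have_colored) {
    top <- ctop; bottom <- x_row_first - 1L
    left <- cleft; right <- cright
  } else if (have_colored) {
    top <- ctop; bottom <- cbot; left <- cleft; right <- cright
  } else {
    stop("blank image: no letter pixels inside the logo area", call. = FALSE)
  }
  if (bottom <= top || right <= left) {
    stop("degenerate logo region after axis removal", call. = FALSE)
  }
  new_logo_region(top, bottom, left, right,
                  has_x_axis = has_x, has_y_axis = has_y,
                  y_axis_height_px = if (has_y) y_len)
}

#' Pixel height corresponding to 2 bits
#'
#' The scale that converts stack heights to information content. With a Y
#' axis the axis length defines the 2-bit scale; without one the tallest
#' letter stack is assumed to carry the maximum 2 bits (which inflates
#' the reconstruction when the true maximum column is weaker -- an
#' unavoidable assumption when no scale is drawn).
#'
#' @param region A [detect_axes()] region.
#' @param cmap The matching color map.
#' @return Pixel count for 2 bits of information content.
#' @export
full_scale_pixels <- function(region, cmap) {
  if (isTRUE(region$has_y_axis)) return(region$y_axis_height_px)
  m <- unclass(cmap)
  sub <- m[(region$top + 1):region$bottom,
           (region$left + 1):region$right, drop = FALSE]
  colored <- sub != class_code("white") & sub != class_code("black")
  rows <- which(rowSums(colored) > 0L)
  if (!length(rows)) stop("blank region: no letter pixels", call. = FALSE)
  # stacks share the baseline, so the tallest stack spans from the
  # highest colored row down to the lowest
  rows[length(rows)] - rows[1L] + 1L
}

# mode of a numeric vector after rounding; ties broken toward the
# smaller value (favors more columns, recoverable by fine-adjustment)
vote_mode <- function(x) {
  x <- round(x)
  tab <- table(x)
  vals <- as.numeric(names(tab))
  vals[order(-as.integer(tab), vals)][1L]
}

#' Segment the logo region into letter columns
#'
#' Projects colored pixels onto the X axis, finds peaks (maximal runs of
#' positive projection separated by zero gaps), votes on the consensus
#' spacing between peak centers to get the column width, derives the
#' column count from the region width, lays out uniform boundaries and
#' snaps each internal boundary to the nearest projection minimum within
#' a quarter column width. When single-pixel gaps fragment individual
#' letters, a 3-px moving-maximum closing is applied before peak finding.
#' A user-supplied column count overrides detection entirely (the rescue
#' for fused or low-resolution logos) and yields uniform boundaries.
#'
#' @param cmap A [classify_colors()] map.
#' @param region A [detect_axes()] region.
#' @param n_override Optional known number of motif positions.
#' @return A `column_layout`: list with `n_columns`, `boundaries`
#'   (n x 2 matrix of 0-based half-open column intervals), and
#'   `column_width_px`.
#' @export
segment_columns <- function(cmap, region, n_override = NULL) {
  m <- unclass(cmap)
  sub <- m[(region$top + 1):region$bottom,
           (region$left + 1):region$right, drop = FALSE]
  colored <- sub != class_code("white") & sub != class_code("black")
  proj <- colSums(colored)
  w_region <- region$right - region$left
  if (all(proj == 0)) stop("blank region: empty X projection", call. = FALSE)

  if (!is.null(n_override)) {
    if (!is.numeric(n_override) || length(n_override) != 1L || n_override < 1) {
      stop("`n_override` must be a positive integer", call. = FALSE)
    }
    n <- as.integer(n_override)
    width <- w_region / n
    cuts <- region$left + round(seq(0, w_region, length.out = n + 1L))
    return(new_column_layout(cuts, width))
  }

  peaks <- projection_peaks(proj)
  if (min_gap_width(proj) == 1L && nrow(peaks) > 1L) {
    # close single-pixel gaps that split one letter into two peaks
    proj_closed <- moving_max(proj, 3L)
    peaks <- projection_peaks(proj_closed)
  }

  if (nrow(peaks) >= 2L) {
    centers <- (peaks[, 1] + peaks[, 2] - 1) / 2
    d <- diff(centers)
    mode_w <- vote_mode(d)
    # consensus width: average the spacings that agree with the voted
    # mode (within 1 px), recovering fractional pitch lost to rounding;
    # off-consensus spacings (e.g. across a blank column) are excluded
    width <- mean(d[abs(d - mode_w) <= 1])
    n <- max(1L, round(w_region / width))
  } else {
    width <- w_region
    n <- 1L
  }

  cuts <- region$left + round(seq(0, w_region, length.out = n + 1L))
  if (n > 1L) {
    win <- max(1L, round(0.25 * width))
    for (k in 2:n) {
      nominal <- cuts[k] - region$left            # 0-based inside region
      lo <- max(1L, nominal - win + 1L)           # 1-based proj indices
      hi <- min(length(proj), nominal + win)
      pos <- lo:hi
      cand <- pos[proj[pos] == min(proj[pos])]    # minima in the window
      best <- cand[which.min(abs(cand - 1L - nominal))]
      cuts[k] <- region$left + best - 1L          # boundary before that pixel
    }
    cuts <- pmin(pmax(cuts, region$left), region$right)
    if (any(diff(cuts) <= 0)) {                   # snapping collapsed a cut
      cuts <- region$left + round(seq(0, w_region, length.out = n + 1L))
    }
  }
  new_column_layout(cuts, width)
}

new_column_layout <- function(cuts, width) {
  n <- length(cuts) - 1L
  structure(list(n_columns = n,
                 boundaries = cbind(left_px = cuts[-(n + 1L)],
                                    right_px = cuts[-1L]),
                 column_width_px = width),
            class = "column_layout")
}

#' @export
print.column_layout <- function(x, ...) {
  cat(sprintf("<column_layout> %d columns, representative width %.1f px\n",
              x$n_columns, x$column_width_px))
  invisible(x)
}

# maximal runs of positive projection: matrix of 1-based [start, end]
projection_peaks <- function(proj) {
  r <- rle(proj > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# width of the narrowest internal zero gap (Inf if none)
min_gap_width <- function(proj) {
  r <- rle(proj > 0)
  v <- r$values; lens <- r$lengths
  internal <- which(!v & seq_along(v) > 1L & seq_along(v) < length(v))
  if (!length(internal)) return(Inf)
  min(lens[internal])
}

moving_max <- function(x, k) {
  half <- k %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    max(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}

#' Measure one letter column
#'
#' Counts, inside one column interval, the pixel rows containing any
#' colored pixel (the stack height) and, per nucleotide, the pixel rows
#' containing at least one pixel of that nucleotide's color (the letter
#' heights), using the fixed code green = A, blue = C, yellow = G,
#' red = T. Letter identity is confirmed by consensus voting over each
#' contiguous letter block: the block is assigned to the color class
#' holding the majority of its colored pixels.
#'
#' @param cmap A [classify_colors()] map.
#' @param region A [detect_axes()] region.
#' @param bounds Length-2 vector, 0-based half-open column interval.
#' @return List with `stack_height_px` and `letter_heights_px` (named
#'   numeric vector over A, C, G, T). Both zero when the column holds no
#'   colored pixels; the caller decides how to handle that.
#' @export
measure_column <- function(cmap, region, bounds) {
  if (bounds[1] < region$left || bounds[2] > region$right ||
      bounds[2] <= bounds[1]) {
    stop("column bounds outside the logo region", call. = FALSE)
  }
  m <- unclass(cmap)
  sub <- m[(region$top + 1):region$bottom,
           (bounds[1] + 1):bounds[2], drop = FALSE]
  base_codes <- vapply(BASE_COLOR_CLASS, class_code, integer(1))
  colored <- matrix(sub %in% base_codes, nrow = nrow(sub))
  stack <- sum(rowSums(colored) > 0L)
  heights <- vapply(base_codes, function(code)
    sum(rowSums(sub == code) > 0L), numeric(1))
  names(heights) <- DNA_BASES
  list(stack_height_px = stack, letter_heights_px = heights)
}
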