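#' Rendering style for synthetic sequence logos
#'
#' Controls the geometry and colors of rendered logos. Defaults mirror
#' the common published style: white background, black axes, and the
#' usual DNA color code (green A, blue C, yellow G, red T) at the six
#' reference centroids used by the classifier.
#'
#' @param width_px,height_px Canvas size in pixels.
#' @param draw_x_axis,draw_y_axis Draw the black coordinate axes.
#' @param margin_px White margin around the drawing.
#' @param inter_column_gap_px White gap separating adjacent letter
#'   columns (split evenly between the two sides of each column).
#' @param letter_colors Named list/vector of RGB triples for A, C, G, T.
#' @param background RGB triple for the background.
#' @param format Output raster format: `"png"`, `"jpeg"` or `"gif"`.
#' @return A `logo_style` list.
#' @export
logo_style <- function(width_px = 600, height_px = 200,
                       draw_x_axis = TRUE, draw_y_axis = TRUE,
                       margin_px = 10, inter_column_gap_px = 4,
                       letter_colors = NULL,
                       background = c(255, 255, 255),
                       format = c("png", "jpeg", "gif")) {
  if (is.null(letter_colors)) {
    letter_colors <- lapply(BASE_COLOR_CLASS, function(cl)
      unname(COLOR_CENTROIDS[cl, ]))
  }
  stopifnot(width_px >= 40, height_px >= 20, margin_px >= 0,
            inter_column_gap_px >= 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 draw_x_axis = isTRUE(draw_x_axis),
                 draw_y_axis = isTRUE(draw_y_axis),
                 margin_px = as.integer(margin_px),
                 inter_column_gap_px = as.integer(inter_column_gap_px),
                 letter_colors = letter_colors,
                 background = background,
                 format = match.arg(format)),
            class = "logo_style")
}

# --- glyph masks -----------------------------------------------------------
# Solid block letterforms built from analytic shapes and stretched to the
# target box. Visual polish is not the point: recognition is by color, so
# the masks only need to (a) look letter-like, (b) cover every row and
# every column of their box so pixel-row heights equal box heights.

glyph_mask <- function(base, h, w) {
  if (h < 1L || w < 1L) return(matrix(FALSE, max(h, 0L), max(w, 0L)))
  x <- matrix((seq_len(w) - 0.5) / w, nrow = h, ncol = w, byrow = TRUE)
  y <- matrix((seq_len(h) - 0.5) / h, nrow = h, ncol = w)
  tx <- max(0.16, 1 / w)   # horizontal stroke half-width / thickness
  ty <- max(0.16, 1 / h)
  mask <- switch(base,
    A = {
      band <- abs(x - 0.5) <= y / 2 & abs(x - 0.5) >= pmax(0, y / 2 - tx)
      apex <- y <= ty
      bar <- y >= 0.58 & y <= 0.58 + ty & abs(x - 0.5) <= 0.35
      band | apex | bar
    },
    C = {
      ring_mask(x, y, tx, ty) & !(x > 0.62 & abs(y - 0.5) < 0.20)
    },
    G = {
      ring <- ring_mask(x, y, tx, ty) & !(x > 0.62 & abs(y - 0.5) < 0.20)
      bar <- x >= 0.52 & x <= 0.92 & y >= 0.46 & y <= 0.46 + ty
      leg <- x >= 0.92 - 2 * tx & x <= 0.92 & y >= 0.46 & y <= 0.80
      ring | bar | leg
    },
    T = {
      bar <- y <= ty
      stem <- abs(x - 0.5) <= tx * 0.75
      bar | stem
    },
    stop("unknown base: ", base, call. = FALSE)
  )
  # guarantee full row and column coverage of the box
  empty_rows <- which(rowSums(mask) == 0L)
  if (length(empty_rows)) mask[empty_rows, max(1L, round(w / 2))] <- TRUE
  empty_cols <- which(colSums(mask) == 0L)
  if (length(empty_cols)) mask[h, empty_cols] <- TRUE
  mask
}

ring_mask <- function(x, y, tx, ty) {
  outer <- ((x - 0.5) / 0.5)^2 + ((y - 0.5) / 0.5)^2 <= 1
  inner <- ((x - 0.5) / max(0.5 - 2 * tx, 0.15))^2 +
           ((y - 0.5) / max(0.5 - 2 * ty, 0.15))^2 < 1
  outer & !inner
}

paint <- function(canvas, rows, cols, rgb) {
  for (ch in 1:3) canvas[rows, cols, ch] <- rgb[ch]
  canvas
}

# integer pixel heights for the letters of one column: proportional to
# p_i * I_j, largest-remainder rounding so they sum to the stack height
allocate_heights <- function(p, stack_h) {
  real <- p / sum(p) * stack_h
  base <- floor(real)
  short <- stack_h - sum(base)
  if (short > 0) {
    extra <- order(real - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Render a sequence logo image from a PWM
#'
#' Draws the logo the standard way: column `j`'s letter stack has total
#' height `(I_j / 2)` of the full 2-bit scale, each letter's height is
#' proportional to its probability, letters are stacked largest on top,
#' and axes (when enabled) are drawn in pure black with the Y axis
#' spanning exactly the 2-bit scale. The returned record carries the
#' ground-truth geometry so tests never have to re-derive it from pixels.
#'
#' @param pwm A [pwm()].
#' @param style A [logo_style()].
#' @param out_path Output file; extension must match `style$format`
#'   conventions (`.png`, `.jpg`/`.jpeg`, `.gif`).
#' @return A `render_record`: list with `image_path`, `truth_pwm`,
#'   `logo_box` (0-based `c(x, y, w, h)`), `full_scale_px`, and `glyphs`
#'   (tibble of drawn glyph boxes: position, base, x, y, w, h).
#' @export
render_logo <- function(pwm, style = logo_style(), out_path) {
  pwm <- as_pwm(pwm)
  L <- ncol(pwm)
  W <- style$width_px; H <- style$height_px
  margin <- style$margin_px
  tick_len <- 3L
  left_pad <- margin + if (style$draw_y_axis) tick_len + 2L else 0L
  bottom_pad <- margin + if (style$draw_x_axis) 2L else 0L
  box_x <- left_pad
  box_y <- margin
  box_w <- W - margin - left_pad
  box_h <- H - margin - bottom_pad
  if (box_w < L || box_h < 4) stop("canvas too small for this PWM",
                                   call. = FALSE)

  canvas <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) canvas[, , ch] <- style$background[ch]

  if (style$draw_y_axis) {
    canvas <- paint(canvas, (box_y + 1):(box_y + box_h),
                    (box_x - 1):box_x, c(0, 0, 0))
    for (frac in c(0, 0.5, 1)) {                 # ticks at 0, 1, 2 bits
      r <- box_y + 1 + round(frac * (box_h - 1))
      canvas <- paint(canvas, r, (box_x - 1 - tick_len):(box_x - 2), c(0, 0, 0))
    }
  }
  if (style$draw_x_axis) {
    x0 <- if (style$draw_y_axis) box_x - 1 else box_x + 1
    canvas <- paint(canvas, (box_y + box_h + 1):(box_y + box_h + 2),
                    x0:(box_x + box_w), c(0, 0, 0))
  }

  pitch <- box_w / L
  gap_half <- floor(style$inter_column_gap_px / 2)
  ic <- information_content(unclass(pwm))
  glyphs <- list()
  for (j in seq_len(L)) {
    c0 <- box_x + round((j - 1) * pitch) + gap_half
    c1 <- box_x + round(j * pitch) - gap_half
    if (c1 - c0 < 1) { c0 <- box_x + round((j - 1) * pitch); c1 <- c0 + 1 }
    stack_h <- round(ic[j] / 2 * box_h)
    if (stack_h < 1) next                        # near-uniform column: blank
    hpx <- allocate_heights(pwm[, j], stack_h)
    ord <- order(hpx, decreasing = TRUE)         # largest letter on top
    cur <- box_y + box_h - stack_h               # 0-based top of the stack
    for (i in ord) {
      if (hpx[i] < 1) next
      base <- DNA_BASES[i]
      mask <- glyph_mask(base, hpx[i], c1 - c0)
      rows <- (cur + 1):(cur + hpx[i])
      cols <- (c0 + 1):c1
      rgb <- style$letter_colors[[base]]
      for (ch in 1:3) {
        slab <- canvas[rows, cols, ch, drop = FALSE]
        slab[mask] <- rgb[ch]
        canvas[rows, cols, ch] <- slab
      }
      glyphs[[length(glyphs) + 1L]] <- tibble::tibble(
        position = j, base = base,
        x = c0, y = cur, w = c1 - c0, h = hpx[i])
      cur <- cur + hpx[i]
    }
  }

  pix <- round(canvas)
  storage.mode(pix) <- "integer"
  write_image(pix, out_path)
  structure(list(image_path = out_path,
                 truth_pwm = pwm,
                 logo_box = c(x = box_x, y = box_y, w = box_w, h = box_h),
                 full_scale_px = box_h,
                 glyphs = if (length(glyphs)) do.call(rbind, glyphs)
                          else tibble::tibble(position = integer(),
                                              base = character(),
                                              x = integer(), y = integer(),
                                              w = integer(), h = integer()),
                 style = style),
            class = "render_record")
}

#' @export
print.render_record <- function(x, ...) {
  cat(sprintf("<render_record> %s: %d positions, logo box %dx%d px\n",
              x$image_path, ncol(x$truth_pwm),
              x$logo_box["w"], x$logo_box["h"]))
  invisible(x)
}

#' Render a corpus of synthetic logos with known PWMs
#'
#' The synthetic stand-in for published logo collections: `n` random
#' PWMs (per-column Dirichlet draws) with lengths sampled uniformly from
#' `lengths`, rendered with the given style variants in rotation. Truth
#' PWMs and geometry are persisted to a JSON-lines manifest so a corpus
#' is fully reproducible from its seed.
#'
#' @param n Number of logos.
#' @param style_variants List of [logo_style()] objects, cycled over logos.
#' @param seed Integer seed; the corpus is a pure function of it.
#' @param out_dir Output directory (created if needed).
#' @param lengths Candidate motif lengths (default 6:15).
#' @param concentration Dirichlet concentration for [random_pwm()].
#' @return Invisibly, the list of `render_record`s; the manifest path is
#'   in `attr(, "manifest")`.
#' @export
render_corpus <- function(n, style_variants = list(logo_style()),
                          seed = 1, out_dir,
                          lengths = 6:15, concentration = 1) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- withr::with_seed(seed, {
    lapply(seq_len(n), function(k) {
      style <- style_variants[[(k - 1L) %% length(style_variants) + 1L]]
      L <- sample(lengths, 1L)
      p <- random_pwm(L, concentration = concentration)
      ext <- switch(style$format, png = "png", jpeg = "jpg", gif = "gif")
      path <- file.path(out_dir, sprintf("logo_%04d.%s", k, ext))
      render_logo(p, style, path)
    })
  })
  manifest <- file.path(out_dir, "manifest.jsonl")
  con <- file(manifest, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(jsonlite::toJSON(list(
      path = rec$image_path,
      n_positions = ncol(rec$truth_pwm),
      truth_pwm = as.vector(t(unclass(rec$truth_pwm))),  # row-major A,C,G,T
      logo_box = unname(rec$logo_box),
      full_scale_px = rec$full_scale_px
    ), auto_unbox = TRUE, digits = NA), con)
  }
  attr(records, "manifest") <- manifest
  invisible(records)
}
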