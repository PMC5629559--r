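test_that("axes are detected and the region matches the recorded logo box", {
  rec <- render_logo(random_pwm(7, seed = 21), logo_style(),
                     tempfile(fileext = ".png"))
  cmap <- classify_colors(read_logo(rec$image_path))
  region <- detect_axes(cmap)
  expect_true(region$has_x_axis)
  expect_true(region$has_y_axis)
  box <- rec$logo_box
  expect_lte(abs(region$left - box["x"]), 2)
  expect_lte(abs(region$top - box["y"]), 2)
  expect_lte(abs(region$right - (box["x"] + box["w"])), 2)
  expect_lte(abs(region$bottom - (box["y"] + box["h"])), 2)
  expect_equal(region$y_axis_height_px, rec$full_scale_px)
})

test_that("without axes the region is the colored bounding box", {
  style <- small_style(draw_x_axis = FALSE, draw_y_axis = FALSE, margin_px = 0)
  rec <- render_logo(random_pwm(5, seed = 22), style,
                     tempfile(fileext = ".png"))
  cmap <- classify_colors(read_logo(rec$image_path))
  region <- detect_axes(cmap)
  expect_false(region$has_x_axis)
  expect_false(region$has_y_axis)
  g <- rec$glyphs
  expect_equal(region$left, min(g$x))
  expect_equal(region$right, max(g$x + g$w))
  expect_equal(region$top, min(g$y))
  expect_equal(region$bottom, max(g$y + g$h))
})

test_that("a blank image is a hard error", {
  cmap <- classify_colors(image_of(solid_array(30, 30)))
  expect_error(detect_axes(cmap), "blank image")
})

test_that("full_scale_pixels uses the Y axis when present, else the tallest stack", {
  region <- logolift:::new_logo_region(0, 100, 0, 50, has_x_axis = TRUE,
                                       has_y_axis = TRUE,
                                       y_axis_height_px = 200)
  expect_equal(full_scale_pixels(region, NULL), 200)

  # no axes: tallest stack spans the colored extent
  chr <- white_mat(100, 60)
  chr[41:80, 5:15] <- "green"     # 40-px stack
  chr[61:80, 25:35] <- "red"      # 20-px stack
  cmap <- cmap_of(chr)
  region2 <- detect_axes(cmap)
  expect_equal(full_scale_pixels(region2, cmap), 40)
})

test_that("full scale with a Y axis does not depend on letter content", {
  f <- sapply(c(31, 32), function(s) {
    rec <- render_logo(random_pwm(6, seed = s), logo_style(),
                       tempfile(fileext = ".png"))
    cmap <- classify_colors(read_logo(rec$image_path))
    full_scale_pixels(detect_axes(cmap), cmap)
  })
  expect_equal(f[1], f[2])
})

test_that("segment_columns solves the hand-computable toy projection", {
  chr <- white_mat(4, 10)
  chr[1:4, c(3, 4, 7, 8)] <- "blue"   # projection 0,0,5,5,0,0,5,5,0,0 shape
  cmap <- cmap_of(chr)
  region <- logolift:::new_logo_region(0, 4, 0, 10)
  layout <- segment_columns(cmap, region)
  expect_equal(layout$n_columns, 2)
  b <- layout$boundaries
  expect_equal(unname(b[1, 1]), 0)
  expect_equal(unname(b[2, 2]), 10)
  # the internal boundary falls in the central zero gap
  expect_true(b[1, 2] %in% 4:6)
})

test_that("column counts are recovered on rendered logos and override wins", {
  for (s in c(41, 42)) {
    L <- c(9, 14)[s - 40]
    rec <- render_logo(random_pwm(L, seed = s), logo_style(),
                       tempfile(fileext = ".png"))
    cmap <- classify_colors(read_logo(rec$image_path))
    region <- detect_axes(cmap)
    expect_equal(segment_columns(cmap, region)$n_columns, L)
    # override always wins, with uniform boundaries
    lay12 <- segment_columns(cmap, region, n_override = 12)
    expect_equal(lay12$n_columns, 12)
    expect_lte(max(abs(diff(lay12$boundaries[, 1]) -
                         lay12$column_width_px)), 1)
  }
  expect_error(segment_columns(cmap_of(white_mat(10, 10)),
                               logolift:::new_logo_region(0, 10, 0, 10)),
               "blank region")
  rec <- render_logo(random_pwm(4, seed = 43), small_style(),
                     tempfile(fileext = ".png"))
  cm <- classify_colors(read_logo(rec$image_path))
  expect_error(segment_columns(cm, detect_axes(cm), n_override = 0),
               "positive")
})

test_that("boundaries tile the region without overlap", {
  rec <- render_logo(random_pwm(11, seed = 44), logo_style(),
                     tempfile(fileext = ".png"))
  cmap <- classify_colors(read_logo(rec$image_path))
  region <- detect_axes(cmap)
  lay <- segment_columns(cmap, region)
  b <- lay$boundaries
  expect_true(all(b[, 2] > b[, 1]))
  expect_true(all(b[-1, 1] == b[-nrow(b), 2]))   # contiguous half-open tiles
  covered <- sum(b[, 2] - b[, 1])
  expect_gte(covered / (region$right - region$left), 0.95)
})

test_that("measure_column counts pixel rows per nucleotide color", {
  chr <- white_mat(100, 30)
  chr[11:60, 3:12] <- "green"          # A glyph, 50 rows
  chr[21:60, 18:27] <- "green"         # A glyph, 40 rows
  chr[61:80, 18:27] <- "blue"          # C glyph, 20 rows beneath
  cmap <- cmap_of(chr)
  region <- logolift:::new_logo_region(0, 100, 0, 30)

  m1 <- measure_column(cmap, region, c(0, 15))
  expect_equal(m1$stack_height_px, 50)
  expect_equal(m1$letter_heights_px, c(A = 50, C = 0, G = 0, T = 0))

  m2 <- measure_column(cmap, region, c(15, 30))
  expect_equal(m2$stack_height_px, 60)
  expect_equal(m2$letter_heights_px, c(A = 40, C = 20, G = 0, T = 0))

  expect_error(measure_column(cmap, region, c(20, 40)), "outside")
})

test_that("measured heights match recorded glyph boxes within 2 px", {
  rec <- render_logo(random_pwm(6, seed = 45), logo_style(),
                     tempfile(fileext = ".png"))
  cmap <- classify_colors(read_logo(rec$image_path))
  region <- detect_axes(cmap)
  lay <- segment_columns(cmap, region)
  for (j in seq_len(lay$n_columns)) {
    m <- measure_column(cmap, region, lay$boundaries[j, ])
    g <- rec$glyphs[rec$glyphs$position == j, ]
    expect_lte(abs(m$stack_height_px - sum(g$h)), 2)
    for (k in seq_len(nrow(g))) {
      expect_lte(abs(m$letter_heights_px[[g$base[k]]] - g$h[k]), 2)
    }
  }
})

test_that("heights scale with uniform image upscaling", {
  rec <- render_logo(random_pwm(5, seed = 46), small_style(),
                     tempfile(fileext = ".png"))
  img <- read_logo(rec$image_path)
  up <- array(0L, dim = c(2 * dim(img$pixels)[1], 2 * dim(img$pixels)[2], 3))
  for (ch in 1:3) up[, , ch] <- kronecker(img$pixels[, , ch],
                                          matrix(1L, 2, 2))
  one <- function(im) {
    cmap <- classify_colors(im)
    region <- detect_axes(cmap)
    lay <- segment_columns(cmap, region)
    sapply(seq_len(lay$n_columns), function(j)
      measure_column(cmap, region, lay$boundaries[j, ])$stack_height_px)
  }
  h1 <- one(img)
  h2 <- one(image_of(up))
  expect_equal(length(h1), length(h2))
  expect_true(all(abs(h2 - 2 * h1) <= 2))
})
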