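test_that("degenerate PWMs render with the expected stack heights", {
  # uniform PWM: zero information everywhere, blank logo area
  uni <- pwm(matrix(0.25, 4, 4))
  rec <- render_logo(uni, small_style(), tempfile(fileext = ".png"))
  expect_equal(nrow(rec$glyphs), 0)
  cmap <- classify_colors(read_logo(rec$image_path))
  cc <- color_class_of(cmap)
  expect_true(all(cc %in% c("white", "black")))   # axes only

  # one-hot PWM: five full-height single-letter stacks
  oh <- pwm(matrix(rep(c(0, 0, 1, 0), 5), nrow = 4))
  rec2 <- render_logo(oh, small_style(), tempfile(fileext = ".png"))
  expect_equal(nrow(rec2$glyphs), 5)
  expect_true(all(rec2$glyphs$base == "G"))
  expect_true(all(rec2$glyphs$h == rec2$full_scale_px))

  # half-information column: two equal glyphs totalling half the scale
  hl <- pwm(matrix(c(0.5, 0.5, 0, 0), 4, 1))
  rec3 <- render_logo(hl, small_style(), tempfile(fileext = ".png"))
  expect_equal(sort(rec3$glyphs$base), c("A", "C"))
  expect_lte(abs(rec3$glyphs$h[1] - rec3$glyphs$h[2]), 1)
  expect_lte(abs(sum(rec3$glyphs$h) - rec3$full_scale_px / 2), 1)
})

test_that("glyph heights are proportional to p * I and stack largest-on-top", {
  p <- random_pwm(8, seed = 77)
  rec <- render_logo(p, logo_style(), tempfile(fileext = ".png"))
  ic <- information_content(unclass(p))
  for (j in unique(rec$glyphs$position)) {
    g <- rec$glyphs[rec$glyphs$position == j, ]
    expected <- p[g$base, j] * ic[j] / 2 * rec$full_scale_px
    expect_true(all(abs(g$h - expected) <= 2))
    # drawn top to bottom in decreasing height
    expect_true(all(diff(g$h) <= 0))
    expect_true(all(diff(g$y) > 0))
  }
})

test_that("rendered glyph pixels classify overwhelmingly to their base color", {
  p <- random_pwm(4, seed = 78)
  rec <- render_logo(p, logo_style(), tempfile(fileext = ".png"))
  cmap <- classify_colors(read_logo(rec$image_path))
  cc <- color_class_of(cmap)
  base_class <- c(A = "green", C = "blue", G = "yellow", T = "red")
  g <- rec$glyphs[rec$glyphs$h >= 5, ]
  for (k in seq_len(nrow(g))) {
    blk <- cc[(g$y[k] + 1):(g$y[k] + g$h[k]), (g$x[k] + 1):(g$x[k] + g$w[k])]
    fg <- blk[blk != "white"]
    expect_gte(mean(fg == base_class[[g$base[k]]]), 0.9)
  }
})

test_that("render and measure agree on stack heights (independent paths)", {
  p <- random_pwm(9, seed = 79)
  rec <- render_logo(p, logo_style(), tempfile(fileext = ".png"))
  cmap <- classify_colors(read_logo(rec$image_path))
  region <- detect_axes(cmap)
  lay <- segment_columns(cmap, region)
  full <- full_scale_pixels(region, cmap)
  ic <- information_content(unclass(p))
  for (j in seq_len(lay$n_columns)) {
    m <- measure_column(cmap, region, lay$boundaries[j, ])
    expect_lte(abs(m$stack_height_px - ic[j] / 2 * full), 2)
  }
})

test_that("render_corpus is deterministic given the seed", {
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- render_corpus(6, seed = 5, out_dir = d1)
  r2 <- render_corpus(6, seed = 5, out_dir = d2)
  expect_equal(length(r1), 6)
  for (k in 1:6) {
    expect_identical(unclass(r1[[k]]$truth_pwm), unclass(r2[[k]]$truth_pwm))
    expect_identical(readBin(r1[[k]]$image_path, "raw", 1e6),
                     readBin(r2[[k]]$image_path, "raw", 1e6))
  }
  m1 <- readLines(attr(r1, "manifest"))
  expect_equal(length(m1), 6)
  rec1 <- jsonlite::fromJSON(m1[1])
  expect_equal(rec1$n_positions, ncol(r1[[1]]$truth_pwm))
  expect_equal(rec1$truth_pwm, as.vector(t(unclass(r1[[1]]$truth_pwm))))
  # style variants are honored and cycled
  rv <- render_corpus(3, style_variants = list(logo_style(format = "png"),
                                               logo_style(format = "gif")),
                      seed = 9, out_dir = tempfile())
  expect_match(rv[[1]]$image_path, "\\.png$")
  expect_match(rv[[2]]$image_path, "\\.gif$")
  expect_match(rv[[3]]$image_path, "\\.png$")
})
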