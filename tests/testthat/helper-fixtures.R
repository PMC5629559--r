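# Shared fixtures and independent oracles for the test suite.

# compact render style for fast tests
small_style <- function(...) logo_style(width_px = 360, height_px = 140, ...)

# build a color_map directly from a character matrix of class names
cmap_of <- function(chr) {
  codes <- match(chr, logolift::color_classes())
  stopifnot(!anyNA(codes))
  logolift:::new_color_map(matrix(codes, nrow = nrow(chr)))
}

# blank white character matrix
white_mat <- function(h, w) matrix("white", h, w)

# build a logo_image from an H x W x 3 integer array
image_of <- function(arr, fmt = "png") {
  storage.mode(arr) <- "integer"
  logolift:::new_logo_image(arr, source_format = fmt)
}

# solid-color H x W x 3 array
solid_array <- function(h, w, rgb = c(255, 255, 255)) {
  arr <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- rgb[ch]
  arr
}

# --- independent brute-force oracles ---------------------------------------
# Pure grid searches over the inversion equations; they share no code with
# the package solvers.

oracle_ic_single <- function(p) {
  q <- (1 - p) / 3
  xl <- function(v) ifelse(v > 0, v * log2(v), 0)
  2 + xl(p) + 3 * xl(q)
}

oracle_single <- function(I, step = 1e-6) {
  g <- seq(0.25, 1, by = step)
  g[which.min(abs(oracle_ic_single(g) - I))]
}

# correlation that tolerates dimension mismatch (returns -Inf)
pwm_correlation_safe <- function(a, b) {
  tryCatch(pwm_correlation(a, b), error = function(e) -Inf)
}

oracle_ic_two <- function(p1, r) {
  p2 <- r * p1
  w <- (1 - p1 - p2) / 2
  xl <- function(v) ifelse(v > 0, v * log2(v), 0)
  2 + xl(p1) + xl(p2) + 2 * xl(w)
}

oracle_two <- function(I, r, step = 1e-6) {
  g <- seq(1 / (1 + 3 * r), 1 / (1 + r), by = step)
  g[which.min(abs(oracle_ic_two(g, r) - I))]
}
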