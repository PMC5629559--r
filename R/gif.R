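# Minimal GIF87a/89a codec.
#
# No installed R raster package reads or writes GIF, so the package
# carries its own small codec: a full LZW decoder for reading (first
# frame, non-interlaced) and a fixed-width "literal codes + periodic
# clear" LZW stream for writing. Only what sequence-logo images need is
# supported: a single image block, global or local color table, no
# interlacing, transparency ignored.

read_u16le <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])

# read data sub-blocks starting at offset i (1-based); returns
# list(data = raw, next_i = offset after the block terminator)
read_subblocks <- function(bytes, i) {
  chunks <- list()
  repeat {
    n <- as.integer(bytes[i]); i <- i + 1L
    if (n == 0L) break
    chunks[[length(chunks) + 1L]] <- bytes[i:(i + n - 1L)]
    i <- i + n
  }
  list(data = do.call(c, c(chunks, list(raw(0)))), next_i = i)
}

# LZW decode of a GIF image data stream into pixel indices (0-based)
lzw_decode <- function(data, min_code_size, n_pixels) {
  bits <- as.integer(rawToBits(data))  # LSB-first per byte, GIF order
  clear <- bitwShiftL(1L, min_code_size)
  eoi <- clear + 1L
  pow2 <- 2L^(0:11)

  dict <- vector("list", 4096L)
  reset_dict <- function() {
    d <- vector("list", 4096L)
    for (k in seq_len(clear)) d[[k]] <- k - 1L
    d
  }
  dict <- reset_dict()
  next_code <- eoi + 1L
  width <- min_code_size + 1L

  out <- integer(n_pixels)
  n_out <- 0L
  pos <- 1L
  prev <- -1L
  nbits <- length(bits)

  while (pos + width - 1L <= nbits && n_out < n_pixels) {
    code <- sum(bits[pos:(pos + width - 1L)] * pow2[seq_len(width)])
    pos <- pos + width
    if (code == clear) {
      dict <- reset_dict()
      next_code <- eoi + 1L
      width <- min_code_size + 1L
      prev <- -1L
      next
    }
    if (code == eoi) break
    if (prev < 0L) {
      entry <- dict[[code + 1L]]
      if (is.null(entry)) stop("corrupt GIF: bad first code", call. = FALSE)
    } else {
      if (code < next_code && !is.null(dict[[code + 1L]])) {
        entry <- dict[[code + 1L]]
        if (next_code < 4096L) {
          dict[[next_code + 1L]] <- c(dict[[prev + 1L]], entry[1L])
          next_code <- next_code + 1L
        }
      } else if (code == next_code) {
        p <- dict[[prev + 1L]]
        entry <- c(p, p[1L])
        if (next_code < 4096L) {
          dict[[next_code + 1L]] <- entry
          next_code <- next_code + 1L
        }
      } else {
        stop("corrupt GIF: LZW code out of range", call. = FALSE)
      }
      if (next_code == bitwShiftL(1L, width) && width < 12L) {
        width <- width + 1L
      }
    }
    n <- length(entry)
    if (n_out + n > n_pixels) n <- n_pixels - n_out
    out[(n_out + 1L):(n_out + n)] <- entry[seq_len(n)]
    n_out <- n_out + n
    prev <- code
  }
  if (n_out < n_pixels) {
    stop("corrupt GIF: truncated pixel data", call. = FALSE)
  }
  out
}

# Read the first frame of a GIF as an H x W x 3 integer array (0-255)
read_gif <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 13L ||
      rawToChar(bytes[1:3]) != "GIF" ||
      !(rawToChar(bytes[4:6]) %in% c("87a", "89a"))) {
    stop("not a GIF file: ", path, call. = FALSE)
  }
  packed <- as.integer(bytes[11])
  i <- 14L
  global_ct <- NULL
  if (bitwAnd(packed, 0x80L) != 0L) {
    n_col <- bitwShiftL(2L, bitwAnd(packed, 0x07L))
    global_ct <- matrix(as.integer(bytes[i:(i + 3L * n_col - 1L)]),
                        ncol = 3L, byrow = TRUE)
    i <- i + 3L * n_col
  }
  repeat {
    if (i > length(bytes)) stop("corrupt GIF: no image block", call. = FALSE)
    intro <- as.integer(bytes[i])
    if (intro == 0x3BL) stop("GIF contains no image data", call. = FALSE)
    if (intro == 0x21L) {           # extension: skip label + sub-blocks
      i <- read_subblocks(bytes, i + 2L)$next_i
      next
    }
    if (intro != 0x2CL) stop("corrupt GIF: unexpected block", call. = FALSE)
    w <- read_u16le(bytes[(i + 5L):(i + 6L)])
    h <- read_u16le(bytes[(i + 7L):(i + 8L)])
    ipacked <- as.integer(bytes[i + 9L])
    i <- i + 10L
    if (bitwAnd(ipacked, 0x40L) != 0L) {
      stop("interlaced GIF images are not supported", call. = FALSE)
    }
    ct <- global_ct
    if (bitwAnd(ipacked, 0x80L) != 0L) {
      n_col <- bitwShiftL(2L, bitwAnd(ipacked, 0x07L))
      ct <- matrix(as.integer(bytes[i:(i + 3L * n_col - 1L)]),
                   ncol = 3L, byrow = TRUE)
      i <- i + 3L * n_col
    }
    if (is.null(ct)) stop("GIF has no color table", call. = FALSE)
    min_code_size <- as.integer(bytes[i]); i <- i + 1L
    sb <- read_subblocks(bytes, i)
    idx <- lzw_decode(sb$data, min_code_size, w * h)
    # pixels are stored row-major, top row first
    rgb <- ct[idx + 1L, , drop = FALSE]
    arr <- array(0L, dim = c(h, w, 3L))
    for (ch in 1:3) arr[, , ch] <- matrix(rgb[, ch], nrow = h, byrow = TRUE)
    return(arr)
  }
}

# pack integer codes of a fixed bit width into GIF's LSB-first byte stream
pack_codes <- function(codes, width) {
  bits <- t(outer(codes, 0:(width - 1L),
                  function(cd, s) bitwAnd(bitwShiftR(cd, s), 1L)))
  bits <- as.integer(bits)
  pad <- (8L - length(bits) %% 8L) %% 8L
  packBits(c(bits, integer(pad)), type = "raw")
}

# Write an H x W x 3 integer array (0-255) as a GIF87a file.
# Uses literal LZW codes with a clear code every 2^m - 2 symbols so the
# code width never grows; simple, valid, and adequate for flat-color logos.
write_gif <- function(img, path) {
  h <- dim(img)[1]; w <- dim(img)[2]
  pix <- matrix(as.integer(img), ncol = 3L)          # column-major H*W rows
  key <- pix[, 1] * 65536L + pix[, 2] * 256L + pix[, 3]
  cols <- sort(unique(key))
  if (length(cols) > 256L) {
    stop("too many distinct colors for GIF output (max 256)", call. = FALSE)
  }
  idx0 <- match(key, cols) - 1L                       # 0-based palette index
  # reorder column-major (down columns) to GIF row-major scan order
  idx0 <- as.integer(t(matrix(idx0, nrow = h)))

  m <- max(2L, ceiling(log2(max(length(cols), 2L))))
  clear <- bitwShiftL(1L, m)
  eoi <- clear + 1L
  width <- m + 1L
  run <- bitwShiftL(1L, m) - 2L                       # literals per clear
  starts <- seq(1L, length(idx0), by = run)
  codes <- integer(0)
  for (s in starts) {
    e <- min(s + run - 1L, length(idx0))
    codes <- c(codes, clear, idx0[s:e])
  }
  codes <- c(codes, eoi)
  stream <- pack_codes(codes, width)

  pal <- matrix(0L, nrow = bitwShiftL(1L, m), ncol = 3L)
  pal[seq_along(cols), ] <- cbind(cols %/% 65536L,
                                  (cols %/% 256L) %% 256L,
                                  cols %% 256L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GIF87a"), con)
  writeBin(as.raw(c(w %% 256, w %/% 256, h %% 256, h %/% 256)), con)
  writeBin(as.raw(c(0x80L + (m - 1L), 0L, 0L)), con)  # global table, 2^m colors
  writeBin(as.raw(t(pal)), con)
  writeBin(as.raw(0x2C), con)                          # image descriptor
  writeBin(as.raw(c(0, 0, 0, 0, w %% 256, w %/% 256, h %% 256, h %/% 256, 0)),
           con)
  writeBin(as.raw(m), con)                             # LZW min code size
  pos <- 1L
  while (pos <= length(stream)) {
    n <- min(255L, length(stream) - pos + 1L)
    writeBin(as.raw(n), con)
    writeBin(stream[pos:(pos + n - 1L)], con)
    pos <- pos + n
  }
  writeBin(as.raw(c(0x00, 0x3B)), con)                 # terminator, trailer
  invisible(path)
}
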