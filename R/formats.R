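# Motif file writers/readers. All files are UTF-8 with Unix newlines;
# probabilities are written with 6 decimals and round-trip within 1e-6.

#' Write a PWM as CSV
#'
#' Layout mirrors the usual printed PWM orientation: one row per
#' nucleotide (A, C, G, T), one column per motif position, a header row
#' of position indices and a leading row-label column.
#'
#' @param pwm A [pwm()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pwm_csv <- function(pwm, path) {
  pwm <- as_pwm(pwm)
  L <- ncol(pwm)
  lines <- c(paste(c("base", seq_len(L)), collapse = ","),
             vapply(1:4, function(i)
               paste(c(DNA_BASES[i], sprintf("%.6f", pwm[i, ])),
                     collapse = ","), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PWM from [write_pwm_csv()] output
#' @param path CSV file.
#' @return A `pwm`.
#' @export
read_pwm_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (nrow(d) != 4L || !identical(as.character(d[[1]]), DNA_BASES)) {
    stop("malformed PWM csv: expected 4 rows labelled A, C, G, T",
         call. = FALSE)
  }
  pwm(renormalize(as.matrix(d[, -1, drop = FALSE])))
}

# columns are written rounded to 6 decimals; scale away the rounding
# so the result passes strict column-sum validation
renormalize <- function(m, tol = 5e-6) {
  s <- colSums(m)
  if (any(abs(s - 1) > 4 * tol)) {
    stop("matrix columns do not sum to 1 (not a probability matrix)",
         call. = FALSE)
  }
  sweep(m, 2, s, "/")
}

#' Write a PWM in MEME minimal motif format
#'
#' The letter-probability matrix form of the MEME suite's motif
#' interchange format, with a uniform background; directly consumable by
#' MEME/FIMO/TOMTOM.
#'
#' @param pwm A [pwm()].
#' @param motif_id Motif name written after `MOTIF`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pwm_meme <- function(pwm, motif_id = "motif_1", path) {
  pwm <- as_pwm(pwm)
  L <- ncol(pwm)
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", "",
    paste("MOTIF", motif_id),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", L),
    vapply(seq_len(L), function(j)
      paste(sprintf("%.6f", pwm[, j]), collapse = " "), character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read the first motif of a MEME minimal motif file
#' @param path MEME motif file.
#' @return A `motif_record`: list with `id`, `pwm`, `source_dialect`.
#' @export
read_pwm_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mline <- grep("^MOTIF\\b", lines)
  if (!length(mline)) stop("no MOTIF block found", call. = FALSE)
  id <- trimws(sub("^MOTIF\\s*", "", lines[mline[1]]))
  hline <- grep("^letter-probability matrix:", lines)
  hline <- hline[hline > mline[1]][1]
  if (is.na(hline)) stop("no letter-probability matrix found", call. = FALSE)
  w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[hline]))
  rows <- lines[(hline + 1):(hline + w)]
  m <- t(vapply(rows, function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]]), numeric(4)))
  new_motif_record(id, pwm(renormalize(t(m))), "meme")
}

#' Write a PWM in the package's enologos-style dialect
#'
#' A TRANSFAC-like probability table: a `PO A C G T` header then one row
#' per position with its 1-based index and the four probabilities,
#' tab-delimited. This is this package's named dialect for logo-renderer
#' input tables; the historical tool's exact on-disk format is not
#' publicly documented.
#'
#' @param pwm A [pwm()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pwm_enologos <- function(pwm, path) {
  pwm <- as_pwm(pwm)
  lines <- c(paste(c("PO", DNA_BASES), collapse = "\t"),
             vapply(seq_len(ncol(pwm)), function(j)
               paste(c(j, sprintf("%.6f", pwm[, j])), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PWM from [write_pwm_enologos()] output
#' @param path Tab-delimited `PO A C G T` file.
#' @return A `pwm`.
#' @export
read_pwm_enologos <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^PO\\b", lines[1])) {
    stop("malformed enologos table: missing 'PO A C G T' header",
         call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  m <- t(vapply(body, function(s) {
    f <- strsplit(trimws(s), "\\s+")[[1]]
    as.numeric(f[2:5])
  }, numeric(4)))
  pwm(renormalize(t(m)))
}

#' Read a JASPAR position frequency matrix
#'
#' Parses the JASPAR text format: a `>` header line then four rows of
#' counts for A, C, G, T (with or without `A [ ... ]` style brackets).
#' Counts are normalized per column to probabilities.
#'
#' @param path JASPAR `.pfm`/`.jaspar` file.
#' @return A `motif_record`: list with `id`, `pwm`, `source_dialect`.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  header <- grepl("^>", lines)
  id <- if (any(header)) sub("^>\\s*", "", lines[which(header)[1]]) else
    basename(path)
  data_lines <- lines[!header]
  if (length(data_lines) != 4L) {
    stop(sprintf("malformed JASPAR PFM: expected 4 count rows, found %d",
                 length(data_lines)), call. = FALSE)
  }
  counts <- lapply(data_lines, function(s) {
    s <- sub("^\\s*[ACGTacgt]?\\s*\\[?", "", s)
    s <- sub("\\]\\s*$", "", s)
    v <- suppressWarnings(as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
    if (anyNA(v)) stop("malformed JASPAR PFM: non-numeric count",
                       call. = FALSE)
    v
  })
  len <- unique(lengths(counts))
  if (length(len) != 1L) {
    stop("malformed JASPAR PFM: rows have different lengths", call. = FALSE)
  }
  m <- do.call(rbind, counts)
  cs <- colSums(m)
  if (any(cs <= 0)) {
    stop("invalid JASPAR PFM: column with zero total count", call. = FALSE)
  }
  new_motif_record(id, pwm(sweep(m, 2, cs, "/")), "jaspar_pfm")
}

new_motif_record <- function(id, pwm, dialect) {
  structure(list(id = id, pwm = pwm, source_dialect = dialect),
            class = "motif_record")
}

#' @export
print.motif_record <- function(x, ...) {
  cat(sprintf("<motif_record> %s (%s)\n", x$id, x$source_dialect))
  print(x$pwm, ...)
  invisible(x)
}
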