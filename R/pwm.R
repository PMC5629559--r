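#' DNA alphabet used throughout the package
#'
#' Row order of every PWM is fixed to A, C, G, T, matching the usual
#' index convention for DNA motifs.
#' @keywords internal
DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' A PWM is a 4 x L matrix of per-position nucleotide probabilities with
#' rows fixed to A, C, G, T (top to bottom) and every column summing to 1.
#' It is the digital form of a DNA binding motif: column `j` gives the
#' probability of observing each base at motif position `j`.
#'
#' @param probs Numeric matrix (4 rows) or vector coercible to one; rows
#'   are taken to be A, C, G, T in that order.
#' @return A `pwm` object (a classed numeric matrix with rownames A,C,G,T).
#' @examples
#' pwm(matrix(c(1, 0, 0, 0, 0.25, 0.25, 0.25, 0.25), nrow = 4))
#' @export
pwm <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) {
    stop("a PWM must have exactly 4 rows (A, C, G, T)", call. = FALSE)
  }
  storage.mode(probs) <- "double"
  rownames(probs) <- DNA_BASES
  colnames(probs) <- NULL
  out <- structure(probs, class = c("pwm", "matrix", "array"))
  validate_pwm(out)
  out
}

#' @rdname pwm
#' @param x Object to test or coerce.
#' @export
is_pwm <- function(x) inherits(x, "pwm")

#' @rdname pwm
#' @export
as_pwm <- function(x) if (is_pwm(x)) x else pwm(x)

#' Validate PWM invariants
#'
#' Checks that all entries lie in \[0, 1\], every column sums to 1 within
#' 1e-9, and there is at least one column.
#'
#' @param x A `pwm` or 4-row matrix.
#' @param tol Column-sum tolerance.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_pwm <- function(x, tol = 1e-9) {
  if (ncol(x) < 1L) stop("a PWM needs at least one column", call. = FALSE)
  if (anyNA(x)) stop("PWM contains missing values", call. = FALSE)
  if (any(x < -tol) || any(x > 1 + tol)) {
    stop("PWM entries must lie in [0, 1]", call. = FALSE)
  }
  bad <- abs(colSums(x) - 1) > tol
  if (any(bad)) {
    stop(sprintf("PWM column(s) %s do not sum to 1",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.pwm <- function(x, digits = 4, ...) {
  cat(sprintf("<pwm> %d position%s\n", ncol(x), if (ncol(x) == 1) "" else "s"))
  m <- unclass(x)
  colnames(m) <- seq_len(ncol(m))
  print(round(m, digits), ...)
  invisible(x)
}

#' Information content of a PWM column
#'
#' For a DNA probability column the information content is
#' `I = 2 - H` bits, where `H = -sum(p * log2(p))` is the Shannon entropy
#' (with the convention `0 * log2(0) = 0`). It ranges from 0 bits for the
#' uniform column to 2 bits for a certain base, and equals the total
#' letter-stack height in a sequence logo.
#'
#' @param col Numeric 4-vector of probabilities summing to 1, or a `pwm`
#'   (in which case a value per column is returned).
#' @param tol Normalisation tolerance.
#' @return Information content in bits, in \[0, 2\].
#' @examples
#' information_content(c(0.25, 0.25, 0.25, 0.25)) # 0
#' information_content(c(1, 0, 0, 0))             # 2
#' @export
information_content <- function(col, tol = 1e-9) {
  if (is.matrix(col)) {
    return(vapply(seq_len(ncol(col)), function(j)
      information_content(col[, j], tol = tol), numeric(1)))
  }
  if (length(col) != 4L || anyNA(col)) {
    stop("column must be a numeric 4-vector", call. = FALSE)
  }
  if (any(col < -tol) || any(col > 1 + tol) || abs(sum(col) - 1) > tol) {
    stop("column is not a normalized probability vector", call. = FALSE)
  }
  i <- 2 + sum(xlog2x(col))
  min(max(i, 0), 2)
}

# p * log2(p) with 0 log 0 = 0; vectorized
xlog2x <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}

#' Draw a random PWM
#'
#' Each column is an independent Dirichlet draw with a common
#' concentration parameter. `concentration = 1` gives columns uniform on
#' the probability simplex (the corpus condition used for round-trip
#' evaluation); small values give sharp, informative columns and large
#' values near-uniform ones.
#'
#' @param length Number of motif positions (L >= 1).
#' @param concentration Positive Dirichlet concentration per base.
#' @param seed Optional integer seed; when supplied the draw is
#'   reproducible and the caller's RNG state is untouched.
#' @return A `pwm` of the requested length.
#' @examples
#' random_pwm(8, seed = 42)
#' @export
random_pwm <- function(length, concentration = 1, seed = NULL) {
  if (!is.numeric(length) || length(length) != 1L || length < 1) {
    stop("`length` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("`concentration` must be positive", call. = FALSE)
  }
  draw <- function() {
    g <- matrix(stats::rgamma(4L * length, shape = concentration),
                nrow = 4L)
    # guard against all-zero columns at tiny concentration
    zero <- colSums(g) == 0
    if (any(zero)) g[cbind(sample.int(4L, sum(zero), replace = TRUE),
                           which(zero))] <- 1
    pwm(sweep(g, 2, colSums(g), "/"))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Correlation between two PWMs
#'
#' The reconstruction accuracy metric: Pearson correlation between the
#' two matrices flattened entry-wise in fixed row-major (A,C,G,T) order.
#' `method = "percol"` instead averages per-column Pearson correlations.
#'
#' @param a,b `pwm` objects of identical dimensions.
#' @param method `"flat"` (default) or `"percol"`.
#' @return Correlation coefficient in \[-1, 1\]. Two constant (e.g. both
#'   uniform) matrices that are equal within 1e-9 give 1; a constant
#'   matrix otherwise is an error since Pearson is undefined there.
#' @examples
#' p <- random_pwm(5, seed = 1)
#' pwm_correlation(p, p) # 1
#' @export
pwm_correlation <- function(a, b, method = c("flat", "percol")) {
  method <- match.arg(method)
  if (!all(dim(a) == dim(b))) {
    stop("PWM dimensions differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  }
  corr1 <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      if (max(abs(x - y)) <= 1e-9) return(1)
      stop("correlation undefined: constant matrix", call. = FALSE)
    }
    stats::cor(x, y)
  }
  if (method == "flat") {
    # t() so entries flatten row-major: all of row A, then C, G, T
    corr1(as.vector(t(unclass(a))), as.vector(t(unclass(b))))
  } else {
    mean(vapply(seq_len(ncol(a)), function(j) corr1(a[, j], b[, j]),
                numeric(1)))
  }
}
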