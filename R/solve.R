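#' Information content of a single-strong column as a function of p_1st
#'
#' Under the single-strong model one base has probability `p` and the
#' other three share the remainder equally, so
#' `I(p) = 2 + p log2 p + (1 - p) log2((1 - p)/3)`.
#' Monotone increasing on \[0.25, 1\] with I(0.25) = 0 and I(1) = 2.
#' @keywords internal
single_strong_ic <- function(p) {
  2 + xlog2x(p) + 3 * xlog2x((1 - p) / 3)
}

#' Pre-computed information-content lookup table
#'
#' Tabulates the single-strong information content `I(p_1st)` on a regular
#' probability grid over \[0.25, 1\]. The table brackets the inverse map
#' (measured stack height in bits back to the strong-letter probability);
#' [solve_single_strong()] refines the bracketed root by bisection.
#'
#' @param step Grid spacing in probability units (0 < step <= 0.25).
#' @return A `lookup_table`: tibble with columns `p_1st` and `I` (bits),
#'   `I` strictly increasing from 0 to 2.
#' @examples
#' build_lookup()      # 76 rows, p_1st = 0.25, 0.26, ..., 1.00
#' @export
build_lookup <- function(step = 0.01) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0 || step > 0.25) {
    stop("`step` must be in (0, 0.25]", call. = FALSE)
  }
  p <- seq(0.25, 1, by = step)
  if (p[length(p)] < 1) p <- c(p, 1)
  tbl <- tibble::tibble(p_1st = p, I = single_strong_ic(p))
  class(tbl) <- c("lookup_table", class(tbl))
  tbl
}

# shared default table, built once per session
the <- new.env(parent = emptyenv())
default_lookup <- function() {
  if (is.null(the$lookup)) the$lookup <- build_lookup(0.01)
  the$lookup
}

# clamp measured IC into [0, 2], tolerating small anti-aliasing overshoot
clamp_ic <- function(I, slack = 0.05) {
  if (!is.numeric(I) || length(I) != 1L || is.na(I)) {
    stop("information content must be a single number", call. = FALSE)
  }
  if (I < -slack || I > 2 + slack) {
    stop(sprintf("information content %.4f outside [0, 2] beyond tolerance",
                 I), call. = FALSE)
  }
  min(max(I, 0), 2)
}

# bisection on a monotone increasing f over [lo, hi] to |f - target| <= tol
bisect_root <- function(f, target, lo, hi, tol = 1e-4, max_iter = 80L) {
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v - target) <= tol) return(mid)
    if (v < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Invert information content for a single strong letter
#'
#' Solves `I = 2 + p log2 p + 3 q log2 q`, `q = (1 - p)/3`, for the strong
#' letter's probability `p` on \[0.25, 1\]. The lookup table supplies the
#' bracketing interval, bisection refines to 1e-4 bits.
#'
#' @param I Measured information content in bits; values outside \[0, 2\]
#'   by at most 0.05 bits (pixel/anti-aliasing slack) are clamped, larger
#'   excursions are an error.
#' @param table A [build_lookup()] table; the package default if missing.
#' @return The strong-letter probability `p_1st` in \[0.25, 1\].
#' @examples
#' solve_single_strong(2)   # 1
#' solve_single_strong(0)   # 0.25
#' solve_single_strong(1)   # ~0.811
#' @export
solve_single_strong <- function(I, table = NULL) {
  if (is.null(table)) table <- default_lookup()
  I <- clamp_ic(I)
  if (I <= 0) return(0.25)
  if (I >= 2) return(1)
  idx <- findInterval(I, table$I, rightmost.closed = TRUE)
  lo <- table$p_1st[idx]
  hi <- table$p_1st[min(idx + 1L, nrow(table))]
  bisect_root(single_strong_ic, I, lo, hi, tol = 1e-4)
}

# IC of a two-strong column (p1, r*p1, w, w), w = (1 - (1+r) p1)/2
two_strong_ic <- function(p1, r) {
  p2 <- r * p1
  w <- (1 - p1 - p2) / 2
  2 + xlog2x(p1) + xlog2x(p2) + 2 * xlog2x(w)
}

#' Invert information content for two strong letters
#'
#' Given the measured column information content and the pixel-height
#' ratio `r = h_2nd / h_1st` of the two tallest letters, solves
#' `I = 2 + p1 log2 p1 + p2 log2 p2 + 2 w log2 w` with `p2 = r * p1` and
#' `w = (1 - p1 - p2)/2` for `(p1, p2)`. `I` is monotone increasing in
#' `p1` on the feasible interval `[1/(1+3r), 1/(1+r)]` (from "all weak
#' letters equal" up to "weak letters zero"), so bisection applies.
#'
#' @param I Measured information content in bits (clamped as in
#'   [solve_single_strong()]).
#' @param height_ratio Ratio `h_2nd / h_1st` in (0, 1\].
#' @param slack Bits of tolerated overshoot beyond the feasible IC range
#'   before the pair is declared inconsistent.
#' @return List with `p_1st`, `p_2nd`, and `ok` (FALSE when the I /
#'   ratio pair is infeasible and the caller should fall back to the
#'   single-strong model).
#' @examples
#' solve_two_strong(1, 1)     # p1 = p2 = 0.5
#' solve_two_strong(0, 1)     # uniform column
#' @export
solve_two_strong <- function(I, height_ratio, slack = 0.05) {
  r <- height_ratio
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0 || r > 1) {
    stop("`height_ratio` must be in (0, 1]", call. = FALSE)
  }
  I <- clamp_ic(I)
  lo <- 1 / (1 + 3 * r)
  hi <- 1 / (1 + r)
  I_lo <- two_strong_ic(lo, r)
  I_hi <- two_strong_ic(hi, r)
  if (I > I_hi) {
    if (I - I_hi <= slack) {
      return(list(p_1st = hi, p_2nd = r * hi, ok = TRUE))
    }
    return(list(p_1st = NA_real_, p_2nd = NA_real_, ok = FALSE))
  }
  if (I <= I_lo) {
    if (I_lo - I <= slack) {
      return(list(p_1st = lo, p_2nd = r * lo, ok = TRUE))
    }
    return(list(p_1st = NA_real_, p_2nd = NA_real_, ok = FALSE))
  }
  if (I >= I_hi) {
    return(list(p_1st = hi, p_2nd = r * hi, ok = TRUE))
  }
  p1 <- bisect_root(function(p) two_strong_ic(p, r), I, lo, hi, tol = 1e-4)
  list(p_1st = p1, p_2nd = r * p1, ok = TRUE)
}

#' Estimate one column's probabilities from pixel measurements
#'
#' Converts the measured letter-stack height and per-letter pixel heights
#' of one logo column into a probability 4-vector. The stack height gives
#' the information content, `I = 2 * stack_height_px / full_scale_px`.
#' If the second-tallest letter spans at least `secondary_min_px` pixel
#' rows it counts as a strong secondary letter and the two-strong
#' inversion is used with `r = h_2nd / h_1st`; otherwise the
#' single-strong inversion is used and the three remaining letters share
#' the residual probability equally.
#'
#' @param stack_height_px Total stack height in pixel rows.
#' @param letter_heights_px Named numeric vector (names among A,C,G,T) of
#'   per-letter pixel heights.
#' @param full_scale_px Pixel height corresponding to 2 bits.
#' @param secondary_min_px Minimum pixel rows for a strong secondary
#'   letter (default 3).
#' @return A `column_estimate`: list with `probs` (named 4-vector summing
#'   to 1), `info_content`, `case_used` (`"single_strong"` or
#'   `"two_strong"`), `top_letter`, `second_letter`, and `warnings`.
#' @examples
#' estimate_column(50, c(C = 25, T = 25), 100)  # two_strong, 0.5 / 0.5
#' @export
estimate_column <- function(stack_height_px, letter_heights_px,
                            full_scale_px, secondary_min_px = 3) {
  h <- stats::setNames(numeric(4), DNA_BASES)
  if (length(letter_heights_px)) {
    nm <- names(letter_heights_px)
    if (is.null(nm) || !all(nm %in% DNA_BASES)) {
      stop("letter heights must be named with bases A, C, G, T",
           call. = FALSE)
    }
    h[nm] <- letter_heights_px
  }
  if (any(h < 0)) stop("letter heights must be nonnegative", call. = FALSE)
  if (all(h == 0) || stack_height_px <= 0) {
    stop("empty column: no letter pixels", call. = FALSE)
  }
  if (full_scale_px <= 0) stop("full scale must be positive", call. = FALSE)

  I <- clamp_ic(2 * stack_height_px / full_scale_px)
  # tallest and second tallest; ties broken alphabetically (h is in
  # A,C,G,T order and order() is stable)
  ord <- order(h, decreasing = TRUE)
  top <- DNA_BASES[ord[1L]]
  second <- DNA_BASES[ord[2L]]
  h1 <- h[ord[1L]]
  h2 <- h[ord[2L]]
  warnings <- character()

  two_strong <- h2 >= secondary_min_px
  probs <- stats::setNames(numeric(4), DNA_BASES)
  case_used <- "single_strong"

  if (two_strong) {
    sol <- solve_two_strong(I, min(h2 / h1, 1))
    if (sol$ok) {
      case_used <- "two_strong"
      weak <- (1 - sol$p_1st - sol$p_2nd) / 2
      probs[] <- weak
      probs[top] <- sol$p_1st
      probs[second] <- sol$p_2nd
    } else {
      warnings <- c(warnings, sprintf(
        "two-strong inversion infeasible (I=%.3f, r=%.3f); using single-strong model",
        I, h2 / h1))
      two_strong <- FALSE
    }
  }
  if (!two_strong) {
    p1 <- solve_single_strong(I)
    probs[] <- (1 - p1) / 3
    probs[top] <- p1
  }

  structure(list(probs = probs,
                 info_content = I,
                 case_used = case_used,
                 top_letter = top,
                 second_letter = if (case_used == "two_strong") second else NA_character_,
                 warnings = warnings),
            class = "column_estimate")
}
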