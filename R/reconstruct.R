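#' Reconstruction options
#'
#' @param n_columns_override Known number of motif positions, used when
#'   column counting fails on fused or low-resolution logos.
#' @param crop Optional rectangle `c(x, y, w, h)` (0-based left/top,
#'   pixels) applied before any analysis -- the manual rescue for images
#'   that contain more than the pure logo.
#' @param secondary_min_px Minimum pixel rows for a strong secondary
#'   letter (default 3).
#' @param flatten_alpha Composite PNG alpha over white instead of
#'   rejecting the file.
#' @param noise_min_component_px Connected components smaller than this
#'   are removed as noise (default 4).
#' @return A `recon_config` list.
#' @export
recon_config <- function(n_columns_override = NULL, crop = NULL,
                         secondary_min_px = 3, flatten_alpha = FALSE,
                         noise_min_component_px = 4) {
  if (!is.null(n_columns_override) &&
      (!is.numeric(n_columns_override) || n_columns_override < 1)) {
    stop("`n_columns_override` must be a positive count", call. = FALSE)
  }
  if (secondary_min_px < 1 || noise_min_component_px < 1) {
    stop("pixel thresholds must be positive", call. = FALSE)
  }
  structure(list(n_columns_override = n_columns_override,
                 crop = crop,
                 secondary_min_px = secondary_min_px,
                 flatten_alpha = isTRUE(flatten_alpha),
                 noise_min_component_px = noise_min_component_px),
            class = "recon_config")
}

#' Reconstruct a PWM from a sequence-logo image
#'
#' Runs the full pipeline: load the image (optionally cropping first),
#' classify every pixel to the six reference colors, remove background
#' noise, detect axes and the pure logo region, fix the 2-bit pixel
#' scale, segment the region into letter columns, then for each column
#' measure the stack and letter heights and invert the information
#' content into probabilities. Recoverable anomalies (an infeasible
#' two-strong inversion, a column with no letter pixels) produce a
#' uniform or fallback column plus a warning in the result rather than an
#' error; hard errors are reserved for unreadable or blank input.
#'
#' @param path Path to a logo image (`.png`, `.jpg`, `.jpeg`, `.gif`), or
#'   a `logo_image` already in memory.
#' @param config A [recon_config()].
#' @return A `logo_reconstruction`: list with `pwm`, `per_column` (tibble
#'   of per-position estimates), `region`, `layout`, `full_scale_px`,
#'   and `warnings`.
#' @examples
#' \donttest{
#' tmp <- tempfile(fileext = ".png")
#' rec <- render_logo(random_pwm(8, seed = 1), logo_style(), tmp)
#' fit <- reconstruct_logo(tmp)
#' pwm_correlation(fit$pwm, rec$truth_pwm)
#' }
#' @export
reconstruct_logo <- function(path, config = recon_config()) {
  img <- if (inherits(path, "logo_image")) path
         else read_logo(path, flatten_alpha = config$flatten_alpha)
  if (!is.null(config$crop)) img <- crop_logo(img, config$crop)

  cmap <- classify_colors(img)
  cmap <- remove_noise(cmap, min_component_px = config$noise_min_component_px)
  region <- detect_axes(cmap)
  full_scale <- full_scale_pixels(region, cmap)
  layout <- segment_columns(cmap, region,
                            n_override = config$n_columns_override)

  warnings <- character()
  if (!is.null(config$n_columns_override)) {
    detected <- tryCatch(segment_columns(cmap, region)$n_columns,
                         error = function(e) NA_integer_)
    if (!is.na(detected) && detected != layout$n_columns) {
      warnings <- c(warnings, sprintf(
        "detected %d columns but override requested %d; override wins",
        detected, layout$n_columns))
    }
  }

  n <- layout$n_columns
  est <- vector("list", n)
  for (j in seq_len(n)) {
    meas <- measure_column(cmap, region, layout$boundaries[j, ])
    if (meas$stack_height_px == 0 || all(meas$letter_heights_px == 0)) {
      warnings <- c(warnings, sprintf(
        "column %d has no letter pixels; filled with uniform 0.25", j))
      est[[j]] <- structure(list(
        probs = stats::setNames(rep(0.25, 4), DNA_BASES),
        info_content = 0, case_used = "single_strong",
        top_letter = NA_character_, second_letter = NA_character_,
        warnings = character()), class = "column_estimate")
      next
    }
    e <- estimate_column(meas$stack_height_px, meas$letter_heights_px,
                         full_scale, secondary_min_px = config$secondary_min_px)
    if (length(e$warnings)) {
      warnings <- c(warnings, sprintf("column %d: %s", j, e$warnings))
    }
    est[[j]] <- e
  }

  probs <- vapply(est, function(e) e$probs, numeric(4))
  per_column <- tibble::tibble(
    position = seq_len(n),
    A = probs[1, ], C = probs[2, ], G = probs[3, ], T = probs[4, ],
    info_content = vapply(est, function(e) e$info_content, numeric(1)),
    case_used = vapply(est, function(e) e$case_used, character(1)),
    top_letter = vapply(est, function(e) e$top_letter, character(1)),
    second_letter = vapply(est, function(e) e$second_letter, character(1))
  )

  structure(list(pwm = pwm(probs),
                 per_column = per_column,
                 region = region,
                 layout = layout,
                 full_scale_px = full_scale,
                 warnings = warnings),
            class = "logo_reconstruction")
}

#' @export
print.logo_reconstruction <- function(x, ...) {
  cat(sprintf("<logo_reconstruction> %d positions, mean IC %.2f bits\n",
              ncol(x$pwm), mean(x$per_column$info_content)))
  if (length(x$warnings)) {
    cat(sprintf("  %d warning(s); first: %s\n", length(x$warnings),
                x$warnings[1]))
  }
  print(x$pwm, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-position estimates of a reconstruction
#'
#' @param x A [reconstruct_logo()] result.
#' @param ... Unused.
#' @return Tibble with one row per motif position: probabilities A, C,
#'   G, T, information content, and which inversion case was used.
#' @export
tidy.logo_reconstruction <- function(x, ...) x$per_column

#' One-row summary of a reconstruction
#'
#' @param x A [reconstruct_logo()] result.
#' @param ... Unused.
#' @return One-row tibble: position count, total and mean information
#'   content, axis flags, warning count.
#' @export
glance.logo_reconstruction <- function(x, ...) {
  tibble::tibble(
    n_positions = ncol(x$pwm),
    total_ic = sum(x$per_column$info_content),
    mean_ic = mean(x$per_column$info_content),
    has_x_axis = x$region$has_x_axis,
    has_y_axis = x$region$has_y_axis,
    full_scale_px = x$full_scale_px,
    n_warnings = length(x$warnings)
  )
}
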