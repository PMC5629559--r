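#' Round-trip accuracy evaluation on a synthetic corpus
#'
#' Renders `n` logos from random PWMs, reconstructs each image, and
#' scores every logo by the Pearson correlation between the flattened
#' reconstructed and true matrices -- the same accuracy measure used to
#' benchmark reconstruction against published logo collections, here on
#' a corpus whose truth is known by construction. Deterministic given
#' the seed.
#'
#' @param n Number of logos.
#' @param seed Integer seed for PWMs and lengths.
#' @param style_variants List of [logo_style()]s cycled over the corpus.
#' @param out_dir Where images and the manifest go (default: a session
#'   temporary directory).
#' @param lengths,concentration Passed to [render_corpus()].
#' @param config A [recon_config()] applied to every reconstruction.
#' @return A `logo_eval`: list with `per_logo` (tibble: path, length,
#'   correlation, warnings, error), `n_logos`, `failures`, and summary
#'   statistics `median`, `minimum`, `mean` over successful logos.
#' @examples
#' \donttest{
#' ev <- eval_roundtrip(5, seed = 7)
#' ev$median
#' }
#' @export
eval_roundtrip <- function(n, seed = 1, style_variants = list(logo_style()),
                           out_dir = tempfile("logo_corpus_"),
                           lengths = 6:15, concentration = 1,
                           config = recon_config()) {
  records <- render_corpus(n, style_variants = style_variants, seed = seed,
                           out_dir = out_dir, lengths = lengths,
                           concentration = concentration)
  rows <- lapply(records, function(rec) {
    res <- tryCatch({
      fit <- reconstruct_logo(rec$image_path, config)
      list(corr = pwm_correlation(fit$pwm, rec$truth_pwm),
           n_warn = length(fit$warnings), err = NA_character_)
    }, error = function(e) {
      list(corr = NA_real_, n_warn = 0L, err = conditionMessage(e))
    })
    tibble::tibble(path = rec$image_path,
                   n_positions = ncol(rec$truth_pwm),
                   correlation = res$corr,
                   n_warnings = res$n_warn,
                   error = res$err)
  })
  per_logo <- do.call(rbind, rows)
  ok <- per_logo$correlation[!is.na(per_logo$correlation)]
  structure(list(per_logo = per_logo,
                 n_logos = n,
                 failures = sum(is.na(per_logo$correlation)),
                 correlations = ok,
                 median = stats::median(ok),
                 minimum = if (length(ok)) min(ok) else NA_real_,
                 mean = mean(ok)),
            class = "logo_eval")
}

#' @export
print.logo_eval <- function(x, ...) {
  cat(sprintf(
    "<logo_eval> %d logos, %d failure(s)\n  correlation median %.4f, min %.4f, mean %.4f\n",
    x$n_logos, x$failures, x$median, x$minimum, x$mean))
  invisible(x)
}

#' Per-logo results of an evaluation
#' @param x A [eval_roundtrip()] result.
#' @param ... Unused.
#' @return Tibble with one row per logo.
#' @export
tidy.logo_eval <- function(x, ...) x$per_logo

#' One-row summary of an evaluation
#' @param x A [eval_roundtrip()] result.
#' @param ... Unused.
#' @return One-row tibble with corpus size, failures, and correlation
#'   summary statistics.
#' @export
glance.logo_eval <- function(x, ...) {
  tibble::tibble(n_logos = x$n_logos, failures = x$failures,
                 median = x$median, minimum = x$minimum, mean = x$mean)
}

#' Correlation distribution plot for an evaluation
#'
#' Boxplot of per-logo correlations, the usual way round-trip accuracy
#' over a logo collection is reported.
#'
#' @param object A [eval_roundtrip()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @export
autoplot.logo_eval <- function(object, ...) {
  d <- object$per_logo[!is.na(object$per_logo$correlation), ]
  ggplot2::ggplot(d, ggplot2::aes(x = "", y = .data$correlation)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = 3,
                          outlier.colour = "red") +
    ggplot2::labs(x = NULL, y = "PWM correlation (reconstructed vs truth)",
                  title = sprintf("Round-trip accuracy over %d logos",
                                  object$n_logos)) +
    ggplot2::ylim(min(0.9, min(d$correlation)), 1) +
    ggplot2::theme_minimal()
}
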