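#' Spearman rank correlation between two markers
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with the exact
#' permutation p-value for small samples and the t approximation otherwise,
#' as provided by [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return A tibble with `rho` and `p_value`.
#' @examples
#' spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)) # rho = 0.8
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("Rank correlation needs at least 3 complete pairs.",
          class = "spectraef_insufficient_sample")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Rank correlation is undefined for a constant vector.",
          class = "spectraef_insufficient_sample")
  }
  fit <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble(rho = unname(fit$estimate), p_value = fit$p.value)
}

#' Bland-Altman agreement between two measurement methods
#'
#' Quantifies agreement between paired measurements of the same quantity by
#' two methods (here typically the blended-image and iodine-map arterial
#' enhancement fractions): the mean difference (systematic bias), the
#' standard deviation of the differences, and the 95% limits of agreement
#' `bias +/- 1.96 * sd`. Spearman and Pearson correlations are reported
#' alongside. Differences are taken as `x - y`.
#'
#' @param x,y Numeric vectors of equal length (at least 3 complete pairs).
#' @param x_name,y_name Method labels used in printing and plotting.
#' @return An object of class `bland_altman` with fields `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `spearman_rho`, `spearman_p`, `pearson_r`, `n`,
#'   and the per-pair `data` (mean and difference).
#' @examples
#' ba <- bland_altman(c(1.4, 1.6, 1.2, 1.5), c(1.3, 1.5, 1.3, 1.4))
#' ba$bias
#' @export
bland_altman <- function(x, y, x_name = "method_x", y_name = "method_y") {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("Agreement analysis needs at least 3 complete pairs.",
          class = "spectraef_insufficient_sample")
  }
  d <- x - y
  bias <- mean(d)
  sd_diff <- sd(d)
  # correlations are undefined when one method is constant; report NA there
  sp <- if (sd(x) > 0 && sd(y) > 0) spearman_cor(x, y) else
    tibble(rho = NA_real_, p_value = NA_real_)
  structure(
    list(bias = bias,
         sd_diff = sd_diff,
         loa_low = bias - 1.96 * sd_diff,
         loa_high = bias + 1.96 * sd_diff,
         spearman_rho = sp$rho,
         spearman_p = sp$p_value,
         pearson_r = if (sd(x) > 0 && sd(y) > 0) stats::cor(x, y) else NA_real_,
         n = length(x),
         x_name = x_name, y_name = y_name,
         data = tibble(mean = (x + y) / 2, difference = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> %s - %s (n = %d)\n", x$x_name, x$y_name, x$n))
  cat(sprintf("  bias %.3f, SD of differences %.3f\n", x$bias, x$sd_diff))
  cat(sprintf("  95%% limits of agreement: %.3f to %.3f\n",
              x$loa_low, x$loa_high))
  cat(sprintf("  Spearman rho %.3f (p = %.3g); Pearson r %.3f\n",
              x$spearman_rho, x$spearman_p, x$pearson_r))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) {
  tibble(
    term = c("bias", "sd_diff", "loa_low", "loa_high",
             "spearman_rho", "pearson_r"),
    estimate = c(x$bias, x$sd_diff, x$loa_low, x$loa_high,
                 x$spearman_rho, x$pearson_r)
  )
}

#' @rdname bland_altman
#' @exportS3Method generics::glance
glance.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high,
         spearman_rho = x$spearman_rho, spearman_p = x$spearman_p,
         pearson_r = x$pearson_r, n = x$n)
}

#' @rdname bland_altman
#' @param object A `bland_altman` object.
#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = object$bias, color = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dotted", color = "firebrick") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = sprintf("Mean of %s and %s", object$x_name, object$y_name),
      y = sprintf("%s - %s", object$x_name, object$y_name),
      title = sprintf("Bias %.3f, limits of agreement %.3f to %.3f",
                      object$bias, object$loa_low, object$loa_high)
    ) +
    ggplot2::theme_minimal()
}
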