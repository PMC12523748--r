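#' Describe a positive, skewed marker by its median and interquartile range
#'
#' Published cohort summaries report continuous CT markers as
#' `median (Q1, Q3)`. `marker_distribution()` captures one such summary; it is
#' the unit from which synthetic cohorts are generated.
#'
#' @param median Median of the marker (marker units, strictly positive).
#' @param q1,q3 First and third quartiles; must satisfy `0 < q1 < median < q3`.
#'
#' @return An object of class `marker_distribution` (a named list with
#'   `median`, `q1`, `q3`).
#' @examples
#' marker_distribution(1.259, 1.112, 1.469)
#' @export
marker_distribution <- function(median, q1, q3) {
  for (v in list(median = median, q1 = q1, q3 = q3)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort("`median`, `q1` and `q3` must be finite numeric scalars.",
            class = "spectraef_invalid_distribution")
    }
  }
  if (q1 <= 0 || !(q1 < median && median < q3)) {
    abort(
      sprintf(
        "Quartiles must satisfy 0 < q1 < median < q3 (got q1 = %g, median = %g, q3 = %g).",
        q1, median, q3
      ),
      class = "spectraef_invalid_distribution"
    )
  }
  structure(list(median = median, q1 = q1, q3 = q3),
            class = "marker_distribution")
}

#' @export
print.marker_distribution <- function(x, ...) {
  cat(sprintf("<marker_distribution> median %g (Q1 %g, Q3 %g)\n",
              x$median, x$q1, x$q3))
  invisible(x)
}

#' Fit a log-normal to a median/IQR summary
#'
#' Inverts a `median (Q1, Q3)` summary to the parameters of a log-normal
#' distribution: `mu = log(median)` and
#' `sigma = log(q3 / q1) / (2 * qnorm(0.75))`. The resulting distribution has
#' exactly the requested median and, in large samples, the requested IQR. A
#' log-normal is used because the markers are strictly positive and their
#' published quartiles are right-skewed.
#'
#' @param dist A [marker_distribution()].
#'
#' @return A named list with components `mu` and `sigma` (log-scale mean and
#'   standard deviation).
#' @examples
#' lognormal_from_median_iqr(marker_distribution(1.259, 1.112, 1.469))
#' @export
lognormal_from_median_iqr <- function(dist) {
  if (!inherits(dist, "marker_distribution")) {
    dist <- do.call(marker_distribution, as.list(unclass(dist)))
  }
  list(mu = log(dist$median), sigma = log(dist$q3 / dist$q1) / (2 * Z75))
}

# Quantile-matched log-normal draws for one marker.
rlnorm_marker <- function(n, dist) {
  p <- lognormal_from_median_iqr(dist)
  exp(rnorm(n, p$mu, p$sigma))
}
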