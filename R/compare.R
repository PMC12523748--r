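#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS test against a normal distribution with mean and standard
#' deviation estimated from the sample. Because the parameters are estimated,
#' the naive KS p-value is anti-conservative; the Lilliefors correction is
#' used instead. A constant sample is maximally non-normal and returns
#' statistic 1 with p-value 0.
#'
#' @param x Numeric vector, length at least 5.
#' @return A tibble with columns `statistic` and `p_value`.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5) {
    abort("Normality testing needs at least 5 finite observations.",
          class = "spectraef_insufficient_sample")
  }
  if (sd(x) == 0) {
    return(tibble(statistic = 1, p_value = 0))
  }
  fit <- nortest::lillie.test(x)
  tibble(statistic = unname(fit$statistic), p_value = fit$p.value)
}

# Classic Levene test (deviations from group means) for two groups.
levene_two_group <- function(x, y) {
  d <- c(abs(x - mean(x)), abs(y - mean(y)))
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  fit <- stats::oneway.test(d ~ g, var.equal = TRUE)
  list(statistic = unname(fit$statistic), p_value = fit$p.value)
}

#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Rank-sum test for two independent groups. For combined sample sizes up to
#' `exact_limit` the two-sided p-value is computed by exhaustive enumeration
#' of all group assignments of the pooled mid-ranks (so ties are handled
#' exactly); for larger samples a tie-corrected normal approximation without
#' continuity correction is used, matching common statistical-software
#' behavior at cohort-scale n.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param exact_limit Largest combined sample size for which the exact
#'   enumeration is used (default 20).
#' @return A tibble with `statistic` (the U statistic for `x`), `p_value`,
#'   and `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney(c(1, 2, 3, 4), c(10, 11, 12, 13)) # exact p = 2/70
#' @export
mann_whitney <- function(x, y, exact_limit = 20) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exact_limit) {
    idx <- combn(n, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-12)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1 # all observations tied
    } else {
      p <- min(1, 2 * pnorm(-abs(u - mu) / sqrt(sigma2)))
    }
    method <- "normal_approx"
  }
  tibble(statistic = u, p_value = p, method = method)
}

#' Compare a continuous marker between benign and malignant cohorts
#'
#' Implements the normality-gated two-group comparison: both groups are
#' tested for normality ([ks_normality()]) and for variance homogeneity
#' (Levene's test on deviations from group means); the pooled-variance
#' t-test is used only if every gate passes at `alpha_normality`, otherwise
#' the Mann-Whitney U test ([mann_whitney()]). Groups smaller than 5 skip
#' the gates (which are undefined there) and go straight to the rank test.
#'
#' @param benign,malignant Numeric vectors of marker values per cohort.
#' @param alpha_normality Significance level for the normality and variance
#'   gates (default 0.05).
#' @param variable Optional variable name carried into the result.
#' @return A one-row tibble: `variable`, `test_used` (`"t_test"` or
#'   `"mann_whitney"`), `statistic`, `p_value`, and per-cohort
#'   `median (Q1, Q3)` summaries.
#' @export
compare_continuous <- function(benign, malignant, alpha_normality = 0.05,
                               variable = NA_character_) {
  benign <- benign[is.finite(benign)]
  malignant <- malignant[is.finite(malignant)]
  if (length(benign) < 3 || length(malignant) < 3) {
    abort("Each cohort needs at least 3 finite observations.",
          class = "spectraef_insufficient_sample")
  }
  gates_ok <- FALSE
  if (length(benign) >= 5 && length(malignant) >= 5 &&
      sd(benign) > 0 && sd(malignant) > 0) {
    gates_ok <- ks_normality(benign)$p_value > alpha_normality &&
      ks_normality(malignant)$p_value > alpha_normality &&
      levene_two_group(benign, malignant)$p_value > alpha_normality
  }
  if (gates_ok) {
    fit <- stats::t.test(benign, malignant, var.equal = TRUE)
    test_used <- "t_test"
    statistic <- unname(fit$statistic)
    p <- fit$p.value
  } else {
    fit <- mann_whitney(benign, malignant)
    test_used <- "mann_whitney"
    statistic <- fit$statistic
    p <- fit$p_value
  }
  summarise_iqr <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    sprintf("%.3f (%.3f, %.3f)", q[2], q[1], q[3])
  }
  tibble(
    variable = variable,
    test_used = test_used,
    statistic = statistic,
    p_value = p,
    benign_summary = summarise_iqr(benign),
    malignant_summary = summarise_iqr(malignant)
  )
}

#' Compare a categorical feature between cohorts
#'
#' Pearson chi-squared test (without continuity correction) when every
#' expected cell count is at least 5; otherwise Fisher's exact test (for
#' 2 x k tables beyond 2 x 2 this is the Freeman-Halton extension).
#'
#' @param counts A 2 x k matrix of non-negative integer counts (rows =
#'   cohorts, columns = categories). Both margins must be positive.
#' @param variable Optional variable name carried into the result.
#' @return A one-row tibble: `variable`, `test_used` (`"chi_square"` or
#'   `"fisher"`), `statistic` (NA for Fisher), `p_value`, and per-cohort
#'   count summaries.
#' @examples
#' compare_categorical(matrix(c(59, 157, 48, 26), 2))
#' @export
compare_categorical <- function(counts, variable = NA_character_) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.",
          class = "spectraef_degenerate_table")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("Contingency table has an empty margin.",
          class = "spectraef_degenerate_table")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (all(expected >= 5)) {
    fit <- suppressWarnings(chisq.test(counts, correct = FALSE))
    test_used <- "chi_square"
    statistic <- unname(fit$statistic)
  } else {
    fit <- fisher.test(counts)
    test_used <- "fisher"
    statistic <- NA_real_
  }
  fmt <- function(r) paste(sprintf("%d (%.1f%%)", r, 100 * r / sum(r)),
                           collapse = "; ")
  tibble(
    variable = variable,
    test_used = test_used,
    statistic = statistic,
    p_value = fit$p.value,
    benign_summary = fmt(counts[1, ]),
    malignant_summary = fmt(counts[2, ])
  )
}

#' Cohort comparison table for a derived-marker data set
#'
#' Runs [compare_continuous()] on every continuous marker column present and
#' [compare_categorical()] on the categorical features, returning one tidy
#' table shaped like a study baseline-characteristics table.
#'
#' @param data A nodule table with a `cohort` column and derived markers
#'   (see [derive_markers()]).
#' @param alpha_normality Gate level passed to [compare_continuous()].
#' @return A tibble with one row per variable.
#' @export
compare_cohorts <- function(data, alpha_normality = 0.05) {
  data <- as_tibble(data)
  stopifnot("cohort" %in% names(data))
  continuous <- intersect(
    c("max_diameter_mm", "ap_lambda_hu", "ap_nic", "ap_nzeff",
      "vp_lambda_hu", "vp_nic", "vp_nzeff", "aef_s", "aef_d"),
    names(data)
  )
  benign <- dplyr::filter(data, .data$cohort == "benign")
  malignant <- dplyr::filter(data, .data$cohort == "malignant")
  cont <- purrr::map_dfr(continuous, function(v) {
    compare_continuous(benign[[v]], malignant[[v]],
                       alpha_normality = alpha_normality, variable = v)
  })
  categorical <- intersect(c("calcification", "enhanced_blurring",
                             "age_ge50", "female"), names(data))
  cat_rows <- purrr::map_dfr(categorical, function(v) {
    tab <- table(factor(data$cohort, levels = COHORTS), data[[v]])
    compare_categorical(unclass(tab), variable = v)
  })
  dplyr::bind_rows(cont, cat_rows)
}
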