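ORIENTATIONS <- c("higher_is_malignant", "lower_is_malignant")

# Orient scores so that larger values indicate malignancy.
orient_scores <- function(scores, orientation) {
  orientation <- match.arg(orientation, ORIENTATIONS)
  if (orientation == "lower_is_malignant") -scores else scores
}

#' Tie-corrected pairwise AUC
#'
#' The probability that a randomly chosen malignant nodule's (oriented) score
#' exceeds a randomly chosen benign nodule's, counting ties as one half:
#' `(#concordant + 0.5 #tied) / (n_malignant * n_benign)`. This equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores_malignant,scores_benign Numeric score vectors, both
#'   non-empty.
#' @param orientation `"higher_is_malignant"` (default) or
#'   `"lower_is_malignant"`.
#' @return The AUC as a single number in `[0, 1]`.
#' @examples
#' auc_pairwise(c(2, 3, 4), c(0, 1)) # 1
#' @export
auc_pairwise <- function(scores_malignant, scores_benign,
                         orientation = "higher_is_malignant") {
  if (length(scores_malignant) == 0 || length(scores_benign) == 0) {
    abort("Both score groups must be non-empty.", class = "spectraef_empty_group")
  }
  m <- orient_scores(scores_malignant, orientation)
  b <- orient_scores(scores_benign, orientation)
  nm <- length(m); nb <- length(b)
  r <- rank(c(m, b))
  u <- sum(r[seq_len(nm)]) - nm * (nm + 1) / 2
  u / (nm * nb)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance of the pairwise AUC from DeLong placement values,
#' with a Wald interval truncated to `[0, 1]`. When every score is tied the
#' variance is undefined; the full `[0, 1]` interval is returned with a
#' degenerate flag.
#'
#' @inheritParams auc_pairwise
#' @param level Confidence level (default 0.95).
#' @return A tibble with `auc`, `ci_low`, `ci_high`, `se`, `degenerate`.
#' @export
delong_ci <- function(scores_malignant, scores_benign,
                      orientation = "higher_is_malignant", level = 0.95) {
  m <- orient_scores(scores_malignant, orientation)
  b <- orient_scores(scores_benign, orientation)
  nm <- length(m); nb <- length(b)
  if (nm < 2 || nb < 2) {
    abort("DeLong variance needs at least 2 scores per group.",
          class = "spectraef_empty_group")
  }
  auc <- auc_pairwise(m, b)
  # placement of each malignant score among the benign scores, and vice versa
  v10 <- vapply(m, function(s) mean((b < s) + 0.5 * (b == s)), numeric(1))
  v01 <- vapply(b, function(s) mean((m > s) + 0.5 * (m == s)), numeric(1))
  if (length(unique(c(m, b))) == 1L) {
    return(tibble(auc = auc, ci_low = 0, ci_high = 1, se = NA_real_,
                  degenerate = TRUE))
  }
  se <- sqrt(var(v10) / nm + var(v01) / nb)
  z <- qnorm(1 - (1 - level) / 2)
  tibble(
    auc = auc,
    ci_low = max(0, auc - z * se),
    ci_high = min(1, auc + z * se),
    se = se,
    degenerate = FALSE
  )
}

# Empirical ROC curve points (FPR, TPR) over all thresholds, for plotting and
# as the trapezoid route to the AUC.
roc_points <- function(scores_malignant, scores_benign,
                       orientation = "higher_is_malignant") {
  m <- orient_scores(scores_malignant, orientation)
  b <- orient_scores(scores_benign, orientation)
  thr <- sort(unique(c(m, b)), decreasing = TRUE)
  tibble(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) mean(m >= t), numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(b >= t), numeric(1)))
  )
}

#' Youden-index optimal cutoff
#'
#' Scans candidate cutoffs at the midpoints between consecutive distinct
#' sorted scores (plus the two infinite endpoints) and returns the cutoff
#' maximizing Youden's J = sensitivity + specificity - 1. Ties are broken in
#' favor of higher sensitivity, then the lower cutoff.
#'
#' @param scores Numeric marker values, one per nodule.
#' @param malignant Logical vector, `TRUE` for malignant nodules.
#' @param orientation Score orientation, as in [auc_pairwise()].
#' @return A list with `cutoff` (on the original marker scale), `youden_j`,
#'   `confusion` (named vector `tp`, `fp`, `tn`, `fn`), and `degenerate`
#'   (`TRUE` when all scores are identical).
#' @export
youden_cutoff <- function(scores, malignant,
                          orientation = "higher_is_malignant") {
  stopifnot(length(scores) == length(malignant))
  if (!any(malignant) || all(malignant)) {
    abort("Both classes must be present.", class = "spectraef_empty_group")
  }
  s <- orient_scores(scores, orientation)
  uniq <- sort(unique(s))
  if (length(uniq) == 1L) {
    conf <- c(tp = 0L, fp = 0L,
              tn = sum(!malignant), fn = sum(malignant))
    return(list(cutoff = uniq, youden_j = 0, confusion = conf,
                degenerate = TRUE))
  }
  cand <- c(-Inf, (head(uniq, -1) + uniq[-1]) / 2, Inf)
  best <- NULL
  for (cutoff in cand) {
    pred <- s > cutoff
    tp <- sum(pred & malignant); fp <- sum(pred & !malignant)
    fn <- sum(!pred & malignant); tn <- sum(!pred & !malignant)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    j <- sens + spec - 1
    better <- is.null(best) ||
      j > best$j + 1e-12 ||
      (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12) ||
      (abs(j - best$j) <= 1e-12 && abs(sens - best$sens) <= 1e-12 &&
         cutoff < best$cutoff)
    if (better) {
      best <- list(cutoff = cutoff, j = j, sens = sens,
                   conf = c(tp = tp, fp = fp, tn = tn, fn = fn))
    }
  }
  # report the cutoff on the original marker scale
  cutoff_out <- if (orientation == "lower_is_malignant") -best$cutoff else best$cutoff
  list(cutoff = cutoff_out, youden_j = best$j, confusion = best$conf,
       degenerate = FALSE)
}

#' Confusion-matrix metric panel
#'
#' Sensitivity, specificity, accuracy, positive and negative predictive
#' value, and the unnecessary biopsy rate (false positives among benign
#' nodules, `fp / (fp + tn)`, i.e. 1 - specificity) from a confusion table.
#' All values are proportions in `[0, 1]`; multiply by 100 for display.
#'
#' @param tp,fp,tn,fn Confusion counts: true/false positives (malignant
#'   calls) and true/false negatives. `tp + fn` and `tn + fp` must be
#'   positive.
#' @return A one-row tibble with the six metrics. When no nodule is
#'   predicted positive (or negative), PPV (or NPV) is undefined and
#'   returned as `NA`.
#' @examples
#' metric_panel(tp = 134, fp = 24, tn = 107, fn = 56)
#' @export
metric_panel <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0 || tn + fp == 0) {
    abort("Both true classes must be represented.",
          class = "spectraef_empty_group")
  }
  tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    unnecessary_biopsy_rate = fp / (fp + tn)
  )
}

#' Evaluate one marker's diagnostic performance
#'
#' Full single-marker ROC analysis: orientation (auto-detected from cohort
#' medians unless given), tie-corrected AUC with DeLong confidence interval,
#' Youden-optimal cutoff, and the confusion-metric panel at that cutoff.
#' Calcification is scored on the ordinal scale absent (0) < macro (1) <
#' micro (2), reflecting the increasing malignancy association of
#' microcalcification. Records flagged `NA` for the marker are excluded
#' (their count is reported); more than `max_missing` missing is refused.
#'
#' @param data Nodule table with a `cohort` column and the marker column.
#' @param marker Name of the marker column.
#' @param orientation `"auto"` (default), `"higher_is_malignant"` or
#'   `"lower_is_malignant"`.
#' @param level Confidence level for the AUC interval.
#' @param max_missing Maximum tolerated fraction of missing marker values.
#' @return An object of class `roc_eval`; see [tidy.roc_eval()],
#'   [glance.roc_eval()] and [autoplot.roc_eval()].
#' @examples
#' cohort <- simulate_cohort(default_cohort_spec(seed = 3)) |> derive_markers()
#' evaluate_marker(cohort, "aef_d")
#' @export
evaluate_marker <- function(data, marker, orientation = "auto",
                            level = 0.95, max_missing = 0.2) {
  data <- as_tibble(data)
  stopifnot(marker %in% names(data), "cohort" %in% names(data))
  scores <- marker_scores(data[[marker]], marker)
  malignant <- data$cohort == "malignant"
  n_missing <- sum(is.na(scores))
  if (n_missing > max_missing * length(scores)) {
    abort(sprintf("Marker '%s' has %d/%d missing values (> %.0f%% tolerated).",
                  marker, n_missing, length(scores), 100 * max_missing),
          class = "spectraef_excessive_missingness")
  }
  keep <- !is.na(scores)
  scores <- scores[keep]; malignant <- malignant[keep]
  m <- scores[malignant]; b <- scores[!malignant]
  if (orientation == "auto") {
    orientation <- if (median(m) < median(b)) "lower_is_malignant"
                   else "higher_is_malignant"
  }
  ci <- if (length(m) >= 2 && length(b) >= 2) {
    delong_ci(m, b, orientation = orientation, level = level)
  } else {
    tibble(auc = auc_pairwise(m, b, orientation = orientation),
           ci_low = NA_real_, ci_high = NA_real_, se = NA_real_,
           degenerate = TRUE)
  }
  yj <- youden_cutoff(scores, malignant, orientation = orientation)
  metrics <- metric_panel(yj$confusion[["tp"]], yj$confusion[["fp"]],
                          yj$confusion[["tn"]], yj$confusion[["fn"]])
  structure(
    list(marker = marker,
         orientation = orientation,
         auc = ci$auc, ci_low = ci$ci_low, ci_high = ci$ci_high,
         se = ci$se, level = level,
         cutoff = yj$cutoff, youden_j = yj$youden_j,
         confusion = yj$confusion,
         metrics = metrics,
         curve = roc_points(m, b, orientation = orientation),
         n_malignant = length(m), n_benign = length(b),
         n_excluded = n_missing),
    class = "roc_eval"
  )
}

# Ordinal score coding for categorical markers; numeric markers pass through.
marker_scores <- function(x, marker) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.logical(x)) return(as.numeric(x))
  if (identical(marker, "calcification")) {
    return(unname(c(absent = 0, macro = 1, micro = 2)[as.character(x)]))
  }
  abort(sprintf("No score coding for non-numeric marker '%s'.", marker),
        class = "spectraef_invalid_measurement")
}

#' @export
print.roc_eval <- function(x, ...) {
  cat(sprintf("<roc_eval> %s (%s)\n", x$marker, x$orientation))
  cat(sprintf("  AUC %.3f (%.0f%% CI %.3f-%.3f), n = %d malignant / %d benign\n",
              x$auc, 100 * x$level, x$ci_low, x$ci_high,
              x$n_malignant, x$n_benign))
  cat(sprintf("  Youden cutoff %.4g (J = %.3f)\n", x$cutoff, x$youden_j))
  with(as.list(x$metrics), cat(sprintf(
    "  sens %.1f%% | spec %.1f%% | acc %.1f%% | PPV %.1f%% | NPV %.1f%% | unnecessary biopsy %.1f%%\n",
    100 * sensitivity, 100 * specificity, 100 * accuracy,
    100 * ppv, 100 * npv, 100 * unnecessary_biopsy_rate)))
  if (x$n_excluded > 0) {
    cat(sprintf("  %d flagged/missing records excluded\n", x$n_excluded))
  }
  invisible(x)
}

#' Tidy a single-marker ROC evaluation
#'
#' @param x A `roc_eval` object.
#' @param ... Unused.
#' @return One row per confusion metric: `metric`, `estimate`.
#' @exportS3Method generics::tidy
tidy.roc_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "estimate")
}

#' One-row summary of a ROC evaluation
#'
#' @param x A `roc_eval` object.
#' @param ... Unused.
#' @return A one-row tibble: marker, orientation, AUC with CI, cutoff,
#'   Youden J, confusion counts and the metric panel.
#' @exportS3Method generics::glance
glance.roc_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble(marker = x$marker, orientation = x$orientation,
           auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
           cutoff = x$cutoff, youden_j = x$youden_j,
           tp = x$confusion[["tp"]], fp = x$confusion[["fp"]],
           tn = x$confusion[["tn"]], fn = x$confusion[["fn"]]),
    x$metrics
  )
}

#' Plot the empirical ROC curve of a marker evaluation
#'
#' @param object A `roc_eval` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_eval <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("%s: AUC %.3f (%.0f%% CI %.3f-%.3f)",
                      object$marker, object$auc, 100 * object$level,
                      object$ci_low, object$ci_high)
    ) +
    ggplot2::theme_minimal()
}
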