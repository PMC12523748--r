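DEFAULT_COMBINATIONS <- list(
  c("calcification", "ap_lambda_hu", "aef_s"),
  c("calcification", "ap_lambda_hu", "aef_d"),
  c("calcification", "ap_lambda_hu", "aef_s", "aef_d")
)

SINGLE_MARKERS <- c("calcification", "ap_lambda_hu", "aef_s", "aef_d")

#' Run the full marker-evaluation pipeline
#'
#' Orchestrates every stage on one cohort: simulate (or accept) nodule
#' records, derive the spectral markers, compare cohorts, quantify AEF
#' inter-method agreement, run forward-selection logistic regression on the
#' arterial-phase spectral parameters, and evaluate each single marker and
#' marker combination with ROC/Youden analysis. All stages are deterministic
#' given the spec and seed.
#'
#' @param spec A [cohort_spec()]; ignored when `records` is supplied.
#' @param seed Optional seed override for simulation.
#' @param records Optional pre-existing nodule-record table (e.g. read from
#'   CSV); raw measurement columns as in [derive_markers()].
#' @param epsilon Blended-image denominator stability threshold (HU).
#' @param combinations List of character vectors of markers to combine; the
#'   default mirrors the study's three reported combinations.
#' @param entry_alpha,removal_alpha Forward-selection thresholds.
#' @param level Confidence level for AUC intervals.
#' @param stages Which analysis stages to run after marker derivation
#'   (derivation itself always runs). Defaults to all four; restrict when
#'   running tiny worked-example tables through derivation only.
#' @param output_dir Optional directory; when given, the derived-marker CSV,
#'   the comparison table CSV and a JSON report are written there.
#' @return An object of class `aef_report` with components `records`
#'   (marker-extended table), `comparison`, `agreement`, `forward_fit`,
#'   `full_fit`, `evaluation` (one row per marker/combination, a
#'   diagnostic-efficiency table), `flagged` (excluded-record count) and
#'   `provenance`.
#' @examples
#' report <- run_pipeline(default_cohort_spec(seed = 5))
#' report$evaluation[, c("marker", "auc", "unnecessary_biopsy_rate")]
#' @export
run_pipeline <- function(spec = default_cohort_spec(), seed = NULL,
                         records = NULL, epsilon = 1,
                         combinations = DEFAULT_COMBINATIONS,
                         entry_alpha = 0.05, removal_alpha = 0.10,
                         level = 0.95,
                         stages = c("compare", "agree", "fit", "evaluate"),
                         output_dir = NULL) {
  if (length(stages) > 0) stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(records)) {
    records <- simulate_cohort(spec, seed = seed)
    used_seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  } else {
    records <- as_tibble(records)
    used_seed <- NA_integer_
  }

  marked <- derive_markers(records, epsilon = epsilon)
  flagged <- sum(marked$flags != "")
  clean <- dplyr::filter(marked, is.na(.data$flags) | .data$flags == "" |
                           .data$flags == "negative_aef")

  comparison <- if ("compare" %in% stages) compare_cohorts(clean) else NULL
  agreement <- if ("agree" %in% stages) {
    bland_altman(clean$aef_s, clean$aef_d, x_name = "aef_s", y_name = "aef_d")
  } else NULL
  forward_fit <- full_fit <- NULL
  if ("fit" %in% stages) {
    forward_fit <- forward_select(clean,
                                  c("ap_lambda_hu", "ap_nic", "ap_nzeff"),
                                  entry_alpha = entry_alpha,
                                  removal_alpha = removal_alpha)
    full_fit <- fit_logistic(clean, c("ap_lambda_hu", "ap_nic", "ap_nzeff"))
  }
  evaluation <- NULL
  if ("evaluate" %in% stages) {
    singles <- purrr::map(SINGLE_MARKERS, function(m) {
      evaluate_marker(clean, m, level = level)
    })
    combos <- purrr::map(combinations, function(ms) {
      evaluate_combination(clean, ms, level = level)
    })
    evaluation <- purrr::map_dfr(c(singles, combos), glance)
  }

  report <- structure(
    list(records = marked,
         comparison = comparison,
         agreement = agreement,
         forward_fit = forward_fit,
         full_fit = full_fit,
         evaluation = evaluation,
         flagged = flagged,
         provenance = list(seed = used_seed,
                           epsilon = epsilon,
                           level = level,
                           entry_alpha = entry_alpha,
                           removal_alpha = removal_alpha,
                           package_version =
                             as.character(utils::packageVersion("spectraef")))),
    class = "aef_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.aef_report <- function(x, ...) {
  cat(sprintf("<aef_report> %d nodules (%d flagged), seed %s\n",
              nrow(x$records), x$flagged, format(x$provenance$seed)))
  if (!is.null(x$evaluation)) {
    cat("\nDiagnostic efficiency:\n")
    print(dplyr::mutate(
      dplyr::select(x$evaluation, "marker", "auc", "ci_low", "ci_high",
                    "sensitivity", "specificity", "accuracy",
                    "unnecessary_biopsy_rate"),
      dplyr::across(c("sensitivity", "specificity", "accuracy",
                      "unnecessary_biopsy_rate"), function(v) round(100 * v, 1))
    ), n = Inf)
  }
  if (!is.null(x$agreement)) {
    cat(sprintf("\nAEF agreement: bias %.3f, LoA %.3f to %.3f, Spearman rho %.3f\n",
                x$agreement$bias, x$agreement$loa_low, x$agreement$loa_high,
                x$agreement$spearman_rho))
  }
  invisible(x)
}

# Serialize the report's tabular pieces; JSON numbers at full precision.
write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$records,
                   file.path(output_dir, "records_with_markers.csv"),
                   row.names = FALSE)
  if (!is.null(report$comparison)) {
    utils::write.csv(report$comparison,
                     file.path(output_dir, "cohort_comparison.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$evaluation)) {
    utils::write.csv(report$evaluation,
                     file.path(output_dir, "diagnostic_efficiency.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(provenance = report$provenance,
         flagged_records = report$flagged,
         agreement = if (!is.null(report$agreement)) glance(report$agreement),
         forward_path = report$forward_fit$path,
         forward_terms = if (!is.null(report$forward_fit)) tidy(report$forward_fit),
         full_model_terms = if (!is.null(report$full_fit)) tidy(report$full_fit),
         evaluation = report$evaluation),
    file.path(output_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(output_dir)
}

#' Write the small worked-example fixture files
#'
#' Writes three plain-text fixtures used by the test-suite and vignette:
#' the two-nodule worked-example record CSV, the calcification contingency
#' counts, and the reconstructed confusion tables behind the published
#' diagnostic-efficiency panel (counts recovered from the printed
#' sensitivity/specificity and cohort sizes).
#'
#' @param output_dir Writable directory.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    worked_example = file.path(output_dir, "worked_example_records.csv"),
    calcification = file.path(output_dir, "calcification_counts.csv"),
    confusion = file.path(output_dir, "reference_confusion_tables.csv")
  )
  utils::write.csv(worked_example_records(), paths["worked_example"],
                   row.names = FALSE)
  utils::write.csv(
    tibble(cohort = c("benign", "malignant"),
           absent = c(121L, 149L), micro = c(3L, 30L), macro = c(7L, 11L)),
    paths["calcification"], row.names = FALSE
  )
  utils::write.csv(
    tibble(marker = c("calcification", "ap_lambda_hu", "aef_s", "aef_d"),
           tp = c(41L, 131L, 135L, 134L),
           fp = c(10L, 32L, 34L, 24L),
           tn = c(121L, 99L, 97L, 107L),
           fn = c(149L, 59L, 55L, 56L)),
    paths["confusion"], row.names = FALSE
  )
  invisible(paths)
}
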