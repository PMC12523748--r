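#' Fit a binary logistic regression for malignancy
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares) of malignant-vs-benign status on a set of marker columns, with
#' Wald standard errors from the inverse observed information. Fits that run
#' into quasi-complete separation (diverging coefficients with fitted
#' probabilities at the boundary) raise an error rather than returning
#' meaningless estimates.
#'
#' @param data Nodule table containing `cohort` (or a logical `malignant`
#'   column) and the predictor columns.
#' @param predictors Character vector of predictor column names; categorical
#'   markers are coded ordinally as in [evaluate_marker()].
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return An object of class `aef_logit`: the fit plus an odds-ratio table,
#'   variance inflation factors, and (when reached through
#'   [forward_select()]) the selection path.
#' @examples
#' cohort <- simulate_cohort(default_cohort_spec(seed = 11)) |> derive_markers()
#' fit <- fit_logistic(cohort, c("ap_lambda_hu", "ap_nic"))
#' tidy(fit)
#' @export
fit_logistic <- function(data, predictors, max_iter = 100, tol = 1e-8) {
  prep <- logit_frame(data, predictors)
  if (nrow(prep) <= length(predictors) + 1) {
    abort("Need more observations than parameters.",
          class = "spectraef_insufficient_sample")
  }
  fml <- stats::reformulate(predictors, response = "malignant")
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = prep, family = binomial(),
        control = stats::glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (sep_warned && max(abs(coef(fit)[-1]), 0) > 15) {
    abort(paste("Quasi-complete separation: coefficients diverge and fitted",
                "probabilities reach 0/1. Remove or coarsen the separating",
                "predictor, or use a penalized fit."),
          class = "spectraef_separation")
  }
  new_aef_logit(fit, predictors, path = NULL)
}

# Shared data preparation: malignant indicator + numeric predictor coding.
logit_frame <- function(data, predictors) {
  data <- as_tibble(data)
  if (!"malignant" %in% names(data)) {
    stopifnot("cohort" %in% names(data))
    data$malignant <- data$cohort == "malignant"
  }
  for (p in predictors) {
    data[[p]] <- marker_scores(data[[p]], p)
  }
  keep <- complete.cases(data[c("malignant", predictors)])
  data[keep, c("malignant", predictors)]
}

new_aef_logit <- function(fit, predictors, path) {
  structure(
    list(fit = fit,
         predictors = predictors,
         or_table = odds_ratio_table(fit),
         vifs = if (length(predictors) >= 2) vif(fit$model[predictors]) else NULL,
         path = path,
         log_likelihood = as.numeric(logLik(fit)),
         converged = fit$converged),
    class = "aef_logit"
  )
}

#' Odds ratio with Wald confidence interval from a coefficient estimate
#'
#' The log-odds-to-odds-ratio arithmetic used for every reported model term:
#' `OR = exp(beta)`, CI `exp(beta +/- z * SE)`, Wald statistic
#' `(beta / SE)^2` with its 1-df chi-squared p-value.
#'
#' @param beta Coefficient (log-odds per unit of the predictor).
#' @param se Standard error of `beta`; strictly positive.
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `estimate`, `std_error`, `wald`, `odds_ratio`,
#'   `or_low`, `or_high`, `p_value`. Vectorized over `beta`/`se`.
#' @examples
#' odds_ratio_from_estimate(-0.511, 0.161) # OR 0.600 (0.437, 0.823)
#' @export
odds_ratio_from_estimate <- function(beta, se, level = 0.95) {
  stopifnot(all(se > 0), level > 0.5, level < 1)
  z <- qnorm(1 - (1 - level) / 2)
  wald <- (beta / se)^2
  tibble(
    estimate = beta,
    std_error = se,
    wald = wald,
    odds_ratio = exp(beta),
    or_low = exp(beta - z * se),
    or_high = exp(beta + z * se),
    p_value = pchisq(wald, df = 1, lower.tail = FALSE)
  )
}

#' Odds ratios with Wald confidence intervals
#'
#' Per-term odds-ratio table for a fitted model; see
#' [odds_ratio_from_estimate()] for the arithmetic.
#'
#' @param fit A fitted `glm` (binomial) or `aef_logit` object.
#' @param level Confidence level (default 0.95).
#' @return A tibble with one row per model term (including the intercept).
#' @export
odds_ratio_table <- function(fit, level = 0.95) {
  if (inherits(fit, "aef_logit")) fit <- fit$fit
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  dplyr::bind_cols(tibble(term = names(beta)),
                   odds_ratio_from_estimate(unname(beta), unname(se),
                                            level = level))
}

#' Variance inflation factors
#'
#' Collinearity diagnostic for a predictor matrix: for each predictor, the
#' auxiliary ordinary-least-squares regression of that predictor on all the
#' others gives `VIF = 1 / (1 - R^2)`. Computed on the raw predictor columns
#' (a linear side-analysis, independent of the logistic weights).
#'
#' @param design A data frame or matrix of numeric predictors (2+ columns).
#' @return A named numeric vector of VIFs; exact collinearity yields `Inf`.
#' @examples
#' x1 <- rnorm(100); x2 <- rnorm(100)
#' vif(data.frame(x1, x2)) # both close to 1
#' @export
vif <- function(design) {
  design <- as.data.frame(design)
  stopifnot(ncol(design) >= 2, all(vapply(design, is.numeric, logical(1))))
  vapply(names(design), function(v) {
    aux <- lm(stats::reformulate(setdiff(names(design), v), response = v),
              data = design)
    r2 <- suppressWarnings(summary(aux)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Forward variable selection by likelihood-ratio tests
#'
#' SPSS-style "Forward: LR" selection: starting from the intercept-only
#' model, repeatedly add the candidate whose likelihood-ratio test against
#' the current model has the smallest p-value below `entry_alpha`; after
#' each entry, drop any included term whose removal LR p-value exceeds
#' `removal_alpha`; stop when no candidate qualifies.
#'
#' @inheritParams fit_logistic
#' @param candidates Character vector of candidate predictor columns.
#' @param entry_alpha LR p-value required to enter (default 0.05).
#' @param removal_alpha LR p-value that triggers removal (default 0.10).
#' @return An `aef_logit` for the selected model (intercept-only if nothing
#'   enters), with the step-by-step `path`.
#' @export
forward_select <- function(data, candidates, entry_alpha = 0.05,
                           removal_alpha = 0.10, max_iter = 100, tol = 1e-8) {
  stopifnot(length(candidates) >= 1)
  prep <- logit_frame(data, candidates)
  ctrl <- stats::glm.control(epsilon = tol, maxit = max_iter)
  deviance_of <- function(terms) {
    fml <- if (length(terms) == 0) malignant ~ 1
           else stats::reformulate(terms, response = "malignant")
    suppressWarnings(glm(fml, data = prep, family = binomial(),
                         control = ctrl))$deviance
  }
  included <- character(0)
  path <- list()
  step <- 0L
  repeat {
    dev0 <- deviance_of(included)
    pool <- setdiff(candidates, included)
    if (length(pool) == 0) break
    entry_p <- vapply(pool, function(v) {
      pchisq(dev0 - deviance_of(c(included, v)), df = 1, lower.tail = FALSE)
    }, numeric(1))
    best <- which.min(entry_p)
    if (entry_p[best] >= entry_alpha) break
    included <- c(included, pool[best])
    step <- step + 1L
    path[[length(path) + 1L]] <- tibble(step = step, action = "enter",
                                        variable = pool[best],
                                        lr_p = unname(entry_p[best]))
    # backward look: drop anything no longer pulling its weight
    repeat {
      if (length(included) < 2) break
      dev_full <- deviance_of(included)
      removal_p <- vapply(included, function(v) {
        pchisq(deviance_of(setdiff(included, v)) - dev_full,
               df = 1, lower.tail = FALSE)
      }, numeric(1))
      worst <- which.max(removal_p)
      if (removal_p[worst] <= removal_alpha) break
      dropped <- included[worst]
      included <- setdiff(included, dropped)
      step <- step + 1L
      path[[length(path) + 1L]] <- tibble(step = step, action = "remove",
                                          variable = dropped,
                                          lr_p = unname(removal_p[worst]))
    }
  }
  path <- if (length(path)) dplyr::bind_rows(path) else
    tibble(step = integer(), action = character(),
           variable = character(), lr_p = numeric())
  if (length(included) == 0) {
    fit <- glm(malignant ~ 1, data = prep, family = binomial(), control = ctrl)
    return(new_aef_logit(fit, character(0), path = path))
  }
  out <- fit_logistic(prep, included, max_iter = max_iter, tol = tol)
  out$path <- path
  out
}

#' Combined-marker score from a fitted logistic model
#'
#' The per-record linear predictor (log-odds of malignancy) under the fitted
#' model, used as a single combined score for ROC evaluation with
#' `higher_is_malignant` orientation. The fitted probability is a monotone
#' transform of this score and gives the identical ROC curve.
#'
#' @param fit An `aef_logit`.
#' @param data Nodule table containing the model's predictor columns.
#' @return Numeric vector of scores (`NA` where a predictor is missing).
#' @export
combined_score <- function(fit, data) {
  stopifnot(inherits(fit, "aef_logit"))
  if (!fit$converged) {
    abort("Refusing to score from a non-converged fit.",
          class = "spectraef_not_converged")
  }
  data <- as_tibble(data)
  for (p in fit$predictors) {
    data[[p]] <- marker_scores(data[[p]], p)
  }
  unname(predict(fit$fit, newdata = data, type = "link"))
}

#' Evaluate a multi-marker combination
#'
#' Fits a logistic model on the named markers (in-sample), scores every
#' record with [combined_score()], and runs the full single-marker ROC
#' evaluation on the combined score.
#'
#' @param data Nodule table with `cohort` and the marker columns.
#' @param markers Character vector of marker names to combine.
#' @param level Confidence level for the AUC interval.
#' @return A `roc_eval` whose `marker` is the concatenated combination name;
#'   the underlying `aef_logit` is attached as attribute `"fit"`.
#' @export
evaluate_combination <- function(data, markers, level = 0.95) {
  fit <- fit_logistic(data, markers)
  data <- as_tibble(data)
  data$.combined <- combined_score(fit, data)
  out <- evaluate_marker(data, ".combined",
                         orientation = "higher_is_malignant", level = level)
  out$marker <- paste(markers, collapse = " + ")
  attr(out, "fit") <- fit
  out
}

#' @export
print.aef_logit <- function(x, ...) {
  cat(sprintf("<aef_logit> malignant ~ %s\n",
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1"))
  cat(sprintf("  log-likelihood %.2f, converged: %s\n",
              x$log_likelihood, x$converged))
  print(x$or_table, n = Inf)
  if (!is.null(x$vifs)) {
    cat("  VIF:", paste(sprintf("%s %.2f", names(x$vifs), x$vifs),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a logistic marker fit
#'
#' @param x An `aef_logit`.
#' @param ... Unused.
#' @return The odds-ratio table: one row per term with coefficient, standard
#'   error, Wald statistic, odds ratio with CI, and p-value.
#' @exportS3Method generics::tidy
tidy.aef_logit <- function(x, ...) x$or_table

#' One-row summary of a logistic marker fit
#'
#' @param x An `aef_logit`.
#' @param ... Unused.
#' @return A one-row tibble: log-likelihood, number of terms, convergence,
#'   and the largest VIF (NA for models with fewer than two predictors).
#' @exportS3Method generics::glance
glance.aef_logit <- function(x, ...) {
  tibble(
    log_likelihood = x$log_likelihood,
    n_predictors = length(x$predictors),
    converged = x$converged,
    max_vif = if (is.null(x$vifs)) NA_real_ else max(x$vifs)
  )
}
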