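test_that("pairwise AUC equals the trapezoidal ROC area on random inputs", {
  expect_equal(auc_pairwise(c(3, 4, 5), c(1, 2)), 1)
  set.seed(601)
  for (i in 1:40) {
    nm <- sample(3:40, 1)
    nb <- sample(3:40, 1)
    # half the cases use integer scores to force heavy ties
    if (i %% 2 == 0) {
      m <- sample(1:5, nm, replace = TRUE)
      b <- sample(1:5, nb, replace = TRUE)
    } else {
      m <- rnorm(nm, 0.5)
      b <- rnorm(nb)
    }
    expect_equal(auc_pairwise(m, b), oracle_trapezoid_auc(m, b),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and flips with orientation", {
  set.seed(602)
  m <- rlnorm(50); b <- rlnorm(40, 0.4)
  a <- auc_pairwise(m, b)
  expect_equal(auc_pairwise(log(m), log(b)), a)
  expect_equal(auc_pairwise(m^3, b^3), a)
  expect_equal(auc_pairwise(m, b, orientation = "lower_is_malignant"), 1 - a)
  # null: interleaved scores from the same distribution
  m0 <- rnorm(10000); b0 <- rnorm(10000)
  expect_lt(abs(auc_pairwise(m0, b0) - 0.5), 0.012)
})

test_that("DeLong interval behaves at the extremes and tracks the jackknife", {
  sep <- delong_ci(c(5, 6, 7), c(1, 2, 3))
  expect_equal(sep$auc, 1)
  expect_equal(c(sep$ci_low, sep$ci_high), c(1, 1))

  tied <- delong_ci(rep(1, 5), rep(1, 5))
  expect_true(tied$degenerate)
  expect_equal(c(tied$ci_low, tied$ci_high), c(0, 1))

  set.seed(603)
  m <- rnorm(10, 1); b <- rnorm(10)
  dl <- delong_ci(m, b)
  jack <- oracle_jackknife_auc_var(m, b)
  expect_equal(dl$se^2, jack, tolerance = 0.1)
})

test_that("DeLong CI agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(604)
  m <- rnorm(80, 0.8); b <- rnorm(60)
  dl <- delong_ci(m, b)
  ref <- pROC::ci.auc(
    pROC::roc(response = rep(c(1, 0), c(80, 60)), predictor = c(m, b),
              direction = "<", quiet = TRUE)
  )
  expect_equal(dl$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(dl$ci_low, as.numeric(ref[1]), tolerance = 1e-8)
  expect_equal(dl$ci_high, as.numeric(ref[3]), tolerance = 1e-8)
})

test_that("Youden scan matches exhaustive-threshold maxima", {
  toy <- youden_cutoff(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(toy$youden_j, 1)
  expect_gt(toy$cutoff, 2)
  expect_lt(toy$cutoff, 3)

  mixed <- youden_cutoff(c(1, 2, 3, 4, 5), c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(mixed$youden_j,
               oracle_best_youden(c(1, 2, 3, 4, 5),
                                  c(FALSE, FALSE, TRUE, FALSE, TRUE)))

  set.seed(605)
  for (i in 1:20) {
    s <- sample(1:6, 30, replace = TRUE)
    lab <- runif(30) < 0.5
    if (!any(lab) || all(lab)) next
    expect_equal(youden_cutoff(s, lab)$youden_j, oracle_best_youden(s, lab),
                 tolerance = 1e-12)
  }

  deg <- youden_cutoff(rep(2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(deg$degenerate)
  expect_equal(deg$youden_j, 0)
})

test_that("metric panel identities hold", {
  p <- metric_panel(tp = 134, fp = 24, tn = 107, fn = 56)
  expect_equal(p$sensitivity + (56 / 190), 1)
  expect_equal(p$unnecessary_biopsy_rate + p$specificity, 1)
  prev <- 190 / 321
  expect_equal(p$accuracy, prev * p$sensitivity + (1 - prev) * p$specificity)

  none_pos <- metric_panel(tp = 0, fp = 0, tn = 10, fn = 10)
  expect_true(is.na(none_pos$ppv))
  expect_equal(none_pos$npv, 0.5)
  expect_error(metric_panel(0, 0, 0, 5), class = "spectraef_empty_group")
})

test_that("binary predictors satisfy AUC = (sens + spec) / 2", {
  co <- calcification_cohort()
  co$any_calc <- co$calcification != "absent"
  ev <- evaluate_marker(co, "any_calc", orientation = "higher_is_malignant")
  p <- ev$metrics
  expect_equal(ev$auc, (p$sensitivity + p$specificity) / 2, tolerance = 1e-12)
})

test_that("evaluate_marker composes orientation, AUC, cutoff and panel", {
  toy <- tibble::tibble(cohort = c("benign", "malignant"),
                        aef_d = c(1.40, 0.93))
  ev <- evaluate_marker(toy, "aef_d")
  expect_equal(ev$orientation, "lower_is_malignant")
  expect_equal(ev$auc, 1)

  co <- derive_markers(simulate_cohort(default_cohort_spec(seed = 66)))
  ev2 <- evaluate_marker(co, "aef_d")
  expect_equal(ev2$orientation, "lower_is_malignant")
  expect_gt(ev2$auc, 0.7)
  expect_true(ev2$ci_low <= ev2$auc && ev2$auc <= ev2$ci_high)
  expect_equal(sum(ev2$confusion), 321)
  g <- glance(ev2)
  expect_equal(g$auc, ev2$auc)
  expect_equal(nrow(tidy(ev2)), 6)
  expect_s3_class(autoplot(ev2), "ggplot")

  co$aef_d[1:100] <- NA
  expect_error(evaluate_marker(co, "aef_d"),
               class = "spectraef_excessive_missingness")
})
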