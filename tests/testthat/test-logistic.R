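simulate_logit <- function(n, beta0, beta1, seed) {
  set.seed(seed)
  x <- rnorm(n)
  p <- 1 / (1 + exp(-(beta0 + beta1 * x)))
  tibble::tibble(x = x, malignant = runif(n) < p)
}

test_that("logistic fit recovers known parameters and the null", {
  d <- simulate_logit(1e5, -1, 0.8, seed = 801)
  fit <- fit_logistic(d, "x")
  expect_true(fit$converged)
  b <- tidy(fit)$estimate
  expect_lt(abs(b[1] - (-1)) / 1, 0.02)
  expect_lt(abs(b[2] - 0.8) / 0.8, 0.02)

  d0 <- simulate_logit(1e4, -0.5, 0, seed = 802)
  fit0 <- fit_logistic(d0, "x")
  row <- tidy(fit0)[tidy(fit0)$term == "x", ]
  expect_lt(abs(row$estimate), 3 * row$std_error)
})

test_that("score equations vanish at the IRLS solution", {
  co <- derive_markers(simulate_cohort(default_cohort_spec(seed = 83)))
  fit <- fit_logistic(co, c("ap_lambda_hu", "ap_nic"))
  mm <- stats::model.matrix(fit$fit)
  resid <- fit$fit$y - stats::fitted(fit$fit)
  score <- drop(t(mm) %*% resid)
  expect_lt(max(abs(score)), 1e-6)
})

test_that("perfect separation raises a dedicated error", {
  d <- tibble::tibble(x = c(-3, -2, -1, -0.5, 0.5, 1, 2, 3),
                      malignant = c(rep(FALSE, 4), rep(TRUE, 4)))
  expect_error(fit_logistic(d, "x"), class = "spectraef_separation")
})

test_that("odds-ratio arithmetic matches the closed form", {
  row <- odds_ratio_from_estimate(-0.511, 0.161)
  expect_equal(row$odds_ratio, exp(-0.511))
  expect_equal(row$wald, (0.511 / 0.161)^2)
  null <- odds_ratio_from_estimate(0, 0.25)
  expect_equal(null$odds_ratio, 1)
  expect_equal(null$or_low * null$or_high, 1, tolerance = 1e-12)
  wide <- odds_ratio_from_estimate(-4.589, 3.126)
  expect_equal(round(wide$odds_ratio, 3), 0.010)
  expect_equal(wide$or_high, 4.658, tolerance = 2e-3)
})

test_that("VIF matches its two-predictor closed form and flags collinearity", {
  set.seed(803)
  n <- 400
  x1 <- rnorm(n)
  x2 <- 0.6 * x1 + rnorm(n, sd = sqrt(1 - 0.36))
  v <- vif(data.frame(x1, x2))
  r <- cor(x1, x2)
  expect_equal(unname(v), rep(1 / (1 - r^2), 2), tolerance = 1e-10)

  x3 <- x1 + rnorm(n, sd = 0.01)
  expect_gt(max(vif(data.frame(x1, x3))), 10)
  expect_equal(vif(data.frame(x1, x1_copy = x1)), c(x1 = Inf, x1_copy = Inf))
})

test_that("forward selection keeps signal and rejects noise", {
  set.seed(804)
  hits <- replicate(60, {
    n <- 400
    x_signal <- rnorm(n)
    p <- 1 / (1 + exp(-(0.0 + 1.2 * x_signal)))
    d <- tibble::tibble(x_signal = x_signal, x_noise = rnorm(n),
                        malignant = runif(n) < p)
    fit <- forward_select(d, c("x_signal", "x_noise"))
    identical(fit$predictors, "x_signal")
  })
  expect_gte(mean(hits), 0.9)

  set.seed(805)
  empty <- replicate(100, {
    d <- tibble::tibble(z1 = rnorm(150), z2 = rnorm(150),
                        malignant = runif(150) < 0.5)
    length(forward_select(d, c("z1", "z2"))$predictors) == 0
  })
  expect_lt(abs(mean(empty) - 0.95^2) , 0.08)
})

test_that("log-likelihood is non-decreasing along the forward path", {
  co <- derive_markers(simulate_cohort(default_cohort_spec(seed = 87)))
  fit <- forward_select(co, c("ap_lambda_hu", "ap_nic", "ap_nzeff"))
  entered <- fit$path$variable[fit$path$action == "enter"]
  lls <- vapply(seq_along(entered), function(k) {
    fit_logistic(co, entered[seq_len(k)])$log_likelihood
  }, numeric(1))
  expect_true(all(diff(lls) > -1e-8))
  expect_true(all(fit$path$lr_p[fit$path$action == "enter"] < 0.05))
})

test_that("combined scores preserve and never shrink in-sample AUC", {
  co <- derive_markers(simulate_cohort(default_cohort_spec(seed = 88)))
  # single-predictor combination equals the marker's own (oriented) ROC
  one <- evaluate_combination(co, "aef_d")
  direct <- evaluate_marker(co, "aef_d")
  expect_equal(one$auc, direct$auc, tolerance = 1e-12)

  multi <- evaluate_combination(co, c("calcification", "ap_lambda_hu", "aef_d"))
  singles <- vapply(c("calcification", "ap_lambda_hu", "aef_d"), function(m) {
    evaluate_marker(co, m)$auc
  }, numeric(1))
  expect_gte(multi$auc, max(singles) - 1e-9)

  co$pure_noise <- rnorm(nrow(co))
  plus_noise <- evaluate_combination(co, c("calcification", "ap_lambda_hu",
                                           "aef_d", "pure_noise"))
  expect_gte(plus_noise$auc, multi$auc - 1e-9)
})

test_that("arterial spectral slope dominates the published-style selection", {
  set.seed(806)
  picked <- replicate(30, {
    co <- derive_markers(simulate_cohort(default_cohort_spec(
      seed = sample.int(1e6, 1))))
    fit <- forward_select(co, c("ap_lambda_hu", "ap_nic", "ap_nzeff"))
    "ap_lambda_hu" %in% fit$predictors
  })
  expect_gte(mean(picked), 0.9)
})
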