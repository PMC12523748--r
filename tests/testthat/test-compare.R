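test_that("normality gate passes normal data and fails log-normal data", {
  set.seed(501)
  reps <- 40
  normal_pass <- vapply(seq_len(reps), function(i) {
    ks_normality(rnorm(500))$p_value > 0.05
  }, logical(1))
  expect_gte(mean(normal_pass), 0.9)
  expect_lt(ks_normality(exp(rnorm(10000)))$p_value, 1e-3)
  const <- ks_normality(rep(2.5, 10))
  expect_equal(const$statistic, 1)
  expect_equal(const$p_value, 0)
  expect_error(ks_normality(c(1, 2, 3)), class = "spectraef_insufficient_sample")
})

test_that("Mann-Whitney exact p matches the permutation oracle, ties included", {
  # separated toy case with known exact p = 2/70
  mw <- mann_whitney(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 2 / 70)
  expect_equal(mw$method, "exact")

  set.seed(502)
  for (i in 1:25) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    # integer-valued draws force ties in most replicates
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    expect_equal(mann_whitney(x, y)$p_value, oracle_mw_p(x, y),
                 tolerance = 1e-12)
  }

  # untied exact case agrees with wilcox.test's exact distribution
  set.seed(503)
  x <- rnorm(6); y <- rnorm(7)
  expect_equal(mann_whitney(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("large-sample Mann-Whitney uses the tie-corrected normal approximation", {
  set.seed(504)
  x <- sample(1:6, 60, replace = TRUE)
  y <- sample(2:7, 80, replace = TRUE)
  mw <- mann_whitney(x, y)
  expect_equal(mw$method, "normal_approx")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mw$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("compare_continuous gates to the right test and handles edge cases", {
  ident <- compare_continuous(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p_value, 1)
  expect_equal(ident$test_used, "mann_whitney")

  sep <- compare_continuous(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(sep$p_value, 2 / 70, tolerance = 1e-12)

  set.seed(505)
  nrm <- compare_continuous(rnorm(60), rnorm(60) + 0.2)
  expect_equal(nrm$test_used, "t_test")
  skw <- compare_continuous(exp(rnorm(60)), exp(rnorm(60)))
  expect_equal(skw$test_used, "mann_whitney")
  expect_error(compare_continuous(c(1, 2), c(1, 2, 3)),
               class = "spectraef_insufficient_sample")
})

test_that("cohorts simulated from the published AEF_D summaries separate decisively", {
  set.seed(506)
  spec <- default_cohort_spec()
  pb <- lognormal_from_median_iqr(spec_distribution(spec, "aef_d", "benign"))
  pm <- lognormal_from_median_iqr(spec_distribution(spec, "aef_d", "malignant"))
  rejected <- vapply(1:100, function(i) {
    b <- exp(rnorm(131, pb$mu, pb$sigma))
    m <- exp(rnorm(190, pm$mu, pm$sigma))
    compare_continuous(b, m)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(rejected), 0.99)
})

test_that("categorical comparison picks chi-square or Fisher appropriately", {
  bal <- compare_categorical(matrix(c(50, 50, 50, 50), 2))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)
  expect_equal(bal$test_used, "chi_square")

  age <- compare_categorical(matrix(c(59, 157, 48, 26), 2), variable = "age")
  expect_equal(age$test_used, "chi_square")
  expect_equal(age$statistic, 33.379, tolerance = 1e-3)
  expect_lt(age$p_value, 0.001)

  # expected count 4.74 < 5 in one cell: Fisher, checked against a
  # hypergeometric enumeration oracle
  tab <- matrix(c(1, 9, 8, 1), 2)
  fsh <- compare_categorical(tab)
  expect_equal(fsh$test_used, "fisher")
  probs <- stats::dhyper(0:9, 10, 9, 9)
  oracle_p <- sum(probs[probs <= probs[2] * (1 + 1e-7)])
  expect_equal(fsh$p_value, oracle_p, tolerance = 1e-10)

  # the published calcification table has all expected counts above 5, so the
  # sparse observed benign microcalcification cell still allows chi-square
  calc <- compare_categorical(matrix(c(121, 149, 3, 30, 7, 11), 2))
  expect_equal(calc$test_used, "chi_square")
  expect_lt(calc$p_value, 0.001)

  expect_error(compare_categorical(matrix(c(0, 0, 5, 5), 2)),
               class = "spectraef_degenerate_table")
})

test_that("chi-square statistic is invariant under row and column permutation", {
  tab <- matrix(c(59, 157, 48, 26), 2)
  s0 <- compare_categorical(tab)$statistic
  expect_equal(compare_categorical(tab[2:1, ])$statistic, s0)
  expect_equal(compare_categorical(tab[, 2:1])$statistic, s0)
})

test_that("adaptive comparison holds its nominal type-I error under the null", {
  set.seed(507)
  reps <- 4000
  rejections <- vapply(seq_len(reps), function(i) {
    compare_continuous(rnorm(30), rnorm(30))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})

test_that("compare_cohorts produces one labelled row per variable", {
  co <- derive_markers(simulate_cohort(default_cohort_spec(seed = 61)))
  tab <- compare_cohorts(co)
  expect_true(all(c("aef_d", "ap_lambda_hu", "calcification", "age_ge50") %in%
                    tab$variable))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_lt(tab$p_value[tab$variable == "aef_d"], 0.001)
  expect_lt(tab$p_value[tab$variable == "ap_nic"], 0.001)
})
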