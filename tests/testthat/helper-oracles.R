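# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# Trapezoidal area under the empirical ROC curve, built from threshold
# sweeps (the implementation uses the rank/pairwise route).
oracle_trapezoid_auc <- function(scores_m, scores_b) {
  thr <- c(-Inf, sort(unique(c(scores_m, scores_b))), Inf)
  tpr <- vapply(thr, function(t) mean(scores_m >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores_b >= t), numeric(1))
  o <- order(fpr, tpr)
  fpr <- fpr[o]
  tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
}

# Pairwise-count U statistic (no ranks involved).
oracle_count_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Exhaustive-permutation two-sided Mann-Whitney p-value.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- oracle_count_u(x, y)
  mu <- n1 * length(y) / 2
  us <- utils::combn(seq_along(pooled), n1, function(idx) {
    oracle_count_u(pooled[idx], pooled[-idx])
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Best Youden J over an exhaustive grid of cutoffs (all scores and
# midpoints), higher-is-malignant convention.
oracle_best_youden <- function(scores, malignant) {
  uniq <- sort(unique(scores))
  cand <- sort(unique(c(-Inf, uniq, uniq - 1e-9, uniq + 1e-9, Inf)))
  best <- -Inf
  for (cutoff in cand) {
    pred <- scores > cutoff
    sens <- sum(pred & malignant) / sum(malignant)
    spec <- sum(!pred & !malignant) / sum(!malignant)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Leave-one-out jackknife variance of the pairwise AUC.
oracle_jackknife_auc_var <- function(scores_m, scores_b) {
  nm <- length(scores_m)
  nb <- length(scores_b)
  auc_of <- function(m, b) oracle_count_u(m, b) / (length(m) * length(b))
  loo_m <- vapply(seq_len(nm), function(i) auc_of(scores_m[-i], scores_b),
                  numeric(1))
  loo_b <- vapply(seq_len(nb), function(i) auc_of(scores_m, scores_b[-i]),
                  numeric(1))
  (nm - 1) / nm * sum((loo_m - mean(loo_m))^2) +
    (nb - 1) / nb * sum((loo_b - mean(loo_b))^2)
}

# Nodule table expanded from calcification contingency counts
# (benign absent/micro/macro then malignant absent/micro/macro).
calcification_cohort <- function(benign = c(121, 3, 7),
                                 malignant = c(149, 30, 11)) {
  lv <- c("absent", "micro", "macro")
  tibble::tibble(
    cohort = rep(c("benign", "malignant"), c(sum(benign), sum(malignant))),
    calcification = c(rep(lv, benign), rep(lv, malignant))
  )
}
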