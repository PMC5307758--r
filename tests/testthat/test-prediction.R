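test_that("ROC thresholds are midpoints with sentinels, classified correctly", {
  v <- c(3, 1, 2, 0)
  y <- c(1, 1, 0, 0)
  roc <- roc_curve(v, y)
  expect_equal(length(roc$thresholds), 5)  # 3 midpoints + 2 sentinels
  # brute-force classification at each threshold
  for (i in seq_along(roc$thresholds)) {
    t <- roc$thresholds[i]
    expect_equal(roc$sensitivity[i], mean(v[y == 1] >= t))
    expect_equal(roc$specificity[i], mean(v[y == 0] < t))
  }
  # sensitivity non-increasing in the threshold
  expect_true(all(diff(roc$sensitivity) <= 0))
  expect_true(all(diff(roc$specificity) >= 0))
})

test_that("degenerate ROCs behave as specified", {
  # perfect separation admits a (1, 1) operating point
  roc <- roc_curve(c(10, 12, 1, 2, 3), c(1, 1, 0, 0, 0))
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))
  # all values identical: only the two sentinel operating points
  roc <- roc_curve(rep(5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(length(roc$thresholds), 2)
  expect_equal(roc$sensitivity, c(1, 0))
  expect_equal(roc$specificity, c(0, 1))
  expect_error(roc_curve(1:5, rep(1, 5)), "non-responder")
})

test_that("AUC equals exhaustive favorable-pair counting", {
  expect_equal(auc_with_p(c(3, 1, 2, 0), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(auc_with_p(c(10, 12, 1, 2, 3), c(1, 1, 0, 0, 0))$auc, 1.0)
  expect_equal(auc_with_p(rep(2, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  set.seed(10)
  for (i in 1:200) {
    n1 <- sample(1:20, 1); n0 <- sample(1:20, 1)
    v <- c(sample(1:12, n1, TRUE) + 0.3, sample(1:12, n0, TRUE))
    y <- rep(c(1, 0), c(n1, n0))
    if (i %% 2 == 0) v <- round(v)  # force ties between groups
    expect_equal(auc_with_p(v, y)$auc,
                 auc_pairs(v[y == 1], v[y == 0]), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(11)
  v <- rnorm(40); y <- rbinom(40, 1, plogis(v))
  if (sum(y) %in% c(0, 40)) y[1:2] <- c(0, 1)
  a0 <- auc_with_p(v, y)$auc
  for (f in list(function(x) exp(x), function(x) x^3, function(x) plogis(2 * x)))
    expect_equal(auc_with_p(f(v), y)$auc, a0)
})

test_that("AUC cross-checks against pROC", {
  skip_if_not_installed("pROC")
  set.seed(12)
  v <- rnorm(60); y <- rbinom(60, 1, plogis(1.2 * v))
  a <- auc_with_p(v, y)$auc
  expect_equal(a, as.numeric(suppressMessages(pROC::auc(y, v))), tolerance = 1e-10)
})

test_that("constrained cutoff reproduces the worked separation example", {
  v <- c(10, 12, 1, 2, 3); y <- c(1, 1, 0, 0, 0)
  co <- constrained_cutoff(v, y, "sensitivity", 1.0)
  expect_equal(co$cutoff, 6.5)
  expect_equal(co$sensitivity, 100)
  expect_equal(co$specificity, 100)
  # a non-responder tied with the lowest responder cannot be excluded
  co <- constrained_cutoff(c(5, 5), c(1, 0), "sensitivity", 1.0)
  expect_equal(co$sensitivity, 100)
  expect_equal(co$specificity, 0)
})

test_that("constrained cutoff agrees with a brute-force scan, both axes", {
  set.seed(13)
  for (i in 1:400) {
    n <- sample(5:100, 1)
    v <- round(rnorm(n, 20, 5), sample(0:2, 1))
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0) y[1] <- 1
    if (sum(y) == n) y[1] <- 0
    axis <- sample(c("sensitivity", "specificity"), 1)
    level <- sample(c(1.0, 0.9, 0.8), 1)
    got <- constrained_cutoff(v, y, axis, level)
    want <- brute_cutoff(v, y, axis, level)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$sensitivity, 100 * want$sens)
    expect_equal(got$specificity, 100 * want$spec)
    # re-classifying at the returned cutoff reproduces the reported rates
    st <- dichotomize_expression(v, got$cutoff)
    expect_equal(100 * mean(st[y == 1] == "high"), got$sensitivity)
    expect_equal(100 * mean(st[y == 0] == "low"), got$specificity)
  }
})

test_that("Mann-Whitney U and exact p match enumeration on small samples", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  set.seed(14)
  for (i in 1:60) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    v <- sample(seq(0.1, 99, by = 0.7), n1 + n2)  # tie-free
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    r <- mann_whitney(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, mw_perm_p(x, y), tolerance = 1e-12)
    expect_true(r$u_statistic >= 0 && r$u_statistic <= n1 * n2)
  }
})

test_that("identical groups give a null-centered U and p of 1", {
  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$u_statistic, 4.5)
  expect_gte(r$p_value, 0.99)
})

test_that("exact and approximate Mann-Whitney p agree for moderate n", {
  set.seed(15)
  for (i in 1:40) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    r_exact <- mann_whitney(x, y, method = "exact")
    r_appr <- mann_whitney(x, y, method = "normal_approximation")
    expect_lt(abs(r_exact$p_value - r_appr$p_value), 0.02)
    # wilcox.test's exact path as independent cross-check
    expect_equal(r_exact$p_value, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("response rates reproduce the printed stratified example", {
  ids <- paste0("S", 1:83)
  st <- setNames(rep(c("high", "low"), c(24, 59)), ids)
  oc <- setNames(rep(0L, 83), ids)
  oc[1:9] <- 1L  # 9 responders, all in the high stratum
  rr <- response_rates(st, oc)
  expect_equal(rr$rate_high, 100 * 9 / 24)  # 37.5%
  expect_equal(rr$rate_low, 0)
  expect_lt(rr$fisher_p, 0.001)

  st44 <- setNames(rep(c("high", "low"), c(44, 39)), ids)
  rr44 <- response_rates(st44, oc)
  expect_equal(round(rr44$rate_high, 1), 20.5)  # 9 of 44

  all_high <- setNames(rep("high", 10), paste0("S", 1:10))
  rr2 <- response_rates(all_high, setNames(rep(0:1, 5), paste0("S", 1:10)))
  expect_true(is.na(rr2$rate_low))
})

test_that("predict_pcr bundles consistent components", {
  set.seed(16)
  v <- setNames(rnorm(70, 37, 2), paste0("S", 1:70))
  y <- setNames(rbinom(70, 1, plogis(-2 + 1.2 * scale(v)[, 1])), names(v))
  if (sum(y) < 2) y[1:2] <- 1
  p <- predict_pcr(v, y, assay = "rt_qpcr")
  expect_s3_class(p, "pcr_prediction")
  expect_equal(p$cutoff$sensitivity, 100)
  expect_equal(p$response$n_high + p$response$n_low, p$n)
  # at a 100%-sensitivity cutoff no responder sits in the low stratum
  expect_equal(p$response$n_low_pcr, 0)
  expect_output(print(p), "AUC")
})
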