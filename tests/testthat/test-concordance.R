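test_that("crosstab counts the four cells and drops incomplete pairs", {
  r <- c(S1 = "positive", S2 = "positive", S3 = "negative", S4 = "negative")
  s <- c(S1 = "positive", S2 = "negative", S3 = "positive", S4 = "negative")
  tab <- crosstab(r, s)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 1))

  allpos <- setNames(rep("positive", 5), paste0("S", 1:5))
  tab <- crosstab(allpos, allpos)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(5, 0, 0, 0))

  expect_error(crosstab(c(A = "positive"), c(B = "positive")), "no complete pairs")

  withna <- r; withna["S2"] <- NA
  tab <- crosstab(withna, s)
  expect_equal(tab$n, 3)
  expect_equal(tab$n_dropped, 1)
})

test_that("agreement metrics follow the percent-agreement formulas", {
  m <- agreement_metrics(list(a = 30, b = 1, c = 3, d = 11))
  expect_equal(m$ppa, 100 * 30 / 33)  # 90.9%
  expect_equal(m$npa, 100 * 11 / 12)  # 91.7%
  expect_equal(round(m$ppa, 1), 90.9)
  expect_equal(round(m$npa, 1), 91.7)
  expect_equal(m$opa, 100 * 41 / 45)

  expect_equal(agreement_metrics(list(a = 7, b = 2, c = 0, d = 1))$ppa, 100)
  expect_true(is.na(agreement_metrics(list(a = 0, b = 2, c = 0, d = 1))$ppa))
  expect_true(is.na(agreement_metrics(list(a = 1, b = 0, c = 2, d = 0))$npa))
})

test_that("agreement identities and swap symmetry hold on random tables", {
  set.seed(6)
  for (i in 1:300) {
    x <- as.list(setNames(rpois(4, 5), c("a", "b", "c", "d")))
    if (sum(unlist(x)) == 0) next
    m <- agreement_metrics(x)
    # count-form decomposition of OPA
    lhs <- m$opa * m$n
    rhs <- ifelse(is.na(m$ppa), 0, m$ppa * (x$a + x$c)) +
      ifelse(is.na(m$npa), 0, m$npa * (x$b + x$d))
    expect_equal(lhs, rhs, tolerance = 1e-10)
    # swapping reference and comparator swaps b/c and the roles of PPA rows
    sw <- agreement_metrics(list(a = x$a, b = x$c, c = x$b, d = x$d))
    expect_equal(sw$opa, m$opa)
    expect_equal(sw$ppa, if (x$a + x$b > 0) 100 * x$a / (x$a + x$b) else NA_real_)
  }
})

test_that("spearman matches the classical d-squared formula on untied ranks", {
  r <- spearman_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$rho, 1 - 6 * 4 / (4 * 15))  # 0.6
  expect_equal(spearman_correlation(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_correlation(1:8, -(1:8)^3)$rho, -1)
  expect_true(is.na(spearman_correlation(rep(1, 5), 1:5)$rho))
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

test_that("spearman equals Pearson on ranks and agrees with cor.test", {
  set.seed(7)
  for (i in 1:500) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    if (i %% 3 == 0) x <- round(x)  # induce ties
    r <- spearman_correlation(x, y)
    expect_equal(r$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(r$rho, unname(cor(x, y, method = "spearman")), tolerance = 1e-12)
  }
  # large-sample p agrees with the t-approximation route of cor.test
  set.seed(8)
  x <- rnorm(60); y <- 0.4 * x + rnorm(60)
  r <- spearman_correlation(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
})

test_that("exact permutation p is valid and symmetric for tiny samples", {
  r <- spearman_correlation(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$rho, 1)
  expect_equal(r$p_value, 2 / 24)  # only the two perfect orderings reach |rho| = 1
  r2 <- spearman_correlation(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(r2$p_value, r$p_value)
})

test_that("fisher 2x2 matches the printed clinicopathological example", {
  # histological grade: 15 vs 3 (grade 2), 30 vs 6 (grade 3)
  p <- fisher_exact(matrix(c(15, 3, 30, 6), 2, 2, byrow = TRUE))$p_value
  expect_equal(round(p, 2), 1.00)
})

test_that("fisher 2x2 equals explicit hypergeometric enumeration", {
  p <- fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value
  expect_equal(p, 2 / 252, tolerance = 1e-12)
  set.seed(9)
  for (i in 1:200) {
    m <- matrix(rpois(4, sample(1:8, 1)), 2)
    expect_equal(fisher_exact(m)$p_value, fisher_2x2_enum(m), tolerance = 1e-9)
  }
})

test_that("zero margins give p = 1 flagged as degenerate", {
  r <- fisher_exact(matrix(c(3, 0, 5, 0), 2))
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("concordance summary assembles tables, metrics and correlations", {
  co <- generate_cohort(quick_config(n = 80, seed = 12, failure_rate = 0))
  ex <- quantify_expression(emit_cq_table(co))
  ihc <- emit_ihc_table(co)
  cfg <- cutoff_config(hormone_mrna_cutoffs = c(ESR1 = 34, PGR = 31))
  st <- marker_status_table(ex, ihc, cfg)
  cont <- rbind(
    data.frame(sample_id = ex$sample_id, marker = "Ki67", assay = "rt_qpcr",
               value = ex$MKI67),
    data.frame(sample_id = ihc$sample_id[ihc$marker == "Ki67" & ihc$method == "digital"],
               marker = "Ki67", assay = "qihc",
               value = ihc$percent_positive[ihc$marker == "Ki67" & ihc$method == "digital"]))
  conc <- concordance_summary(st, cont, pairs = list(c("rt_qpcr", "qihc")))
  ki <- conc[conc$marker == "Ki67", ]
  expect_equal(ki$n, ki$a + ki$b + ki$c + ki$d)
  expect_equal(ki$opa, 100 * (ki$a + ki$d) / ki$n)
  expect_false(is.na(ki$spearman_rho))
})
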