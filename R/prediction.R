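#' Empirical ROC curve for a continuous marker against a binary outcome
#'
#' High-is-positive orientation: a sample is test-positive at threshold t
#' when its value >= t. Candidate thresholds are the midpoints between
#' consecutive distinct sorted values plus two sentinels, one below the
#' minimum (everything positive: sensitivity 1, specificity 0) and one above
#' the maximum (nothing positive: sensitivity 0, specificity 1).
#'
#' @param values numeric marker measurements (missing values dropped with
#'   their labels).
#' @param labels binary outcomes (0/1, logical, or a factor with two
#'   levels; the second level / 1 / TRUE is the event).
#' @return object of class `roc_binary`: list with `thresholds`,
#'   `sensitivity`, `specificity` (parallel vectors, increasing threshold
#'   order), `n_pos`, `n_neg`, `values`, `labels`.
#' @export
roc_curve <- function(values, labels) {
  y <- as_binary_labels(labels)
  ok <- !is.na(values) & !is.na(y)
  v <- values[ok]; y <- y[ok]
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stopf("ROC needs at least one responder and one non-responder")
  u <- sort(unique(v))
  thr <- if (length(u) > 1) (head(u, -1) + u[-1]) / 2 else numeric()
  eps <- max(1, abs(u[1]), abs(u[length(u)])) * 1e-6
  thr <- c(u[1] - eps, thr, u[length(u)] + eps)
  sens <- vapply(thr, function(t) sum(v >= t & y == 1L) / n_pos, 0)
  spec <- vapply(thr, function(t) sum(v < t & y == 0L) / n_neg, 0)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 n_pos = n_pos, n_neg = n_neg, values = v, labels = y),
            class = "roc_binary")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stopf("factor labels must have two levels")
    return(as.integer(labels == levels(labels)[2]))
  }
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L, NA))) stopf("labels must be binary (0/1)")
  y
}

#' @export
print.roc_binary <- function(x, ...) {
  a <- auc_with_p(x$values, x$labels)
  cat(sprintf("ROC: %d responders vs %d non-responders, %d thresholds\n",
              x$n_pos, x$n_neg, length(x$thresholds)))
  cat(sprintf("AUC = %.3f (p vs 0.5 = %.4g)\n", a$auc, a$p_vs_half))
  invisible(x)
}

#' @export
plot.roc_binary <- function(x, ...) {
  plot(1 - x$specificity, x$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Area under the ROC curve with a test against AUC = 0.5
#'
#' AUC through the rank-sum (Mann-Whitney) identity with ties counted one
#' half; the two-sided p-value tests the null that the area equals 0.50
#' using the tie-corrected normal approximation of the Mann-Whitney
#' statistic.
#'
#' @inheritParams roc_curve
#' @return list with `auc`, `p_vs_half`, `u`, `n_pos`, `n_neg`.
#' @export
auc_with_p <- function(values, labels) {
  y <- as_binary_labels(labels)
  ok <- !is.na(values) & !is.na(y)
  v <- values[ok]; y <- y[ok]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stopf("AUC needs at least one responder and one non-responder")
  r <- rank(v)
  u <- sum(r[y == 1L]) - n1 * (n1 + 1) / 2  # favorable pairs, ties half
  auc <- u / (n1 * n0)
  n <- n1 + n0
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n0 / 12 * ((n + 1) - tie_term)
  p <- if (sigma2 <= 0) 1 else 2 * pnorm(-abs(u - n1 * n0 / 2) / sqrt(sigma2))
  list(auc = auc, p_vs_half = min(p, 1), u = u, n_pos = n1, n_neg = n0)
}

#' Sensitivity- or specificity-constrained optimal cutoff
#'
#' Scans the ROC candidate thresholds, keeps those whose constrained axis
#' meets or exceeds `level`, and returns the one maximizing the free axis;
#' ties are broken toward the larger cutoff. The default reproduces the
#' "detect all responders" rule: sensitivity fixed at 100\%, specificity
#' maximized.
#'
#' @inheritParams roc_curve
#' @param fixed_axis `"sensitivity"` or `"specificity"`.
#' @param level required minimum on the fixed axis, fraction in [0, 1].
#' @return object of class `cutoff_result`: list with `cutoff`,
#'   `sensitivity`, `specificity` (percent), `constraint` description,
#'   `n_pos`, `n_neg`.
#' @export
constrained_cutoff <- function(values, labels,
                               fixed_axis = c("sensitivity", "specificity"),
                               level = 1.0) {
  fixed_axis <- match.arg(fixed_axis)
  assert_fraction(level, "level")
  roc <- roc_curve(values, labels)
  fixed <- roc[[fixed_axis]]
  free <- roc[[setdiff(c("sensitivity", "specificity"), fixed_axis)]]
  ok <- which(fixed >= level - 1e-12)
  if (!length(ok)) stopf("no threshold satisfies %s >= %g", fixed_axis, level)
  best_free <- max(free[ok])
  cand <- ok[free[ok] >= best_free - 1e-12]
  pick <- cand[which.max(roc$thresholds[cand])]
  structure(list(cutoff = roc$thresholds[pick],
                 sensitivity = 100 * roc$sensitivity[pick],
                 specificity = 100 * roc$specificity[pick],
                 constraint = sprintf("%s >= %g%%", fixed_axis, 100 * level),
                 n_pos = roc$n_pos, n_neg = roc$n_neg),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Cutoff %.4g under %s: sensitivity %.1f%%, specificity %.1f%% (%d+/%d-)\n",
              x$cutoff, x$constraint, x$sensitivity, x$specificity,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Mann-Whitney rank test comparing two groups
#'
#' U counts favorable pairs for the first group with ties counted one half.
#' The two-sided p-value is exact (full enumeration of rank assignments)
#' when n1 + n2 <= 16 and the data are tie-free, otherwise a normal
#' approximation with tie correction and continuity correction.
#'
#' @param group_pos,group_neg numeric vectors (e.g. responders and
#'   non-responders).
#' @param method `"auto"` (the rule above), or force `"exact"` /
#'   `"normal_approximation"`.
#' @return list with `u_statistic`, `p_value`, `method` (`"exact"` or
#'   `"normal_approximation"`), `n1`, `n2`.
#' @export
mann_whitney <- function(group_pos, group_neg,
                         method = c("auto", "exact", "normal_approximation")) {
  method <- match.arg(method)
  x <- group_pos[!is.na(group_pos)]
  y <- group_neg[!is.na(group_neg)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stopf("both groups must be non-empty")
  v <- c(x, y)
  r <- rank(v)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(v) > 0L
  n <- n1 + n2
  use_exact <- switch(method,
                      auto = !has_ties && n <= 16L,
                      exact = {
                        if (has_ties) stopf("exact method requires tie-free data")
                        TRUE
                      },
                      normal_approximation = FALSE)
  if (use_exact) {
    # exact: enumerate all C(n, n1) assignments of ranks to group 1
    combos <- combn(n, n1)
    us <- colSums(combos) - n1 * (n1 + 1) / 2
    # two-sided by symmetry of the null around n1 n2 / 2
    dev <- abs(us - n1 * n2 / 2)
    p <- mean(dev >= abs(u - n1 * n2 / 2) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- u - n1 * n2 / 2
    cc <- sign(z) * 0.5
    p <- if (sigma2 <= 0) 1 else 2 * pnorm(-abs(z - cc) / sqrt(sigma2))
    method <- "normal_approximation"
  }
  list(u_statistic = u, p_value = min(p, 1), method = method, n1 = n1, n2 = n2)
}

#' Response rates stratified by biomarker status
#'
#' Tabulates pathological complete response within the high and low strata
#' of a dichotomized marker and tests the 2x2 association with the
#' two-sided Fisher exact test.
#'
#' @param statuses named character vector (or data.frame with `sample_id`,
#'   `status`) of `"high"`/`"low"` statuses.
#' @param outcomes named binary vector (or data.frame with `sample_id`,
#'   `pcr`).
#' @return list with `n_high`, `n_high_pcr`, `n_low`, `n_low_pcr`,
#'   `rate_high`, `rate_low` (percent, `NA` for an empty stratum) and
#'   `fisher_p`.
#' @export
response_rates <- function(statuses, outcomes) {
  if (is.data.frame(statuses))
    statuses <- setNames(as.character(statuses$status), statuses$sample_id)
  if (is.data.frame(outcomes))
    outcomes <- setNames(outcomes$pcr, outcomes$sample_id)
  ids <- intersect(names(statuses), names(outcomes))
  st <- statuses[ids]; oc <- as_binary_labels(outcomes[ids])
  ok <- !is.na(st) & !is.na(oc)
  st <- st[ok]; oc <- oc[ok]
  n_high <- sum(st == "high"); n_low <- sum(st == "low")
  n_high_pcr <- sum(oc[st == "high"]); n_low_pcr <- sum(oc[st == "low"])
  tab <- matrix(c(n_high_pcr, n_high - n_high_pcr,
                  n_low_pcr, n_low - n_low_pcr), 2, 2, byrow = TRUE)
  fp <- if (n_high + n_low > 0) fisher_exact(tab)$p_value else NA_real_
  list(n_high = n_high, n_high_pcr = n_high_pcr,
       n_low = n_low, n_low_pcr = n_low_pcr,
       rate_high = if (n_high > 0) 100 * n_high_pcr / n_high else NA_real_,
       rate_low = if (n_low > 0) 100 * n_low_pcr / n_low else NA_real_,
       fisher_p = fp)
}

#' Fit a pCR prediction analysis for one assay
#'
#' Convenience wrapper bundling the ROC curve, AUC with null test,
#' sensitivity-constrained cutoff, Mann-Whitney comparison of responders vs
#' non-responders, and the stratified response-rate table at the derived
#' cutoff.
#'
#' @inheritParams roc_curve
#' @param fixed_axis,level constraint passed to [constrained_cutoff()].
#' @param assay label carried into the result.
#' @return object of class `pcr_prediction` with components `assay`, `roc`,
#'   `auc`, `cutoff`, `mann_whitney`, `response` and `n`.
#' @export
predict_pcr <- function(values, labels, fixed_axis = "sensitivity",
                        level = 1.0, assay = "assay") {
  y <- as_binary_labels(labels)
  ok <- !is.na(values) & !is.na(y)
  v <- values[ok]; y <- y[ok]
  nm <- names(values)[ok] %||% as.character(seq_along(v))
  roc <- roc_curve(v, y)
  auc <- auc_with_p(v, y)
  co <- constrained_cutoff(v, y, fixed_axis = fixed_axis, level = level)
  mw <- mann_whitney(v[y == 1L], v[y == 0L])
  st <- setNames(dichotomize_expression(v, co$cutoff), nm)
  rr <- response_rates(st, setNames(y, nm))
  structure(list(assay = assay, n = length(v), roc = roc, auc = auc,
                 cutoff = co, mann_whitney = mw, response = rr),
            class = "pcr_prediction")
}

#' @export
print.pcr_prediction <- function(x, ...) {
  cat(sprintf("pCR prediction by %s (n = %d: %d responders, %d non-responders)\n",
              x$assay, x$n, x$roc$n_pos, x$roc$n_neg))
  cat(sprintf("  AUC %.2f (p vs 0.5 = %.3g); Mann-Whitney U = %.1f, p = %.3g (%s)\n",
              x$auc$auc, x$auc$p_vs_half, x$mann_whitney$u_statistic,
              x$mann_whitney$p_value, x$mann_whitney$method))
  cat(sprintf("  cutoff %.4g (%s): sensitivity %.1f%%, specificity %.1f%%\n",
              x$cutoff$cutoff, x$cutoff$constraint,
              x$cutoff$sensitivity, x$cutoff$specificity))
  cat(sprintf("  pCR %d/%d (%.1f%%) above vs %d/%d (%s%%) below; Fisher p = %.3g\n",
              x$response$n_high_pcr, x$response$n_high, x$response$rate_high,
              x$response$n_low_pcr, x$response$n_low,
              ifelse(is.na(x$response$rate_low), "-",
                     sprintf("%.1f", x$response$rate_low)),
              x$response$fisher_p))
  invisible(x)
}
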