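#' Cross-classify two binary status vectors
#'
#' Builds the 2x2 concordance table between a reference and a comparator
#' method. Samples with either status missing are dropped and counted.
#' Cell layout: a = both positive, b = reference negative & comparator
#' positive, c = reference positive & comparator negative, d = both
#' negative.
#'
#' @param reference named vector of statuses (names = sample ids), or a
#'   data.frame with `sample_id` and `status`.
#' @param comparator same form as `reference`.
#' @param positive which level counts as positive (default `"positive"`;
#'   use `"high"` for proliferation statuses).
#' @param reference_label,comparator_label labels carried into the result.
#' @return an object of class `concordance_table`: list with counts `a`,
#'   `b`, `c`, `d`, `n`, `n_dropped` and the labels.
#' @export
crosstab <- function(reference, comparator, positive = "positive",
                     reference_label = "reference",
                     comparator_label = "comparator") {
  as_named <- function(x) {
    if (is.data.frame(x)) setNames(as.character(x$status), x$sample_id)
    else setNames(as.character(x), names(x))
  }
  r <- as_named(reference)
  s <- as_named(comparator)
  ids <- union(names(r), names(s))
  rr <- r[ids]
  ss <- s[ids]
  complete <- !is.na(rr) & !is.na(ss)
  n_dropped <- sum(!complete)
  rr <- rr[complete]
  ss <- ss[complete]
  if (!length(rr)) stopf("no complete pairs between reference and comparator")
  rp <- rr == positive
  sp <- ss == positive
  structure(list(a = sum(rp & sp), b = sum(!rp & sp), c = sum(rp & !sp),
                 d = sum(!rp & !sp), n = length(rr), n_dropped = n_dropped,
                 reference_label = reference_label,
                 comparator_label = comparator_label),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("2x2 concordance (%s vs %s), n = %d (%d dropped)\n",
              x$reference_label, x$comparator_label, x$n, x$n_dropped))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(reference = c("+", "-"), comparator = c("+", "-")))
  print(m)
  invisible(x)
}

#' Percent-agreement metrics from a 2x2 table
#'
#' Positive percent agreement PPA = 100 a/(a+c), negative percent agreement
#' NPA = 100 d/(b+d), overall percent agreement OPA = 100 (a+d)/n. A metric
#' whose denominator is zero is reported as `NA`.
#'
#' @param table a [crosstab()] result, or a list/vector with `a`, `b`, `c`,
#'   `d`.
#' @return list with `ppa`, `npa`, `opa` (percent) and `n`.
#' @export
agreement_metrics <- function(table) {
  a <- table[["a"]]; b <- table[["b"]]; c <- table[["c"]]; d <- table[["d"]]
  stopifnot(all(c(a, b, c, d) >= 0))
  n <- a + b + c + d
  if (n < 1) stopf("agreement metrics need at least one classified pair")
  list(ppa = if (a + c > 0) 100 * a / (a + c) else NA_real_,
       npa = if (b + d > 0) 100 * d / (b + d) else NA_real_,
       opa = 100 * (a + d) / n,
       n = n)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Tie-corrected Spearman correlation (Pearson correlation of mid-ranks).
#' The two-sided p-value is computed by full permutation enumeration for
#' n <= 9 and by the t-approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom
#' otherwise. Pairs with either value missing are dropped.
#'
#' @param x,y numeric vectors of paired measurements.
#' @return list with `rho`, `p_value`, `n`; `rho` is `NA` when either input
#'   is constant.
#' @export
spearman_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("spearman_correlation needs at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9) {
    # exact permutation null: all n! rank assignments of y against fixed x
    perms <- all_permutations(n)
    cx <- rx - mean(rx)
    denom <- sqrt(sum(cx^2))
    ystd <- (ry - mean(ry)) / sqrt(sum((ry - mean(ry))^2))
    rhos <- as.vector((matrix(ystd[perms], nrow(perms), n) %*% cx) / denom)
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = min(p, 1), n = n)
}

# All permutations of 1:n as a matrix (n! rows); n <= 9 keeps this feasible.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                 sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Exact test of independence for a contingency table
#'
#' Two-sided Fisher exact test using the probability-mass criterion for 2x2
#' tables (sum of hypergeometric probabilities of all margin-fixed tables no
#' more probable than the observed one) and the Freeman-Halton
#' generalization for r x c tables. A table with a zero row or column
#' margin has no evidence against independence: p = 1, flagged as
#' degenerate.
#'
#' @param table matrix of non-negative integer counts.
#' @return list with `p_value` and `degenerate` (logical).
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) stopf("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(p_value = 1, degenerate = TRUE))
  list(p_value = fisher.test(m)$p.value, degenerate = FALSE)
}

#' Marker-by-marker concordance summary across assay pairs
#'
#' For each marker and each ordered assay pair, the 2x2 agreement table,
#' PPA/NPA/OPA, and the Spearman correlation of the underlying continuous
#' measurements. Complete-case per pair; exclusion counts are reported.
#'
#' @param status long status table ([marker_status_table()] schema).
#' @param continuous optional long table of continuous measurements with
#'   columns `sample_id`, `marker`, `assay`, `value` used for the Spearman
#'   column.
#' @param pairs list of length-2 character vectors of assays, reference
#'   first.
#' @return data.frame with one row per marker x pair:
#'   `marker,reference,comparator,n,n_dropped,a,b,c,d,ppa,npa,opa,spearman_rho,spearman_p`.
#' @export
concordance_summary <- function(status, continuous = NULL,
                                pairs = list(c("rt_qpcr", "qihc"),
                                             c("rt_qpcr", "vihc"),
                                             c("qihc", "vihc"))) {
  rows <- list()
  for (m in unique(status$marker)) {
    st <- status[status$marker == m, ]
    pos <- if (m == "Ki67") "high" else "positive"
    for (p in pairs) {
      r <- st[st$assay == p[1], ]
      s <- st[st$assay == p[2], ]
      if (!nrow(r) || !nrow(s)) next
      tab <- tryCatch(crosstab(r, s, positive = pos,
                               reference_label = p[1], comparator_label = p[2]),
                      error = function(e) NULL)
      if (is.null(tab)) next
      ag <- agreement_metrics(tab)
      rho <- p_rho <- NA_real_
      if (!is.null(continuous)) {
        cr <- continuous[continuous$marker == m & continuous$assay == p[1], ]
        cs <- continuous[continuous$marker == m & continuous$assay == p[2], ]
        xs <- setNames(cr$value, cr$sample_id)
        ys <- setNames(cs$value, cs$sample_id)
        ids <- intersect(names(xs), names(ys))
        ok <- ids[!is.na(xs[ids]) & !is.na(ys[ids])]
        if (length(ok) >= 3) {
          sc <- spearman_correlation(xs[ok], ys[ok])
          rho <- sc$rho; p_rho <- sc$p_value
        }
      }
      rows[[paste(m, p[1], p[2])]] <- data.frame(
        marker = m, reference = p[1], comparator = p[2],
        n = tab$n, n_dropped = tab$n_dropped,
        a = tab$a, b = tab$b, c = tab$c, d = tab$d,
        ppa = ag$ppa, npa = ag$npa, opa = ag$opa,
        spearman_rho = rho, spearman_p = p_rho,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a concordance summary table
#'
#' TSV, one row per marker x method pair.
#'
#' @param conc output of [concordance_summary()].
#' @param path output file path.
#' @export
write_concordance_table <- function(conc, path) {
  out <- conc
  for (col in c("ppa", "npa", "opa"))
    out[[col]] <- ifelse(is.na(out[[col]]), "", sprintf("%.1f", out[[col]]))
  out$spearman_rho <- ifelse(is.na(out$spearman_rho), "",
                             sprintf("%.2f", out$spearman_rho))
  out$spearman_p <- ifelse(is.na(out$spearman_p), "",
                           format(out$spearman_p, digits = 3))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
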