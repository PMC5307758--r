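make_records <- function(sample_id, gene, cqs, run_id = "R1") {
  data.frame(sample_id = sample_id, run_id = run_id, gene = gene,
             replicate = seq_along(cqs), cq = cqs, stringsAsFactors = FALSE)
}

test_that("triplicate aggregation takes the median of detected wells", {
  cases <- list(
    list(cq = c(20, 20, 20), median = 20, n = 3L),
    list(cq = c(20.1, 20.3, 35.0), median = 20.3, n = 3L),  # robust to one outlier
    list(cq = c(21.0, 20.0, NA), median = 20.5, n = 2L),    # mean-of-two rule
    list(cq = c(22.5, NA, NA), median = 22.5, n = 1L),
    list(cq = c(NA, NA, NA), median = NA_real_, n = 0L)
  )
  for (cs in cases) {
    m <- aggregate_triplicates(make_records("S1", "MKI67", cs$cq))
    expect_equal(m$median_cq, cs$median)
    expect_equal(m$n_replicates_used, cs$n)
  }
})

test_that("duplicate well keys are rejected", {
  rec <- make_records("S1", "MKI67", c(20, 21, 22))
  rec$replicate <- c(1L, 1L, 2L)
  expect_error(aggregate_triplicates(rec), "duplicate")
})

test_that("QC flags missing references, low yield, spread and thin replicates", {
  rules <- qc_rules(max_ref_mean_cq = 32, max_replicate_spread = 1,
                    min_valid_replicates = 2)
  base <- do.call(rbind, lapply(c("ESR1", "PGR", "MKI67", "ERBB2", "B2M", "CALM2"),
                                function(g) make_records("S1", g, c(25, 25, 25))))

  expect_equal(apply_qc(aggregate_triplicates(base), rules)$qc_status, "valid")

  no_b2m <- base[base$gene != "B2M", ]
  qc <- apply_qc(aggregate_triplicates(no_b2m), rules)
  expect_equal(qc$qc_status, "invalid")
  expect_equal(qc$qc_reason, "reference gene missing")

  low <- base
  low$cq[low$gene %in% c("B2M", "CALM2")] <- 33
  qc <- apply_qc(aggregate_triplicates(low), rules)
  expect_equal(qc$qc_reason, "low RNA yield")

  wide <- base
  wide$cq[wide$gene == "MKI67"] <- c(24, 25, 26)
  qc <- apply_qc(aggregate_triplicates(wide), rules)
  expect_equal(qc$qc_reason, "replicate spread too large")

  thin <- base
  thin$cq[thin$gene == "ESR1"][2:3] <- NA
  qc <- apply_qc(aggregate_triplicates(thin), rules)
  expect_equal(qc$qc_reason, "too few detected replicates")
})

test_that("normalization reproduces the 40-ddCq formula by hand", {
  cal <- make_calibrator(c(ESR1 = 25, PGR = 25, MKI67 = 27, ERBB2 = 25), 20)
  cq <- c(ESR1 = 25, PGR = 25, MKI67 = 25, ERBB2 = 25, B2M = 20, CALM2 = 20)
  vals <- normalize_expression(make_medians("S1", cq), cal)
  # (25 - 20) - (27 - 20) = -2  ->  42
  expect_equal(unname(vals["MKI67"]), 42)
  # genes identical to the calibrator give exactly 40
  expect_equal(unname(vals["ESR1"]), 40)
  expect_equal(unname(vals["ERBB2"]), 40)
})

test_that("shift invariance: adding a constant to all sample Cqs changes nothing", {
  cal <- make_calibrator(c(ESR1 = 25, PGR = 26, MKI67 = 27, ERBB2 = 24), 22)
  cq <- c(ESR1 = 27, PGR = 30, MKI67 = 25, ERBB2 = 28, B2M = 21, CALM2 = 23)
  v0 <- normalize_expression(make_medians("S1", cq), cal)
  v3 <- normalize_expression(make_medians("S1", cq + 3), cal)
  expect_equal(v0, v3)
})

test_that("run-gene offsets shared with the calibrator cancel", {
  cq <- c(ESR1 = 27, PGR = 30, MKI67 = 25, ERBB2 = 28, B2M = 21, CALM2 = 23)
  tgt <- c(ESR1 = 25, PGR = 26, MKI67 = 27, ERBB2 = 24)
  v0 <- normalize_expression(make_medians("S1", cq),
                             make_calibrator(tgt, 22))
  off <- 1.7  # same gene offset on sample and calibrator wells
  cq2 <- cq; cq2["MKI67"] <- cq2["MKI67"] + off
  tgt2 <- tgt; tgt2["MKI67"] <- tgt2["MKI67"] + off
  v1 <- normalize_expression(make_medians("S1", cq2),
                             make_calibrator(tgt2, 22))
  expect_equal(v0, v1)
})

test_that("lowering a target median by delta raises its value by exactly delta", {
  cal <- make_calibrator(c(ESR1 = 25, PGR = 26, MKI67 = 27, ERBB2 = 24), 22)
  cq <- c(ESR1 = 27, PGR = 30, MKI67 = 25, ERBB2 = 28, B2M = 21, CALM2 = 23)
  v0 <- normalize_expression(make_medians("S1", cq), cal)
  for (delta in c(0.25, 1, 3.75)) {
    cq2 <- cq; cq2["MKI67"] <- cq2["MKI67"] - delta
    v1 <- normalize_expression(make_medians("S1", cq2), cal)
    expect_equal(unname(v1["MKI67"] - v0["MKI67"]), delta)
    expect_equal(v1["ESR1"], v0["ESR1"])
  }
})

test_that("normalization matches a direct formula transcription on random inputs", {
  set.seed(101)
  for (i in 1:200) {
    cq <- setNames(runif(6, 18, 34), c("ESR1", "PGR", "MKI67", "ERBB2", "B2M", "CALM2"))
    tgt <- setNames(runif(4, 18, 34), c("ESR1", "PGR", "MKI67", "ERBB2"))
    ref_pc <- runif(1, 18, 30)
    vals <- normalize_expression(make_medians("S1", cq),
                                 make_calibrator(tgt, ref_pc))
    for (g in c("ESR1", "PGR", "MKI67", "ERBB2")) {
      expect_equal(unname(vals[g]),
                   ddcq_direct(cq[[g]], mean(cq[c("B2M", "CALM2")]), tgt[[g]], ref_pc),
                   tolerance = 1e-13)
    }
  }
})

test_that("quantify_expression errors when a run has no calibrator", {
  rec <- do.call(rbind, lapply(c("ESR1", "PGR", "MKI67", "ERBB2", "B2M", "CALM2"),
                               function(g) make_records("S1", g, c(25, 25, 25))))
  expect_error(quantify_expression(rec), "CALIBRATOR")
  cal <- do.call(rbind, lapply(c("ESR1", "PGR", "MKI67", "ERBB2", "B2M", "CALM2"),
                               function(g) make_records("CALIBRATOR", g, c(25, 25, 25),
                                                        run_id = "R9")))
  expect_error(quantify_expression(rbind(rec, cal)), "run R1")
})

test_that("cq table validation names the offending row", {
  tab <- data.frame(sample_id = "S1", run_id = "R1", gene = "GAPDH",
                    replicate = 1L, cq = 25, stringsAsFactors = FALSE)
  expect_error(pcrconcord:::validate_cq_table(tab), "GAPDH")
  tab$gene <- "ESR1"; tab$cq <- 44
  expect_error(pcrconcord:::validate_cq_table(tab), "row 1")
})
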