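#' Quality-control rules for RT-qPCR samples
#'
#' Operationalizes the per-sample validity criteria: a ceiling on the mean
#' reference-gene Cq (low values indicate sufficient RNA input), a maximum
#' spread (max - min) among the replicates used for a gene median, and a
#' minimum number of detected replicates per gene.
#'
#' @param max_ref_mean_cq maximum allowed mean of the B2M and CALM2 median
#'   Cqs, cycles.
#' @param max_replicate_spread maximum allowed max-min spread of used
#'   replicates for any gene, cycles.
#' @param min_valid_replicates minimum detected replicates per gene.
#' @return an object of class `qc_rules`.
#' @export
qc_rules <- function(max_ref_mean_cq = 32.0,
                     max_replicate_spread = 1.0,
                     min_valid_replicates = 2L) {
  stopifnot(max_ref_mean_cq > 0, max_replicate_spread > 0,
            min_valid_replicates >= 1L)
  structure(list(max_ref_mean_cq = max_ref_mean_cq,
                 max_replicate_spread = max_replicate_spread,
                 min_valid_replicates = as.integer(min_valid_replicates)),
            class = "qc_rules")
}

#' Aggregate triplicate Cq wells to per-gene medians
#'
#' For each (sample, gene), the median of the detected replicates. With
#' exactly two detected replicates this is their mean; with one, that single
#' value is used and counted; with none, the gene-level median is missing.
#'
#' @param records data.frame of well measurements with columns `sample_id`,
#'   `run_id`, `gene`, `replicate`, `cq` (`NA` = undetected).
#' @return data.frame with one row per (sample, gene): `sample_id`,
#'   `run_id`, `gene`, `median_cq`, `n_replicates_used`, `spread`
#'   (max - min of the used replicates).
#' @export
aggregate_triplicates <- function(records) {
  req <- c("sample_id", "run_id", "gene", "replicate", "cq")
  if (!all(req %in% names(records)))
    stopf("records must have columns %s", paste(req, collapse = ", "))
  key <- paste(records$sample_id, records$run_id, records$gene,
               records$replicate, sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicate (sample_id, run_id, gene, replicate) keys in Cq records")
  if (any(!is.na(records$cq) & (records$cq <= 0 | records$cq > 40)))
    stopf("detected Cq values must lie in (0, 40]")

  grp <- paste(records$sample_id, records$run_id, records$gene, sep = "\r")
  idx <- split(seq_len(nrow(records)), grp)
  out <- lapply(idx, function(i) {
    cq <- records$cq[i]
    used <- cq[!is.na(cq)]
    data.frame(sample_id = records$sample_id[i[1]],
               run_id = records$run_id[i[1]],
               gene = records$gene[i[1]],
               median_cq = if (length(used)) median(used) else NA_real_,
               n_replicates_used = length(used),
               spread = if (length(used)) max(used) - min(used) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$sample_id, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Apply per-sample quality control to gene medians
#'
#' A sample is invalid if any reference gene median is missing, if the mean
#' reference Cq exceeds the RNA-yield ceiling, if any gene's replicate
#' spread exceeds the allowed maximum, or if any gene has fewer detected
#' replicates than required. The first failing rule is recorded as the
#' reason.
#'
#' @param medians output of [aggregate_triplicates()] (calibrator rows are
#'   ignored).
#' @param rules a [qc_rules()] object.
#' @return data.frame with columns `sample_id`, `qc_status` (`"valid"` or
#'   `"invalid"`), `qc_reason` (`NA` when valid).
#' @export
apply_qc <- function(medians, rules = qc_rules()) {
  stopifnot(inherits(rules, "qc_rules"))
  medians <- medians[medians$sample_id != CALIBRATOR_ID, , drop = FALSE]
  ids <- unique(medians$sample_id)
  res <- lapply(ids, function(sid) {
    m <- medians[medians$sample_id == sid, ]
    reason <- NA_character_
    ref <- m[m$gene %in% REF_GENES, ]
    if (nrow(ref) < length(REF_GENES) || any(is.na(ref$median_cq))) {
      reason <- "reference gene missing"
    } else if (mean(ref$median_cq) > rules$max_ref_mean_cq) {
      reason <- "low RNA yield"
    } else if (any(m$spread > rules$max_replicate_spread, na.rm = TRUE)) {
      reason <- "replicate spread too large"
    } else if (any(m$n_replicates_used < rules$min_valid_replicates)) {
      reason <- "too few detected replicates"
    }
    data.frame(sample_id = sid,
               qc_status = if (is.na(reason)) "valid" else "invalid",
               qc_reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Extract per-run calibrator profiles from Cq records
#'
#' Aggregates the calibrator (positive control) wells of each run into the
#' per-gene median Cqs and the mean reference-gene Cq needed for inter-run
#' correction.
#'
#' @param records well-level Cq data.frame including rows with sample id
#'   `"CALIBRATOR"`.
#' @return named list (by run id) of calibrator profiles, each with
#'   `run_id`, `cq_target` (named vector over target genes) and
#'   `mean_cq_ref`.
#' @export
calibrator_profiles <- function(records) {
  cal <- records[records$sample_id == CALIBRATOR_ID, , drop = FALSE]
  if (nrow(cal) == 0L) stopf("no calibrator rows (sample_id '%s') found", CALIBRATOR_ID)
  med <- aggregate_triplicates(cal)
  out <- lapply(split(med, med$run_id), function(m) {
    tg <- setNames(m$median_cq[match(TARGET_GENES, m$gene)], TARGET_GENES)
    rf <- m$median_cq[match(REF_GENES, m$gene)]
    if (any(is.na(tg)) || any(is.na(rf)))
      stopf("calibrator for run %s is missing gene medians", m$run_id[1])
    list(run_id = m$run_id[1], cq_target = tg, mean_cq_ref = mean(rf))
  })
  out
}

#' Normalize one sample's gene medians to 40-ddCq expression
#'
#' Implements relative quantification on the 40-minus scale: for each target
#' gene g of sample S with per-run calibrator pc,
#' \deqn{40-\Delta\Delta Cq(g)_S = 40 - ((Cq[g]_S - \overline{Cq}[REF]_S) -
#'   (Cq[g]_{pc} - \overline{Cq}[REF]_{pc}))}
#' where \eqn{\overline{Cq}[REF]} is the unweighted mean of the B2M and
#' CALM2 median Cqs. Larger values mean higher expression; a constant shift
#' of all of a sample's Cqs, or a per-run gene offset shared with the
#' calibrator, leaves the result unchanged.
#'
#' @param medians gene medians for a single sample ([aggregate_triplicates()]
#'   rows).
#' @param calibrator one element of [calibrator_profiles()], matching the
#'   sample's run.
#' @return named numeric vector of 40-\eqn{\Delta\Delta}Cq values over the
#'   target genes (`NA` where the target median is missing).
#' @export
normalize_expression <- function(medians, calibrator) {
  sid <- unique(medians$sample_id)
  if (length(sid) != 1L) stopf("normalize_expression expects a single sample")
  ref <- medians$median_cq[match(REF_GENES, medians$gene)]
  if (any(is.na(ref))) stopf("sample %s: reference gene median missing", sid)
  mean_ref_s <- mean(ref)
  tg <- medians$median_cq[match(TARGET_GENES, medians$gene)]
  ddcq <- (tg - mean_ref_s) - (calibrator$cq_target[TARGET_GENES] - calibrator$mean_cq_ref)
  setNames(40 - ddcq, TARGET_GENES)
}

#' Quantify expression for a full plate of Cq records
#'
#' End-to-end quantification: triplicate aggregation, per-sample quality
#' control, per-run calibrator extraction, and calibrator-corrected
#' reference-normalized 40-\eqn{\Delta\Delta}Cq computation for every sample
#' that passes QC.
#'
#' @param records well-level Cq data.frame (see [aggregate_triplicates()])
#'   including calibrator rows for every run that has samples.
#' @param rules a [qc_rules()] object.
#' @return an `expression_profile` data.frame: `sample_id`, `qc_status`,
#'   `qc_reason`, then one column per target gene (NA for invalid samples).
#' @export
quantify_expression <- function(records, rules = qc_rules()) {
  cals <- calibrator_profiles(records)
  smp <- records[records$sample_id != CALIBRATOR_ID, , drop = FALSE]
  if (nrow(smp) == 0L) {
    out <- data.frame(sample_id = character(), qc_status = character(),
                      qc_reason = character(), stringsAsFactors = FALSE)
    for (g in TARGET_GENES) out[[g]] <- numeric()
    class(out) <- c("expression_profile", "data.frame")
    return(out)
  }
  med <- aggregate_triplicates(smp)
  qc <- apply_qc(med, rules)
  runs <- smp$run_id[match(qc$sample_id, smp$sample_id)]
  vals <- matrix(NA_real_, nrow(qc), length(TARGET_GENES),
                 dimnames = list(NULL, TARGET_GENES))
  for (i in seq_len(nrow(qc))) {
    if (qc$qc_status[i] != "valid") next
    run <- runs[i]
    if (is.null(cals[[run]]))
      stopf("no calibrator available for run %s", run)
    m <- med[med$sample_id == qc$sample_id[i], ]
    vals[i, ] <- normalize_expression(m, cals[[run]])
  }
  out <- cbind(qc, as.data.frame(vals))
  out <- out[order(out$sample_id), ]
  rownames(out) <- NULL
  class(out) <- c("expression_profile", "data.frame")
  out
}

#' Read a long-format Cq table
#'
#' CSV with header `sample_id,run_id,gene,replicate,cq`; an empty `cq` field
#' means the well was undetected. Calibrator rows use sample id
#' `"CALIBRATOR"`. Genes are restricted to the six-gene panel (ESR1, PGR,
#' MKI67, ERBB2, B2M, CALM2).
#'
#' @param path file path.
#' @return validated data.frame of Cq records.
#' @export
read_cq_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(sample_id = "character", run_id = "character",
                               gene = "character", replicate = "integer",
                               cq = "numeric"))
  validate_cq_table(x)
}

validate_cq_table <- function(x) {
  req <- c("sample_id", "run_id", "gene", "replicate", "cq")
  if (!all(req %in% names(x)))
    stopf("cq table must have columns %s", paste(req, collapse = ", "))
  bad <- which(!(x$gene %in% PANEL_GENES))
  if (length(bad))
    stopf("cq table row %d: unknown gene symbol '%s' (panel: %s)",
          bad[1], x$gene[bad[1]], paste(PANEL_GENES, collapse = ", "))
  bad <- which(!is.na(x$cq) & (x$cq <= 0 | x$cq > 40))
  if (length(bad))
    stopf("cq table row %d: cq %.3f outside (0, 40]", bad[1], x$cq[bad[1]])
  key <- paste(x$sample_id, x$run_id, x$gene, x$replicate, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad))
    stopf("cq table row %d: duplicate (sample_id, run_id, gene, replicate) key", bad[1])
  x
}

#' Write an expression profile table
#'
#' TSV with header `sample_id,qc_status,ESR1,PGR,MKI67,ERBB2`; values to two
#' decimals, empty for QC-invalid samples.
#'
#' @param profile an `expression_profile` from [quantify_expression()].
#' @param path output file path.
#' @export
write_expression_table <- function(profile, path) {
  out <- data.frame(sample_id = profile$sample_id,
                    qc_status = profile$qc_status, stringsAsFactors = FALSE)
  for (g in TARGET_GENES)
    out[[g]] <- ifelse(is.na(profile[[g]]), "", sprintf("%.2f", profile[[g]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
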