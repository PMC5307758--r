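#' Dichotomization cutoffs for biomarker status
#'
#' Holds the positivity rules used to dichotomize protein and mRNA
#' measurements. Hormone receptors by IHC are positive when the Remmele
#' immunoreactive score exceeds `irs_positive_above` OR the percentage of
#' positive nuclei exceeds `percent_positive_above` (both comparisons
#' strict). Ki-67 / MKI67 measurements are split at per-assay cutoffs
#' (`value >= cutoff` is "high"); the defaults are the ROC-derived values
#' 37.31 (RT-qPCR, 40-\eqn{\Delta\Delta}Cq units), 13.2\% (digital IHC) and
#' 3.5\% (visual IHC). Hormone-receptor mRNA positivity cutoffs have no
#' default and must be supplied when mRNA hormone status is computed.
#'
#' @param irs_positive_above IRS strictly above this is positive (default 3).
#' @param percent_positive_above percent strictly above this is positive
#'   (default 1).
#' @param mki67_cutoffs named list/vector with `rt_qpcr`, `qihc`, `vihc`.
#' @param hormone_mrna_cutoffs optional named vector with `ESR1` and `PGR`
#'   40-\eqn{\Delta\Delta}Cq positivity cutoffs.
#' @return an object of class `cutoff_config`.
#' @export
cutoff_config <- function(irs_positive_above = 3,
                          percent_positive_above = 1,
                          mki67_cutoffs = c(rt_qpcr = 37.31, qihc = 13.2, vihc = 3.5),
                          hormone_mrna_cutoffs = NULL) {
  stopifnot(is.finite(irs_positive_above), is.finite(percent_positive_above))
  stopifnot(all(c("rt_qpcr", "qihc", "vihc") %in% names(mki67_cutoffs)))
  if (!is.null(hormone_mrna_cutoffs))
    stopifnot(all(c("ESR1", "PGR") %in% names(hormone_mrna_cutoffs)),
              all(is.finite(unlist(hormone_mrna_cutoffs))))
  structure(list(irs_positive_above = irs_positive_above,
                 percent_positive_above = percent_positive_above,
                 mki67_cutoffs = mki67_cutoffs,
                 hormone_mrna_cutoffs = hormone_mrna_cutoffs),
            class = "cutoff_config")
}

#' Hormone-receptor status from IHC scores
#'
#' Positive when IRS > `irs_positive_above` or percent positive nuclei >
#' `percent_positive_above` (both strict). Applies to ER and PR only; Ki-67
#' records are rejected (Ki-67 is dichotomized high/low by cutoff, not by
#' the hormone-receptor rule).
#'
#' @param scores data.frame of IHC records with columns `sample_id`,
#'   `marker`, `method`, `percent_positive`, `irs`.
#' @param cfg a [cutoff_config()].
#' @return data.frame `sample_id`, `marker`, `assay` (`qihc`/`vihc`),
#'   `status` (`"positive"`/`"negative"`), `cutoff_used` (descriptive).
#' @export
hormone_status_ihc <- function(scores, cfg = cutoff_config()) {
  stopifnot(inherits(cfg, "cutoff_config"))
  if (any(scores$marker == "Ki67"))
    stopf("hormone_status_ihc applies to ER/PR only; got Ki67 records")
  if (!all(scores$marker %in% c("ER", "PR")))
    stopf("unknown marker in IHC scores")
  if (any(!is.na(scores$percent_positive) &
          (scores$percent_positive < 0 | scores$percent_positive > 100)))
    stopf("percent_positive outside [0, 100]")
  pos <- (!is.na(scores$irs) & scores$irs > cfg$irs_positive_above) |
    (!is.na(scores$percent_positive) &
       scores$percent_positive > cfg$percent_positive_above)
  data.frame(sample_id = scores$sample_id, marker = scores$marker,
             assay = ifelse(scores$method == "digital", "qihc", "vihc"),
             status = ifelse(pos, "positive", "negative"),
             cutoff_used = sprintf("IRS>%g | %%>%g", cfg$irs_positive_above,
                                   cfg$percent_positive_above),
             stringsAsFactors = FALSE)
}

#' Dichotomize a continuous measurement at a cutoff
#'
#' Returns the "high" (or "positive") label when `value >= cutoff`
#' (inclusive boundary), the "low" label otherwise, and `NA` for missing
#' values, which propagate as undetermined status.
#'
#' @param value numeric vector of measurements.
#' @param cutoff single finite threshold.
#' @param labels length-2 character vector `c(high, low)`.
#' @return character vector of statuses.
#' @export
dichotomize_expression <- function(value, cutoff, labels = c("high", "low")) {
  stopifnot(length(cutoff) == 1L, is.finite(cutoff), length(labels) == 2L)
  ifelse(is.na(value), NA_character_, ifelse(value >= cutoff, labels[1], labels[2]))
}

#' Biomarker status table across assays
#'
#' Builds the full long-format status table: hormone-receptor
#' positive/negative by the IHC rule (both scoring methods) and, when mRNA
#' cutoffs are configured, by ESR1/PGR expression; Ki-67/MKI67 high/low at
#' the per-assay cutoffs.
#'
#' @param expression an `expression_profile` from [quantify_expression()]
#'   (or any data.frame with `sample_id` and gene columns), or `NULL`.
#' @param ihc data.frame of IHC scores (see [emit_ihc_table()] for the
#'   schema), or `NULL`.
#' @param cfg a [cutoff_config()].
#' @return data.frame `sample_id`, `marker`, `assay`, `status`,
#'   `cutoff_used`.
#' @export
marker_status_table <- function(expression = NULL, ihc = NULL,
                                cfg = cutoff_config()) {
  out <- list()
  if (!is.null(ihc)) {
    hr <- ihc[ihc$marker %in% c("ER", "PR"), , drop = FALSE]
    if (nrow(hr)) out$hr_ihc <- hormone_status_ihc(hr, cfg)
    ki <- ihc[ihc$marker == "Ki67", , drop = FALSE]
    for (meth in unique(ki$method)) {
      assay <- if (meth == "digital") "qihc" else "vihc"
      co <- cfg$mki67_cutoffs[[assay]]
      k <- ki[ki$method == meth, ]
      out[[paste0("ki_", assay)]] <- data.frame(
        sample_id = k$sample_id, marker = "Ki67", assay = assay,
        status = dichotomize_expression(k$percent_positive, co),
        cutoff_used = sprintf("%g", co), stringsAsFactors = FALSE)
    }
  }
  if (!is.null(expression)) {
    valid <- if ("qc_status" %in% names(expression))
      expression$qc_status == "valid" else rep(TRUE, nrow(expression))
    ex <- expression[valid, , drop = FALSE]
    if (nrow(ex)) {
      co <- cfg$mki67_cutoffs[["rt_qpcr"]]
      out$ki_mrna <- data.frame(
        sample_id = ex$sample_id, marker = "Ki67", assay = "rt_qpcr",
        status = dichotomize_expression(ex$MKI67, co),
        cutoff_used = sprintf("%g", co), stringsAsFactors = FALSE)
      if (!is.null(cfg$hormone_mrna_cutoffs)) {
        for (m in c("ER", "PR")) {
          g <- MARKER_GENE[[m]]
          co <- cfg$hormone_mrna_cutoffs[[g]]
          out[[paste0("hr_mrna_", m)]] <- data.frame(
            sample_id = ex$sample_id, marker = m, assay = "rt_qpcr",
            status = dichotomize_expression(ex[[g]], co,
                                            labels = c("positive", "negative")),
            cutoff_used = sprintf("%g", co), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), marker = character(),
                      assay = character(), status = character(),
                      cutoff_used = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$marker, res$assay, res$sample_id), ]
  rownames(res) <- NULL
  res
}

#' Read an IHC score table
#'
#' CSV with header `sample_id,marker,method,percent_positive,intensity,irs`.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_ihc_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  validate_ihc_table(x)
}

validate_ihc_table <- function(x) {
  req <- c("sample_id", "marker", "method", "percent_positive", "intensity", "irs")
  if (!all(req %in% names(x)))
    stopf("ihc table must have columns %s", paste(req, collapse = ", "))
  bad <- which(!(x$marker %in% MARKERS))
  if (length(bad)) stopf("ihc table row %d: unknown marker '%s'", bad[1], x$marker[bad[1]])
  bad <- which(!(x$method %in% IHC_METHODS))
  if (length(bad)) stopf("ihc table row %d: method must be visual or digital", bad[1])
  bad <- which(!is.na(x$percent_positive) &
                 (x$percent_positive < 0 | x$percent_positive > 100))
  if (length(bad))
    stopf("ihc table row %d: percent_positive %.1f outside [0, 100]",
          bad[1], x$percent_positive[bad[1]])
  bad <- which(!is.na(x$irs) & (x$irs < 0 | x$irs > 12))
  if (length(bad)) stopf("ihc table row %d: irs outside 0-12", bad[1])
  key <- paste(x$sample_id, x$marker, x$method, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad))
    stopf("ihc table row %d: duplicate (sample_id, marker, method) key", bad[1])
  x
}

#' Write a marker status table
#'
#' TSV with header `sample_id,marker,assay,status,cutoff_used`.
#'
#' @param status output of [marker_status_table()].
#' @param path output file path.
#' @export
write_status_table <- function(status, path) {
  write.table(status, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
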