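#' Configuration for an end-to-end pipeline run
#'
#' Either points at existing input tables (`cq_path`, `ihc_path`,
#' `outcome_path`) or embeds a [generator_config()] to simulate them. The
#' remaining fields parameterize the downstream stages.
#'
#' @param generator a [generator_config()], or `NULL` when reading files.
#' @param cq_path,ihc_path,outcome_path input file paths (all three
#'   required when `generator` is `NULL`).
#' @param qc a [qc_rules()] object.
#' @param cutoffs a [cutoff_config()] object.
#' @param constraint_axis,constraint_level constrained-cutoff settings for
#'   the prediction stage.
#' @param out_dir output directory (created if missing), or `NULL` to skip
#'   writing files.
#' @param seed master seed; required (and used) when generating.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, cq_path = NULL, ihc_path = NULL,
                            outcome_path = NULL, qc = qc_rules(),
                            cutoffs = cutoff_config(),
                            constraint_axis = "sensitivity",
                            constraint_level = 1.0,
                            out_dir = NULL, seed = NULL) {
  if (is.null(generator)) {
    if (is.null(cq_path) || is.null(ihc_path) || is.null(outcome_path))
      stopf("either a generator config or all three input paths are required")
  } else {
    stopifnot(inherits(generator, "generator_config"))
    if (!is.null(seed)) generator$seed <- as.integer(seed)
  }
  stopifnot(inherits(qc, "qc_rules"), inherits(cutoffs, "cutoff_config"))
  assert_fraction(constraint_level, "constraint_level")
  structure(list(generator = generator, cq_path = cq_path, ihc_path = ihc_path,
                 outcome_path = outcome_path, qc = qc, cutoffs = cutoffs,
                 constraint_axis = match.arg(constraint_axis,
                                             c("sensitivity", "specificity")),
                 constraint_level = constraint_level,
                 out_dir = out_dir,
                 seed = seed %||% (if (!is.null(generator)) generator$seed else NULL)),
            class = "pipeline_config")
}

#' Read and validate the pipeline input tables
#'
#' Applies each table's schema (six-gene panel, Cq range, percent range,
#' IRS range, key uniqueness); violations are reported with the offending
#' row.
#'
#' @param config a [pipeline_config()] with input paths.
#' @return list with validated `cq`, `ihc`, `outcome` data.frames.
#' @export
read_tables <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$cq_path, config$ihc_path, config$outcome_path))
    if (!file.exists(p)) stopf("input file not found: %s", p)
  outc <- read.csv(config$outcome_path, stringsAsFactors = FALSE)
  req <- c("sample_id", "pcr")
  if (!all(req %in% names(outc)))
    stopf("outcome table must have columns %s", paste(req, collapse = ", "))
  bad <- which(!(outc$pcr %in% c(0, 1)))
  if (length(bad)) stopf("outcome table row %d: pcr must be 0 or 1", bad[1])
  bad <- which(duplicated(outc$sample_id))
  if (length(bad)) stopf("outcome table row %d: duplicate sample_id", bad[1])
  list(cq = read_cq_table(config$cq_path),
       ihc = read_ihc_table(config$ihc_path),
       outcome = outc)
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> quantify -> status -> concordance -> predict ->
#' report. All stage outputs are returned in a `report_bundle` and, when
#' `out_dir` is set, written as plain-text tables plus a run log and a JSON
#' summary. Exclusions (QC failures, incomplete pairs) are counted so that
#' n_input = n_analyzed + n_excluded at every stage.
#'
#' @param config a [pipeline_config()].
#' @return object of class `report_bundle`: list with `expression`,
#'   `status`, `concordance`, `prediction` (data.frame),
#'   `prediction_detail` (per-assay `pcr_prediction` objects), `attrition`,
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  if (!is.null(config$generator)) {
    inputs <- stage("simulate", {
      cohort <- generate_cohort(config$generator)
      list(cq = emit_cq_table(cohort), ihc = emit_ihc_table(cohort),
           outcome = emit_outcome_table(cohort))
    })
  } else {
    inputs <- stage("read", read_tables(config))
  }

  expression <- stage("quantify", quantify_expression(inputs$cq, config$qc))
  n_input <- nrow(expression)
  n_qc_failed <- sum(expression$qc_status != "valid")

  status <- stage("status",
                  marker_status_table(expression, inputs$ihc, config$cutoffs))

  continuous <- stage("status", {
    rows <- list()
    valid <- expression[expression$qc_status == "valid", ]
    for (m in MARKERS)
      rows[[m]] <- data.frame(sample_id = valid$sample_id, marker = m,
                              assay = "rt_qpcr",
                              value = valid[[MARKER_GENE[[m]]]],
                              stringsAsFactors = FALSE)
    ih <- inputs$ihc
    rows$ihc <- data.frame(sample_id = ih$sample_id, marker = ih$marker,
                           assay = ifelse(ih$method == "digital", "qihc", "vihc"),
                           value = ih$percent_positive, stringsAsFactors = FALSE)
    do.call(rbind, rows)
  })

  concordance <- stage("concordance", concordance_summary(status, continuous))

  prediction_detail <- stage("predict", {
    oc <- setNames(inputs$outcome$pcr, inputs$outcome$sample_id)
    res <- list()
    for (assay in c("rt_qpcr", "qihc", "vihc")) {
      cc <- continuous[continuous$marker == "Ki67" & continuous$assay == assay, ]
      v <- setNames(cc$value, cc$sample_id)
      ids <- intersect(names(v), names(oc))
      ids <- ids[!is.na(v[ids])]
      if (length(unique(oc[ids])) < 2L) next
      res[[assay]] <- predict_pcr(v[ids], oc[ids],
                                  fixed_axis = config$constraint_axis,
                                  level = config$constraint_level,
                                  assay = assay)
    }
    res
  })

  prediction <- do.call(rbind, lapply(prediction_detail, function(p)
    data.frame(assay = p$assay, n = p$n, auc = p$auc$auc,
               auc_p = p$auc$p_vs_half, cutoff = p$cutoff$cutoff,
               sensitivity = p$cutoff$sensitivity,
               specificity = p$cutoff$specificity,
               mw_u = p$mann_whitney$u_statistic, mw_p = p$mann_whitney$p_value,
               rate_high = p$response$rate_high, rate_low = p$response$rate_low,
               fisher_p = p$response$fisher_p, stringsAsFactors = FALSE)))
  if (!is.null(prediction)) rownames(prediction) <- NULL

  attrition <- list(n_input = n_input, n_qc_failed = n_qc_failed,
                    n_analyzed = n_input - n_qc_failed)

  bundle <- structure(list(expression = expression, status = status,
                           concordance = concordance, prediction = prediction,
                           prediction_detail = prediction_detail,
                           attrition = attrition, config = config),
                      class = "report_bundle")

  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' Writes `expression.tsv`, `status.tsv`, `concordance.tsv`,
#' `prediction.tsv`, a plain-text `run_log.txt` with the attrition
#' accounting, and a machine-readable `summary.json` (including a config
#' echo and full ROC coordinates per assay).
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param out_dir output directory, created if missing.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(bundle$expression, file.path(out_dir, "expression.tsv"))
  write_status_table(bundle$status, file.path(out_dir, "status.tsv"))
  if (!is.null(bundle$concordance))
    write_concordance_table(bundle$concordance, file.path(out_dir, "concordance.tsv"))
  if (!is.null(bundle$prediction)) {
    pred <- bundle$prediction
    for (col in c("sensitivity", "specificity", "rate_high", "rate_low"))
      pred[[col]] <- ifelse(is.na(pred[[col]]), "", sprintf("%.1f", pred[[col]]))
    for (col in c("auc", "cutoff"))
      pred[[col]] <- sprintf("%.2f", pred[[col]])
    write.table(pred, file.path(out_dir, "prediction.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  att <- bundle$attrition
  log_lines <- c(
    sprintf("pcrconcord %s run at %s", as.character(utils::packageVersion("pcrconcord")),
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("R %s.%s", R.version$major, R.version$minor),
    sprintf("samples in: %d", att$n_input),
    sprintf("QC failures: %d", att$n_qc_failed),
    sprintf("samples analyzed: %d", att$n_analyzed),
    sprintf("attrition reconciles: %s",
            att$n_input == att$n_analyzed + att$n_qc_failed))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  roc_coords <- lapply(bundle$prediction_detail, function(p)
    list(thresholds = p$roc$thresholds, sensitivity = p$roc$sensitivity,
         specificity = p$roc$specificity))
  summary <- list(attrition = att,
                  config = config_echo(bundle$config),
                  prediction = bundle$prediction,
                  roc = roc_coords)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

# Serializable echo of a pipeline config sufficient to reproduce the run.
config_echo <- function(config) {
  gen <- config$generator
  list(generator = if (is.null(gen)) NULL else unclass(gen),
       cq_path = config$cq_path, ihc_path = config$ihc_path,
       outcome_path = config$outcome_path,
       qc = unclass(config$qc), cutoffs = unclass(config$cutoffs),
       constraint_axis = config$constraint_axis,
       constraint_level = config$constraint_level,
       seed = config$seed)
}

#' @export
print.report_bundle <- function(x, ...) {
  att <- x$attrition
  cat(sprintf("Report bundle: %d samples in, %d QC-failed, %d analyzed\n",
              att$n_input, att$n_qc_failed, att$n_analyzed))
  if (!is.null(x$prediction)) {
    cat("pCR prediction:\n")
    print(x$prediction, digits = 3)
  }
  invisible(x)
}
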