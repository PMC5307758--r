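#' Configuration for the synthetic cohort generator
#'
#' Defines the joint statistical structure of a simulated neoadjuvant
#' breast-cancer cohort: per-marker mRNA (40-\eqn{\Delta\Delta}Cq scale) and
#' protein (percent positive nuclei) marginals, the target rank correlations
#' between the mRNA, digital-IHC and visual-IHC layers of each marker, a
#' logistic link from latent proliferation (the MKI67 mRNA-layer latent
#' score) to pathological complete response, reference-gene Cq levels,
#' triplicate replicate noise, per-run gene offsets, and an assay failure
#' rate emulating insufficient RNA input.
#'
#' Each marker's three measurement layers (mRNA, digital IHC, visual IHC)
#' share a Gaussian copula: target Spearman correlations are converted to
#' latent Pearson correlations via \eqn{2\sin(\pi\rho/6)}, so any monotone
#' marginal transform preserves the configured rank correlations.
#'
#' @param n_samples number of patients to simulate.
#' @param pcr_prevalence target marginal probability of pathological complete
#'   response; used to solve the logistic intercept when
#'   `outcome_link$intercept` is `NULL`.
#' @param marker_params per-marker list (`ER`, `PR`, `Ki67`) with elements
#'   `mrna_mean`, `mrna_sd` (40-\eqn{\Delta\Delta}Cq scale), `protein` (a list
#'   with `digital` and `visual`, each `c(loc, scale)` on the logit-percent
#'   scale), and `rho` (`c(mrna_qihc, mrna_vihc, qihc_vihc)` Spearman
#'   targets). See `default_marker_params()` for the packaged study
#'   conditions.
#' @param outcome_link list with `intercept` (logit scale; `NULL` to solve
#'   from `pcr_prevalence`) and `slope` per standard-deviation of latent
#'   proliferation.
#' @param ref_gene_params list with `B2M` and `CALM2`, each `c(mean, sd)`
#'   cycles.
#' @param erbb2_params `c(mean, sd)` for the ERBB2 transcript (simulated
#'   independently; not part of the three-marker concordance analysis).
#' @param sample_shift_sd SD (cycles) of a per-sample global Cq shift shared
#'   by all wells of a sample (RNA input amount); cancels in normalization.
#' @param replicate_sd SD (cycles) of well-level replicate noise.
#' @param run_count number of PCR runs; samples are assigned round-robin.
#' @param run_gene_offset_sd SD (cycles) of per-run, per-gene offsets applied
#'   identically to sample and calibrator wells of that run.
#' @param failure_rate probability a sample's assay fails for lack of RNA.
#' @param failure_shift cycles added to every well of a failed sample.
#' @param calibrator_profile list with `target_cq` (named vector over the
#'   four target genes) and `ref_cq` (named vector over B2M and CALM2):
#'   the per-run positive-control well levels before run offsets.
#' @param category_freqs named list of categorical frequency vectors for
#'   `grade`, `histotype` and `her2`.
#' @param seed master seed; all randomness is derived from it through fixed
#'   labeled streams.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_samples = 101L,
                             pcr_prevalence = 12 / 83,
                             marker_params = default_marker_params(),
                             outcome_link = list(intercept = NULL, slope = 1.3),
                             ref_gene_params = list(B2M = c(mean = 24, sd = 1.2),
                                                    CALM2 = c(mean = 26, sd = 1.2)),
                             erbb2_params = c(mean = 31, sd = 2),
                             sample_shift_sd = 1.0,
                             replicate_sd = 0.2,
                             run_count = 4L,
                             run_gene_offset_sd = 0.3,
                             failure_rate = 18 / 101,
                             failure_shift = 10,
                             calibrator_profile = list(
                               target_cq = c(ESR1 = 25, PGR = 25, MKI67 = 25, ERBB2 = 25),
                               ref_cq = c(B2M = 24, CALM2 = 26)),
                             category_freqs = list(
                               grade = c("2" = 1 / 3, "3" = 2 / 3),
                               histotype = c(ductal = 0.85, lobular = 0.12, other = 0.03),
                               her2 = c(negative = 0.8, positive = 0.2)),
                             seed = 1L) {
  stopifnot(is.numeric(n_samples), length(n_samples) == 1L, n_samples >= 0)
  assert_fraction(pcr_prevalence, "pcr_prevalence")
  assert_fraction(failure_rate, "failure_rate")
  assert_nonneg(replicate_sd, "replicate_sd")
  assert_nonneg(run_gene_offset_sd, "run_gene_offset_sd")
  assert_nonneg(sample_shift_sd, "sample_shift_sd")
  stopifnot(run_count >= 1L)
  stopifnot(setequal(names(marker_params), MARKERS))
  for (m in MARKERS) {
    p <- marker_params[[m]]
    assert_nonneg(p$mrna_sd, sprintf("marker_params$%s$mrna_sd", m))
    rho <- p$rho
    if (length(rho) != 3L || any(abs(rho) > 1))
      stopf("marker %s: rho must be 3 correlations in [-1, 1]", m)
    # Latent 3x3 correlation over (mRNA, qIHC, vIHC) must be PSD.
    R <- latent_corr_matrix(rho)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stopf("marker %s: correlation targets (%s) imply a non-positive-semi-definite latent matrix",
            m, paste(format(rho), collapse = ", "))
  }
  stopifnot(setequal(names(calibrator_profile$target_cq), TARGET_GENES),
            setequal(names(calibrator_profile$ref_cq), REF_GENES))
  if (is.null(outcome_link$slope)) stopf("outcome_link$slope is required")
  cfg <- list(n_samples = as.integer(n_samples), pcr_prevalence = pcr_prevalence,
              marker_params = marker_params, outcome_link = outcome_link,
              ref_gene_params = ref_gene_params, erbb2_params = erbb2_params,
              sample_shift_sd = sample_shift_sd, replicate_sd = replicate_sd,
              run_count = as.integer(run_count),
              run_gene_offset_sd = run_gene_offset_sd,
              failure_rate = failure_rate, failure_shift = failure_shift,
              calibrator_profile = calibrator_profile,
              category_freqs = category_freqs, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' Default per-marker study conditions
#'
#' mRNA levels are centered at plausible 40-\eqn{\Delta\Delta}Cq values with
#' MKI67 at 37.0 (the reported cohort median is 37.01); Ki-67 protein logit
#' locations put the digital and visual medians at 23.4\% and 35.0\%; the
#' wide hormone-receptor logit scales give strongly bimodal percent-positive
#' marginals with roughly 20\% ER-negative and 26\% PR-negative tumors; the
#' Spearman targets are 0.82/0.85/0.88 (ER), 0.86/0.88/0.90 (PR) and
#' 0.50/0.56/0.80 (Ki-67) for the (mRNA-qIHC, mRNA-vIHC, qIHC-vIHC) pairs.
#'
#' @return named list suitable for the `marker_params` argument of
#'   [generator_config()].
#' @export
default_marker_params <- function() {
  list(
    ER = list(mrna_mean = 36.0, mrna_sd = 2.5,
              protein = list(digital = c(loc = 0.85, scale = 6.5),
                             visual = c(loc = 1.0, scale = 6.5)),
              rho = c(mrna_qihc = 0.82, mrna_vihc = 0.85, qihc_vihc = 0.88)),
    PR = list(mrna_mean = 33.0, mrna_sd = 3.0,
              protein = list(digital = c(loc = 0, scale = 7),
                             visual = c(loc = 0.2, scale = 7)),
              rho = c(mrna_qihc = 0.86, mrna_vihc = 0.88, qihc_vihc = 0.90)),
    Ki67 = list(mrna_mean = 37.0, mrna_sd = 2.0,
                protein = list(digital = c(loc = qlogis(0.234), scale = 0.8),
                               visual = c(loc = qlogis(0.35), scale = 0.8)),
                rho = c(mrna_qihc = 0.50, mrna_vihc = 0.56, qihc_vihc = 0.80))
  )
}

latent_corr_matrix <- function(rho_spearman) {
  r <- spearman_to_pearson(rho_spearman)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- r[1]
  R[1, 3] <- R[3, 1] <- r[2]
  R[2, 3] <- R[3, 2] <- r[3]
  R
}

# Solve the logistic intercept so that E[plogis(a + b Z)] = target for
# Z ~ N(0,1), by quadrature on a fine grid.
solve_logit_intercept <- function(target, slope) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  z <- seq(-8, 8, length.out = 4001)
  w <- stats::dnorm(z)
  w <- w / sum(w)
  f <- function(a) sum(plogis(a + slope * z) * w) - target
  uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Generate a synthetic cohort
#'
#' Draws correlated latent scores per marker (Gaussian copula over the mRNA,
#' digital-IHC and visual-IHC layers), transforms them monotonically to the
#' observed scales, links pathological complete response to the MKI67
#' mRNA-layer latent score through a logistic model, assigns samples to PCR
#' runs, and samples assay failures. Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return an object of class `synthetic_cohort`: a list with `config`,
#'   `samples` (one row per patient), `latent` (per-marker n x 3 matrices),
#'   `expression` (true 40-\eqn{\Delta\Delta}Cq per target gene), `protein`
#'   (percent/intensity/IRS per marker and scoring method) and `runs`
#'   (per-run, per-gene Cq offsets).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_samples
  seed <- config$seed

  run_ids <- sprintf("R%d", seq_len(config$run_count))
  run_offsets <- with_stream(seed, "runs", {
    m <- matrix(rnorm(config$run_count * length(PANEL_GENES),
                      sd = config$run_gene_offset_sd),
                nrow = config$run_count,
                dimnames = list(run_ids, PANEL_GENES))
    m
  })

  if (n == 0L) {
    cohort <- list(config = config,
                   samples = data.frame(sample_id = character(), run_id = character(),
                                        pcr = integer(), assay_failed = logical(),
                                        grade = character(), histotype = character(),
                                        her2 = character(),
                                        b2m_cq = numeric(), calm2_cq = numeric(),
                                        stringsAsFactors = FALSE),
                   latent = setNames(lapply(MARKERS, function(m)
                     matrix(numeric(), 0, 3,
                            dimnames = list(NULL, c("mrna", "qihc", "vihc")))), MARKERS),
                   expression = data.frame(matrix(numeric(), 0, 4,
                                                  dimnames = list(NULL, TARGET_GENES))),
                   protein = data.frame(),
                   runs = list(run_ids = run_ids, offsets = run_offsets))
    class(cohort) <- "synthetic_cohort"
    return(cohort)
  }

  sample_id <- sprintf("S%04d", seq_len(n))
  run_id <- run_ids[((seq_len(n) - 1L) %% config$run_count) + 1L]

  latent <- with_stream(seed, "latent", {
    out <- list()
    for (m in MARKERS) {
      R <- latent_corr_matrix(config$marker_params[[m]]$rho)
      L <- tryCatch(chol(R), error = function(e) {
        # PSD but singular: eigen factor
        e2 <- eigen(R, symmetric = TRUE)
        t(e2$vectors %*% diag(sqrt(pmax(e2$values, 0))))
      })
      Z <- matrix(rnorm(n * 3), n, 3) %*% L
      colnames(Z) <- c("mrna", "qihc", "vihc")
      out[[m]] <- Z
    }
    out$erbb2 <- rnorm(n)
    out
  })

  expression <- data.frame(row.names = sample_id)
  for (m in MARKERS) {
    p <- config$marker_params[[m]]
    expression[[MARKER_GENE[[m]]]] <- p$mrna_mean + p$mrna_sd * latent[[m]][, "mrna"]
  }
  expression[["ERBB2"]] <- config$erbb2_params[["mean"]] +
    config$erbb2_params[["sd"]] * latent$erbb2
  expression <- expression[, TARGET_GENES]

  # Protein layers: logistic transform of the latent score, scaled to percent.
  protein <- data.frame(row.names = sample_id)
  for (m in MARKERS) {
    p <- config$marker_params[[m]]
    for (meth in c("digital", "visual")) {
      layer <- if (meth == "digital") "qihc" else "vihc"
      ps <- p$protein[[meth]]
      protein[[paste(m, meth, "percent", sep = "_")]] <-
        100 * plogis(ps[["loc"]] + ps[["scale"]] * latent[[m]][, layer])
    }
  }

  # Staining intensity (ER/PR): ordinal 0-3, increasing stochastically with
  # percent positivity; IRS = intensity x Remmele percentage category.
  intensity_noise <- with_stream(seed, "intensity",
                                 matrix(runif(n * 4), n, 4))
  k <- 0L
  for (m in c("ER", "PR")) {
    for (meth in c("digital", "visual")) {
      k <- k + 1L
      pct <- protein[[paste(m, meth, "percent", sep = "_")]]
      base <- 1L + (pct >= 10) + (pct > 60)
      jit <- ifelse(intensity_noise[, k] < 0.15, -1L,
                    ifelse(intensity_noise[, k] > 0.85, 1L, 0L))
      inten <- pmin(3L, pmax(1L, base + jit))
      inten[pct == 0] <- 0L
      protein[[paste(m, meth, "intensity", sep = "_")]] <- as.integer(inten)
      protein[[paste(m, meth, "irs", sep = "_")]] <-
        as.integer(inten * percent_category(pct))
    }
  }

  # Outcome: logistic on standardized latent proliferation (MKI67 mRNA layer).
  slope <- config$outcome_link$slope
  intercept <- config$outcome_link$intercept %||%
    solve_logit_intercept(config$pcr_prevalence, slope)
  z_prolif <- latent$Ki67[, "mrna"]
  pr <- plogis(intercept + slope * z_prolif)
  pcr <- with_stream(seed, "outcome", rbinom(n, 1L, pr))

  assay_failed <- with_stream(seed, "failure",
                              runif(n) < config$failure_rate)

  shift <- with_stream(seed, "shift", rnorm(n, sd = config$sample_shift_sd))
  ref_cq <- with_stream(seed, "refs", {
    b <- config$ref_gene_params$B2M
    cm <- config$ref_gene_params$CALM2
    cbind(B2M = rnorm(n, b[["mean"]], b[["sd"]]) + shift,
          CALM2 = rnorm(n, cm[["mean"]], cm[["sd"]]) + shift)
  })

  cats <- with_stream(seed, "categories", {
    draw <- function(freqs) {
      stopifnot(abs(sum(freqs) - 1) < 1e-8)
      names(freqs)[1L + findInterval(runif(n), cumsum(freqs), left.open = TRUE)]
    }
    data.frame(grade = draw(config$category_freqs$grade),
               histotype = draw(config$category_freqs$histotype),
               her2 = draw(config$category_freqs$her2),
               stringsAsFactors = FALSE)
  })

  samples <- data.frame(sample_id = sample_id, run_id = run_id,
                        pcr = as.integer(pcr), assay_failed = assay_failed,
                        grade = cats$grade, histotype = cats$histotype,
                        her2 = cats$her2,
                        b2m_cq = ref_cq[, "B2M"], calm2_cq = ref_cq[, "CALM2"],
                        stringsAsFactors = FALSE)

  cohort <- list(config = config, samples = samples,
                 latent = latent[MARKERS], expression = expression,
                 protein = protein,
                 runs = list(run_ids = run_ids, offsets = run_offsets),
                 outcome_link = list(intercept = intercept, slope = slope))
  class(cohort) <- "synthetic_cohort"
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples, %d runs, %d assay failures, %d pCR\n",
              nrow(x$samples), length(x$runs$run_ids),
              sum(x$samples$assay_failed), sum(x$samples$pcr)))
  invisible(x)
}

#' Emit the raw Cq plate table for a cohort
#'
#' Produces one row per well (sample x gene x replicate, plus calibrator
#' wells per run). Target-gene wells are constructed so that median
#' aggregation followed by reference normalization and calibrator correction
#' recovers the cohort's true 40-\eqn{\Delta\Delta}Cq values:
#' \deqn{Cq[g]_S = \overline{Cq}[REF]_S + (40 - E[g]_S) +
#'   (Cq[g]_{pc} - \overline{Cq}[REF]_{pc}) + run\ offset + noise.}
#' Run offsets apply identically to sample and calibrator wells of a run and
#' therefore cancel in quantification. Wells past the 40-cycle ceiling are
#' emitted as undetected (`NA`). Failed samples carry a global cycle shift
#' emulating insufficient RNA.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config optional override of `cohort$config`.
#' @return data.frame with columns `sample_id`, `run_id`, `gene`,
#'   `replicate`, `cq` (NA = undetected). Calibrator rows use sample id
#'   `"CALIBRATOR"`.
#' @export
emit_cq_table <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- nrow(cohort$samples)
  pc <- config$calibrator_profile
  pc_refmean <- mean(pc$ref_cq)
  n_rep <- 3L

  sample_rows <- if (n > 0) {
    grid <- expand.grid(replicate = seq_len(n_rep), gene = PANEL_GENES,
                        idx = seq_len(n), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    s <- cohort$samples[grid$idx, ]
    ref_mean_s <- (s$b2m_cq + s$calm2_cq) / 2
    base <- numeric(nrow(grid))
    is_ref <- grid$gene %in% REF_GENES
    base[grid$gene == "B2M"] <- s$b2m_cq[grid$gene == "B2M"]
    base[grid$gene == "CALM2"] <- s$calm2_cq[grid$gene == "CALM2"]
    tg <- !is_ref
    em <- as.matrix(cohort$expression)
    e_true <- em[cbind(grid$idx[tg], match(grid$gene[tg], colnames(em)))]
    base[tg] <- ref_mean_s[tg] + (40 - e_true) +
      (pc$target_cq[grid$gene[tg]] - pc_refmean)
    offs <- cohort$runs$offsets[cbind(s$run_id, grid$gene)]
    fail_shift <- ifelse(s$assay_failed, config$failure_shift, 0)
    data.frame(sample_id = s$sample_id, run_id = s$run_id, gene = grid$gene,
               replicate = grid$replicate, cq_true = base + offs + fail_shift,
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = character(), run_id = character(), gene = character(),
               replicate = integer(), cq_true = numeric(), stringsAsFactors = FALSE)
  }

  cal_grid <- expand.grid(replicate = seq_len(n_rep), gene = PANEL_GENES,
                          run_id = cohort$runs$run_ids, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  cal_base <- ifelse(cal_grid$gene %in% REF_GENES,
                     pc$ref_cq[cal_grid$gene],
                     pc$target_cq[cal_grid$gene])
  cal_rows <- data.frame(sample_id = CALIBRATOR_ID, run_id = cal_grid$run_id,
                         gene = cal_grid$gene, replicate = cal_grid$replicate,
                         cq_true = cal_base +
                           cohort$runs$offsets[cbind(cal_grid$run_id, cal_grid$gene)],
                         stringsAsFactors = FALSE)

  tab <- rbind(sample_rows, cal_rows)
  noise <- with_stream(config$seed, "replicates",
                       rnorm(nrow(tab), sd = config$replicate_sd))
  cq <- tab$cq_true + noise
  cq[cq > 40 | cq <= 0] <- NA_real_
  out <- data.frame(sample_id = tab$sample_id, run_id = tab$run_id,
                    gene = tab$gene, replicate = tab$replicate, cq = cq,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Emit the IHC score table for a cohort
#'
#' One record per sample x marker (ER, PR, Ki67) x scoring method (visual,
#' digital) with percent positive nuclei and, for hormone receptors, the
#' staining intensity and Remmele immunoreactive score. Ki-67 records carry
#' no intensity or IRS.
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame with columns `sample_id`, `marker`, `method`,
#'   `percent_positive`, `intensity`, `irs`.
#' @export
emit_ihc_table <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- nrow(cohort$samples)
  if (n == 0L)
    return(data.frame(sample_id = character(), marker = character(),
                      method = character(), percent_positive = numeric(),
                      intensity = integer(), irs = integer(),
                      stringsAsFactors = FALSE))
  rows <- list()
  for (m in MARKERS) {
    for (meth in c("visual", "digital")) {
      pct <- if (n > 0) cohort$protein[[paste(m, meth, "percent", sep = "_")]] else numeric()
      if (m %in% c("ER", "PR") && n > 0) {
        inten <- cohort$protein[[paste(m, meth, "intensity", sep = "_")]]
        irs <- cohort$protein[[paste(m, meth, "irs", sep = "_")]]
      } else {
        inten <- rep(NA_integer_, n)
        irs <- rep(NA_integer_, n)
      }
      rows[[paste(m, meth)]] <- data.frame(
        sample_id = cohort$samples$sample_id, marker = m, method = meth,
        percent_positive = pct, intensity = inten, irs = irs,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$marker, out$method), ]
  rownames(out) <- NULL
  out
}

#' Emit the clinical outcome table for a cohort
#'
#' One record per sample with the pathological complete response indicator
#' (pCR, defined as ypT0 ypN0) and categorical covariates.
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame with columns `sample_id`, `pcr`, `grade`, `histotype`,
#'   `her2`.
#' @export
emit_outcome_table <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  out <- cohort$samples[, c("sample_id", "pcr", "grade", "histotype", "her2")]
  rownames(out) <- NULL
  out
}
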