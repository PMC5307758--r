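# Independent brute-force oracles used to validate the implementation.

# Direct transcription of the 40-minus-ddCq quantity for one gene.
ddcq_direct <- function(cq_target_s, mean_ref_s, cq_target_pc, mean_ref_pc) {
  40 - ((cq_target_s - mean_ref_s) - (cq_target_pc - mean_ref_pc))
}

# Build the per-sample gene-median frame normalize_expression() expects.
make_medians <- function(sample_id, cq) {
  data.frame(sample_id = sample_id, run_id = "R1", gene = names(cq),
             median_cq = unname(cq), n_replicates_used = 3L, spread = 0,
             stringsAsFactors = FALSE)
}

make_calibrator <- function(target_cq, mean_cq_ref) {
  list(run_id = "R1", cq_target = target_cq, mean_cq_ref = mean_cq_ref)
}

# Two-sided Fisher 2x2 by explicit enumeration of margin-fixed tables,
# probability-mass criterion.
fisher_2x2_enum <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  as <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(as, function(x) {
    choose(c1, x) * choose(c2, r1 - x) / choose(c1 + c2, r1)
  }, 0)
  p_obs <- probs[as == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided Mann-Whitney p by enumeration of all group assignments of the
# pooled values, counting favorable pairs directly (tie-free inputs).
mw_perm_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x); n <- length(v)
  u_of <- function(g1) {
    g2 <- setdiff(seq_len(n), g1)
    sum(outer(v[g1], v[g2], ">"))
  }
  u_obs <- u_of(seq_len(n1))
  mid <- n1 * (n - n1) / 2
  combos <- combn(n, n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# AUC by exhaustive favorable-pair counting, ties one half.
auc_pairs <- function(pos, neg) {
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Brute-force constrained cutoff: classify exhaustively at every candidate
# midpoint threshold, filter on the fixed axis, maximize the free axis,
# break ties toward the larger cutoff.
brute_cutoff <- function(values, labels, fixed_axis, level) {
  u <- sort(unique(values))
  thr <- if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else numeric()
  eps <- max(1, abs(u[1]), abs(u[length(u)])) * 1e-6
  thr <- c(u[1] - eps, thr, u[length(u)] + eps)
  best <- NULL
  for (t in thr) {
    sens <- sum(values >= t & labels == 1) / sum(labels == 1)
    spec <- sum(values < t & labels == 0) / sum(labels == 0)
    fixed <- if (fixed_axis == "sensitivity") sens else spec
    free <- if (fixed_axis == "sensitivity") spec else sens
    if (fixed >= level - 1e-12 &&
        (is.null(best) || free > best$free + 1e-12 ||
         (free >= best$free - 1e-12 && t > best$cutoff)))
      best <- list(cutoff = t, sens = sens, spec = spec, free = free)
  }
  best
}

# Small generator config for fast tests.
quick_config <- function(n = 20, seed = 42, ...) {
  generator_config(n_samples = n, seed = seed, ...)
}
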