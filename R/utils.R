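# Internal helpers shared across modules.

# Labeled RNG streams: each purpose draws under its own seed derived from the
# master seed by a fixed offset, so enlarging one stage (e.g. more samples)
# never perturbs draws in another.
.STREAM_OFFSETS <- c(
  latent     = 101L,
  refs       = 211L,
  runs       = 307L,
  failure    = 401L,
  replicates = 503L,
  intensity  = 601L,
  outcome    = 701L,
  categories = 809L,
  shift      = 907L
)

stream_seed <- function(seed, label) {
  stopifnot(label %in% names(.STREAM_OFFSETS))
  s <- (as.double(seed) + .STREAM_OFFSETS[[label]]) %% 2147483647
  as.integer(s)
}

with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, label))
  expr
}

# Remmele percentage category: 0 = none, 1 = <10%, 2 = 10-50%, 3 = 51-80%,
# 4 = >80% positive nuclei.
percent_category <- function(percent) {
  stopifnot(all(percent >= 0 & percent <= 100, na.rm = TRUE))
  ifelse(percent == 0, 0L,
    ifelse(percent < 10, 1L,
      ifelse(percent <= 50, 2L,
        ifelse(percent <= 80, 3L, 4L))))
}

# Spearman target correlation -> Pearson correlation of the Gaussian latent
# layer (Pearson's classical relation for bivariate normal ranks).
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("%s must be a single number in [0, 1]", what)
  invisible(x)
}

assert_nonneg <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
    stopf("%s must be non-negative", what)
  invisible(x)
}
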