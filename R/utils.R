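# Internal helpers shared across modules.

# x*log(y) with the 0*log(0) = 0 convention used in likelihood sums.
xlogy <- function(x, y) {
  out <- numeric(length(x))
  nz <- x != 0
  out[nz] <- x[nz] * log(y[nz])
  out
}

# Derive a stage-specific RNG seed from a master seed so that adding a
# stage never perturbs the draws of earlier stages. Kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 7919 + h) %% 2147483587
}

with_stage_seed <- function(seed, stage, expr) {
  if (!is.null(seed)) set.seed(derive_seed(seed, stage))
  expr
}

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# GRanges helper for locus tables with 1-based inclusive start/end.
loci_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
}
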