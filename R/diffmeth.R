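#' Unite per-sample methylation calls into a count matrix
#'
#' Keeps loci covered at `min_coverage` or more in every sample and drops
#' loci whose coverage exceeds the per-sample `max_coverage_percentile`
#' quantile (a PCR-duplicate guard). Both filters are reported in the
#' object's attributes.
#'
#' @param samples named list of per-sample call data frames (`chrom`,
#'   `pos`, `n_meth`, `n_unmeth`), e.g. from [read_bismark_cov()] or
#'   [simulate_counts()].
#' @param design two-group design data frame (`sample_id`, `group`) with
#'   a `reference` attribute; see [read_design()].
#' @param min_coverage minimum coverage required in every sample
#'   (default 10).
#' @param max_coverage_percentile upper per-sample coverage percentile cut
#'   (default 99.9; `NULL` disables).
#' @return object of class `meth_matrix`: list with `loci` (`chrom`,
#'   `start`, `end`, sorted), integer matrices `n_meth` and `coverage`
#'   (loci x samples), `design`, and `type = "site"`. Attributes
#'   `n_dropped_low`, `n_dropped_high` record the filters.
#' @export
unite <- function(samples, design, min_coverage = 10,
                  max_coverage_percentile = 99.9) {
  design <- validate_design(design)
  if (!all(design$sample_id %in% names(samples)))
    stop("design lists samples absent from the call set: ",
         paste(setdiff(design$sample_id, names(samples)), collapse = ", "))
  samples <- samples[design$sample_id]
  keys <- lapply(samples, function(s) paste(s$chrom, s$pos))
  common <- Reduce(intersect, keys)
  if (!length(common))
    stop("no locus is covered in all samples; consider lowering min_coverage")
  n_meth <- vapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    as.integer(s$n_meth[match(common, keys[[i]])])
  }, integer(length(common)))
  cov <- vapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    as.integer((s$n_meth + s$n_unmeth)[match(common, keys[[i]])])
  }, integer(length(common)))
  if (length(common) == 1) {
    n_meth <- matrix(n_meth, nrow = 1)
    cov <- matrix(cov, nrow = 1)
  }
  colnames(n_meth) <- colnames(cov) <- design$sample_id
  keep_low <- rowSums(cov >= min_coverage) == ncol(cov)
  n_low <- sum(!keep_low)
  keep <- keep_low
  n_high <- 0L
  if (!is.null(max_coverage_percentile)) {
    cuts <- apply(cov, 2, stats::quantile,
                  probs = max_coverage_percentile / 100, names = FALSE)
    keep_high <- rowSums(sweep(cov, 2, cuts, `>`)) == 0
    n_high <- sum(keep_low & !keep_high)
    keep <- keep_low & keep_high
  }
  if (!any(keep))
    stop("all loci removed by coverage filters; ",
         "consider lowering min_coverage")
  sp <- strsplit(common[keep], " ", fixed = TRUE)
  loci <- data.frame(chrom = vapply(sp, `[`, character(1), 1L),
                     start = as.integer(vapply(sp, `[`, character(1), 2L)),
                     stringsAsFactors = FALSE)
  loci$end <- loci$start
  o <- order(loci$chrom, loci$start)
  out <- list(loci = loci[o, , drop = FALSE],
              n_meth = n_meth[keep, , drop = FALSE][o, , drop = FALSE],
              coverage = cov[keep, , drop = FALSE][o, , drop = FALSE],
              design = design, type = "site")
  rownames(out$loci) <- NULL
  attr(out, "n_dropped_low") <- n_low
  attr(out, "n_dropped_high") <- n_high
  class(out) <- "meth_matrix"
  out
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d %s loci x %d samples (%s)\n",
              nrow(x$loci), x$type, ncol(x$coverage),
              paste(table(x$design$group), names(table(x$design$group)),
                    collapse = " vs ")))
  invisible(x)
}

#' Per-sample methylation percentages of a united matrix
#'
#' @param mm a `meth_matrix`.
#' @return numeric matrix (loci x samples) of percent methylation.
#' @export
percent_meth <- function(mm) {
  stopifnot(inherits(mm, "meth_matrix"))
  100 * mm$n_meth / mm$coverage
}

# Vectorized binomial logistic-regression likelihood-ratio test for a
# two-group contrast. With the group indicator as the only covariate the
# binomial MLE is the pooled proportion per group, so the deviance
# difference has the closed form below; tests check it against glm().
lrt_two_group <- function(M1, N1, M0, N0) {
  p1 <- M1 / N1
  p0 <- M0 / N0
  pp <- (M1 + M0) / (N1 + N0)
  stat <- 2 * (xlogy(M1, p1) + xlogy(N1 - M1, 1 - p1) +
                 xlogy(M0, p0) + xlogy(N0 - M0, 1 - p0) -
                 xlogy(M1 + M0, pp) - xlogy(N1 + N0 - M1 - M0, 1 - pp))
  pmax(stat, 0)
}

#' Locus-wise differential methylation test
#'
#' Fits, at every locus of a united matrix, a binomial logistic regression
#' of methylated count out of coverage on the group indicator and compares
#' it to the intercept-only model by a likelihood-ratio (deviance) test on
#' 1 degree of freedom. The methylation difference is the difference of
#' coverage-weighted group methylation percentages, signed patient minus
#' control. Complete separation (one group fully methylated, the other
#' fully unmethylated) is well-defined through the deviance limit.
#'
#' @param mm a `meth_matrix` from [unite()] or
#'   [aggregate_region_counts()].
#' @param fdr_method passed to [adjust_fdr()].
#' @param diff_method "weighted" (coverage-weighted pooled proportions,
#'   default) or "sample_mean" (mean of per-sample percentages).
#' @return object of class `meth_diff` (a data.frame): `chrom`, `start`,
#'   `end`, `meth_diff`, `statistic`, `df`, `p_value`, `q_value`,
#'   `direction` (filled with "ns" until [call_differential()]).
#' @seealso [call_differential()], [adjust_fdr()]
#' @export
diff_methylation <- function(mm, fdr_method = "bh",
                             diff_method = c("weighted", "sample_mean")) {
  stopifnot(inherits(mm, "meth_matrix"))
  diff_method <- match.arg(diff_method)
  design <- mm$design
  ref <- attr(design, "reference")
  groups <- unique(design$group)
  if (length(groups) != 2)
    stop("diff_methylation requires exactly two groups")
  case <- setdiff(groups, ref)
  idx1 <- which(design$group == case)    # patient group
  idx0 <- which(design$group == ref)
  if (any(mm$coverage < 1)) stop("every cell must have coverage >= 1")
  M1 <- rowSums(mm$n_meth[, idx1, drop = FALSE])
  N1 <- rowSums(mm$coverage[, idx1, drop = FALSE])
  M0 <- rowSums(mm$n_meth[, idx0, drop = FALSE])
  N0 <- rowSums(mm$coverage[, idx0, drop = FALSE])
  stat <- lrt_two_group(M1, N1, M0, N0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  md <- if (diff_method == "weighted") 100 * (M1 / N1 - M0 / N0) else {
    pm <- percent_meth(mm)
    rowMeans(pm[, idx1, drop = FALSE]) - rowMeans(pm[, idx0, drop = FALSE])
  }
  res <- data.frame(mm$loci, meth_diff = md, statistic = stat, df = 1L,
                    p_value = p,
                    q_value = adjust_fdr(p, method = fdr_method),
                    direction = "ns", stringsAsFactors = FALSE)
  attr(res, "comparison") <- c(case = case, control = ref)
  attr(res, "type") <- mm$type
  attr(res, "params") <- list(fdr_method = fdr_method,
                              diff_method = diff_method)
  class(res) <- c("meth_diff", "data.frame")
  res
}

#' Adjust p-values for false discovery
#'
#' Benjamini--Hochberg step-up q-values by default. Any alternative
#' procedure (e.g. a SLIM implementation) can be plugged in by passing a
#' function taking and returning a numeric vector in input order.
#'
#' @param p_values numeric vector in `[0, 1]`; `NA`/`NaN` is an error.
#' @param method "bh", "none", or a function.
#' @return q-values in the order of the input.
#' @export
adjust_fdr <- function(p_values, method = "bh") {
  if (anyNA(p_values)) stop("adjust_fdr: p-values contain NA/NaN")
  if (any(p_values < 0 | p_values > 1))
    stop("adjust_fdr: p-values must lie in [0, 1]")
  if (is.function(method)) return(method(p_values))
  switch(match.arg(method, c("bh", "none")),
         bh = stats::p.adjust(p_values, method = "BH"),
         none = p_values)
}

#' Call hyper- and hypomethylated loci
#'
#' A locus is called when `q_value <= q_max` and
#' `|meth_diff| >= min_abs_diff`; the direction is the sign of the
#' difference (patient minus control).
#'
#' @param results a `meth_diff` object.
#' @param q_max q-value ceiling (default 0.01).
#' @param min_abs_diff minimum absolute methylation difference in
#'   percentage points (default 25).
#' @return the input with its `direction` column set to "hyper", "hypo"
#'   or "ns" and call parameters recorded in attributes.
#' @export
call_differential <- function(results, q_max = 0.01, min_abs_diff = 25) {
  stopifnot(inherits(results, "meth_diff"))
  called <- results$q_value <= q_max & abs(results$meth_diff) >= min_abs_diff
  results$direction <- ifelse(!called, "ns",
                              ifelse(results$meth_diff > 0, "hyper", "hypo"))
  attr(results, "params") <- c(attr(results, "params"),
                               list(q_max = q_max,
                                    min_abs_diff = min_abs_diff))
  results
}

#' Extract called loci from a tested comparison
#'
#' @param results a `meth_diff` after [call_differential()].
#' @param direction "both" (default), "hyper" or "hypo".
#' @return data frame of called loci.
#' @export
get_calls <- function(results, direction = c("both", "hyper", "hypo")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") results$direction != "ns" else
    results$direction == direction
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("comparison", "type", "params"))
    attr(out, a) <- attr(results, a)
  out
}

#' @export
print.meth_diff <- function(x, ...) {
  cmp <- attr(x, "comparison")
  cat(sprintf("meth_diff: %d %s loci tested, %s vs %s (reference)\n",
              nrow(x), attr(x, "type"), cmp[["case"]], cmp[["control"]]))
  if (any(x$direction != "ns")) {
    cat(sprintf("  called: %d hyper, %d hypo\n",
                sum(x$direction == "hyper"), sum(x$direction == "hypo")))
  } else {
    cat("  no loci called yet (see call_differential())\n")
  }
  invisible(x)
}

#' @export
summary.meth_diff <- function(object, ...) {
  out <- list(n = nrow(object),
              comparison = attr(object, "comparison"),
              type = attr(object, "type"),
              n_hyper = sum(object$direction == "hyper"),
              n_hypo = sum(object$direction == "hypo"),
              p_quantiles = stats::quantile(object$p_value),
              diff_quantiles = stats::quantile(object$meth_diff))
  class(out) <- "summary.meth_diff"
  out
}

#' @export
print.summary.meth_diff <- function(x, ...) {
  cat(sprintf("Differential methylation (%s), %s vs %s: %d loci\n",
              x$type, x$comparison[["case"]], x$comparison[["control"]],
              x$n))
  cat(sprintf("  hyper: %d  hypo: %d\n", x$n_hyper, x$n_hypo))
  cat("  meth_diff quantiles (pp):\n")
  print(round(x$diff_quantiles, 2))
  invisible(x)
}

#' Volcano plot of a tested comparison
#'
#' @param x a `meth_diff` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.meth_diff <- function(x, ...) {
  col <- ifelse(x$direction == "hyper", "firebrick",
                ifelse(x$direction == "hypo", "steelblue", "grey60"))
  graphics::plot(x$meth_diff, -log10(pmax(x$q_value, 1e-300)), col = col,
                 pch = 16, cex = 0.4,
                 xlab = "methylation difference (pp, patient - control)",
                 ylab = expression(-log[10] ~ q), ...)
  invisible(x)
}

#' Principal-component analysis of sample methylation profiles
#'
#' Column-centered PCA of the loci x samples percent-methylation matrix;
#' components are ordered by decreasing explained variance.
#'
#' @param mm a `meth_matrix` (or a numeric loci x samples percent matrix).
#' @return list of class `meth_pca`: `scores` (samples x components),
#'   `var_explained` (fractions, non-increasing, summing to <= 1),
#'   `sdev`, `design` when available.
#' @export
pca_samples <- function(mm) {
  pm <- if (inherits(mm, "meth_matrix")) percent_meth(mm) else as.matrix(mm)
  if (ncol(pm) < 2 || nrow(pm) < 2)
    stop("pca_samples needs at least 2 samples and 2 loci")
  if (anyNA(pm)) stop("pca_samples: matrix contains missing cells")
  pr <- stats::prcomp(t(pm), center = TRUE, scale. = FALSE)
  if (all(pr$sdev < 1e-12))
    stop("pca_samples: constant matrix, no variance to decompose")
  out <- list(scores = pr$x,
              var_explained = pr$sdev^2 / sum(pr$sdev^2),
              sdev = pr$sdev,
              design = if (inherits(mm, "meth_matrix")) mm$design else NULL)
  class(out) <- "meth_pca"
  out
}

#' @export
print.meth_pca <- function(x, ...) {
  cat(sprintf("meth_pca: %d samples; PC1 %.1f%%, PC2 %.1f%% variance\n",
              nrow(x$scores), 100 * x$var_explained[1],
              100 * x$var_explained[min(2, length(x$var_explained))]))
  invisible(x)
}

#' @export
plot.meth_pca <- function(x, ...) {
  grp <- if (!is.null(x$design)) factor(x$design$group) else
    factor(rep("sample", nrow(x$scores)))
  graphics::plot(x$scores[, 1], x$scores[, 2],
                 col = as.integer(grp) + 1, pch = 16,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$var_explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$var_explained[2]),
                 ...)
  graphics::legend("topright", legend = levels(grp),
                   col = seq_along(levels(grp)) + 1, pch = 16, bty = "n")
  invisible(x)
}
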