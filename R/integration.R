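#' Gene-level methylation summaries from called DMCs
#'
#' For every gene with at least `min_dmcs` member DMCs within
#' TSS +/- `window` of any of its transcripts, reports the member count
#' and the unweighted mean (or median) of the member methylation
#' differences.
#'
#' @param dmcs called DMC data frame with `chrom`, `start`, `end`,
#'   `meth_diff`.
#' @param annotation transcript model.
#' @param window half-width around the TSS in bp (default 10000).
#' @param min_dmcs minimum member DMCs per gene (default 2, inclusive).
#' @param summary_fun "mean" (default) or "median".
#' @return data frame: `gene_id`, `n_dmcs`, `mean_meth_diff`.
#' @export
gene_meth_summaries <- function(dmcs, annotation, window = 10000,
                                min_dmcs = 2,
                                summary_fun = c("mean", "median")) {
  summary_fun <- match.arg(summary_fun)
  f <- if (summary_fun == "mean") mean else stats::median
  hits <- dmcs_per_transcript(dmcs, annotation, window, "all")
  empty <- data.frame(gene_id = character(), n_dmcs = integer(),
                      mean_meth_diff = numeric(), stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  hits$gene_id <- annotation$gene_id[match(hits$transcript_id,
                                           annotation$transcript_id)]
  # gene-level: union of the gene's transcript windows, each DMC once
  hits <- unique(hits[, c("gene_id", "dmc_idx")])
  sp <- split(hits$dmc_idx, hits$gene_id)
  sp <- sp[lengths(sp) >= min_dmcs]
  if (!length(sp)) return(empty)
  out <- data.frame(gene_id = names(sp),
                    n_dmcs = as.integer(lengths(sp)),
                    mean_meth_diff = vapply(sp, function(i)
                      f(dmcs$meth_diff[i]), numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Spearman correlation of methylation change with expression change
#'
#' Rank correlation between the gene-level mean methylation difference
#' and the expression log2 fold change over genes present in both
#' inputs, with tie-aware rho and the standard t approximation for the
#' p-value.
#'
#' @param summaries output of [gene_meth_summaries()].
#' @param expression expression table (`gene_id`, `log2_fold_change`,
#'   `adjusted_p`, `de_flag`); see [read_expression()].
#' @param de_only restrict to genes flagged differentially expressed
#'   (default TRUE, mirroring a DEG-anchored comparison).
#' @return list: `rho`, `p_value`, `n_genes`, `pairs` (the audited
#'   paired table).
#' @export
meth_expr_correlation <- function(summaries, expression, de_only = TRUE) {
  stopifnot_cols(summaries, c("gene_id", "mean_meth_diff"), "summaries")
  stopifnot_cols(expression, c("gene_id", "log2_fold_change"), "expression")
  if (de_only) {
    if (is.null(expression$de_flag))
      stop("de_only = TRUE but expression has no de_flag column")
    expression <- expression[expression$de_flag, , drop = FALSE]
  }
  pairs <- merge(summaries[, c("gene_id", "mean_meth_diff")],
                 expression[, c("gene_id", "log2_fold_change")],
                 by = "gene_id")
  if (nrow(pairs) < 3)
    stop("insufficient paired genes (", nrow(pairs), " < 3)")
  ct <- suppressWarnings(
    stats::cor.test(pairs$mean_meth_diff, pairs$log2_fold_change,
                    method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_genes = nrow(pairs), pairs = pairs)
}

#' Fisher-exact (hypergeometric) gene-set enrichment
#'
#' One-sided enrichment test per term: with `N` universe genes, `K` of
#' them in the term, `n` study genes and `k` study genes in the term,
#' the p-value is the upper hypergeometric tail `P(X >= k)`. P-values
#' are Benjamini--Hochberg adjusted across the tested terms; terms
#' without any study hit are reported with their one-sided p and
#' flagged.
#'
#' @param study_genes character vector; must be a subset of the
#'   universe.
#' @param universe_genes character vector (e.g. all genes with at least
#'   one tested CpG).
#' @param term_map named list term -> gene vector (see [read_gmt()]);
#'   genes outside the universe are ignored.
#' @return data frame: `term_id`, `k`, `K`, `n`, `N`, `odds_ratio`,
#'   `p_value`, `p_adjusted`, `no_hit`.
#' @export
enrichment_fisher <- function(study_genes, universe_genes, term_map) {
  universe <- unique(universe_genes)
  if (!length(universe)) stop("enrichment_fisher: empty universe")
  if (!length(term_map)) stop("enrichment_fisher: empty term map")
  study <- unique(study_genes)
  if (!all(study %in% universe))
    stop("study genes must be a subset of the universe")
  n <- length(study); N <- length(universe)
  rows <- lapply(names(term_map), function(tm) {
    term <- intersect(unique(term_map[[tm]]), universe)
    K <- length(term)
    k <- length(intersect(term, study))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / ((K - k) * (n - k))
    data.frame(term_id = tm, k = k, K = K, n = n, N = N,
               odds_ratio = or, p_value = p, no_hit = k == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[, c("term_id", "k", "K", "n", "N", "odds_ratio", "p_value",
                 "p_adjusted", "no_hit")]
  out[order(out$p_value, out$term_id), , drop = FALSE]
}
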