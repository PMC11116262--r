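# Independent oracles and fixture builders shared across test files.

# Likelihood-ratio (G) statistic of a 2x2 table from observed vs expected
# under independence -- derived independently of the package's pooled
# binomial log-likelihood formulation.
g_test_stat <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  cells <- tab > 0
  2 * sum(tab[cells] * log(tab[cells] / E[cells]))
}

# Benjamini-Hochberg step-up by the hand formula:
# q_(i) = min_{j >= i} min(1, p_(j) * m / j), mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Upper hypergeometric tail P(X >= k) as an explicit sum of choose() terms.
hyper_tail_oracle <- function(k, K, n, N) {
  if (k > min(K, n)) return(0)
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Exhaustive nearest-TSS scan: per locus, loop over every transcript.
brute_nearest_tss <- function(loci, ann) {
  out <- data.frame(transcript_id = character(nrow(loci)),
                    distance = numeric(nrow(loci)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(loci))) {
    cand <- ann[ann$chrom == loci$chrom[i], , drop = FALSE]
    if (!nrow(cand)) {
      out$transcript_id[i] <- "unassigned"; out$distance[i] <- NA
      next
    }
    d <- numeric(nrow(cand))
    for (j in seq_len(nrow(cand))) {
      tss <- cand$tss[j]
      d[j] <- if (tss < loci$start[i]) loci$start[i] - tss
      else if (tss > loci$end[i]) tss - loci$end[i] else 0
    }
    best <- which(d == min(d))
    best <- best[order(cand$transcript_id[best])][1]
    raw <- d[best]
    up <- if (cand$strand[best] == "+") loci$end[i] < cand$tss[best]
    else loci$start[i] > cand$tss[best]
    out$transcript_id[i] <- cand$transcript_id[best]
    out$distance[i] <- if (raw == 0) 0 else if (up) -raw else raw
  }
  out
}

# Hand-built annotation: three transcripts on two chromosomes.
tiny_annotation <- function() {
  data.frame(
    transcript_id = c("txA", "txB", "txC"),
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tx_start = c(5000L, 12000L, 3000L),
    tx_end = c(8000L, 16000L, 6000L),
    tss = c(5000L, 16000L, 3000L),
    exon_starts = c("5000,7000", "12000,15000", "3000"),
    exon_ends = c("6000,8000", "13000,16000", "6000"),
    stringsAsFactors = FALSE)
}

# Build a meth_matrix directly from count matrices (loci x samples).
make_meth_matrix <- function(n_meth, coverage, chrom = NULL, pos = NULL,
                             n_case = ncol(n_meth) / 2) {
  n <- nrow(n_meth)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = n)
  spg_ctrl <- ncol(n_meth) - n_case
  design <- data.frame(
    sample_id = c(paste0("ctrl_", seq_len(spg_ctrl)),
                  paste0("case_", seq_len(n_case))),
    group = c(rep("control", spg_ctrl), rep("case", n_case)),
    stringsAsFactors = FALSE)
  attr(design, "reference") <- "control"
  colnames(n_meth) <- colnames(coverage) <- design$sample_id
  out <- list(loci = data.frame(chrom = chrom, start = pos, end = pos,
                                stringsAsFactors = FALSE),
              n_meth = n_meth, coverage = coverage, design = design,
              type = "site")
  class(out) <- "meth_matrix"
  out
}

# One-locus LRT through the package: control counts then case counts as
# (n_meth, coverage) pair lists.
one_locus_test <- function(ctrl, case) {
  nm <- matrix(c(vapply(ctrl, `[`, numeric(1), 1),
                 vapply(case, `[`, numeric(1), 1)), nrow = 1)
  cv <- matrix(c(vapply(ctrl, `[`, numeric(1), 2),
                 vapply(case, `[`, numeric(1), 2)), nrow = 1)
  mm <- make_meth_matrix(nm, cv, n_case = length(case))
  diff_methylation(mm)
}

# glm-based deviance-difference oracle for one locus.
glm_lrt_oracle <- function(ctrl, case) {
  nm <- c(vapply(ctrl, `[`, numeric(1), 1),
          vapply(case, `[`, numeric(1), 1))
  cv <- c(vapply(ctrl, `[`, numeric(1), 2),
          vapply(case, `[`, numeric(1), 2))
  grp <- factor(c(rep("control", length(ctrl)), rep("case", length(case))))
  fit1 <- glm(cbind(nm, cv - nm) ~ grp, family = binomial())
  fit0 <- glm(cbind(nm, cv - nm) ~ 1, family = binomial())
  fit0$deviance - fit1$deviance
}
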