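#' Top DMC genes: strong effects close to a TSS
#'
#' Keeps DMCs with an absolute TSS distance strictly below `max_dist` and
#' an absolute methylation difference strictly above `min_abs_diff`
#' (strict inequalities on both, following the usual "less than 10 kb" /
#' "larger than 30%" phrasing), and returns the distinct associated
#' genes.
#'
#' @param dmcs annotated DMCs: data frame with `meth_diff`,
#'   `distance_to_tss`, `gene_id` (see [nearest_tss()]).
#' @param max_dist TSS distance bound in bp (default 10000, strict `<`).
#' @param min_abs_diff methylation-difference bound in percentage points
#'   (default 30, strict `>`).
#' @return character vector of gene ids.
#' @export
top_dmc_genes <- function(dmcs, max_dist = 10000, min_abs_diff = 30) {
  stopifnot_cols(dmcs, c("meth_diff", "distance_to_tss", "gene_id"), "dmcs")
  keep <- !is.na(dmcs$distance_to_tss) &
    abs(dmcs$distance_to_tss) < max_dist &
    abs(dmcs$meth_diff) > min_abs_diff
  sort(unique(dmcs$gene_id[keep]))
}

# Count DMCs per transcript window (TSS +/- window); every DMC counts
# toward every transcript whose window contains it (multi-assignment),
# or toward its nearest transcript only when assignment = "nearest".
dmcs_per_transcript <- function(dmcs, annotation, window = 10000,
                                assignment = c("all", "nearest")) {
  assignment <- match.arg(assignment)
  if (!nrow(dmcs) || !nrow(annotation))
    return(data.frame(transcript_id = character(), dmc_idx = integer(),
                      stringsAsFactors = FALSE))
  if (assignment == "nearest") {
    if (is.null(dmcs$transcript_id)) dmcs <- nearest_tss(dmcs, annotation)
    keep <- which(!is.na(dmcs$distance_to_tss) &
                    abs(dmcs$distance_to_tss) <= window)
    return(data.frame(transcript_id = dmcs$transcript_id[keep],
                      dmc_idx = keep, stringsAsFactors = FALSE))
  }
  win <- data.frame(chrom = annotation$chrom,
                    start = pmax(1L, annotation$tss - as.integer(window)),
                    end = annotation$tss + as.integer(window),
                    stringsAsFactors = FALSE)
  ov <- GenomicRanges::findOverlaps(loci_granges(dmcs), loci_granges(win))
  data.frame(transcript_id = annotation$transcript_id[
    S4Vectors::subjectHits(ov)],
    dmc_idx = S4Vectors::queryHits(ov), stringsAsFactors = FALSE)
}

#' High-frequency DMC genes
#'
#' Counts DMCs per transcript within TSS +/- `window` and reports
#' transcripts carrying at least `min_count` of them, with member DMCs
#' and the dominant direction (majority sign of the methylation
#' difference; exact ties are "mixed").
#'
#' @param dmcs called DMC data frame with `chrom`, `start`, `end`,
#'   `meth_diff`.
#' @param annotation transcript model.
#' @param window half-width around the TSS in bp (default 10000).
#' @param min_count minimum DMCs per transcript (default 5, inclusive
#'   "at least").
#' @param assignment "all" (a DMC counts toward every transcript whose
#'   window contains it, default) or "nearest".
#' @return data frame: `transcript_id`, `gene_id`, `dmc_count`,
#'   `dominant_direction`; member DMCs in the `members` attribute (a
#'   named list of data frames).
#' @export
high_frequency_genes <- function(dmcs, annotation, window = 10000,
                                 min_count = 5,
                                 assignment = c("all", "nearest")) {
  hits <- dmcs_per_transcript(dmcs, annotation, window, assignment)
  empty <- data.frame(transcript_id = character(), gene_id = character(),
                      dmc_count = integer(),
                      dominant_direction = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(hits)) { attr(empty, "members") <- list(); return(empty) }
  sp <- split(hits$dmc_idx, hits$transcript_id)
  cnt <- lengths(sp)
  keep <- cnt >= min_count
  if (!any(keep)) { attr(empty, "members") <- list(); return(empty) }
  sp <- sp[keep]
  dom <- vapply(sp, function(i) {
    s <- sign(dmcs$meth_diff[i])
    if (sum(s > 0) > sum(s < 0)) "hyper"
    else if (sum(s < 0) > sum(s > 0)) "hypo"
    else "mixed"
  }, character(1))
  out <- data.frame(transcript_id = names(sp),
                    gene_id = annotation$gene_id[
                      match(names(sp), annotation$transcript_id)],
                    dmc_count = as.integer(lengths(sp)),
                    dominant_direction = dom, stringsAsFactors = FALSE)
  o <- order(-out$dmc_count, out$transcript_id)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- lapply(sp[out$transcript_id], function(i)
    dmcs[i, , drop = FALSE])
  out
}

#' Distribution of DMC counts per transcript
#'
#' Counts per transcript within TSS +/- `window`, including transcripts
#' with fewer than five DMCs, plus median and quartiles of the count
#' vector.
#'
#' @inheritParams high_frequency_genes
#' @return list: `counts` (named integer vector per transcript),
#'   `summary` (median and quartiles).
#' @export
dmc_frequency_distribution <- function(dmcs, annotation, window = 10000,
                                       assignment = c("all", "nearest")) {
  hits <- dmcs_per_transcript(dmcs, annotation, window, assignment)
  counts <- table(hits$transcript_id)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts,
       summary = if (length(counts))
         stats::quantile(counts, c(0.25, 0.5, 0.75)) else
           stats::setNames(rep(NA_real_, 3), c("25%", "50%", "75%")))
}

#' Distribution of absolute DMC distances to the nearest TSS
#'
#' @param dmcs annotated DMCs with `distance_to_tss`.
#' @return list: `distances` (absolute, bp), `median`, `iqr`,
#'   `frac_within_10kb`.
#' @export
tss_distance_distribution <- function(dmcs) {
  stopifnot_cols(dmcs, "distance_to_tss", "dmcs")
  d <- abs(dmcs$distance_to_tss[!is.na(dmcs$distance_to_tss)])
  list(distances = d,
       median = stats::median(d),
       iqr = stats::IQR(d),
       frac_within_10kb = mean(d < 10000))
}

#' Per-chromosome hyper/hypo counts of called loci
#'
#' @param results a called `meth_diff` (or any data frame with `chrom`
#'   and `direction`).
#' @return data frame: `chrom`, `hyper`, `hypo`.
#' @export
chromosome_direction_counts <- function(results) {
  stopifnot_cols(results, c("chrom", "direction"), "results")
  called <- results[results$direction %in% c("hyper", "hypo"), ,
                    drop = FALSE]
  chroms <- sort(unique(results$chrom))
  tab <- table(factor(called$chrom, levels = chroms),
               factor(called$direction, levels = c("hyper", "hypo")))
  data.frame(chrom = chroms, hyper = as.integer(tab[, "hyper"]),
             hypo = as.integer(tab[, "hypo"]), stringsAsFactors = FALSE)
}

#' Venn partition of named sets
#'
#' Full Venn partition of 2--4 named sets: every non-empty membership
#' pattern with its cardinality and member list, plus pairwise Jaccard
#' indices. Partitions are disjoint and exhaustive over the union.
#'
#' @param sets named list of 2--4 character vectors.
#' @return list of class `overlap_report`: `partition` (data frame with
#'   `pattern`, `n`), `members` (named list), `jaccard` (matrix).
#' @export
overlap_sets <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("overlap_sets: sets must be named")
  if (length(sets) < 2 || length(sets) > 4)
    stop("overlap_sets: between 2 and 4 sets are supported")
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets)))
  if (!length(universe)) {
    out <- list(partition = data.frame(pattern = character(),
                                       n = integer(),
                                       stringsAsFactors = FALSE),
                members = list(),
                jaccard = matrix(NA_real_, length(sets), length(sets),
                                 dimnames = list(names(sets),
                                                 names(sets))))
    class(out) <- "overlap_report"
    return(out)
  }
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL,
                                                            names(sets)))
  pattern <- apply(memb, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  members <- split(universe, pattern)
  partition <- data.frame(pattern = names(members),
                          n = lengths(members), stringsAsFactors = FALSE)
  rownames(partition) <- NULL
  k <- length(sets)
  jac <- matrix(1, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    u <- length(union(sets[[i]], sets[[j]]))
    jac[i, j] <- if (u == 0) NA_real_ else
      length(intersect(sets[[i]], sets[[j]])) / u
  }
  out <- list(partition = partition, members = members, jaccard = jac)
  class(out) <- "overlap_report"
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report:\n")
  print(x$partition)
  invisible(x)
}

#' Cross-category gene overlaps (DMC vs DMR vs DMP)
#'
#' Intersects per-category gene sets; when `direction_aware`, a gene
#' matches across categories only if its direction agrees in every
#' category of the combination, so the direction-aware result is always
#' a subset of the direction-agnostic one.
#'
#' @param dmc_genes,dmr_genes,dmp_genes data frames with `gene_id` and
#'   `direction` ("hyper"/"hypo"); `dmp_genes` may be `NULL`.
#' @param direction_aware require matching directions (default TRUE).
#' @return named list of gene-id vectors, one per category combination
#'   ("DMC&DMR", "DMC&DMP", "DMR&DMP", "DMC&DMR&DMP").
#' @export
cross_category_overlap <- function(dmc_genes, dmr_genes, dmp_genes = NULL,
                                   direction_aware = TRUE) {
  cats <- list(DMC = dmc_genes, DMR = dmr_genes)
  if (!is.null(dmp_genes)) cats$DMP <- dmp_genes
  for (nm in names(cats))
    stopifnot_cols(cats[[nm]], c("gene_id", "direction"), nm)
  keyed <- lapply(cats, function(df) {
    df <- df[df$direction %in% c("hyper", "hypo"), , drop = FALSE]
    if (direction_aware) unique(paste(df$gene_id, df$direction)) else
      unique(df$gene_id)
  })
  combos <- utils::combn(names(cats), 2, simplify = FALSE)
  if (length(cats) == 3) combos <- c(combos, list(names(cats)))
  out <- lapply(combos, function(cc) {
    common <- Reduce(intersect, keyed[cc])
    if (direction_aware) sort(unique(sub(" .*$", "", common))) else
      sort(common)
  })
  stats::setNames(out, vapply(combos, paste, character(1), collapse = "&"))
}
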