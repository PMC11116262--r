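#' Tile chromosomes into fixed, non-overlapping windows
#'
#' Windows are anchored at `k*window + 1` in 1-based inclusive
#' coordinates, so with the default 1-kb window position 1,203,500 falls
#' in the window `[1203001, 1204000]`. The last window of each chromosome
#' is truncated at the chromosome end.
#'
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param window window size in bp (default 1000).
#' @return data frame: `chrom`, `start`, `end`, `kind = "tile"`.
#' @export
tile_genome <- function(chrom_sizes, window = 1000) {
  stopifnot(window >= 1, !is.null(names(chrom_sizes)))
  out <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    n <- ceiling(L / window)
    start <- (seq_len(n) - 1L) * as.integer(window) + 1L
    data.frame(chrom = ch, start = start,
               end = pmin(start + as.integer(window) - 1L, as.integer(L)),
               kind = "tile", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Promoter regions around transcription start sites
#'
#' One region per transcript, `TSS - flank` to `TSS + flank`, clipped at
#' position 1 (and at the chromosome end when sizes are given).
#' Transcript isoforms producing identical intervals are deduplicated,
#' keeping the lexicographically smallest transcript id as owner.
#'
#' @param annotation transcript model (see [read_annotation()]).
#' @param flank half-width in bp (default 1000).
#' @param chrom_sizes optional named vector used to clip at chromosome
#'   ends.
#' @param dedup drop duplicate identical intervals (default TRUE).
#' @return data frame: `chrom`, `start`, `end`, `kind = "promoter"`,
#'   `owner` (transcript id), `gene_id`.
#' @export
promoter_regions <- function(annotation, flank = 1000, chrom_sizes = NULL,
                             dedup = TRUE) {
  if (!nrow(annotation))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), kind = character(),
                      owner = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  start <- pmax(1L, annotation$tss - as.integer(flank))
  end <- annotation$tss + as.integer(flank)
  if (!is.null(chrom_sizes))
    end <- pmin(end, as.integer(chrom_sizes[annotation$chrom]))
  out <- data.frame(chrom = annotation$chrom, start = start, end = end,
                    kind = "promoter", owner = annotation$transcript_id,
                    gene_id = annotation$gene_id, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$owner), , drop = FALSE]
  if (dedup)
    out <- out[!duplicated(out[, c("chrom", "start", "end")]), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate site counts into region counts
#'
#' Sums methylated counts and coverage over the CpG sites contained in
#' each region, per sample; regions containing no united site are dropped
#' (their number is recorded in the `n_dropped_empty` attribute). The
#' result feeds [diff_methylation()] unchanged.
#'
#' @param mm a site-level `meth_matrix`.
#' @param regions data frame with `chrom`, `start`, `end`, optional
#'   `kind`/`owner`.
#' @return a `meth_matrix` over regions (`type` from `regions$kind`).
#' @export
aggregate_region_counts <- function(mm, regions) {
  stopifnot(inherits(mm, "meth_matrix"))
  stopifnot_cols(regions, c("chrom", "start", "end"), "regions")
  gr_sites <- loci_granges(mm$loci)
  gr_regions <- loci_granges(regions)
  ov <- GenomicRanges::findOverlaps(gr_sites, gr_regions)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  if (!length(qi))
    stop("no region contains any united CpG site")
  nm <- rowsum(mm$n_meth[qi, , drop = FALSE], si)
  cv <- rowsum(mm$coverage[qi, , drop = FALSE], si)
  ridx <- as.integer(rownames(nm))
  loci <- regions[ridx, c("chrom", "start", "end"), drop = FALSE]
  if (!is.null(regions$owner)) loci$owner <- regions$owner[ridx]
  o <- order(loci$chrom, loci$start)
  out <- list(loci = loci[o, , drop = FALSE],
              n_meth = nm[o, , drop = FALSE],
              coverage = cv[o, , drop = FALSE],
              design = mm$design,
              type = if (!is.null(regions$kind)) regions$kind[ridx[1]] else
                "region")
  rownames(out$loci) <- NULL
  colnames(out$n_meth) <- colnames(out$coverage) <- mm$design$sample_id
  attr(out, "n_dropped_empty") <- nrow(regions) - length(ridx)
  class(out) <- "meth_matrix"
  out
}

#' Annotate loci with their nearest transcription start site
#'
#' For each locus, the transcript whose TSS is closest is reported with a
#' signed distance in transcript orientation: negative upstream of the
#' TSS, positive downstream, 0 when the locus overlaps/contains the TSS
#' base. For an interval locus the distance is the minimum over its
#' bases. Ties are broken by the lexicographically smallest transcript
#' id. Loci on chromosomes absent from the annotation get the sentinel
#' transcript "unassigned" and an `NA` distance.
#'
#' @param loci data frame with `chrom`, `start`, `end` (sites have
#'   `start == end`).
#' @param annotation transcript model.
#' @return the loci joined with `transcript_id`, `gene_id`,
#'   `distance_to_tss`.
#' @export
nearest_tss <- function(loci, annotation) {
  stopifnot_cols(loci, c("chrom", "start", "end"), "loci")
  n <- nrow(loci)
  tx <- rep("unassigned", n)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  ann_by_chrom <- split(annotation, annotation$chrom)
  for (ch in unique(loci$chrom)) {
    li <- which(loci$chrom == ch)
    ann <- ann_by_chrom[[ch]]
    if (is.null(ann) || !nrow(ann)) next
    ann <- ann[order(ann$transcript_id), , drop = FALSE]
    # edge distance of every locus to every TSS on this chromosome;
    # columns sorted by transcript id so the first minimum is the
    # tie-break winner
    D <- outer(loci$start[li], ann$tss, `-`)          # start - tss
    D2 <- outer(loci$end[li], ann$tss, `-`)           # end - tss
    A <- pmax(D, -D2, 0)                              # |edge distance|
    best <- max.col(-A, ties.method = "first")
    sel <- cbind(seq_along(li), best)
    tx[li] <- ann$transcript_id[best]
    gene[li] <- ann$gene_id[best]
    raw <- A[sel]
    upstream <- ifelse(ann$strand[best] == "+",
                       loci$end[li] < ann$tss[best],
                       loci$start[li] > ann$tss[best])
    dist[li] <- ifelse(raw == 0, 0, ifelse(upstream, -raw, raw))
  }
  if (any(tx == "unassigned"))
    message(sum(tx == "unassigned"),
            " locus/loci on chromosomes absent from the annotation left ",
            "unassigned")
  out <- as.data.frame(loci)
  class(out) <- "data.frame"
  out$transcript_id <- tx
  out$gene_id <- gene
  out$distance_to_tss <- dist
  out
}

#' Classify loci into gene feature classes
#'
#' Precedence promoter > exon > intron > intergenic: a locus overlapping
#' a promoter is "promoter" regardless of exons; "intron" means inside a
#' transcript body but overlapping no exon; anything else is
#' "intergenic". The classes partition any locus set.
#'
#' @param loci data frame with `chrom`, `start`, `end`.
#' @param annotation transcript model.
#' @param promoters promoter regions from [promoter_regions()].
#' @param precedence class order, highest first.
#' @return character vector of feature classes, one per locus.
#' @export
classify_feature <- function(loci, annotation, promoters,
                             precedence = c("promoter", "exon", "intron",
                                            "intergenic")) {
  stopifnot(setequal(precedence,
                     c("promoter", "exon", "intron", "intergenic")))
  gr <- loci_granges(loci)
  in_prom <- overlaps_any(gr, promoters)
  ex <- exon_table(annotation)
  in_exon <- overlaps_any(gr, ex)
  bodies <- data.frame(chrom = annotation$chrom,
                       start = annotation$tx_start,
                       end = annotation$tx_end, stringsAsFactors = FALSE)
  in_body <- overlaps_any(gr, bodies)
  flags <- cbind(promoter = in_prom, exon = in_exon,
                 intron = in_body & !in_exon,
                 intergenic = TRUE)
  # first TRUE in precedence order wins
  ord <- flags[, precedence, drop = FALSE]
  precedence[max.col(ord, ties.method = "first")]
}

overlaps_any <- function(gr, regions) {
  if (is.null(regions) || !nrow(regions))
    return(rep(FALSE, length(gr)))
  IRanges::overlapsAny(gr, loci_granges(regions))
}

exon_table <- function(annotation) {
  if (!nrow(annotation))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  st <- strsplit(annotation$exon_starts, ",")
  en <- strsplit(annotation$exon_ends, ",")
  data.frame(chrom = rep(annotation$chrom, lengths(st)),
             start = as.integer(unlist(st)),
             end = as.integer(unlist(en)), stringsAsFactors = FALSE)
}

#' Feature-class proportions of a called locus set
#'
#' @param feature_class character vector from [classify_feature()] (or a
#'   loci data frame with a `feature_class` column).
#' @return named numeric vector of fractions over promoter, exon,
#'   intron, intergenic, summing to 1.
#' @export
feature_proportions <- function(feature_class) {
  if (is.data.frame(feature_class)) {
    stopifnot_cols(feature_class, "feature_class")
    feature_class <- feature_class$feature_class
  }
  if (!length(feature_class))
    stop("feature_proportions: empty locus set")
  lv <- c("promoter", "exon", "intron", "intergenic")
  tab <- table(factor(feature_class, levels = lv))
  stats::setNames(as.numeric(tab) / length(feature_class), lv)
}
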