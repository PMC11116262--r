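#' Read a Bismark-coverage-style methylation call file
#'
#' Six tab-separated columns: chrom, start, end, percent methylation,
#' methylated count, unmethylated count. Both the 1-based
#' (`start == end`) and the 0-based half-open (`start == end - 1`)
#' dialects are autodetected per file; a mix within one file is an error.
#' The percent column is recomputed from the counts and must agree within
#' 0.5 percentage points, otherwise a warning is emitted and the counts
#' win. Records with zero coverage are dropped; the drop count is kept in
#' the `n_dropped` attribute.
#'
#' @param path file path.
#' @param merge_strands when `TRUE`, counts reported on the `-` strand (as
#'   position of the G) are merged onto the `+`-strand CpG position one
#'   base upstream when both appear; merges are counted in the
#'   `n_merged` attribute. Off by default: most callers destrand upstream.
#' @return data frame: `chrom`, `pos` (1-based C position), `strand`,
#'   `n_meth`, `n_unmeth`; attributes `n_dropped`, `n_merged`.
#' @export
read_bismark_cov <- function(path, merge_strands = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 6L)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected 6 tab-separated fields",
                 bad[1], path))
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  if (anyNA(start) || anyNA(end))
    stop("non-numeric start/end field in ", path)
  one_based <- all(start == end)
  zero_based <- all(start == end - 1L)
  if (!one_based && !zero_based)
    stop("inconsistent coordinate dialect in ", path,
         ": expected start == end (1-based) or start == end - 1 (0-based) ",
         "on every line")
  pos <- end
  n_meth <- as.integer(m[, 5]); n_unmeth <- as.integer(m[, 6])
  if (anyNA(n_meth) || anyNA(n_unmeth) || any(n_meth < 0) || any(n_unmeth < 0))
    stop("invalid count field in ", path)
  cov <- n_meth + n_unmeth
  pct_stored <- suppressWarnings(as.numeric(m[, 4]))
  has_cov <- cov > 0
  pct <- ifelse(has_cov, 100 * n_meth / pmax(cov, 1L), NA_real_)
  off <- which(has_cov & !is.na(pct_stored) & abs(pct - pct_stored) > 0.5)
  if (length(off))
    warning(sprintf(paste0("%d record(s) in %s have a stored %%methylation ",
                           "differing from the counts by > 0.5 points; ",
                           "counts win"), length(off), path))
  n_dropped <- sum(!has_cov)
  out <- data.frame(chrom = m[has_cov, 1], pos = pos[has_cov],
                    strand = "+", n_meth = n_meth[has_cov],
                    n_unmeth = n_unmeth[has_cov], stringsAsFactors = FALSE)
  n_merged <- 0L
  if (merge_strands && nrow(out) > 1) {
    # a record at pos p+1 whose predecessor sits at p is treated as the
    # G of the same CpG and merged onto p
    key <- paste(out$chrom, out$pos)
    prev <- paste(out$chrom, out$pos - 1L)
    hit <- match(prev, key)
    is_minus <- !is.na(hit)
    if (any(is_minus)) {
      tgt <- hit[is_minus]
      src <- which(is_minus)
      agg_m <- tapply(out$n_meth[src], tgt, sum)
      agg_u <- tapply(out$n_unmeth[src], tgt, sum)
      ti <- as.integer(names(agg_m))
      out$n_meth[ti] <- out$n_meth[ti] + as.integer(agg_m)
      out$n_unmeth[ti] <- out$n_unmeth[ti] + as.integer(agg_u)
      n_merged <- length(src)
      out <- out[-src, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_merged") <- n_merged
  out
}

#' Write methylation calls in Bismark coverage format
#'
#' @param calls data frame with `chrom`, `pos`, `n_meth`, `n_unmeth`.
#' @param path output path.
#' @export
write_bismark_cov <- function(calls, path) {
  stopifnot_cols(calls, c("chrom", "pos", "n_meth", "n_unmeth"), "calls")
  cov <- calls$n_meth + calls$n_unmeth
  df <- data.frame(calls$chrom, calls$pos, calls$pos,
                   formatC(100 * calls$n_meth / cov, format = "f",
                           digits = 6),
                   calls$n_meth, calls$n_unmeth)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group design table
#'
#' Two-column TSV (`sample_id`, `group`) describing one two-group
#' comparison.
#'
#' @param path file path.
#' @param reference the reference (control) group label; defaults to
#'   "control" when present, otherwise the first group in file order.
#' @return data frame with attribute `reference`.
#' @export
read_design <- function(path, reference = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot_cols(df, c("sample_id", "group"), "design")
  validate_design(df, reference)
}

validate_design <- function(df, reference = NULL) {
  if (anyDuplicated(df$sample_id))
    stop("design: sample_id values must be unique")
  groups <- unique(df$group)
  if (length(groups) != 2)
    stop("design must describe exactly 2 groups, got ",
         length(groups))
  if (is.null(reference)) reference <- attr(df, "reference")
  if (is.null(reference))
    reference <- if ("control" %in% groups) "control" else groups[1]
  if (!reference %in% groups)
    stop("reference group '", reference, "' is not among the design groups")
  attr(df, "reference") <- reference
  df
}

#' Read a transcript annotation (BED12 or GTF)
#'
#' Returns the transcript model used throughout the package: one row per
#' transcript with a strand-aware TSS (`tx_start` on `+`, `tx_end` on
#' `-`) and exon intervals in 1-based inclusive coordinates.
#'
#' @param path file path.
#' @param format "bed12" or "gtf".
#' @return data frame: `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `tss`, `exon_starts`, `exon_ends`.
#' @export
read_annotation <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "bed12") read_annotation_bed12(path) else
    read_annotation_gtf(path)
}

read_annotation_bed12 <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 12) stop("BED12 requires 12 columns, got ", ncol(df))
  strand <- df[[6]]
  if (any(!strand %in% c("+", "-")))
    stop("transcript without strand: TSS is undefined")
  name <- df[[4]]
  tx_id <- sub("\\|.*$", "", name)
  gene <- ifelse(grepl("|", name, fixed = TRUE),
                 sub("^[^|]*\\|", "", name), tx_id)
  tx_start <- df[[2]] + 1L          # BED is 0-based half-open
  tx_end <- df[[3]]
  sizes <- lapply(strsplit(sub(",$", "", df[[11]]), ","), as.integer)
  offs <- lapply(strsplit(sub(",$", "", df[[12]]), ","), as.integer)
  ex_start <- mapply(function(s, o, txs) txs + o, sizes, offs, tx_start,
                     SIMPLIFY = FALSE)
  ex_end <- mapply(function(st, sz) st + sz - 1L, ex_start, sizes,
                   SIMPLIFY = FALSE)
  build_annotation(tx_id, gene, df[[1]], strand, tx_start, tx_end,
                   ex_start, ex_end)
}

read_annotation_gtf <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 9) stop("GTF requires 9 columns, got ", ncol(df))
  get_attr <- function(attrs, key) {
    rx <- regexpr(paste0(key, ' "[^"]+"'), attrs)
    res <- rep(NA_character_, length(attrs))
    hit <- rx > 0
    val <- regmatches(attrs, rx)
    res[hit] <- sub('"$', "", sub(paste0(key, ' "'), "", val, fixed = TRUE))
    res
  }
  ex <- df[df[[3]] == "exon", , drop = FALSE]
  if (!nrow(ex)) stop("GTF contains no exon features")
  if (any(!ex[[7]] %in% c("+", "-")))
    stop("transcript without strand: TSS is undefined")
  tx_id <- get_attr(ex[[9]], "transcript_id")
  gene <- get_attr(ex[[9]], "gene_id")
  if (anyNA(tx_id)) stop("GTF exon without transcript_id attribute")
  sp <- split(seq_len(nrow(ex)), tx_id)
  ids <- names(sp)
  ex_start <- lapply(sp, function(i) sort(as.integer(ex[i, 4])))
  ex_end <- lapply(sp, function(i) sort(as.integer(ex[i, 5])))
  first <- vapply(sp, `[`, integer(1), 1L)
  build_annotation(ids, gene[first], ex[first, 1], ex[first, 7],
                   vapply(ex_start, min, integer(1)),
                   vapply(ex_end, max, integer(1)),
                   ex_start, ex_end)
}

build_annotation <- function(tx_id, gene, chrom, strand, tx_start, tx_end,
                             ex_start, ex_end) {
  for (i in seq_along(ex_start)) {
    o <- order(ex_start[[i]])
    ex_start[[i]] <- ex_start[[i]][o]; ex_end[[i]] <- ex_end[[i]][o]
    if (length(o) > 1 && any(ex_start[[i]][-1] <= ex_end[[i]][-length(o)]))
      stop("overlapping exons within transcript ", tx_id[i])
  }
  ann <- data.frame(
    transcript_id = tx_id, gene_id = gene, chrom = chrom, strand = strand,
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    tss = ifelse(strand == "+", as.integer(tx_start), as.integer(tx_end)),
    exon_starts = vapply(ex_start, paste, character(1), collapse = ","),
    exon_ends = vapply(ex_end, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  ann <- ann[order(ann$transcript_id), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Write a transcript annotation as BED12
#'
#' The BED name field carries `transcript_id|gene_id` so the gene mapping
#' round-trips.
#'
#' @param ann annotation data frame (see [read_annotation()]).
#' @param path output path.
#' @export
write_annotation_bed12 <- function(ann, path) {
  starts <- lapply(strsplit(ann$exon_starts, ","), as.integer)
  ends <- lapply(strsplit(ann$exon_ends, ","), as.integer)
  sizes <- mapply(function(s, e) paste0(paste(e - s + 1L, collapse = ","),
                                        ","), starts, ends)
  offs <- mapply(function(s, txs) paste0(paste(s - txs, collapse = ","),
                                         ","), starts, ann$tx_start)
  df <- data.frame(ann$chrom, ann$tx_start - 1L, ann$tx_end,
                   paste0(ann$transcript_id, "|", ann$gene_id), 0L,
                   ann$strand, ann$tx_start - 1L, ann$tx_end, "0,0,0",
                   lengths(starts), sizes, offs)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a results table with a parameter-recording header
#'
#' TSV with stable column order and `#`-prefixed header comments recording
#' thresholds, seed and package version; [read_results()] reads it back.
#'
#' @param results data frame.
#' @param path output path.
#' @param kind one of "dmc", "dmr", "dmp", "genes".
#' @param params named list recorded in the header.
#' @export
write_results <- function(results, path,
                          kind = c("dmc", "dmr", "dmp", "genes"),
                          params = list()) {
  kind <- match.arg(kind)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s", kind), con)
  writeLines(sprintf("# package=methdiffscan %s",
                     as.character(utils::packageVersion("methdiffscan"))),
             con)
  for (nm in names(params))
    writeLines(sprintf("# %s=%s", nm, paste(params[[nm]], collapse = ",")),
               con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Export loci as BED intervals
#'
#' Converts the package's 1-based inclusive loci to BED's 0-based
#' half-open convention: a single site at position p becomes `[p-1, p)`.
#'
#' @param loci data frame with `chrom`, `start`, `end` (and optionally
#'   `name`, `score`).
#' @param path output path.
#' @export
write_bed <- function(loci, path) {
  stopifnot_cols(loci, c("chrom", "start", "end"), "loci")
  df <- data.frame(loci$chrom, loci$start - 1L, loci$end,
                   loci$name %||% ".", loci$score %||% 0L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: term, description, then member genes, tab
#'   separated.
#' @return named list of character vectors (term -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": need term, description, >=1 gene")
  stats::setNames(lapply(parts, function(x) unique(x[-(1:2)])),
                  vapply(parts, `[`, character(1), 1L))
}

#' Read a differential-expression table
#'
#' TSV with columns `gene_id`, `log2_fold_change`, `adjusted_p` and
#' optionally `de_flag` (derived as `adjusted_p < 0.05` when absent).
#'
#' @param path file path.
#' @return validated data frame.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot_cols(df, c("gene_id", "log2_fold_change", "adjusted_p"),
                 "expression")
  if (any(df$adjusted_p < 0 | df$adjusted_p > 1))
    stop("expression: adjusted_p must lie in [0, 1]")
  if (is.null(df$de_flag)) df$de_flag <- df$adjusted_p < 0.05
  df
}
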