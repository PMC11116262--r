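#' Build and validate a pipeline run configuration
#'
#' Collects paths, the comparison, stage parameters and the seed for
#' [run_pipeline()]. All referenced files are checked for existence at
#' validation time, before any compute.
#'
#' @param samples named character vector or list: sample id -> Bismark
#'   coverage file.
#' @param design design-table path or data frame (see [read_design()]).
#' @param annotation annotation path or data frame (see
#'   [read_annotation()]).
#' @param annotation_format "bed12" or "gtf" (for a path).
#' @param out_dir output directory.
#' @param expression optional expression-table path or data frame.
#' @param gmt optional GMT gene-set path for enrichment.
#' @param params named list overriding stage defaults: `min_coverage`
#'   (10), `max_coverage_percentile` (99.9), `q_max` (0.01),
#'   `min_abs_diff` (25), `tile_window` (1000), `promoter_flank` (1000),
#'   `score_window` (10000), `hifreq_min_count` (5), `topdmc_max_dist`
#'   (10000), `topdmc_min_diff` (30), `min_dmcs` (2).
#' @param seed RNG seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @param verbose emit per-stage messages.
#' @return list of class `run_config`.
#' @export
run_config <- function(samples, design, annotation,
                       annotation_format = "bed12", out_dir,
                       expression = NULL, gmt = NULL, params = list(),
                       seed = 1L, verbose = TRUE) {
  defaults <- list(min_coverage = 10, max_coverage_percentile = 99.9,
                   q_max = 0.01, min_abs_diff = 25, tile_window = 1000,
                   promoter_flank = 1000, score_window = 10000,
                   hifreq_min_count = 5, topdmc_max_dist = 10000,
                   topdmc_min_diff = 30, min_dmcs = 2)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("run_config: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, params)
  with(params, stopifnot(min_coverage >= 1, q_max > 0, q_max <= 1,
                         min_abs_diff >= 0, tile_window >= 1,
                         promoter_flank >= 1, score_window >= 1,
                         hifreq_min_count >= 1, min_dmcs >= 1))
  for (p in c(unlist(samples),
              if (is.character(design)) design,
              if (is.character(annotation)) annotation,
              if (is.character(expression)) expression,
              if (is.character(gmt)) gmt)) {
    if (is.character(p) && !file.exists(p))
      stop("run_config: file does not exist: ", p)
  }
  cfg <- list(samples = samples, design = design, annotation = annotation,
              annotation_format = annotation_format, out_dir = out_dir,
              expression = expression, gmt = gmt, params = params,
              seed = as.integer(seed), verbose = isTRUE(verbose))
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()]: `samples` (map of
#' id to path), `design`, `annotation`, `annotation_format`, `out_dir`,
#' optional `expression`, `gmt`, `params`, `seed`.
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the differential-methylation pipeline end to end
#'
#' Executes import, unite, the DMC/DMR/DMP tests, TSS annotation, gene
#' scoring, overlap analysis and (when inputs are given) the
#' methylation--expression correlation and gene-set enrichment, writing
#' plain-text intermediates for every stage plus a JSON manifest with
#' parameters, seed, per-stage record counts and output checksums. A
#' stage failure aborts with the stage name.
#'
#' @param config a `run_config` (or YAML path).
#' @return invisibly, a list with the manifest and the in-memory stage
#'   results (`dmc`, `dmr`, `dmp`, `dmc_annotated`, `top_dmc_genes`,
#'   `hifreq`, `feature_proportions`, `chrom_counts`, `correlation`,
#'   `enrichment`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  pp <- config$params
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "methdiffscan",
                   version = as.character(
                     utils::packageVersion("methdiffscan")),
                   seed = config$seed, params = pp, stages = list())
  outputs <- character()
  res <- list()
  stage <- function(name, expr) {
    msg("stage: ", name, verbose = config$verbose)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  record <- function(name, n, files = character()) {
    manifest$stages[[name]] <<- list(n_records = n,
                                     outputs = as.list(files))
    outputs <<- c(outputs, files)
  }
  out_path <- function(x) file.path(config$out_dir, x)

  design <- stage("import", {
    if (is.character(config$design)) read_design(config$design) else
      validate_design(config$design)
  })
  samples <- stage("import", {
    lapply(config$samples, function(s)
      if (is.character(s)) read_bismark_cov(s) else s)
  })
  ann <- stage("import", {
    if (is.character(config$annotation))
      read_annotation(config$annotation, config$annotation_format) else
        config$annotation
  })
  record("import", length(samples))

  mm <- stage("unite", unite(samples, design,
                             min_coverage = pp$min_coverage,
                             max_coverage_percentile =
                               pp$max_coverage_percentile))
  record("unite", nrow(mm$loci))

  hdr <- list(seed = config$seed, q_max = pp$q_max,
              min_abs_diff = pp$min_abs_diff)
  res$dmc <- stage("dmc", {
    r <- call_differential(diff_methylation(mm), q_max = pp$q_max,
                           min_abs_diff = pp$min_abs_diff)
    write_results(as.data.frame(r), out_path("dmc.tsv"), "dmc", hdr)
    r
  })
  record("dmc", nrow(res$dmc), out_path("dmc.tsv"))

  chrom_sizes <- stage("dmr", {
    s <- tapply(c(mm$loci$end, ann$tx_end),
                c(mm$loci$chrom, ann$chrom), max)
    stats::setNames(as.integer(s), names(s))
  })
  res$dmr <- stage("dmr", {
    tiles <- tile_genome(chrom_sizes, window = pp$tile_window)
    rm <- aggregate_region_counts(mm, tiles)
    r <- call_differential(diff_methylation(rm), q_max = pp$q_max,
                           min_abs_diff = pp$min_abs_diff)
    write_results(as.data.frame(r), out_path("dmr.tsv"), "dmr", hdr)
    r
  })
  record("dmr", nrow(res$dmr), out_path("dmr.tsv"))

  proms <- stage("dmp", promoter_regions(ann, flank = pp$promoter_flank,
                                         chrom_sizes = chrom_sizes))
  res$dmp <- stage("dmp", {
    pm <- aggregate_region_counts(mm, proms)
    r <- call_differential(diff_methylation(pm), q_max = pp$q_max,
                           min_abs_diff = pp$min_abs_diff)
    write_results(as.data.frame(r), out_path("dmp.tsv"), "dmp", hdr)
    r
  })
  record("dmp", nrow(res$dmp), out_path("dmp.tsv"))

  res$dmc_annotated <- stage("annotate", {
    called <- get_calls(res$dmc)
    a <- nearest_tss(called, ann)
    a$feature_class <- if (nrow(a))
      classify_feature(a, ann, proms) else character()
    write_results(a, out_path("dmc_annotated.tsv"), "genes", hdr)
    a
  })
  record("annotate", nrow(res$dmc_annotated),
         out_path("dmc_annotated.tsv"))

  score <- stage("score", {
    tg <- top_dmc_genes(res$dmc_annotated,
                        max_dist = pp$topdmc_max_dist,
                        min_abs_diff = pp$topdmc_min_diff)
    hf <- high_frequency_genes(get_calls(res$dmc), ann,
                               window = pp$score_window,
                               min_count = pp$hifreq_min_count)
    fp <- if (nrow(res$dmc_annotated))
      feature_proportions(res$dmc_annotated) else NULL
    cc <- chromosome_direction_counts(res$dmc)
    write_results(data.frame(gene_id = tg),
                  out_path("top_dmc_genes.tsv"), "genes", hdr)
    write_results(hf, out_path("hifreq_genes.tsv"), "genes", hdr)
    write_results(cc, out_path("chrom_counts.tsv"), "genes", hdr)
    list(top_dmc_genes = tg, hifreq = hf, feature_proportions = fp,
         chrom_counts = cc)
  })
  res <- c(res, score)
  record("score", length(res$top_dmc_genes) + nrow(res$hifreq),
         out_path(c("top_dmc_genes.tsv", "hifreq_genes.tsv",
                    "chrom_counts.tsv")))

  if (!is.null(config$expression)) {
    res$correlation <- stage("integrate", {
      expr <- if (is.character(config$expression))
        read_expression(config$expression) else config$expression
      summ <- gene_meth_summaries(get_calls(res$dmc_annotated), ann,
                                  window = pp$score_window,
                                  min_dmcs = pp$min_dmcs)
      cor <- tryCatch(meth_expr_correlation(summ, expr),
                      error = function(e) {
                        msg("integrate: ", conditionMessage(e),
                            verbose = config$verbose)
                        NULL
                      })
      if (!is.null(cor))
        write_results(cor$pairs, out_path("meth_expr_pairs.tsv"),
                      "genes", c(hdr, rho = cor$rho, p = cor$p_value))
      cor
    })
    record("integrate", res$correlation$n_genes %||% 0L,
           if (!is.null(res$correlation)) out_path("meth_expr_pairs.tsv")
           else character())
  }

  if (!is.null(config$gmt)) {
    res$enrichment <- stage("enrich", {
      terms <- read_gmt(config$gmt)
      universe <- unique(ann$gene_id[ann$transcript_id %in%
                                       unique(nearest_tss(mm$loci,
                                                          ann)$transcript_id)])
      study <- intersect(res$top_dmc_genes, universe)
      e <- enrichment_fisher(study, universe, terms)
      write_results(e, out_path("enrichment.tsv"), "genes", hdr)
      e
    })
    record("enrich", nrow(res$enrichment), out_path("enrichment.tsv"))
  }

  manifest$stages <- manifest$stages
  manifest$checksums <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
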