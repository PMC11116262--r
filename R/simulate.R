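#' Simulation configuration for WGBS-like CpG count data
#'
#' Builds and validates the configuration driving [simulate_annotation()],
#' [simulate_counts()] and [simulate_expression()]. Defaults emulate the
#' empirical structure of duodenal WGBS data: coverage concentrated around
#' 10 reads per CpG and a bimodal methylation-percent profile with a
#' dominant peak near 95--100% and a smaller peak near 0--5%.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param cpg_spacing_bp mean distance between consecutive CpG sites (bp).
#' @param n_transcripts total number of simulated transcripts.
#' @param samples_per_group samples in each of the two groups.
#' @param mean_coverage expected reads per CpG per sample.
#' @param coverage_dispersion negative-binomial size parameter of the
#'   coverage distribution; larger is closer to Poisson. The default keeps
#'   the modal coverage at the configured mean.
#' @param bb_rho beta-binomial correlation for extra between-sample
#'   variation of methylation proportions; 0 (default) is pure binomial
#'   sampling, matching the model assumed by the locus-level test.
#' @param baseline_mixture two-component Beta mixture for the baseline
#'   methylation proportion: a list with `weight_high`, `shape_high`
#'   (length-2 Beta parameters), `weight_low`, `shape_low`.
#' @param planted_dmc,planted_dmr_tiles,planted_dmp_promoters data frames
#'   (see [plant_effects()]) with one row per planted single-CpG effect,
#'   1-kb tile effect, or promoter effect: columns `delta_percent` and
#'   `direction` ("hyper", "hypo" or "random").
#' @param planted_hifreq data frame with one row per planted DMC cluster:
#'   columns `n_dmcs` (cluster size, CpGs shifted within TSS +/- 10 kb of
#'   one transcript), `delta_percent`, `direction`.
#' @param expr_coupling_rho target rank correlation between planted
#'   gene-level methylation change and expression log2 fold change.
#' @param seed master RNG seed (mandatory); each simulation stage derives
#'   its own stream from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 3,
                       chrom_length_bp = 1e6,
                       cpg_spacing_bp = 100,
                       n_transcripts = 200,
                       samples_per_group = 3,
                       mean_coverage = 10,
                       coverage_dispersion = 20,
                       bb_rho = 0,
                       baseline_mixture = list(weight_high = 0.75,
                                               shape_high = c(20, 1),
                                               weight_low = 0.25,
                                               shape_low = c(1, 20)),
                       planted_dmc = NULL,
                       planted_dmr_tiles = NULL,
                       planted_dmp_promoters = NULL,
                       planted_hifreq = NULL,
                       expr_coupling_rho = 0,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config: 'seed' is mandatory")
  stopifnot(n_chroms >= 1, chrom_length_bp >= 1000, cpg_spacing_bp >= 2,
            n_transcripts >= 0, samples_per_group >= 1,
            mean_coverage > 0, coverage_dispersion > 0,
            bb_rho >= 0, bb_rho < 1, abs(expr_coupling_rho) <= 1)
  bm <- baseline_mixture
  w <- c(bm$weight_high, bm$weight_low)
  if (any(w < 0) || any(w > 1) || abs(sum(w) - 1) > 1e-8)
    stop("baseline_mixture weights must lie in [0,1] and sum to 1")
  for (nm in c("planted_dmc", "planted_dmr_tiles", "planted_dmp_promoters")) {
    pl <- get(nm)
    if (!is.null(pl)) {
      stopifnot_cols(pl, c("delta_percent", "direction"), nm)
      if (any(pl$delta_percent <= 0 | pl$delta_percent > 100))
        stop(nm, ": delta_percent must lie in (0, 100]")
      if (!all(pl$direction %in% c("hyper", "hypo", "random")))
        stop(nm, ": direction must be 'hyper', 'hypo' or 'random'")
    }
  }
  if (!is.null(planted_hifreq)) {
    stopifnot_cols(planted_hifreq, c("n_dmcs", "delta_percent", "direction"),
                   "planted_hifreq")
    if (any(planted_hifreq$n_dmcs < 1))
      stop("planted_hifreq: n_dmcs must be >= 1")
    if (any(planted_hifreq$delta_percent <= 0 |
            planted_hifreq$delta_percent > 100))
      stop("planted_hifreq: delta_percent must lie in (0, 100]")
  }
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length_bp = as.integer(chrom_length_bp),
              cpg_spacing_bp = cpg_spacing_bp,
              n_transcripts = as.integer(n_transcripts),
              samples_per_group = as.integer(samples_per_group),
              mean_coverage = mean_coverage,
              coverage_dispersion = coverage_dispersion,
              bb_rho = bb_rho,
              baseline_mixture = bm,
              planted_dmc = planted_dmc,
              planted_dmr_tiles = planted_dmr_tiles,
              planted_dmp_promoters = planted_dmp_promoters,
              planted_hifreq = planted_hifreq,
              expr_coupling_rho = expr_coupling_rho,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Describe a batch of planted effects
#'
#' Convenience constructor for the `planted_*` slots of [sim_config()].
#'
#' @param n number of planted entities.
#' @param delta_percent methylation difference per entity, percentage points
#'   in (0, 100].
#' @param direction "hyper", "hypo" or "random" (resolved per entity at
#'   simulation time).
#' @param n_dmcs for high-frequency clusters only: DMCs per cluster.
#' @return data frame suitable for `sim_config()`.
#' @export
plant_effects <- function(n, delta_percent, direction = "random",
                          n_dmcs = NULL) {
  out <- data.frame(delta_percent = rep_len(delta_percent, n),
                    direction = rep_len(direction, n),
                    stringsAsFactors = FALSE)
  if (!is.null(n_dmcs)) out$n_dmcs <- rep_len(as.integer(n_dmcs), n)
  out[, c(if (!is.null(n_dmcs)) "n_dmcs", "delta_percent", "direction"),
      drop = FALSE]
}

#' Simulate a transcript annotation
#'
#' Places non-overlapping transcript bodies on the configured chromosomes,
#' with random strand (about 50/50), 1--5 exons per transcript, and a
#' strand-aware TSS (transcript start on `+`, transcript end on `-`).
#'
#' @param config a [sim_config()].
#' @return data frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`, `tss`,
#'   `exon_starts`, `exon_ends` (comma-separated, 1-based inclusive).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_transcripts
  empty <- data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      tx_start = integer(), tx_end = integer(),
                      tss = integer(), exon_starts = character(),
                      exon_ends = character(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  with_stage_seed(config$seed, "annotation", {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    per_chrom <- tabulate(rep_len(seq_len(config$n_chroms), n),
                          nbins = config$n_chroms)
    min_body <- 2000L
    rows <- vector("list", n)
    i <- 0L
    for (ci in seq_len(config$n_chroms)) {
      k <- per_chrom[ci]
      if (k == 0) next
      slot <- config$chrom_length_bp %/% k
      if (slot < min_body + 200L)
        stop(sprintf(paste0("infeasible packing: %d transcripts on a %d bp ",
                            "chromosome leave slots of %d bp (< %d bp ",
                            "needed per transcript body)"),
                     k, config$chrom_length_bp, slot, min_body + 200L))
      for (j in seq_len(k)) {
        i <- i + 1L
        max_body <- min(10000L, slot - 200L)
        body <- if (max_body > min_body)
          sample(min_body:max_body, 1L) else min_body
        off <- sample.int(slot - body - 100L, 1L) + 50L
        tx_start <- (j - 1L) * slot + off
        tx_end <- tx_start + body - 1L
        strand <- sample(c("+", "-"), 1L)
        n_ex <- sample.int(5L, 1L)
        nseg <- 2L * n_ex - 1L
        wmin <- 50L
        extra <- body - nseg * wmin
        widths <- wmin + as.vector(stats::rmultinom(1L, extra,
                                                    rep(1, nseg) / nseg))
        ends <- tx_start - 1L + cumsum(widths)
        starts <- c(tx_start, ends[-nseg] + 1L)
        ex <- seq(1L, nseg, by = 2L)
        rows[[i]] <- data.frame(
          transcript_id = sprintf("tx%04d", i),
          gene_id = sprintf("g%04d", i),
          chrom = chroms[ci], strand = strand,
          tx_start = tx_start, tx_end = tx_end,
          tss = if (strand == "+") tx_start else tx_end,
          exon_starts = paste(starts[ex], collapse = ","),
          exon_ends = paste(ends[ex], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# Draw from the baseline Beta mixture; optionally truncated to an interval
# (rejection sampling with a clamping fallback, counted by the caller).
draw_baseline <- function(n, bm, lower = 0, upper = 1) {
  comp <- stats::runif(n) < bm$weight_high
  p <- ifelse(comp,
              stats::rbeta(n, bm$shape_high[1], bm$shape_high[2]),
              stats::rbeta(n, bm$shape_low[1], bm$shape_low[2]))
  if (lower > 0 || upper < 1) {
    bad <- which(p < lower | p > upper)
    tries <- 0L
    while (length(bad) && tries < 200L) {
      comp <- stats::runif(length(bad)) < bm$weight_high
      p[bad] <- ifelse(comp,
                       stats::rbeta(length(bad), bm$shape_high[1],
                                    bm$shape_high[2]),
                       stats::rbeta(length(bad), bm$shape_low[1],
                                    bm$shape_low[2]))
      bad <- bad[p[bad] < lower | p[bad] > upper]
      tries <- tries + 1L
    }
    p <- pmin(pmax(p, lower), upper)
  }
  p
}

resolve_direction <- function(direction) {
  rand <- direction == "random"
  direction[rand] <- sample(c("hyper", "hypo"), sum(rand), replace = TRUE)
  direction
}

#' Simulate per-sample CpG methylation counts with planted effects
#'
#' Draws CpG positions along each chromosome, a baseline methylation
#' proportion per site from the configured Beta mixture, and per-sample
#' coverage from a zero-truncated negative binomial around
#' `mean_coverage`. The case group's proportion is shifted by the
#' configured delta at planted loci; the baseline at a planted locus is
#' drawn from the mixture restricted to the feasible range for the
#' requested direction so the realized group difference equals the
#' configured `delta_percent` (an infeasible draw is clamped and counted
#' in the `n_clamped` attribute of the truth table).
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_annotation()]; may be `NULL` when
#'   no promoter or high-frequency effects are planted.
#' @return list of class `wgbs_sim` with elements `samples` (named list of
#'   per-sample data frames: `chrom`, `pos`, `strand`, `n_meth`,
#'   `n_unmeth`), `design` (sample/group table, reference group
#'   "control"), `truth` (one row per planted entity: `entity_id`,
#'   `category`, `chrom`, `start`, `end`, `delta_percent`, `direction`,
#'   `transcript_id`), and `planted_sites` (per-CpG membership of planted
#'   entities, for recovery audits).
#' @export
simulate_counts <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  needs_ann <- !is.null(config$planted_dmp_promoters) ||
    !is.null(config$planted_hifreq)
  if (needs_ann && is.null(annotation))
    stop("promoter or high-frequency effects are planted but no annotation ",
         "was supplied")
  with_stage_seed(config$seed, "counts", {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    pos_l <- lapply(chroms, function(ch) {
      n_est <- ceiling(config$chrom_length_bp / config$cpg_spacing_bp * 1.3) + 20
      gaps <- pmax(2, round(stats::rexp(n_est, 1 / config$cpg_spacing_bp)))
      p <- cumsum(gaps)
      as.integer(p[p <= config$chrom_length_bp])
    })
    sites <- data.frame(chrom = rep(chroms, lengths(pos_l)),
                        pos = unlist(pos_l), stringsAsFactors = FALSE)
    ns <- nrow(sites)
    bm <- config$baseline_mixture
    p_ctrl <- draw_baseline(ns, bm)
    delta <- numeric(ns)            # signed shift applied to the case group
    used <- logical(ns)
    truth <- list()
    planted_sites <- list()
    n_clamped <- 0L
    eid <- 0L

    plant_at <- function(idx, entity, dp, dir) {
      # re-draw baseline at planted sites within the feasible range
      lo <- if (dir == "hyper") 0 else dp / 100
      hi <- if (dir == "hyper") 1 - dp / 100 else 1
      b <- draw_baseline(length(idx), bm, lo, hi)
      n_clamped <<- n_clamped + sum(b < lo - 1e-12 | b > hi + 1e-12)
      p_ctrl[idx] <<- b
      delta[idx] <<- if (dir == "hyper") dp / 100 else -dp / 100
      used[idx] <<- TRUE
      planted_sites[[length(planted_sites) + 1L]] <<-
        data.frame(entity_id = entity, chrom = sites$chrom[idx],
                   pos = sites$pos[idx], delta_percent = dp,
                   direction = dir, stringsAsFactors = FALSE)
    }

    # single-CpG effects
    pd <- config$planted_dmc
    if (!is.null(pd) && nrow(pd)) {
      dirs <- resolve_direction(pd$direction)
      free <- which(!used)
      if (length(free) < nrow(pd))
        stop("not enough free CpG sites to plant ", nrow(pd), " DMCs")
      picks <- sample(free, nrow(pd))
      for (r in seq_len(nrow(pd))) {
        eid <- eid + 1L
        id <- sprintf("dmc%04d", r)
        plant_at(picks[r], id, pd$delta_percent[r], dirs[r])
        truth[[eid]] <- data.frame(entity_id = id, category = "DMC",
                                   chrom = sites$chrom[picks[r]],
                                   start = sites$pos[picks[r]],
                                   end = sites$pos[picks[r]],
                                   delta_percent = pd$delta_percent[r],
                                   direction = dirs[r],
                                   transcript_id = NA_character_,
                                   stringsAsFactors = FALSE)
      }
    }

    # 1-kb tile effects
    pt <- config$planted_dmr_tiles
    if (!is.null(pt) && nrow(pt)) {
      dirs <- resolve_direction(pt$direction)
      tile_id <- paste(sites$chrom, (sites$pos - 1L) %/% 1000L)
      elig <- split(seq_len(ns), tile_id)
      elig <- elig[vapply(elig, function(i) length(i) >= 3 && !any(used[i]),
                          logical(1))]
      if (length(elig) < nrow(pt))
        stop("not enough eligible 1-kb tiles (>= 3 free CpGs) to plant ",
             nrow(pt), " tile effects")
      picks <- sample(names(elig), nrow(pt))
      for (r in seq_len(nrow(pt))) {
        idx <- elig[[picks[r]]]
        eid <- eid + 1L
        id <- sprintf("dmr%04d", r)
        plant_at(idx, id, pt$delta_percent[r], dirs[r])
        k <- (sites$pos[idx[1]] - 1L) %/% 1000L
        truth[[eid]] <- data.frame(entity_id = id, category = "DMR",
                                   chrom = sites$chrom[idx[1]],
                                   start = k * 1000L + 1L,
                                   end = (k + 1L) * 1000L,
                                   delta_percent = pt$delta_percent[r],
                                   direction = dirs[r],
                                   transcript_id = NA_character_,
                                   stringsAsFactors = FALSE)
      }
    }

    # promoter and clustered (high-frequency) effects need transcripts
    used_tx <- character()
    site_in_window <- function(tx, flank) {
      which(sites$chrom == tx$chrom &
              sites$pos >= tx$tss - flank & sites$pos <= tx$tss + flank)
    }
    pp <- config$planted_dmp_promoters
    if (!is.null(pp) && nrow(pp)) {
      dirs <- resolve_direction(pp$direction)
      for (r in seq_len(nrow(pp))) {
        cand <- annotation[!(annotation$transcript_id %in% used_tx), ,
                           drop = FALSE]
        ok <- NULL
        for (t in sample(seq_len(nrow(cand)))) {
          idx <- site_in_window(cand[t, ], 1000L)
          idx <- idx[!used[idx]]
          if (length(idx) >= 1) { ok <- list(tx = cand[t, ], idx = idx); break }
        }
        if (is.null(ok))
          stop("no transcript with free CpGs in TSS +/- 1 kb left to plant ",
               "promoter effect ", r)
        eid <- eid + 1L
        id <- sprintf("dmp%04d", r)
        plant_at(ok$idx, id, pp$delta_percent[r], dirs[r])
        used_tx <- c(used_tx, ok$tx$transcript_id)
        truth[[eid]] <- data.frame(entity_id = id, category = "DMP",
                                   chrom = ok$tx$chrom,
                                   start = max(1L, ok$tx$tss - 1000L),
                                   end = ok$tx$tss + 1000L,
                                   delta_percent = pp$delta_percent[r],
                                   direction = dirs[r],
                                   transcript_id = ok$tx$transcript_id,
                                   stringsAsFactors = FALSE)
      }
    }
    ph <- config$planted_hifreq
    if (!is.null(ph) && nrow(ph)) {
      dirs <- resolve_direction(ph$direction)
      for (r in seq_len(nrow(ph))) {
        k <- ph$n_dmcs[r]
        cand <- annotation[!(annotation$transcript_id %in% used_tx), ,
                           drop = FALSE]
        ok <- NULL
        for (t in sample(seq_len(nrow(cand)))) {
          idx <- site_in_window(cand[t, ], 10000L)
          idx <- idx[!used[idx]]
          if (length(idx) >= k) {
            ok <- list(tx = cand[t, ], idx = sample(idx, k))
            break
          }
        }
        if (is.null(ok))
          stop("no transcript with ", k, " free CpGs in TSS +/- 10 kb left ",
               "to plant high-frequency cluster ", r)
        eid <- eid + 1L
        id <- sprintf("hifreq%04d", r)
        plant_at(ok$idx, id, ph$delta_percent[r], dirs[r])
        used_tx <- c(used_tx, ok$tx$transcript_id)
        truth[[eid]] <- data.frame(entity_id = id, category = "HIFREQ",
                                   chrom = ok$tx$chrom,
                                   start = max(1L, ok$tx$tss - 10000L),
                                   end = ok$tx$tss + 10000L,
                                   delta_percent = ph$delta_percent[r],
                                   direction = dirs[r],
                                   transcript_id = ok$tx$transcript_id,
                                   stringsAsFactors = FALSE)
      }
    }

    p_case <- pmin(pmax(p_ctrl + delta, 0), 1)
    spg <- config$samples_per_group
    design <- data.frame(
      sample_id = c(paste0("ctrl_", seq_len(spg)),
                    paste0("case_", seq_len(spg))),
      group = rep(c("control", "case"), each = spg),
      stringsAsFactors = FALSE)
    attr(design, "reference") <- "control"

    samples <- vector("list", nrow(design))
    names(samples) <- design$sample_id
    for (s in seq_len(nrow(design))) {
      p <- if (design$group[s] == "control") p_ctrl else p_case
      cov <- stats::rnbinom(ns, mu = config$mean_coverage,
                            size = config$coverage_dispersion)
      z <- which(cov == 0)
      while (length(z)) {          # zero-truncation by redraw
        cov[z] <- stats::rnbinom(length(z), mu = config$mean_coverage,
                                 size = config$coverage_dispersion)
        z <- z[cov[z] == 0]
      }
      ps <- p
      if (config$bb_rho > 0) {
        m <- 1 / config$bb_rho - 1  # Beta(a,b) with a+b = m keeps mean p
        inner <- p > 0 & p < 1
        ps[inner] <- stats::rbeta(sum(inner), p[inner] * m,
                                  (1 - p[inner]) * m)
      }
      nm <- stats::rbinom(ns, cov, ps)
      samples[[s]] <- data.frame(chrom = sites$chrom, pos = sites$pos,
                                 strand = "+", n_meth = nm,
                                 n_unmeth = cov - nm,
                                 stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(entity_id = character(), category = character(),
                 chrom = character(), start = integer(), end = integer(),
                 delta_percent = numeric(), direction = character(),
                 transcript_id = character(), stringsAsFactors = FALSE)
    attr(truth, "n_clamped") <- n_clamped
    out <- list(samples = samples, design = design, truth = truth,
                planted_sites = if (length(planted_sites))
                  do.call(rbind, planted_sites) else
                    data.frame(entity_id = character(), chrom = character(),
                               pos = integer(), delta_percent = numeric(),
                               direction = character(),
                               stringsAsFactors = FALSE))
    class(out) <- "wgbs_sim"
    out
  })
}

#' Simulate an expression table coupled to planted methylation changes
#'
#' Genes owning a planted promoter-proximal effect (promoter or clustered
#' DMC entities) receive a log2 fold change whose rank correlation with
#' the planted (signed) methylation delta approaches `rho` as the gene
#' count grows, via a Gaussian copula on the delta normal scores; all
#' other genes receive independent null-centered noise.
#'
#' @param truth truth table from [simulate_counts()].
#' @param annotation transcript annotation (for the gene universe).
#' @param rho target rank correlation in `[-1, 1]`.
#' @param seed RNG seed.
#' @return data frame: `gene_id`, `log2_fold_change`, `adjusted_p`,
#'   `de_flag`, `planted_delta` (signed percentage points; 0 for
#'   unplanted genes).
#' @export
simulate_expression <- function(truth, annotation, rho, seed) {
  stopifnot(abs(rho) <= 1)
  with_stage_seed(seed, "expression", {
    own <- truth[!is.na(truth$transcript_id), , drop = FALSE]
    sgn <- ifelse(own$direction == "hyper", 1, -1)
    gmap <- annotation$gene_id[match(own$transcript_id,
                                     annotation$transcript_id)]
    pd <- tapply(sgn * own$delta_percent, gmap, mean)
    genes <- unique(annotation$gene_id)
    lfc <- stats::rnorm(length(genes), 0, 1.5)
    names(lfc) <- genes
    if (length(pd)) {
      np <- length(pd)
      z_meth <- stats::qnorm((rank(pd, ties.method = "average") - 0.5) / np)
      eps <- stats::rnorm(np)
      z <- rho * z_meth + sqrt(1 - rho^2) * eps
      lfc[names(pd)] <- 1.5 * z
    }
    p_raw <- 2 * stats::pnorm(-abs(lfc) * 2)
    padj <- stats::p.adjust(p_raw, method = "BH")
    out <- data.frame(gene_id = genes, log2_fold_change = unname(lfc),
                      adjusted_p = unname(padj),
                      de_flag = unname(padj < 0.05),
                      planted_delta = 0, stringsAsFactors = FALSE)
    if (length(pd)) out$planted_delta[match(names(pd), out$gene_id)] <-
      unname(pd)
    out
  })
}

#' Run the full simulator and optionally write its files
#'
#' Convenience wrapper: annotation, counts and expression in one call.
#' When `out_dir` is given, writes one Bismark-coverage-style file per
#' sample, a BED12 annotation, and TSV design, expression and truth
#' tables.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return the `wgbs_sim` list, extended with `annotation`, `expression`
#'   and (when written) `paths`.
#' @export
simulate_wgbs <- function(config, out_dir = NULL) {
  ann <- simulate_annotation(config)
  sim <- simulate_counts(config, annotation = ann)
  sim$annotation <- ann
  sim$expression <- simulate_expression(sim$truth, ann,
                                        rho = config$expr_coupling_rho,
                                        seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    for (s in names(sim$samples)) {
      p <- file.path(out_dir, paste0(s, ".cov"))
      write_bismark_cov(sim$samples[[s]], p)
      paths[[s]] <- p
    }
    paths$annotation <- file.path(out_dir, "annotation.bed12")
    write_annotation_bed12(sim$annotation, paths$annotation)
    paths$design <- file.path(out_dir, "design.tsv")
    utils::write.table(sim$design, paths$design, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$expression <- file.path(out_dir, "expression.tsv")
    utils::write.table(sim$expression, paths$expression, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$truth <- file.path(out_dir, "truth.tsv")
    utils::write.table(sim$truth, paths$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sim$paths <- paths
  }
  sim
}
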