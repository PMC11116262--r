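test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_chroms = 2, chrom_length_bp = 150000,
                    n_transcripts = 10,
                    planted_dmc = plant_effects(5, 40),
                    expr_coupling_rho = -0.5, seed = 99)
  a1 <- simulate_annotation(cfg); a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  s1 <- simulate_counts(cfg, a1); s2 <- simulate_counts(cfg, a2)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$truth, s2$truth)
  e1 <- simulate_expression(s1$truth, a1, -0.5, seed = 99)
  e2 <- simulate_expression(s2$truth, a2, -0.5, seed = 99)
  expect_identical(e1, e2)
})

test_that("annotation respects counts, strand rules and packing", {
  cfg0 <- sim_config(n_transcripts = 0, seed = 1)
  expect_identical(nrow(simulate_annotation(cfg0)), 0L)

  cfg <- sim_config(n_chroms = 2, chrom_length_bp = 1e6,
                    n_transcripts = 200, seed = 5)
  ann <- simulate_annotation(cfg)
  expect_identical(nrow(ann), 200L)
  expect_false(anyDuplicated(ann$transcript_id) > 0)
  expect_true(all(ann$strand %in% c("+", "-")))
  expect_identical(ann$tss,
                   ifelse(ann$strand == "+", ann$tx_start, ann$tx_end))
  # brute-force pairwise overlap scan of transcript bodies
  for (ch in unique(ann$chrom)) {
    a <- ann[ann$chrom == ch, ]
    a <- a[order(a$tx_start), ]
    expect_true(all(a$tx_start[-1] > a$tx_end[-nrow(a)]))
    expect_true(all(a$tx_end <= cfg$chrom_length_bp))
  }
  # exons lie within the body
  ex_ok <- mapply(function(s, e, ts, te) {
    st <- as.integer(strsplit(s, ",")[[1]])
    en <- as.integer(strsplit(e, ",")[[1]])
    all(st >= ts) && all(en <= te) && all(st <= en)
  }, ann$exon_starts, ann$exon_ends, ann$tx_start, ann$tx_end)
  expect_true(all(ex_ok))

  cfg_bad <- sim_config(n_chroms = 1, chrom_length_bp = 50000,
                        n_transcripts = 100, seed = 2)
  expect_error(simulate_annotation(cfg_bad), "infeasible packing")
})

test_that("counts conserve coverage and an effect-free run has empty truth", {
  cfg <- sim_config(n_chroms = 1, chrom_length_bp = 50000,
                    n_transcripts = 0, seed = 3)
  sim <- simulate_counts(cfg)
  expect_identical(nrow(sim$truth), 0L)
  for (s in sim$samples) {
    expect_true(all(s$n_meth >= 0 & s$n_unmeth >= 0))
    expect_true(all(s$n_meth + s$n_unmeth >= 1))
  }
  # same CpG grid across samples
  expect_identical(sim$samples[[1]]$pos, sim$samples[[4]]$pos)
  expect_identical(names(sim$samples), sim$design$sample_id)
})

test_that("planted loci are disjoint across categories and inside bounds", {
  cfg <- sim_config(n_chroms = 2, chrom_length_bp = 400000,
                    n_transcripts = 40,
                    planted_dmc = plant_effects(20, 40),
                    planted_dmr_tiles = plant_effects(3, 35),
                    planted_dmp_promoters = plant_effects(3, 30),
                    planted_hifreq = plant_effects(3, 50, n_dmcs = 6),
                    seed = 17)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  expect_identical(nrow(sim$truth), 29L)
  expect_false(anyDuplicated(sim$truth$entity_id) > 0)
  expect_true(all(sim$truth$start >= 1))
  expect_true(all(sim$truth$end <= cfg$chrom_length_bp + 10000))
  # a CpG belongs to at most one planted entity
  key <- paste(sim$planted_sites$chrom, sim$planted_sites$pos)
  expect_false(anyDuplicated(key) > 0)
})

test_that("planted high-frequency clusters sit within TSS +/- 10 kb", {
  cfg <- sim_config(n_chroms = 2, chrom_length_bp = 500000,
                    n_transcripts = 50,
                    planted_hifreq = plant_effects(5, 50, n_dmcs = 7),
                    seed = 23)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  hf <- sim$truth[sim$truth$category == "HIFREQ", ]
  expect_identical(nrow(hf), 5L)
  for (i in seq_len(nrow(hf))) {
    tx <- ann[ann$transcript_id == hf$transcript_id[i], ]
    mem <- sim$planted_sites[sim$planted_sites$entity_id ==
                               hf$entity_id[i], ]
    expect_identical(nrow(mem), 7L)
    expect_true(all(mem$chrom == tx$chrom))
    expect_true(all(abs(mem$pos - tx$tss) <= 10000))
  }
})

test_that("planted case-control shifts are realized at the configured size", {
  cfg <- sim_config(n_chroms = 1, chrom_length_bp = 300000,
                    cpg_spacing_bp = 50, n_transcripts = 0,
                    mean_coverage = 60, samples_per_group = 5,
                    planted_dmc = plant_effects(100, 40), seed = 31)
  sim <- simulate_counts(cfg)
  key <- paste(sim$samples[[1]]$chrom, sim$samples[[1]]$pos)
  idx <- match(paste(sim$planted_sites$chrom, sim$planted_sites$pos), key)
  pct <- function(s) 100 * s$n_meth[idx] / (s$n_meth[idx] + s$n_unmeth[idx])
  grp <- split(sim$design$sample_id, sim$design$group)
  d <- rowMeans(sapply(sim$samples[grp$case], pct)) -
    rowMeans(sapply(sim$samples[grp$control], pct))
  sgn <- ifelse(sim$planted_sites$direction == "hyper", 1, -1)
  # empirical shift concentrates around the configured 40 points
  expect_gt(mean(sgn * d), 30)
  expect_lt(mean(abs(sgn * d - 40)), 10)
})

test_that("expression coupling hits its limits and its null", {
  cfg <- sim_config(n_chroms = 2, chrom_length_bp = 500000,
                    n_transcripts = 100, seed = 41,
                    planted_dmp_promoters = plant_effects(12, seq(15, 70, by = 5)))
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  # rho = -1, zero noise: perfectly anti-monotone ranks
  e <- simulate_expression(sim$truth, ann, rho = -1, seed = 41)
  planted <- e[e$planted_delta != 0, ]
  expect_identical(nrow(planted), 12L)
  expect_identical(order(planted$planted_delta),
                   rev(order(planted$log2_fold_change)))
  # rho = 0: fold changes independent of deltas
  rhos <- vapply(1:40, function(s) {
    e0 <- simulate_expression(sim$truth, ann, rho = 0, seed = 1000 + s)
    p0 <- e0[e0$planted_delta != 0, ]
    cor(p0$planted_delta, p0$log2_fold_change, method = "spearman")
  }, numeric(1))
  expect_gt(mean(abs(rhos) < 0.6), 0.9)
})

test_that("simulate_wgbs writes a consistent file bundle", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_chroms = 1, chrom_length_bp = 80000,
                    n_transcripts = 5,
                    planted_dmc = plant_effects(3, 40), seed = 55)
  sim <- simulate_wgbs(cfg, out_dir = dir)
  expect_true(all(file.exists(unlist(sim$paths))))
  back <- read_bismark_cov(sim$paths[[sim$design$sample_id[1]]])
  s1 <- sim$samples[[sim$design$sample_id[1]]]
  expect_identical(back$pos, s1$pos)
  expect_identical(back$n_meth, s1$n_meth)
  ann_back <- read_annotation(sim$paths$annotation, "bed12")
  expect_identical(ann_back$tss,
                   sim$annotation[order(sim$annotation$transcript_id), ]$tss)
})
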