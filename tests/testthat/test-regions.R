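test_that("genome tiles follow the k*W+1 anchoring convention", {
  tiles <- tile_genome(c(chr5 = 1300000L), window = 1000)
  hit <- tiles[tiles$start <= 1203500 & tiles$end >= 1203500, ]
  expect_identical(hit$start, 1203001L)
  expect_identical(hit$end, 1204000L)

  t2 <- tile_genome(c(chr1 = 2500L), window = 1000)
  expect_identical(t2$start, c(1L, 1001L, 2001L))
  expect_identical(t2$end, c(1000L, 2000L, 2500L))
  # boundary membership
  expect_identical(t2$start[t2$start <= 1000 & t2$end >= 1000], 1L)
  expect_identical(t2$start[t2$start <= 1001 & t2$end >= 1001], 1001L)

  # tiles partition each chromosome: disjoint, gap-free, full cover
  t3 <- tile_genome(c(a = 5230L, b = 999L), window = 250)
  for (ch in c("a", "b")) {
    tt <- t3[t3$chrom == ch, ]
    expect_identical(tt$start, c(1L, head(tt$end, -1) + 1L))
    expect_identical(sum(tt$end - tt$start + 1L),
                     c(a = 5230L, b = 999L)[[ch]])
  }
})

test_that("promoters are strand-aware TSS +/- flank, clipped and deduped", {
  ann <- tiny_annotation()
  pr <- promoter_regions(ann, flank = 1000)
  expect_identical(pr$start[pr$owner == "txA"], 4000L)
  expect_identical(pr$end[pr$owner == "txA"], 6000L)
  # minus strand: promoter centered on tx_end
  expect_identical(pr$start[pr$owner == "txB"], 15000L)
  expect_identical(pr$end[pr$owner == "txB"], 17000L)

  ann2 <- ann[1, ]
  ann2$tss <- 500L
  expect_identical(promoter_regions(ann2, flank = 1000)$start, 1L)
  expect_identical(promoter_regions(ann2, flank = 1000)$end, 1500L)

  # identical isoform promoters collapse to the smallest owner id
  ann3 <- rbind(ann[1, ], ann[1, ])
  ann3$transcript_id <- c("txZ", "txA")
  pr3 <- promoter_regions(ann3, flank = 1000)
  expect_identical(nrow(pr3), 1L)
  expect_identical(pr3$owner, "txA")
})

test_that("region aggregation sums counts and conserves totals", {
  nm <- matrix(c(3L, 7L, 2L, 1L, 5L, 4L), ncol = 2)
  cv <- matrix(10L, 3, 2)
  mm <- make_meth_matrix(nm, cv, pos = c(100L, 900L, 5000L), n_case = 1)
  regions <- data.frame(chrom = "chr1", start = c(1L, 4001L, 8001L),
                        end = c(1000L, 5000L, 9000L), kind = "tile")
  agg <- aggregate_region_counts(mm, regions)
  # two sites (3/10) and (7/10) fall in the first region -> (10/20)
  expect_identical(agg$n_meth[1, 1], 10L)
  expect_identical(agg$coverage[1, 1], 20L)
  # region with no sites dropped
  expect_identical(nrow(agg$loci), 2L)
  expect_identical(attr(agg, "n_dropped_empty"), 1L)
  # conservation over covered sites (brute-force re-sum)
  expect_identical(colSums(agg$n_meth), colSums(mm$n_meth))
  expect_identical(colSums(agg$coverage), colSums(mm$coverage))

  # conservation also under a full random tiling
  set.seed(13)
  nm2 <- matrix(rbinom(400, 15, 0.5), ncol = 4)
  mm2 <- make_meth_matrix(nm2, matrix(15L, 100, 4),
                          pos = sort(sample(1:20000, 100)))
  tiles <- tile_genome(c(chr1 = 20000L), window = 1000)
  agg2 <- aggregate_region_counts(mm2, tiles)
  expect_identical(colSums(agg2$n_meth), colSums(mm2$n_meth))
  expect_identical(colSums(agg2$coverage), colSums(mm2$coverage))
})

test_that("nearest TSS follows orientation, tie and sentinel rules", {
  ann <- tiny_annotation()
  # + strand TSS at 5000: site at 7000 is downstream (+2000)
  r <- nearest_tss(data.frame(chrom = "chr1", start = 7000L, end = 7000L),
                   ann)
  expect_identical(r$transcript_id, "txA")
  expect_identical(r$distance_to_tss, 2000)
  # upstream of a + strand TSS is negative
  r2 <- nearest_tss(data.frame(chrom = "chr1", start = 4500L, end = 4500L),
                    ann)
  expect_identical(r2$distance_to_tss, -500)
  # - strand: positions above the TSS are upstream (negative)
  r3 <- nearest_tss(data.frame(chrom = "chr1", start = 16800L,
                               end = 16800L), ann)
  expect_identical(r3$transcript_id, "txB")
  expect_identical(r3$distance_to_tss, -800)
  # equidistant TSSs: smaller transcript id wins
  ann_tie <- tiny_annotation()
  ann_tie$tss <- c(4000L, 6000L, 3000L)
  r4 <- nearest_tss(data.frame(chrom = "chr1", start = 5000L, end = 5000L),
                    ann_tie)
  expect_identical(r4$transcript_id, "txA")
  # region containing a TSS has distance zero
  r5 <- nearest_tss(data.frame(chrom = "chr1", start = 4900L, end = 5100L),
                    ann)
  expect_identical(r5$distance_to_tss, 0)
  # absent chromosome -> sentinel
  expect_message(
    r6 <- nearest_tss(data.frame(chrom = "chrX", start = 10L, end = 10L),
                      ann),
    "unassigned")
  expect_identical(r6$transcript_id, "unassigned")
  expect_true(is.na(r6$distance_to_tss))
})

test_that("nearest TSS matches the exhaustive scan on random fixtures", {
  set.seed(19)
  cfg <- sim_config(n_chroms = 2, chrom_length_bp = 1000000,
                    n_transcripts = 200, seed = 5)
  ann <- simulate_annotation(cfg)
  loci <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                     start = sample.int(1000000L, 300))
  loci$end <- pmin(loci$start + sample(c(0L, 0L, 500L), 300, TRUE),
                   1000000L)
  got <- nearest_tss(loci, ann)
  want <- brute_nearest_tss(loci, ann)
  expect_identical(got$transcript_id, want$transcript_id)
  expect_equal(got$distance_to_tss, want$distance)
})

test_that("feature classification applies precedence over a partition", {
  ann <- tiny_annotation()
  pr <- promoter_regions(ann, flank = 1000)
  loci <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(5500L, 6500L, 7500L, 30000L, 2500L))
  loci$end <- loci$start
  cls <- classify_feature(loci, ann, pr)
  # 5500: inside promoter [4000,6000] AND exon [5000,6000] -> promoter
  # 6500: inside body, no exon, no promoter -> intron
  # 7500: exon [7000,8000] -> exon
  # 30000: nothing -> intergenic ; 2500: promoter of txC [2000,4000]
  expect_identical(cls, c("promoter", "intron", "exon", "intergenic",
                          "promoter"))
  expect_true(all(cls %in% c("promoter", "exon", "intron", "intergenic")))

  fp <- feature_proportions(c(rep("promoter", 2), "exon", "intron",
                              rep("intergenic", 4)))
  expect_equal(unname(fp), c(0.25, 0.125, 0.125, 0.5))
  expect_equal(sum(fp), 1)
  expect_error(feature_proportions(character()), "empty")

  # proportions sum to 1 for random fixtures
  set.seed(3)
  loci2 <- data.frame(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                      start = sample.int(20000L, 50))
  loci2$end <- loci2$start
  cls2 <- classify_feature(loci2, ann, pr)
  expect_equal(sum(feature_proportions(cls2)), 1)
})
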