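test_that("unite applies coverage filters and keeps complete loci", {
  s1 <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                   n_meth = c(5L, 5L, 5L), n_unmeth = c(5L, 4L, 15L))
  s2 <- data.frame(chrom = "chr1", pos = c(100L, 300L),
                   n_meth = c(2L, 8L), n_unmeth = c(8L, 4L))
  design <- data.frame(sample_id = c("a", "b"),
                       group = c("control", "case"))
  mm <- unite(list(a = s1, b = s2), design, min_coverage = 10,
              max_coverage_percentile = NULL)
  # pos 200 absent in sample b -> dropped
  expect_identical(mm$loci$start, c(100L, 300L))
  expect_identical(attr(mm, "n_dropped_low"), 0L)

  # coverage 9 in one sample at min_coverage 10 -> dropped
  s2b <- s2; s2b$n_unmeth[1] <- 6L
  mm2 <- unite(list(a = s1, b = s2b), design, min_coverage = 10,
               max_coverage_percentile = NULL)
  expect_identical(mm2$loci$start, 300L)
  expect_identical(attr(mm2, "n_dropped_low"), 1L)

  # all loci covered everywhere, no extreme coverage: identity
  mm3 <- unite(list(a = s1[c(1, 3), ], b = s2), design, min_coverage = 10,
               max_coverage_percentile = 100)
  expect_identical(nrow(mm3$loci), 2L)

  expect_error(unite(list(a = s1[1, ], b = s2[2, ]), design),
               "min_coverage")
})

test_that("the LRT matches its trivial and derived worked cases", {
  # identical proportions: no effect at all
  r0 <- one_locus_test(ctrl = list(c(5, 10)),
                       case = list(c(5, 10), c(5, 10)))
  expect_equal(r0$meth_diff, 0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # complete separation: statistic = G of [[20,0],[0,20]] = 80*ln(2)
  r1 <- one_locus_test(ctrl = list(c(0, 10), c(0, 10)),
                       case = list(c(10, 10), c(10, 10)))
  expect_equal(r1$meth_diff, 100)
  expect_equal(r1$statistic, 80 * log(2), tolerance = 1e-12)
  expect_equal(r1$statistic,
               g_test_stat(matrix(c(20, 0, 0, 20), 2)), tolerance = 1e-12)

  # 7/10 vs 3/10: p equals the G-test p of [[7,3],[3,7]]
  r2 <- one_locus_test(ctrl = list(c(3, 10)), case = list(c(7, 10)))
  expect_equal(r2$meth_diff, 40)
  expect_equal(r2$p_value,
               pchisq(g_test_stat(matrix(c(7, 3, 3, 7), 2)), 1,
                      lower.tail = FALSE), tolerance = 1e-12)
})

test_that("the LRT equals glm deviance differences and the pooled G-test", {
  set.seed(404)
  for (i in 1:60) {
    n_ctrl <- sample(1:4, 1); n_case <- sample(1:4, 1)
    ctrl <- replicate(n_ctrl, {
      cv <- sample(1:40, 1); c(rbinom(1, cv, runif(1)), cv)
    }, simplify = FALSE)
    case <- replicate(n_case, {
      cv <- sample(1:40, 1); c(rbinom(1, cv, runif(1)), cv)
    }, simplify = FALSE)
    r <- one_locus_test(ctrl, case)
    expect_equal(r$statistic, glm_lrt_oracle(ctrl, case),
                 tolerance = 1e-6)
    M <- vapply(list(case, ctrl), function(g)
      sum(vapply(g, `[`, numeric(1), 1)), numeric(1))
    N <- vapply(list(case, ctrl), function(g)
      sum(vapply(g, `[`, numeric(1), 2)), numeric(1))
    tab <- rbind(M, N - M)
    if (all(rowSums(tab) > 0))
      expect_equal(r$statistic, g_test_stat(tab), tolerance = 1e-8)
  }
})

test_that("results are invariant to sample order within groups", {
  set.seed(7)
  nm <- matrix(rbinom(60, 20, 0.4), ncol = 6)
  cv <- matrix(20L, 10, 6)
  mm <- make_meth_matrix(nm, cv)
  r1 <- diff_methylation(mm)
  perm <- c(3, 1, 2, 6, 5, 4)  # permute within control and within case
  mm2 <- mm
  mm2$n_meth <- mm$n_meth[, perm]
  mm2$coverage <- mm$coverage[, perm]
  colnames(mm2$n_meth) <- colnames(mm2$coverage) <- mm$design$sample_id
  r2 <- diff_methylation(mm2)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$meth_diff, r2$meth_diff)
})

test_that("meth_diff sign convention is patient minus control", {
  r <- one_locus_test(ctrl = list(c(9, 10)), case = list(c(1, 10)))
  expect_equal(r$meth_diff, -80)
  r <- call_differential(r, q_max = 1, min_abs_diff = 10)
  expect_identical(r$direction, "hypo")
})

test_that("BH adjustment matches the hand formula and its bounds", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.37), 0.37)
  expect_equal(adjust_fdr(numeric(0)), numeric(0))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- adjust_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
    # q monotone w.r.t. p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(adjust_fdr(c(0.1, NaN)), "NA")
  expect_error(adjust_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # pluggable alternative procedure
  expect_equal(adjust_fdr(c(0.2, 0.4), method = function(p) p / 2),
               c(0.1, 0.2))
})

test_that("differential calls respect both thresholds and are monotone", {
  res <- one_locus_test(ctrl = list(c(0, 50)), case = list(c(25, 50)))
  fake <- function(q, d) {
    r <- res
    r$q_value <- q; r$meth_diff <- d
    r
  }
  expect_identical(call_differential(fake(0.005, 30))$direction, "hyper")
  expect_identical(call_differential(fake(0.02, 90))$direction, "ns")
  expect_identical(call_differential(fake(0.001, -26))$direction, "hypo")
  expect_identical(call_differential(fake(0.005, 24))$direction, "ns")

  set.seed(21)
  nm <- matrix(rbinom(300, 30, runif(50)), ncol = 6)
  cv <- matrix(30L, 50, 6)
  r <- diff_methylation(make_meth_matrix(nm, cv))
  called_n <- function(q_max, min_diff)
    nrow(get_calls(call_differential(r, q_max, min_diff)))
  for (q in c(0.5, 0.2, 0.05)) {
    expect_gte(called_n(q, 10), called_n(q, 20))
    expect_gte(called_n(0.5, 10), called_n(q, 10))
  }
})

test_that("PCA orders components and separates simulated groups", {
  set.seed(31)
  nm <- matrix(rbinom(120, 20, 0.5), ncol = 4)
  nm[, 4] <- nm[, 3]  # two identical samples
  cv <- matrix(20L, 30, 4)
  p <- pca_samples(make_meth_matrix(nm, cv, n_case = 2))
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lt(sum((p$scores[3, ] - p$scores[4, ])^2), 1e-20)
  expect_lte(sum(p$var_explained), 1 + 1e-8)

  expect_error(pca_samples(make_meth_matrix(matrix(5L, 10, 4),
                                            matrix(10L, 10, 4))),
               "constant")

  # two well-separated groups: delta 40 pp at 20% of sites
  cfg <- sim_config(n_chroms = 1, chrom_length_bp = 100000,
                    cpg_spacing_bp = 100, n_transcripts = 0,
                    mean_coverage = 30,
                    planted_dmc = plant_effects(200, 40), seed = 77)
  sim <- simulate_counts(cfg)
  mm <- unite(sim$samples, sim$design, min_coverage = 10)
  p2 <- pca_samples(mm)
  grp <- mm$design$group
  centroids <- tapply(p2$scores[, 1], grp, mean)
  within <- max(tapply(p2$scores[, 1], grp, function(x) diff(range(x))))
  expect_gt(abs(diff(centroids)), within)
})
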