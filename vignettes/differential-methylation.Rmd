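---
title: "Differential CpG methylation analysis: model, conventions and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential CpG methylation analysis: model, conventions and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(methdiffscan)
```

# The analysis problem

Whole-genome bisulfite sequencing (WGBS) reports, for every CpG cytosine in
every sample, how many reads carried a methylated C and how many an
unmethylated one. Comparing a patient group against controls then becomes a
locus-by-locus comparison of binomial proportions at millions of sites, with
typical clinical designs contributing only 3–5 biopsies per group at roughly
10× coverage per CpG. methdiffscan implements this comparison at three
resolutions:

* **DMC** — a single CpG site;
* **DMR** — a fixed 1-kb genomic tile, tested on counts summed over its CpGs;
* **DMP** — a promoter, defined as TSS ± 1 kb of a transcript.

Downstream, loci are annotated by their nearest transcription start site
(TSS), summarized into gene-level statistics, and optionally integrated with
an expression table and gene-set terms.

# The locus-level model

At one locus let $m_{gs}$ and $n_{gs}$ be the methylated count and coverage
of sample $s$ in group $g \in \{0, 1\}$ (0 = control, 1 = patient). The model
is a binomial logistic regression on the group indicator,

$$m_{gs} \sim \mathrm{Binomial}(n_{gs},\, p_g), \qquad
\operatorname{logit} p_g = \beta_0 + \beta_1 g,$$

tested against the intercept-only null by the likelihood-ratio (deviance)
statistic on one degree of freedom. Because the group indicator is the only
covariate, the maximum-likelihood fit pools counts within groups
($\hat p_g = \sum_s m_{gs} / \sum_s n_{gs}$), and the deviance difference
reduces to the likelihood-ratio (G) statistic of the pooled 2×2
methylated/unmethylated × group table. `diff_methylation()` evaluates this
closed form vectorized over all loci; the test suite verifies it against
`glm()` deviance differences and an independently written G-test oracle at
1e-8. Complete separation (one group fully methylated, the other fully
unmethylated) is the finite deviance limit — for 20 reads against 20 reads
it equals $80\ln 2 \approx 55.45$ — so no special-casing is needed.

The reported effect size `meth_diff` is the difference of coverage-weighted
group methylation percentages, $100(\hat p_1 - \hat p_0)$, signed patient
minus control (positive = hypermethylated in patients). An unweighted
per-sample mean is available via `diff_method = "sample_mean"`; the
coverage-weighted form is the default because it is the quantity the
likelihood actually contrasts.

## Multiple testing and calling

`adjust_fdr()` applies Benjamini–Hochberg step-up q-values by default.
Sliding-linear-model (SLIM) q-values, which some WGBS pipelines use, are not
reimplemented — the procedure has tuning choices that cannot be fixed from a
methods description alone — but any function mapping p-values to q-values
can be plugged in unchanged, so a SLIM implementation drops into the same
slot. A locus is called by `call_differential()` when
$q \le q_{\max}$ **and** $|\Delta| \ge \Delta_{\min}$, both inclusive, with
defaults $q_{\max} = 0.01$ and $\Delta_{\min} = 25$ percentage points — the
conventional thresholds of methylKit-style analyses. Both are configurable;
the gene-level "top DMC" filter below deliberately uses *strict*
inequalities because it is defined by "larger than 30%" / "less than 10 kb"
phrasing.

## Tunable parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `min_coverage` | 10 | reads | per-sample floor at `unite()`; matches the ~10× coverage mode |
| `max_coverage_percentile` | 99.9 | percentile | per-sample ceiling; guards against PCR duplicates |
| `q_max` | 0.01 | — | FDR ceiling for calls (inclusive) |
| `min_abs_diff` | 25 | pp | effect floor for calls (inclusive) |
| `tile_window` | 1000 | bp | DMR tile width |
| `promoter_flank` | 1000 | bp | DMP half-width around the TSS |
| `score_window` | 10000 | bp | TSS window for gene scoring and summaries |
| `hifreq_min_count` | 5 | DMCs | "at least five DMCs per transcript" (inclusive) |
| `topdmc_max_dist` | 10000 | bp | top-DMC distance bound (strict `<`) |
| `topdmc_min_diff` | 30 | pp | top-DMC effect bound (strict `>`) |
| `min_dmcs` | 2 | DMCs | member floor for gene methylation summaries |

# Genome geometry conventions

All internal coordinates are **1-based inclusive**; BED input/output converts
at the boundary (a site at position $p$ exports as `[p-1, p)`).

* **Tiles** are anchored at $k \cdot W + 1$: with $W = 1000$, position
  1,203,500 lies in [1,203,001, 1,204,000]. The last tile is truncated at
  the chromosome end, so tiles partition each chromosome exactly.
* **Promoters** are TSS ± flank with the strand-aware TSS (transcript start
  on `+`, transcript end on `-`), clipped at position 1; identical isoform
  promoters are deduplicated to the smallest transcript id.
* **Nearest-TSS distance** is signed in transcript orientation (upstream
  negative). For an interval locus the distance is the minimum over its
  bases — zero when the interval contains the TSS. Edge-minimum was chosen
  over midpoint distance because it makes "distance 0" coincide exactly
  with TSS containment; ties between equidistant TSSs resolve to the
  lexicographically smallest transcript id, which makes results
  deterministic and oracle-checkable.
* **Feature classes** use the precedence promoter > exon > intron >
  intergenic (configurable), which yields an exhaustive, mutually exclusive
  partition of any locus set.
* **Gene scoring** counts a DMC toward *every* transcript whose TSS window
  contains it (multi-assignment); per-transcript counting of clustered DMCs
  implies this. A nearest-transcript-only mode is available
  (`assignment = "nearest"`) and is always a restriction of the default.

# The simulator

`simulate_wgbs()` generates data with the statistical structure the analysis
assumes, plus a ground-truth ledger (`truth`, `planted_sites`) that makes
recovery measurable.

* **Coverage**: zero-truncated negative binomial with mean 10 and size 20
  per sample. This reproduces a unimodal profile with its mode at 9–10
  reads per CpG while leaving room for overdispersion stress tests via the
  size parameter. Truncation is by redraw, so the mean stays at the
  configured value.
* **Baseline methylation**: a two-component Beta mixture, 0.75 weight on
  Beta(20, 1) (high mode) and 0.25 on Beta(1, 20) (low mode). Pooled
  percent-methylation histograms then place their global maximum in
  95–100% and a smaller local maximum in 0–5%, the canonical bimodal WGBS
  profile.
* **Between-sample noise**: `bb_rho` adds beta-binomial variation around
  the group proportion. The default is 0 (pure binomial) because that is
  the sampling model the likelihood-ratio test assumes; calibration under
  overdispersion is a stress test, not the reference condition.
* **Effect injection**: planted entities (single CpGs, 1-kb tiles,
  promoters, clustered DMCs within TSS ± 10 kb) shift the case-group
  proportion by the configured delta *on the proportion scale*, with the
  baseline at planted sites drawn from the mixture restricted to the
  feasible range for the requested direction. This keeps the realized
  group difference equal to the configured delta even near the boundaries,
  which is what makes the truth ledger a meaningful recovery target; an
  infeasible draw is clamped and counted. Planted loci are disjoint across
  categories by construction.
* **Expression coupling**: genes owning a planted promoter-proximal effect
  receive a log2 fold change through a Gaussian copula on the normal scores
  of the planted deltas, so the sample Spearman correlation approaches the
  target `rho` as the gene count grows; at `rho = -1` with the noise term
  vanishing the ranks are exactly anti-monotone. Unplanted genes get
  independent null-centered noise.
* **Reproducibility**: every stage derives its own RNG stream from the
  master seed, so adding a stage never perturbs earlier draws, and an
  identical configuration reproduces byte-identical outputs.

## What the simulator does and does not emulate

It emulates the coverage distribution, the bimodal methylation profile,
small two-group designs, and spatially coherent effects (tiles, promoters,
TSS-proximal clusters). It does **not** emulate spatial correlation of
baseline methylation between neighboring CpGs, read-level artifacts
(incomplete bisulfite conversion, SNPs under CpGs, mapping bias), non-CpG
methylation, or cell-type composition shifts between groups. Passing
recovery tests on simulated data therefore demonstrates the correctness and
calibration of the statistical machinery under its own assumptions, not
robustness to those real-data artifacts.

# Numerical and calibration choices

* **Degenerate sites and calibration studies.** At sites whose true
  proportion sits at 0 or 1, every count test is degenerate: both groups
  produce identical saturated counts and the p-value is exactly 1. Under
  the bimodal default baseline a large fraction of sites is quasi-degenerate,
  so the p-value distribution under the null is far from uniform *by
  design of the data, not by a fault of the test*. Calibration studies
  (type-I error, p-value uniformity) therefore use a mid-range Beta(2, 2)
  baseline, where the discrete G-test at pooled group totals of ~30 reads
  is close to its chi-square reference: at ~22,000 united null sites the
  fraction of $p < 0.05$ lands near 0.054 and BH at $q < 0.05$ calls
  nothing.
* **0·log 0 = 0** is applied throughout the deviance sums; the statistic is
  clamped at 0 against floating-point negatives.
* **Ties in p** receive equal BH q-values (stable sort); q is monotone in p
  within a comparison.
* **Empty and boundary inputs** error loudly (`feature_proportions` on an
  empty set, PCA on a constant matrix, correlation below 3 paired genes)
  rather than returning NaN.

## Problem sizes used by the checks

The packaged statistical checks run at deliberately desk-sized scales:
~1.2M simulated CpGs (~22,000 surviving the 10× everywhere filter) for null
calibration; 10 × (20,000 null + 500 planted) sites at coverage 30 for DMC
recovery; 5 planted and 20 null genomes of 100 transcripts for
high-frequency gene recovery; 100 Monte-Carlo seeds at 15 genes for the
expression coupling; 1,000 random loci × 200 transcripts for the
nearest-TSS oracle. These sizes give stable rates while keeping a full run
in minutes on one core.

# Known limitations

* Exactly two groups, no covariates, no paired designs — matching the
  two-group contrasts the method targets. `df` is always 1.
* No overdispersion correction in the test itself; with `bb_rho > 0` in the
  simulator the test is anticonservative, which is the expected behavior of
  a binomial LRT and can be quantified with the generator.
* SLIM q-values are a plugin slot, not a reimplementation, so q-value
  parity with SLIM-based analyses near the threshold is not attainable.
* Gene-level summaries use the unweighted mean of member DMC differences
  (median by flag); analyses that summarize by the single strongest DMC
  will rank genes differently.
* The enrichment universe defaults to genes with at least one tested CpG —
  the background must reflect testability — but is configurable.
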