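scored_toy <- function(p, spacing = 100) {
  tr <- toy_track(rep(0, length(p)), spacing = spacing)
  tr$p <- p
  tr
}

test_that("peak calling applies the >=2 significant probes criterion", {
  pk <- call_peaks(scored_toy(c(0.5, 0.005, 0.004, 0.5)))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$n_probes, 2)
  expect_equal(pk$start, 100)
  expect_equal(pk$end, 250)
  expect_equal(pk$min_p, 0.004)

  # A lone candidate is never a peak.
  expect_equal(nrow(call_peaks(scored_toy(c(0.5, 0.001, 0.5)))), 0)

  # An intervening non-candidate probe breaks the run.
  pk2 <- call_peaks(scored_toy(c(0.005, 0.5, 0.004, 0.003)))
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$n_probes, 2)

  # Midpoint gaps beyond max_gap_bp break the run.
  pk3 <- call_peaks(scored_toy(c(0.005, 0.004), spacing = 600))
  expect_equal(nrow(pk3), 0)
})

test_that("peak calling matches a brute-force scan on random tracks", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    p <- ifelse(runif(n) < 0.35, runif(n, 0, 0.01), runif(n, 0.02, 1))
    spacing <- sample(c(100, 300, 600), 1)
    sc <- scored_toy(p, spacing = spacing)
    got <- call_peaks(sc)
    want <- brute_peaks(sc$chrom, sc$start, sc$end, p, max_gap_bp = 500)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_probes, want$n_probes)
      expect_equal(got$min_p, want$min_p)
    }
  }
})

test_that("peaks and methylated sets shrink monotonically with the cutoff", {
  set.seed(31)
  p <- runif(300, 0, 0.05)
  sc <- scored_toy(p)
  cutoffs <- c(0.02, 0.01, 0.005, 0.001, 0)
  prev <- Inf
  for (ct in cutoffs) {
    n <- nrow(call_peaks(sc, p_cutoff = ct))
    expect_lte(n, prev)
    prev <- n
  }
  expect_equal(nrow(call_peaks(sc, p_cutoff = 0)), 0)
})

test_that("gene calls follow half-open interval overlap", {
  prom <- data.frame(gene = "G1", chrom = "chr1", strand = "+", tss = 5000,
                     stringsAsFactors = FALSE)
  prom <- promoter_windows(prom, 3000, 1000)  # window [2000, 6000)
  pk <- data.frame(chrom = "chr1", start = 2500, end = 2700,
                   n_probes = 3L, min_p = 1e-4, stringsAsFactors = FALSE)
  expect_true(call_promoter_methylation(pk, prom)$methylated)

  # Half-open abutment: a peak ending exactly at the window start misses.
  pk2 <- transform(pk, start = 1800, end = 2000)
  expect_false(call_promoter_methylation(pk2, prom)$methylated)
  pk3 <- transform(pk, start = 1800, end = 2001)
  expect_true(call_promoter_methylation(pk3, prom)$methylated)

  # No peaks at all: empty call set, no methylation.
  none <- call_peaks(scored_toy(rep(1, 5)))
  expect_false(call_promoter_methylation(none, prom)$methylated)
})

test_that("gene-level recovery on planted methylomes is accurate", {
  cfg <- sim_config(n_genes = 500, effect_mean = 2.0, background_sd = 0.3,
                    seed = 202)
  sim <- simulate_methylome(cfg, generate_layout(cfg))
  sc <- windowed_ks_score(sim$track, "qHSC")
  calls <- call_promoter_methylation(call_peaks(sc), sim$layout$promoters)
  truth <- sim$truth$meth_qHSC[match(calls$gene, sim$truth$gene)]
  expect_gte(mean(calls$methylated[truth]), 0.90)
  expect_lte(mean(calls$methylated[!truth]), 0.05)
})

test_that("sensitivity is monotone non-decreasing in the planted effect size", {
  sens <- vapply(c(0.5, 1.0, 2.0), function(eff) {
    cfg <- sim_config(n_genes = 150, effect_mean = eff, seed = 33)
    sim <- simulate_methylome(cfg, generate_layout(cfg))
    sc <- windowed_ks_score(sim$track, "qHSC")
    calls <- call_promoter_methylation(call_peaks(sc), sim$layout$promoters)
    truth <- sim$truth$meth_qHSC[match(calls$gene, sim$truth$gene)]
    mean(calls$methylated[truth])
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("MaxTen equals the top-ten mean, with low-coverage handling", {
  prom <- promoter_windows(
    data.frame(gene = "G1", chrom = "chr1", strand = "+", tss = 3000,
               stringsAsFactors = FALSE), 3000, 1000)
  tr <- toy_track(rep(0.7, 40))
  expect_equal(maxten(tr, prom, "s1")$maxten, 0.7)

  tr2 <- toy_track(c(rep(0, 30), rep(1, 10)))
  expect_equal(maxten(tr2, prom, "s1")$maxten, 1.0)

  # Fewer than ten probes: mean of all present, flagged.
  tr3 <- toy_track(c(1, 2, 3))
  m3 <- maxten(tr3, prom, "s1")
  expect_equal(m3$maxten, 2)
  expect_true(m3$low_coverage)

  # No probes in the window: missing value.
  prom_far <- promoter_windows(
    data.frame(gene = "G2", chrom = "chr2", strand = "+", tss = 3000,
               stringsAsFactors = FALSE), 3000, 1000)
  expect_true(is.na(maxten(tr, prom_far, "s1")$maxten))
})

test_that("MaxTen matches the sort-and-average oracle on random promoters", {
  set.seed(55)
  cfg <- sim_config(n_genes = 100, seed = 56)
  sim <- simulate_methylome(cfg, generate_layout(cfg))
  mx <- maxten(sim$track, sim$layout$promoters, "HEP")
  mid <- (sim$track$start + sim$track$end) / 2
  for (i in sample(nrow(sim$layout$promoters), 100, replace = TRUE)) {
    pr <- sim$layout$promoters[i, ]
    vals <- sim$track$HEP[sim$track$chrom == pr$chrom &
                            mid >= pr$window_start & mid < pr$window_end]
    expect_equal(mx$maxten[i], mean(sort(vals, decreasing = TRUE)[1:10]))
  }
})

test_that("positional classes are computed strand-aware over region bounds", {
  prom <- promoter_windows(
    data.frame(gene = "G1", chrom = "chr1", strand = "+", tss = 10000,
               stringsAsFactors = FALSE), 3000, 1000)
  pk <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                  n_probes = 2L, min_p = 1e-3,
                                  stringsAsFactors = FALSE)
  # Wholly upstream: rel [-2500, -2200).
  expect_equal(classify_position(pk(7500, 7800), prom)$class, "upstream")
  # Spanning the upstream/TSS boundary: rel [-600, -300).
  expect_equal(classify_position(pk(9400, 9700), prom)$class, "upstream,TSS")
  # Downstream only: rel [600, 900).
  expect_equal(classify_position(pk(10600, 10900), prom)$class, "downstream")

  # Minus strand: genomic [tss+300, tss+600) is rel [-599, -299) -> spans.
  promm <- promoter_windows(
    data.frame(gene = "G2", chrom = "chr1", strand = "-", tss = 10000,
               stringsAsFactors = FALSE), 3000, 1000)
  expect_equal(classify_position(pk(10300, 10600), promm)$class, "upstream,TSS")

  # Unmethylated promoter: positional class undefined.
  expect_error(classify_position(pk(1, 10), prom), "unmethylated")
})

test_that("called classes recover the planted peak region", {
  cfg <- sim_config(n_genes = 300, seed = 61)
  sim <- simulate_methylome(cfg, generate_layout(cfg))
  sc <- windowed_ks_score(sim$track, "qHSC")
  peaks <- call_peaks(sc)
  calls <- call_promoter_methylation(peaks, sim$layout$promoters)
  called <- calls$gene[calls$methylated]
  truth <- sim$truth[match(called, sim$truth$gene), ]
  tp <- called[truth$meth_qHSC]
  prom <- sim$layout$promoters[match(tp, sim$layout$promoters$gene), ]
  cls <- classify_position(peaks, prom)
  breaks <- c(-3000, -500, 500, 1000)
  labels <- c("upstream", "TSS", "downstream")
  # A region counts as planted when it holds at least two shifted probe
  # midpoints -- the same evidence unit the peak criterion requires; regions
  # touched by a single boundary probe are the documented boundary misses.
  probes <- sim$layout$probes
  ok <- vapply(seq_along(tp), function(i) {
    ps <- sim$truth$peak_start[sim$truth$gene == tp[i]]
    pe <- sim$truth$peak_end[sim$truth$gene == tp[i]]
    mids <- probes$rel_mid[probes$gene == tp[i]]
    mids <- mids[mids >= ps & mids < pe]
    planted <- labels[vapply(seq_along(labels), function(r) {
      sum(mids >= breaks[r] & mids < breaks[r + 1]) >= 2
    }, logical(1))]
    all(planted %in% strsplit(cls$class[i], ",")[[1]])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("the positional chi-square test is Pearson's on the k x 2 table", {
  same <- position_shift_test(c(10, 20, 30), c(10, 20, 30))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  a <- c(upstream = 30, TSS = 40, downstream = 30)
  b <- c(upstream = 58, TSS = 21, downstream = 21)
  got <- position_shift_test(a, b)
  tab <- cbind(a, b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((tab - expected)^2 / expected)
  expect_equal(got$statistic, hand, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(got$p_value, pchisq(hand, 2, lower.tail = FALSE))

  # Pearson's statistic scales linearly with counts.
  expect_equal(position_shift_test(2 * a, 2 * b)$statistic, 2 * got$statistic)

  expect_error(position_shift_test(c(0, 10), c(0, 20)), "zero expected")
})
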