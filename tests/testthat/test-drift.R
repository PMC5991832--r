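test_that("gene-body signal is the exact per-base mean, length-weighted at bin edges", {
  gm <- genome_model("chr1", 20, bin_size = 10)
  tr <- coverage_track(c(1, 3), gm, units = "scaled")
  g <- gene_annotation(data.frame(gene_id = "g1", chrom = "chr1",
                                  start = 5, end = 15, strand = "+"))
  expect_equal(unname(gene_body_signal(tr, g)), 2)

  const <- coverage_track(c(2, 2), gm, units = "scaled")
  expect_equal(unname(gene_body_signal(const, g)), 2)

  # random tracks and gene bodies against the per-base oracle
  set.seed(5)
  gm2 <- genome_model("chr1", 5000, bin_size = 100)
  v <- runif(50, 0, 10)
  tr2 <- coverage_track(v, gm2, units = "scaled")
  for (i in 1:30) {
    s <- sample(0:4998, 1); e <- sample((s + 1):5000, 1)
    g2 <- gene_annotation(data.frame(gene_id = "g", chrom = "chr1",
                                     start = s, end = e, strand = "+"))
    expect_equal(unname(gene_body_signal(tr2, g2)),
                 oracle_gene_signal(v, 100, s, e))
  }

  out <- gene_annotation(data.frame(gene_id = "g", chrom = "chr1",
                                    start = 4000, end = 6000, strand = "+"))
  expect_error(gene_body_signal(tr2, out), "beyond chromosome end")
})

test_that("gene-body signal is linear in the track", {
  set.seed(6)
  gm <- genome_model("chr1", 5000, bin_size = 100)
  a <- runif(50); b <- runif(50)
  genes <- gene_annotation(data.frame(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    start = c(150, 2000, 4990), end = c(1850, 2100, 5000), strand = "+"))
  tA <- coverage_track(a, gm, units = "scaled")
  tB <- coverage_track(b, gm, units = "scaled")
  tC <- coverage_track(2 * a + 3 * b, gm, units = "scaled")
  expect_equal(gene_body_signal(tC, genes),
               2 * gene_body_signal(tA, genes) +
                 3 * gene_body_signal(tB, genes))
})

test_that("difference tracks subtract bin-wise and carry the difference flag", {
  gm <- genome_model("chr1", 1000, bin_size = 100)
  set.seed(8)
  a <- coverage_track(runif(10, 0, 5), gm, units = "scaled")
  b <- coverage_track(runif(10, 0, 5), gm, units = "scaled")
  d <- subtract_tracks(a, b)
  expect_identical(d$units, "difference")
  expect_equal(unname(d$values$chr1),
               unname(a$values$chr1 - b$values$chr1))
  expect_equal(unname(subtract_tracks(a, a)$values$chr1), rep(0, 10))
  ap1 <- coverage_track(a$values$chr1 + 1, gm, units = "scaled")
  expect_equal(unname(subtract_tracks(ap1, a)$values$chr1), rep(1, 10))
  raw <- coverage_track(runif(10), gm, units = "raw")
  expect_error(subtract_tracks(raw, a), "reference-adjusted")
})

test_that("bootstrap_mean is deterministic, degenerate-safe and correctly sized", {
  b <- bootstrap_mean(rep(7, 40), draws = 500, subsample_n = 100, seed = 9)
  expect_equal(b$point_mean, 7)
  expect_equal(c(b$ci_low, b$ci_high), c(7, 7))
  expect_length(b$boot_means, 500)

  x <- rnorm(200)
  b1 <- bootstrap_mean(x, draws = 1000, seed = 42)
  b2 <- bootstrap_mean(x, draws = 1000, seed = 42)
  expect_identical(b1$boot_means, b2$boot_means)
  b3 <- bootstrap_mean(x, draws = 1000, seed = 43)
  expect_false(identical(b1$boot_means, b3$boot_means))

  expect_error(bootstrap_mean(numeric(0)), "non-empty")

  # RNG state of the caller is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(bootstrap_mean(x, draws = 100, seed = 5))
  expect_identical(runif(1), before)
})

test_that("drift summary reproduces the published worked examples from CI midpoints", {
  ci <- reference_bootstrap_cis()
  m <- function(tissue, cond, set)
    ci$mid[ci$tissue == tissue & ci$condition == cond & ci$gene_set == set]

  ds <- drift_summary(
    peak_younger = m("muscle", "3d", "peak"),
    peak_older = m("muscle", "15d", "peak"),
    interpeak_younger = m("muscle", "3d", "interpeak"),
    interpeak_older = m("muscle", "15d", "interpeak"),
    labels = c("3d", "15d"))
  expect_equal(round(ds$relative_gain_pct_peak, 1), 9.4)
  expect_equal(round(ds$relative_gain_pct_interpeak, 1), 36.6)

  # late-onset selectivity from the 15d-3d gain midpoints: about 9%
  sel <- 100 * (m("muscle", "lateonset_15d", "peak") /
                  m("muscle", "lateonset_15d", "interpeak") - 1)
  expect_equal(round(sel), 9)

  expect_equal(round(signal_reduction_pct(
    m("head", "WT_30d", "interpeak"),
    m("head", "PRC2mut_30d", "interpeak")), 1), 38.9)
  expect_equal(round(signal_reduction_pct(
    m("head", "WT_30d", "peak"),
    m("head", "PRC2mut_30d", "peak")), 1), 18.3)

  expect_equal(drift_summary(2, 2, 1, 1)$relative_gain_pct_peak, 0)
  expect_equal(drift_summary(2, 2, 1, 1)$selectivity_pct_lateonset, 0)
  expect_equal(signal_reduction_pct(3, 3), 0)
  expect_error(signal_reduction_pct(0, 1), "positive")
  expect_error(drift_summary(0, 1, 1, 2), "zero")
})

test_that("track correlation aggregates to windows and matches the textbook formula", {
  gm <- genome_model("chr1", 4000, bin_size = 100)
  set.seed(13)
  a <- coverage_track(runif(40, 1, 5), gm, units = "scaled")
  expect_equal(track_correlation(a, a), 1)

  neg <- coverage_track(-a$values$chr1 + 6, gm, units = "difference")
  expect_equal(track_correlation(a, neg), -1)

  b <- coverage_track(runif(40, 1, 5), gm, units = "scaled")
  # manual windowed Pearson r at 1 kb (10 bins per window)
  wmean <- function(v) vapply(1:4, function(k)
    mean(v[((k - 1) * 10 + 1):(k * 10)]), numeric(1))
  x <- wmean(a$values$chr1); y <- wmean(b$values$chr1)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(track_correlation(a, b), r_manual)

  expect_error(track_correlation(a, b, window = 150), "multiple")
  const <- coverage_track(rep(2, 40), gm, units = "scaled")
  expect_error(track_correlation(a, const), "constant")
})

test_that("gene_signal_table assembles per-sample columns with an optional log2 view", {
  gm <- genome_model("chr1", 2000, bin_size = 100)
  t1 <- coverage_track(rep(1, 20), gm, units = "scaled")
  t2 <- coverage_track(rep(3, 20), gm, units = "scaled")
  genes <- gene_annotation(data.frame(
    gene_id = c("a", "b"), chrom = "chr1",
    start = c(0, 1000), end = c(500, 1800), strand = "+"))
  tab <- gene_signal_table(list(young = t1, old = t2), genes)
  expect_equal(dim(tab), c(2, 2))
  expect_equal(tab$old, c(3, 3))
  lt <- gene_signal_table(list(young = t1, old = t2), genes,
                          log2 = TRUE, offset = 1)
  expect_equal(lt$old, log2(c(4, 4)))
})
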