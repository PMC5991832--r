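test_that("call_peaks applies the run/merge/filter criteria at their boundaries", {
  gm <- genome_model("chr1", 5e4, bin_size = 10)
  flat <- tiny_track(rep(1, 5000), gm)
  expect_equal(nrow(call_peaks(flat)), 0)

  # 3000 bp at ratio 3 is kept (inclusive span threshold); 2990 bp is not
  v <- rep(1, 5000); v[101:400] <- 3
  expect_equal(nrow(call_peaks(tiny_track(v, gm))), 1)
  expect_equal(call_peaks(tiny_track(v, gm))$span_bp, 3000)
  expect_equal(call_peaks(tiny_track(v, gm))$mean_ratio, 3)
  v2 <- rep(1, 5000); v2[101:399] <- 3
  expect_equal(nrow(call_peaks(tiny_track(v2, gm))), 0)

  # two 2 kb runs, 4 kb gap: merged to one 8 kb region (gap < 5 kb)
  v3 <- rep(1, 5000); v3[101:300] <- 4; v3[701:900] <- 4
  pk <- call_peaks(tiny_track(v3, gm))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$span_bp, 8000)
  expect_equal(c(pk$start, pk$end), c(1000, 9000))
  # 6 kb gap: two unmerged 2 kb candidates, both below min_span
  v4 <- rep(1, 5000); v4[101:300] <- 4; v4[901:1100] <- 4
  expect_equal(nrow(call_peaks(tiny_track(v4, gm))), 0)

  expect_error(call_peaks(coverage_track(v3, gm, units = "raw")),
               "ratio track")
})

test_that("call_peaks matches the brute-force enumerator on random tracks", {
  set.seed(11)
  gm <- genome_model("chr1", 2e4, bin_size = 100)
  for (i in 1:200) {
    v <- random_ratio_values(200)
    ms <- sample(c(2000, 3000), 1)
    md <- sample(c(3000, 5000), 1)
    got <- call_peaks(tiny_track(v, gm), ratio_threshold = 2,
                      min_span = ms, merge_dist = md)
    want <- oracle_call_peaks(v, 100, 2e4, 2, ms, md)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("call_peaks is idempotent and monotone in the ratio threshold", {
  set.seed(12)
  gm <- genome_model("chr1", 2e4, bin_size = 100)
  for (i in 1:25) {
    v <- random_ratio_values(200)
    p1 <- call_peaks(tiny_track(v, gm))
    p2 <- call_peaks(tiny_track(v, gm))
    expect_identical(as.data.frame(p1), as.data.frame(p2))
    cov_by_thr <- vapply(c(1.5, 2, 2.5, 3), function(th)
      peak_coverage_bp(call_peaks(tiny_track(v, gm), ratio_threshold = th)),
      numeric(1))
    expect_true(all(diff(cov_by_thr) <= 0))
  }
})

test_that("replicate reconciliation keeps regions overlapping in all replicates", {
  gm <- genome_model("chr1", 5e4, bin_size = 10)
  v <- rep(1, 5000); v[101:400] <- 3; v[2001:2500] <- 4
  p <- call_peaks(tiny_track(v, gm))
  expect_equal(nrow(p), 2)

  # identical replicates: unchanged (for any k)
  for (k in c(2, 4))
    expect_equal(as.data.frame(merge_replicate_peaks(rep(list(p), k)))[
                   c("chrom", "start", "end")],
                 as.data.frame(p)[c("chrom", "start", "end")])

  # disjoint replicates: empty
  v2 <- rep(1, 5000); v2[3001:3400] <- 3
  p2 <- call_peaks(tiny_track(v2, gm))
  expect_equal(nrow(merge_replicate_peaks(list(p, p2))), 0)

  # union-extent of overlapping replicate regions
  gm2 <- genome_model("chr1", 2e4, bin_size = 10)
  va <- rep(1, 2000); va[11:500] <- 3     # [100, 5000)
  vb <- rep(1, 2000); vb[301:900] <- 3    # [3000, 9000)
  m <- merge_replicate_peaks(list(call_peaks(tiny_track(va, gm2)),
                                  call_peaks(tiny_track(vb, gm2))))
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(100, 9000))

  # min_replicates relaxation: 1-of-2 keeps both extents
  m1 <- merge_replicate_peaks(list(call_peaks(tiny_track(v, gm)),
                                   call_peaks(tiny_track(v2, gm))),
                              min_replicates = 1)
  expect_equal(nrow(m1), 3)
})

test_that("gene partition uses >= 1 bp overlap under the half-open convention", {
  gm <- genome_model("chr1", 5e4, bin_size = 10)
  v <- rep(1, 5000); v[1001:1400] <- 3   # peak [10000, 14000)
  pk <- call_peaks(tiny_track(v, gm))
  genes <- gene_annotation(data.frame(
    gene_id = c("inside", "abut_left", "abut_right", "straddle", "far"),
    chrom = "chr1",
    start = c(11000, 8000, 14000, 9500, 30000),
    end   = c(12000, 10000, 16000, 10500, 31000),
    strand = "+"))
  part <- partition_genes(genes, pk)
  expect_setequal(part$peak_genes, c("inside", "straddle"))
  expect_setequal(part$interpeak_genes, c("abut_left", "abut_right", "far"))
  expect_length(intersect(part$peak_genes, part$interpeak_genes), 0)

  # random genes/peaks against the quadratic all-pairs oracle
  set.seed(21)
  gmr <- genome_model(c("chr1", "chr2"), c(3e4, 3e4), bin_size = 100)
  for (i in 1:20) {
    gs <- sample(c(0:260) * 100, 30)
    genes <- gene_annotation(data.frame(
      gene_id = sprintf("g%02d", 1:30),
      chrom = sample(c("chr1", "chr2"), 30, TRUE,
                     prob = c(0.6, 0.4)),
      start = gs, end = pmin(gs + sample(50:3000, 30), 3e4),
      strand = "+"))
    ps <- sort(sample(c(0:26) * 1000, 4))
    peaks_df <- data.frame(chrom = sample(c("chr1", "chr2"), 4, TRUE),
                           start = ps, end = pmin(ps + 3000, 3e4))
    peaks_df$span_bp <- peaks_df$end - peaks_df$start
    peaks_df$mean_ratio <- 3
    pk <- epidrift:::peak_set(peaks_df, gmr)
    part <- partition_genes(genes, pk)
    want <- oracle_partition(genes, peaks_df)
    expect_setequal(part$peak_genes, genes$gene_id[want])
  }
})

test_that("peak coverage sums spans and matches a per-base bitmap", {
  gm <- genome_model("chr1", 5e4, bin_size = 10)
  empty <- call_peaks(tiny_track(rep(1, 5000), gm))
  expect_equal(peak_coverage_bp(empty), 0)
  v <- rep(1, 5000); v[101:400] <- 3; v[2001:2500] <- 4
  p <- call_peaks(tiny_track(v, gm))
  expect_equal(peak_coverage_bp(p), 3000 + 5000)
  expect_equal(peak_coverage_bp(p),
               oracle_coverage_bp(as.data.frame(p), c(chr1 = 5e4)))
})

test_that("planted domains are recovered at deep coverage with no spurious calls", {
  cfg <- epigenome_sim_config(reads_per_sample = 2e6, seed = 33)
  sim <- simulate_epigenome(cfg)
  su <- sim$summaries[[1]][[1]]
  rt <- ratio_track(sim$tracks[[1]]$ip[[1]], sim$tracks[[1]]$input[[1]],
                    ip_total_millions = su$ip$reads_experimental_millions,
                    input_total_millions = su$input$reads_experimental_millions)
  pk <- call_peaks(rt)
  dom <- sim$truth$domains
  # recall: every planted domain midpoint is inside a called peak
  hit <- vapply(seq_len(nrow(dom)), function(j) {
    mid <- (dom$start[j] + dom$end[j]) / 2
    any(pk$chrom == dom$chrom[j] & pk$start <= mid & pk$end > mid)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
  # precision: every called peak lies within a planted domain +- merge_dist
  ok <- vapply(seq_len(nrow(pk)), function(j) {
    d <- dom[dom$chrom == pk$chrom[j], , drop = FALSE]
    any(pk$start[j] >= d$start - 5000 & pk$end[j] <= d$end + 5000)
  }, logical(1))
  expect_true(all(ok))
})
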