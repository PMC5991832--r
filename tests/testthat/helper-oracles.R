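# Independent brute-force oracles.  Deliberately written as plain loops over
# bases/bins so they share no code path with the package implementation.

# rasterize bedGraph-style records onto bins by walking every base
oracle_rasterize <- function(records, chrom_len, bin_size) {
  per_base <- numeric(chrom_len)
  for (i in seq_len(nrow(records))) {
    idx <- (records$start[i] + 1):records$end[i]
    per_base[idx] <- records$value[i]
  }
  nb <- ceiling(chrom_len / bin_size)
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    lo <- (b - 1) * bin_size + 1
    hi <- min(b * bin_size, chrom_len)
    out[b] <- sum(per_base[lo:hi]) / (hi - lo + 1)
  }
  out
}

# enumerate runs / merge / filter on one chromosome of bin values
oracle_call_peaks <- function(v, bin_size, chrom_len, thr, min_span,
                              merge_dist) {
  runs <- list()
  in_run <- FALSE
  for (b in seq_along(v)) {
    if (v[b] >= thr && !in_run) { s <- b; in_run <- TRUE }
    if (in_run && (v[b] < thr)) {
      runs[[length(runs) + 1]] <- c(s, b - 1); in_run <- FALSE
    }
  }
  if (in_run) runs[[length(runs) + 1]] <- c(s, length(v))
  if (!length(runs)) return(data.frame(start = numeric(0), end = numeric(0)))
  iv <- do.call(rbind, lapply(runs, function(r)
    c((r[1] - 1) * bin_size, min(r[2] * bin_size, chrom_len))))
  # merge any two candidates with gap < merge_dist, repeatedly
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(iv)) {
      if (iv[i + 1, 1] - iv[i, 2] < merge_dist) {
        iv[i, 2] <- iv[i + 1, 2]
        iv <- iv[-(i + 1), , drop = FALSE]
        merged <- TRUE
      } else i <- i + 1
    }
    if (!merged) break
  }
  keep <- (iv[, 2] - iv[, 1]) >= min_span
  data.frame(start = iv[keep, 1], end = iv[keep, 2])
}

# per-base mean of piecewise-constant bin values over [start, end)
oracle_gene_signal <- function(v, bin_size, start, end) {
  per_base <- rep(v, each = bin_size)
  mean(per_base[(start + 1):end])
}

# quadratic all-pairs overlap classification
oracle_partition <- function(genes, peaks) {
  is_peak <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(peaks))) {
      if (genes$chrom[i] == peaks$chrom[j] &&
          genes$start[i] < peaks$end[j] &&
          peaks$start[j] < genes$end[i]) {
        is_peak[i] <- TRUE
        break
      }
    }
  }
  is_peak
}

# per-base bitmap count of bases covered by a set of regions
oracle_coverage_bp <- function(peaks, chrom_lens) {
  total <- 0
  for (ch in names(chrom_lens)) {
    bitmap <- logical(chrom_lens[[ch]])
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(p)))
      bitmap[(p$start[j] + 1):p$end[j]] <- TRUE
    total <- total + sum(bitmap)
  }
  total
}

# random well-formed ratio track values for the peak-caller equivalence test:
# baseline below threshold with occasional above-threshold blocks
random_ratio_values <- function(n_bins, thr = 2) {
  v <- runif(n_bins, 0.2, thr - 0.1)
  n_blocks <- sample(0:4, 1)
  for (b in seq_len(n_blocks)) {
    w <- sample(1:60, 1)
    s <- sample(1:(n_bins - w + 1), 1)
    v[s:(s + w - 1)] <- runif(w, thr, thr + 3)
  }
  # salt-and-pepper so runs break and merge in interesting ways
  flip <- runif(n_bins) < 0.05
  v[flip] <- runif(sum(flip), 0.2, thr + 3)
  v
}

# small single-chromosome genome + track builders used across test files
tiny_genome <- function(len = 2e4, bin = 100, chrom = "chr1")
  genome_model(chrom, len, bin_size = bin)

tiny_track <- function(v, genome, units = "ratio")
  coverage_track(v, genome, units = units)
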