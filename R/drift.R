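#' Mean signal over gene bodies
#'
#' Per-base mean of a track over each gene body \code{[start, end)} (TSS to
#' TTS), with bins partially covered by the gene contributing
#' length-weighted.  Strand is ignored: gene-body summarization of a
#' chromatin mark is strand-agnostic.  The computation is exact and O(1)
#' per gene via prefix sums of the piecewise-constant track.
#'
#' @param track a \code{\link{coverage_track}} (typically reference-adjusted
#'   or a difference track).
#' @param genes a \code{\link{gene_annotation}} table within the track's
#'   genome.
#' @return Named numeric vector of per-gene per-base means, in gene order.
#' @examples
#' gm <- genome_model("chr1", 20, bin_size = 10)
#' tr <- coverage_track(c(1, 3), gm, units = "scaled")
#' g <- gene_annotation(data.frame(gene_id = "g1", chrom = "chr1",
#'                                 start = 5, end = 15, strand = "+"))
#' gene_body_signal(tr, g)  # (5*1 + 5*3)/10 = 2
#' @export
gene_body_signal <- function(track, genes) {
  stopifnot(inherits(track, "coverage_track"))
  genes <- gene_annotation(genes, track$genome)
  genome <- track$genome
  B <- genome$bin_size
  out <- numeric(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    v <- track$values[[ch]]
    w <- bin_widths(genome, ch)
    pre <- c(0, cumsum(v * w))          # integral up to each bin boundary
    integral_to <- function(x) {        # integral of signal over [0, x)
      b <- pmin(x %/% B, length(v) - 1)
      pre[b + 1] + v[b + 1] * (x - b * B)
    }
    out[gi] <- (integral_to(genes$end[gi]) - integral_to(genes$start[gi])) /
      (genes$end[gi] - genes$start[gi])
  }
  stats::setNames(out, genes$gene_id)
}

#' Gene-by-sample signal table
#'
#' Applies \code{\link{gene_body_signal}} to each track of a list and
#' assembles the per-gene means into a data.frame, one column per sample,
#' optionally log2-transformed with an offset.
#'
#' @param tracks named list of \code{\link{coverage_track}}s on one genome.
#' @param genes a \code{\link{gene_annotation}} table.
#' @param log2 if \code{TRUE}, return \code{log2(value + offset)}.
#' @param offset offset for the log2 view, default 1.
#' @return data.frame with rownames = gene ids, one numeric column per
#'   track.
#' @export
gene_signal_table <- function(tracks, genes, log2 = FALSE, offset = 1) {
  stopifnot(is.list(tracks), length(tracks) > 0)
  cols <- lapply(tracks, gene_body_signal, genes = genes)
  df <- as.data.frame(cols, optional = TRUE)
  names(df) <- if (is.null(names(tracks))) paste0("sample", seq_along(tracks))
               else names(tracks)
  if (log2) df[] <- lapply(df, function(x) base::log2(x + offset))
  df
}

#' Difference of two reference-adjusted tracks
#'
#' Bin-wise \code{older - younger}; the result isolates the signal acquired
#' between the two ages (late-onset signal) and may be negative, so it is
#' flagged with units \code{"difference"}.
#'
#' @param older,younger \code{\link{coverage_track}}s on the same genome,
#'   both reference-adjusted (units \code{"scaled"} or \code{"difference"}).
#' @return \code{coverage_track} with units \code{"difference"}.
#' @export
subtract_tracks <- function(older, younger) {
  stopifnot(inherits(older, "coverage_track"),
            inherits(younger, "coverage_track"))
  if (!same_genome(older$genome, younger$genome))
    stop("tracks are on different genomes")
  if (older$units %in% c("raw", "ratio") ||
      younger$units %in% c("raw", "ratio"))
    stop("subtract_tracks expects reference-adjusted tracks")
  coverage_track(map_bins(`-`, older, younger), older$genome,
                 label = sprintf("%s - %s", older$label, younger$label),
                 units = "difference")
}

#' Bootstrap the mean of a gene-set signal column
#'
#' Percentile bootstrap of a mean: each of \code{draws} resamples takes
#' \code{subsample_n} values with replacement and records their mean; the
#' 95\% interval is the 2.5 and 97.5 percentiles of the resampled means.
#' Deterministic given \code{seed}; the caller's RNG state is left
#' untouched.
#'
#' @param values non-empty numeric vector (per-gene signal of one set).
#' @param draws number of resamples, default 10000.
#' @param subsample_n resample size, default 500.
#' @param seed integer seed.
#' @return Object of class \code{bootstrap_result}: \code{point_mean},
#'   \code{boot_means} (length \code{draws}), \code{ci_low}, \code{ci_high},
#'   plus the parameters.
#' @export
bootstrap_mean <- function(values, draws = 10000, subsample_n = 500,
                           seed = 1L) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("values must be a non-empty finite numeric vector")
  boot <- with_seed(seed, {
    idx <- sample.int(length(values), draws * subsample_n, replace = TRUE)
    .colMeans(values[idx], subsample_n, draws)
  })
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  structure(
    list(point_mean = mean(values), boot_means = boot,
         ci_low = ci[1], ci_high = ci[2],
         draws = draws, subsample_n = subsample_n, seed = seed),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> mean %.4g, 95%% CI [%.4g, %.4g] (%d draws of n = %d)\n",
              x$point_mean, x$ci_low, x$ci_high, x$draws, x$subsample_n))
  invisible(x)
}

#' Drift summary statistics between two conditions
#'
#' Computes the three statistics that quantify drift of a mark between a
#' younger and an older condition, from the four gene-set means:
#' \itemize{
#'   \item net gain per set: \code{older - younger};
#'   \item relative gain per set (\%): \code{100 * net_gain / younger};
#'   \item selectivity (\%): percent excess of the peak-gene mean over the
#'     inter-peak-gene mean, computed both for the baseline (younger)
#'     signal and for the late-onset signal (the per-set net gains).
#' }
#' High baseline selectivity with low late-onset selectivity is the drift
#' signature: signal acquired with age lands almost uniformly instead of at
#' pre-existing domains.
#'
#' @param peak_younger,peak_older mean signal of peak genes in the two
#'   conditions.
#' @param interpeak_younger,interpeak_older mean signal of inter-peak genes.
#' @param labels length-2 character vector naming the conditions.
#' @return Object of class \code{drift_summary} with fields
#'   \code{net_gain_peak}, \code{net_gain_interpeak},
#'   \code{relative_gain_pct_peak}, \code{relative_gain_pct_interpeak},
#'   \code{selectivity_pct_baseline}, \code{selectivity_pct_lateonset}.
#' @examples
#' # CI midpoints of a muscle aging series, 3d vs 15d
#' drift_summary(peak_younger = 3.544, peak_older = 3.878,
#'               interpeak_younger = 0.8875, interpeak_older = 1.212,
#'               labels = c("3d", "15d"))
#' @export
drift_summary <- function(peak_younger, peak_older,
                          interpeak_younger, interpeak_older,
                          labels = c("younger", "older")) {
  vals <- c(peak_younger, peak_older, interpeak_younger, interpeak_older)
  if (any(!is.finite(vals))) stop("all four set means must be finite")
  if (peak_younger == 0 || interpeak_younger == 0)
    stop("undefined percentage: younger/baseline mean is zero")
  ng_p <- peak_older - peak_younger
  ng_i <- interpeak_older - interpeak_younger
  if (ng_i == 0 && ng_p == 0) {
    sel_late <- 0       # no gain anywhere: no late-onset preference
  } else if (ng_i == 0) {
    stop("undefined percentage: inter-peak net gain is zero")
  } else {
    sel_late <- 100 * (ng_p - ng_i) / ng_i
  }
  structure(
    list(labels = labels,
         peak_means = c(younger = peak_younger, older = peak_older),
         interpeak_means = c(younger = interpeak_younger,
                             older = interpeak_older),
         net_gain_peak = ng_p, net_gain_interpeak = ng_i,
         relative_gain_pct_peak = 100 * ng_p / peak_younger,
         relative_gain_pct_interpeak = 100 * ng_i / interpeak_younger,
         selectivity_pct_baseline =
           100 * (peak_younger - interpeak_younger) / interpeak_younger,
         selectivity_pct_lateonset = sel_late),
    class = "drift_summary"
  )
}

#' @export
print.drift_summary <- function(x, ...) {
  cat(sprintf("<drift_summary> %s -> %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  net gain: peak %+.3f (%.1f%%), inter-peak %+.3f (%.1f%%)\n",
              x$net_gain_peak, x$relative_gain_pct_peak,
              x$net_gain_interpeak, x$relative_gain_pct_interpeak))
  cat(sprintf("  selectivity: baseline about %.0f%%, late-onset about %.0f%%\n",
              x$selectivity_pct_baseline, x$selectivity_pct_lateonset))
  invisible(x)
}

#' Percent signal reduction between wild type and a mutant
#'
#' \code{100 * (wt_mean - mut_mean) / wt_mean}, the statistic used to state
#' how much less signal a writer-deficient mutant carries in a gene set.
#'
#' @param wt_mean wild-type mean signal (> 0).
#' @param mut_mean mutant mean signal.
#' @return Percent reduction (negative if the mutant has more signal).
#' @export
signal_reduction_pct <- function(wt_mean, mut_mean) {
  if (!is.finite(wt_mean) || wt_mean <= 0)
    stop("wt_mean must be a positive finite number")
  100 * (wt_mean - mut_mean) / wt_mean
}

#' Pearson correlation of two tracks at fixed windows
#'
#' Bins are aggregated to non-overlapping windows (mean of the bins in each
#' window) and the Pearson correlation is computed over all windows
#' genome-wide — the standard summary for comparing genome-wide occupancy
#' patterns between samples.
#'
#' @param a,b \code{\link{coverage_track}}s on the same genome.
#' @param window window size in bp, a multiple of the bin size;
#'   default 1000.
#' @return Pearson r.
#' @export
track_correlation <- function(a, b, window = 1000) {
  stopifnot(inherits(a, "coverage_track"), inherits(b, "coverage_track"))
  if (!same_genome(a$genome, b$genome))
    stop("tracks are on different genomes")
  B <- a$genome$bin_size
  if (window %% B != 0 || window < B)
    stop("window must be a positive multiple of the bin size")
  per <- window %/% B
  agg <- function(track) {
    unlist(lapply(a$genome$chrom_names, function(ch) {
      v <- track$values[[ch]]
      grp <- (seq_along(v) - 1L) %/% per
      as.numeric(tapply(v, grp, mean))
    }), use.names = FALSE)
  }
  x <- agg(a); y <- agg(b)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant track")
  stats::cor(x, y)
}
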