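#' Call broad enriched domains from an IP/input ratio track
#'
#' Detects broad domains of a repressive mark with the run/merge/filter
#' criteria used for broad histone domains: maximal runs of consecutive
#' bins whose enrichment ratio is at or above \code{ratio_threshold} become
#' candidate regions; candidates on the same chromosome separated by less
#' than \code{merge_dist} bp are merged (the sub-threshold gap bins are
#' included in the merged region); merged candidates spanning less than
#' \code{min_span} bp are discarded.  The span threshold is inclusive
#' (a region of exactly \code{min_span} bp is kept) and evaluated after
#' merging.  The per-bin threshold defines detection; the region's mean
#' ratio is reported, not filtered on.
#'
#' @param ratio a \code{\link{coverage_track}} with units \code{"ratio"}
#'   (see \code{\link{ratio_track}}).
#' @param ratio_threshold minimum per-bin IP/input ratio, default 2.
#' @param min_span minimum region span in bp after merging, default 3000.
#' @param merge_dist candidates closer than this many bp are merged,
#'   default 5000.
#' @return Object of class \code{peak_set}: a data.frame of regions
#'   (\code{chrom, start, end, span_bp, mean_ratio}; 0-based half-open,
#'   sorted, non-overlapping) with the parameters and genome attached as
#'   attributes.
#' @examples
#' gm <- genome_model("chr1", 2e4, bin_size = 100)
#' v <- rep(1, 200); v[51:90] <- 4
#' rt <- coverage_track(v, gm, units = "ratio")
#' call_peaks(rt)  # one 4 kb domain
#' @export
call_peaks <- function(ratio, ratio_threshold = 2, min_span = 3000,
                       merge_dist = 5000) {
  stopifnot(inherits(ratio, "coverage_track"))
  if (ratio$units != "ratio")
    stop("call_peaks expects a ratio track (see ratio_track())")
  if (ratio_threshold <= 0 || min_span <= 0 || merge_dist < 0)
    stop("thresholds must be positive")
  genome <- ratio$genome
  B <- genome$bin_size
  regions <- list()
  for (ch in genome$chrom_names) {
    v <- ratio$values[[ch]]
    r <- rle(v >= ratio_threshold)
    if (!any(r$values)) next
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values
    cs <- starts_bin[keep] * B
    ce <- pmin(ends_bin[keep] * B, genome$chrom_lengths[[ch]])
    # merge candidates separated by < merge_dist
    ms <- cs[1]; me <- ce[1]
    out_s <- numeric(0); out_e <- numeric(0)
    if (length(cs) > 1L) {
      for (i in 2:length(cs)) {
        if (cs[i] - me < merge_dist) {
          me <- ce[i]
        } else {
          out_s <- c(out_s, ms); out_e <- c(out_e, me)
          ms <- cs[i]; me <- ce[i]
        }
      }
    }
    out_s <- c(out_s, ms); out_e <- c(out_e, me)
    span <- out_e - out_s
    ok <- span >= min_span
    if (!any(ok)) next
    out_s <- out_s[ok]; out_e <- out_e[ok]
    w <- bin_widths(genome, ch)
    mr <- mapply(function(s, e) {
      idx <- (s %/% B + 1):ceiling(e / B)
      sum(v[idx] * w[idx]) / sum(w[idx])
    }, out_s, out_e)
    regions[[ch]] <- data.frame(chrom = ch, start = out_s, end = out_e,
                                span_bp = out_e - out_s, mean_ratio = mr,
                                stringsAsFactors = FALSE)
  }
  df <- if (length(regions)) do.call(rbind, regions)
        else data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), span_bp = numeric(0),
                        mean_ratio = numeric(0))
  rownames(df) <- NULL
  peak_set(df, genome,
           params = list(ratio_threshold = ratio_threshold,
                         min_span = min_span, merge_dist = merge_dist))
}

# internal constructor; regions assumed sorted within chromosome
peak_set <- function(regions, genome, params = list()) {
  regions <- regions[order(match(regions$chrom, genome$chrom_names),
                           regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  structure(regions,
            genome = genome, params = params,
            class = c("peak_set", "data.frame"))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d region(s), %.4g Mb covered\n",
              nrow(x), peak_coverage_bp(x) / 1e6))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

# IRanges view of a peak set's regions on one chromosome (1-based closed)
.regions_iranges <- function(df, ch) {
  r <- df[df$chrom == ch, , drop = FALSE]
  IRanges::IRanges(start = r$start + 1, end = r$end)
}

#' Reconcile peak sets across replicates
#'
#' Returns the regions reproducibly found across replicates: genomic
#' positions covered by at least \code{min_replicates} of the input peak
#' sets seed a reproducible region, which is reported as the union extent
#' of all replicate regions overlapping that seed.  With the default
#' (\code{min_replicates = length(peaksets)}) a region must have at least
#' 1 bp of overlap in every replicate — the strictest reading of
#' "reproducibly identified from all replicates".
#'
#' @param peaksets list of \code{\link{call_peaks}} results on the same
#'   genome.
#' @param min_replicates minimum number of replicates that must cover a
#'   position; default all.
#' @return A \code{peak_set} of reproducible regions; \code{mean_ratio} is
#'   the span-weighted mean of the contributing replicate regions' means.
#' @export
merge_replicate_peaks <- function(peaksets,
                                  min_replicates = length(peaksets)) {
  if (length(peaksets) == 0L) stop("need at least one peak set")
  stopifnot(all(vapply(peaksets, inherits, logical(1), "peak_set")))
  genome <- attr(peaksets[[1]], "genome")
  for (p in peaksets)
    if (!same_genome(attr(p, "genome"), genome))
      stop("peak sets are on different genomes")
  if (min_replicates < 1 || min_replicates > length(peaksets))
    stop("min_replicates out of range")
  if (length(peaksets) == 1L) return(peaksets[[1]])

  out <- list()
  for (ch in genome$chrom_names) {
    irs <- lapply(peaksets, .regions_iranges, ch = ch)
    all_ir <- do.call(c, irs)
    if (length(all_ir) == 0L) next
    cov <- IRanges::coverage(all_ir,
                             width = genome$chrom_lengths[[ch]])
    core <- IRanges::slice(cov, lower = min_replicates, rangesOnly = TRUE)
    if (length(core) == 0L) next
    hits <- IRanges::findOverlaps(core, all_ir)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ext_s <- tapply(IRanges::start(all_ir)[sh], qh, min)
    ext_e <- tapply(IRanges::end(all_ir)[sh], qh, max)
    ext <- IRanges::reduce(IRanges::IRanges(start = as.numeric(ext_s),
                                            end = as.numeric(ext_e)))
    # span-weighted mean ratio of contributing replicate regions
    mrs <- unlist(lapply(peaksets, function(p) {
      r <- p[p$chrom == ch, , drop = FALSE]; r$mean_ratio
    }))
    sps <- IRanges::width(all_ir)
    h2 <- IRanges::findOverlaps(ext, all_ir)
    q2 <- S4Vectors::queryHits(h2); s2 <- S4Vectors::subjectHits(h2)
    mr <- as.numeric(tapply(mrs[s2] * sps[s2], q2, sum) /
                       tapply(sps[s2], q2, sum))
    out[[ch]] <- data.frame(
      chrom = ch,
      start = IRanges::start(ext) - 1,
      end = as.numeric(IRanges::end(ext)),
      span_bp = as.numeric(IRanges::width(ext)),
      mean_ratio = mr, stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out)
        else data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), span_bp = numeric(0),
                        mean_ratio = numeric(0))
  peak_set(df, genome,
           params = c(attr(peaksets[[1]], "params"),
                      list(min_replicates = min_replicates,
                           n_replicates = length(peaksets))))
}

#' Partition genes into peak genes and inter-peak genes
#'
#' A gene is a peak gene iff its body \code{[start, end)} overlaps any
#' region of the reproducible peak set by at least 1 bp; all other genes
#' are inter-peak genes.  Under the half-open convention a gene ending
#' exactly where a peak starts does not overlap it.
#'
#' @param genes a \code{\link{gene_annotation}} table.
#' @param common_peaks a \code{peak_set}.
#' @return Object of class \code{gene_partition}: list with character
#'   vectors \code{peak_genes} and \code{interpeak_genes} (disjoint, union
#'   = all genes).
#' @export
partition_genes <- function(genes, common_peaks) {
  stopifnot(inherits(genes, "gene_annotation"),
            inherits(common_peaks, "peak_set"))
  genome <- attr(common_peaks, "genome")
  genes <- gene_annotation(genes, genome)
  in_peak <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pk <- .regions_iranges(common_peaks, ch)
    if (length(pk) == 0L) next
    gr <- IRanges::IRanges(start = genes$start[gi] + 1, end = genes$end[gi])
    in_peak[gi] <- IRanges::overlapsAny(gr, pk)
  }
  structure(
    list(peak_genes = genes$gene_id[in_peak],
         interpeak_genes = genes$gene_id[!in_peak]),
    class = "gene_partition"
  )
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf("<gene_partition> %d peak gene(s), %d inter-peak gene(s)\n",
              length(x$peak_genes), length(x$interpeak_genes)))
  invisible(x)
}

#' Total base pairs covered by a peak set
#'
#' @param peaks a \code{peak_set}.
#' @return Sum of region spans in bp.
#' @export
peak_coverage_bp <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  sum(peaks$span_bp)
}

#' Write a peak set as BED4
#'
#' Columns: chrom, start, end, mean_ratio.
#'
#' @param peaks a \code{peak_set}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  writeLines(sprintf("%s\t%.0f\t%.0f\t%.6g",
                     peaks$chrom, peaks$start, peaks$end, peaks$mean_ratio),
             path)
  invisible(path)
}
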