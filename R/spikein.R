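#' Alignment read-count summary for one sample
#'
#' Book-keeping container for the read counts that drive spike-in
#' normalization: how many reads of an IP or input library aligned to the
#' experimental genome versus the exogenous spike-in genome.
#'
#' @param sample_id sample identifier.
#' @param role \code{"IP"} or \code{"input"}.
#' @param reads_experimental_millions reads aligned to the experimental
#'   genome, in millions (> 0).
#' @param reads_spikein_millions reads aligned to the spike-in genome, in
#'   millions (>= 0).
#' @param total_reads_millions total reads, in millions (> 0); must be at
#'   least the sum of the two aligned counts.
#' @return An object of class \code{alignment_summary}.
#' @export
alignment_summary <- function(sample_id, role,
                              reads_experimental_millions,
                              reads_spikein_millions,
                              total_reads_millions) {
  if (!role %in% c("IP", "input"))
    stop("role must be 'IP' or 'input'")
  if (!is.finite(reads_experimental_millions) ||
      reads_experimental_millions <= 0)
    stop("reads_experimental_millions must be > 0")
  if (!is.finite(reads_spikein_millions) || reads_spikein_millions < 0)
    stop("reads_spikein_millions must be >= 0")
  if (!is.finite(total_reads_millions) || total_reads_millions <= 0)
    stop("total_reads_millions must be > 0")
  if (reads_experimental_millions + reads_spikein_millions >
      total_reads_millions + 1e-9)
    stop("aligned reads exceed total reads")
  structure(
    list(sample_id = as.character(sample_id), role = role,
         reads_experimental_millions = reads_experimental_millions,
         reads_spikein_millions = reads_spikein_millions,
         total_reads_millions = total_reads_millions),
    class = "alignment_summary"
  )
}

#' Percentage of spike-in reads in an input library
#'
#' The quantity \emph{d} of the normalization: the percentage of the paired
#' input sample's reads that mapped to the spike-in genome.  Because the
#' input library samples total chromatin, this percentage estimates the
#' fixed fraction of spike-in material added to each sample.
#'
#' @param input_summary an \code{\link{alignment_summary}} with role
#'   \code{"input"}.
#' @return Percentage (0-100).
#' @examples
#' inp <- alignment_summary("inp", "input", 0.95, 0.05, 1.0)
#' spikein_percent(inp)  # 5
#' @export
spikein_percent <- function(input_summary) {
  stopifnot(inherits(input_summary, "alignment_summary"))
  if (input_summary$role != "input")
    stop("spikein_percent is defined on the input sample")
  if (input_summary$total_reads_millions <= 0)
    stop("zero total reads")
  100 * input_summary$reads_spikein_millions /
    input_summary$total_reads_millions
}

#' Spike-in scale factor for an IP sample
#'
#' Computes the reference-adjusted scale factor \eqn{\hat a = d / c}, where
#' \eqn{c} is the IP sample's spike-in-aligned read count in millions and
#' \eqn{d} the percentage of spike-in reads in the paired input library.
#' The derivation sets the (constant) reference signal \eqn{b} from the
#' spike-in material to one, so that \eqn{b = a c / d} gives
#' \eqn{\hat a = d / c}; multiplying a sample's raw coverage by \eqn{\hat a}
#' makes samples with different IP efficiencies and sequencing depths
#' directly comparable.
#'
#' @param ip_summary \code{\link{alignment_summary}} with role \code{"IP"}.
#' @param input_summary paired \code{\link{alignment_summary}} with role
#'   \code{"input"}.
#' @return Object of class \code{scale_factor} with fields \code{a_hat},
#'   \code{c}, \code{d}, \code{b_reference} (fixed at 1) and
#'   \code{sample_id}.
#' @examples
#' ip  <- alignment_summary("ip",  "IP",    4.0, 0.5, 5.0)
#' inp <- alignment_summary("inp", "input", 0.95, 0.05, 1.0)
#' compute_scale_factor(ip, inp)  # a_hat = 5 / 0.5 = 10
#' @export
compute_scale_factor <- function(ip_summary, input_summary) {
  stopifnot(inherits(ip_summary, "alignment_summary"),
            inherits(input_summary, "alignment_summary"))
  if (ip_summary$role != "IP") stop("first argument must have role 'IP'")
  if (input_summary$role != "input")
    stop("second argument must have role 'input'")
  cc <- ip_summary$reads_spikein_millions
  if (cc <= 0)
    stop("no spike-in reads in IP sample: cannot derive a scale factor")
  d <- spikein_percent(input_summary)
  if (d <= 0)
    stop("degenerate input: no spike-in reads in the paired input sample")
  structure(
    list(a_hat = d / cc, c = cc, d = d, b_reference = 1,
         sample_id = ip_summary$sample_id),
    class = "scale_factor"
  )
}

#' @export
print.scale_factor <- function(x, ...) {
  cat(sprintf("<scale_factor> sample '%s': a_hat = %.6g (d = %.4g%%, c = %.4g M)\n",
              x$sample_id, x$a_hat, x$d, x$c))
  invisible(x)
}

#' Apply a spike-in scale factor to a raw track
#'
#' Multiplies every bin of a raw count track by \code{a_hat}, producing the
#' reference-adjusted track used by all downstream drift statistics.  Total
#' signal mass scales by exactly \code{a_hat}.  Applying the function to an
#' already-scaled track is an error (double-scaling guard).
#'
#' @param track raw \code{\link{coverage_track}}.
#' @param sf \code{\link{scale_factor}}.
#' @return Reference-adjusted \code{coverage_track} (units \code{"scaled"}).
#' @export
scale_track <- function(track, sf) {
  stopifnot(inherits(track, "coverage_track"), inherits(sf, "scale_factor"))
  if (track$units != "raw")
    stop(sprintf("refusing to scale a '%s' track: scale_track expects raw counts",
                 track$units))
  coverage_track(map_bins(function(v) v * sf$a_hat, track),
                 track$genome,
                 label = paste0(track$label, " [reference-adjusted]"),
                 units = "scaled")
}

#' IP/input enrichment ratio track
#'
#' Depth-normalizes both tracks to reads-per-million internally (dividing
#' each bin by that track's mapped-read total in millions) and returns the
#' per-bin ratio \code{(ip_rpm + pseudocount) / (input_rpm + pseudocount)}.
#' The pseudocount keeps broad low-coverage domains from producing
#' infinities where the input has empty bins.  Spike-in reads are
#' normalization cargo, not signal, so when explicit totals are given they
#' should be experimental-genome mapped reads only; by default each track's
#' own bin-count total is used.
#'
#' @param ip,input raw \code{\link{coverage_track}}s on the same genome.
#' @param pseudocount added to both RPM values before division; default 1.
#' @param ip_total_millions,input_total_millions optional mapped-read totals
#'   (millions) used for the internal RPM normalization; defaults to the
#'   sum of the track's own bins / 1e6.
#' @return \code{coverage_track} with units \code{"ratio"}.
#' @export
ratio_track <- function(ip, input, pseudocount = 1,
                        ip_total_millions = NULL,
                        input_total_millions = NULL) {
  stopifnot(inherits(ip, "coverage_track"), inherits(input, "coverage_track"))
  if (!same_genome(ip$genome, input$genome))
    stop("ip and input tracks are on different genomes")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  ipM <- if (is.null(ip_total_millions)) track_sum(ip) / 1e6
         else ip_total_millions
  inM <- if (is.null(input_total_millions)) track_sum(input) / 1e6
         else input_total_millions
  if (ipM <= 0 || inM <= 0) stop("cannot RPM-normalize an empty track")
  vals <- map_bins(function(a, b) {
    r <- (a / ipM + pseudocount) / (b / inM + pseudocount)
    r[!is.finite(r)] <- 0   # 0/0 with pseudocount 0
    r
  }, ip, input)
  coverage_track(vals, ip$genome,
                 label = sprintf("%s / %s", ip$label, input$label),
                 units = "ratio")
}

#' Reference-adjusted reads per million (RRPM) total
#'
#' The genome-wide quantitative summary of a ChIP-Rx sample: its raw mapped
#' read total rescaled by the spike-in scale factor.  Rising RRPM across an
#' age series indicates a genuine global gain of the mark, which plain
#' depth normalization would erase.
#'
#' @param sf \code{\link{scale_factor}} for the sample.
#' @param raw_total_millions raw mapped-read total in millions (> 0).
#' @param sample_id optional id, defaults to the scale factor's.
#' @return Object of class \code{rrpm_summary} with \code{rrpm_total}.
#' @export
rrpm_total <- function(sf, raw_total_millions, sample_id = sf$sample_id) {
  stopifnot(inherits(sf, "scale_factor"))
  if (!is.finite(raw_total_millions) || raw_total_millions <= 0)
    stop("raw_total_millions must be > 0")
  structure(
    list(sample_id = sample_id,
         rrpm_total = sf$a_hat * raw_total_millions),
    class = "rrpm_summary"
  )
}

#' @export
print.rrpm_summary <- function(x, ...) {
  cat(sprintf("<rrpm_summary> sample '%s': RRPM total %.4g\n",
              x$sample_id, x$rrpm_total))
  invisible(x)
}
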