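#' Reference bootstrap confidence intervals for worked examples
#'
#' Bootstrapped 95\% confidence intervals for the mean reference-adjusted
#' H3K27me3 intensity of peak-gene and inter-peak-gene sets in fly muscle
#' and head tissue — across an aging series (3d/15d/30d), for late-onset
#' (older minus 3d) signal, and for wild type versus a PRC2
#' trans-heterozygous mutant at 30d.  These printed interval bounds serve
#' as worked-example inputs to the drift statistics: the interval midpoint
#' is used as the point estimate of each gene-set mean.
#'
#' @param midpoints if \code{TRUE} (default) add a \code{mid} column,
#'   \code{(ci_low + ci_high) / 2}.
#' @return data.frame with columns \code{tissue}, \code{condition},
#'   \code{gene_set}, \code{ci_low}, \code{ci_high} (and \code{mid}).
#' @examples
#' ci <- reference_bootstrap_cis()
#' # relative gain of muscle peak genes, 3d -> 15d: about 9.4%
#' m <- function(cond, set)
#'   ci$mid[ci$tissue == "muscle" & ci$condition == cond &
#'          ci$gene_set == set]
#' drift_summary(m("3d", "peak"), m("15d", "peak"),
#'               m("3d", "interpeak"), m("15d", "interpeak"))
#' @export
reference_bootstrap_cis <- function(midpoints = TRUE) {
  path <- system.file("extdata", "h3k27me3_reference_cis.tsv",
                      package = "epidrift", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (midpoints) df$mid <- (df$ci_low + df$ci_high) / 2
  df
}
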