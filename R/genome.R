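#' Define a binned genome model
#'
#' A genome model fixes the chromosome names, chromosome lengths and the
#' bin size onto which all coverage is rasterized.  Every coverage track,
#' peak set and gene annotation in the pipeline is validated against one of
#' these.  All coordinates in the package are 0-based half-open (BED
#' convention).
#'
#' @param chrom_names character vector of chromosome identifiers.
#' @param chrom_lengths integer-ish vector of chromosome lengths in base
#'   pairs, one per chromosome, all positive.
#' @param bin_size positive integer bin width in base pairs.  The default of
#'   10 bp matches common deepTools practice for quantitative ChIP tracks;
#'   synthetic tests typically use 100 bp for speed.
#'
#' @return An object of class \code{genome_model} with fields
#'   \code{chrom_names}, \code{chrom_lengths} (named) and \code{bin_size}.
#' @examples
#' gm <- genome_model(c("chr2L", "chr2R"), c(2e6, 1.5e6), bin_size = 100)
#' n_bins(gm)
#' @export
genome_model <- function(chrom_names, chrom_lengths, bin_size = 10L) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) == 0L)
    stop("genome must have at least one chromosome")
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths differ in length")
  if (anyDuplicated(chrom_names))
    stop("duplicate chromosome names")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be positive and finite")
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1L)
    stop("bin_size must be a positive integer")
  names(chrom_lengths) <- chrom_names
  structure(
    list(chrom_names = chrom_names, chrom_lengths = chrom_lengths,
         bin_size = bin_size),
    class = "genome_model"
  )
}

#' Number of bins per chromosome
#'
#' @param genome a \code{genome_model}.
#' @return Named integer vector: \code{ceiling(length / bin_size)} per
#'   chromosome.
#' @export
n_bins <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  as.integer(ceiling(genome$chrom_lengths / genome$bin_size))
}

# widths of the bins of one chromosome (last bin may be short)
bin_widths <- function(genome, chrom) {
  L <- genome$chrom_lengths[[chrom]]
  B <- genome$bin_size
  nb <- as.integer(ceiling(L / B))
  w <- rep(as.numeric(B), nb)
  w[nb] <- L - (nb - 1) * B
  w
}

same_genome <- function(a, b) {
  identical(a$chrom_names, b$chrom_names) &&
    identical(unname(a$chrom_lengths), unname(b$chrom_lengths)) &&
    identical(a$bin_size, b$bin_size)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosome(s), %.3g Mb total, %d bp bins\n",
              length(x$chrom_names), sum(x$chrom_lengths) / 1e6, x$bin_size))
  invisible(x)
}
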