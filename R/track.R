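#' Binned coverage track
#'
#' A coverage track stores one non-negative value per genomic bin per
#' chromosome.  The \code{units} field records where the track sits in the
#' pipeline and guards against nonsense operations such as double scaling
#' or calling peaks on a non-ratio track:
#' \describe{
#'   \item{\code{"raw"}}{read counts per bin, straight from alignment.}
#'   \item{\code{"scaled"}}{reference-adjusted signal: raw counts multiplied
#'     by the spike-in scale factor (see \code{\link{scale_track}}).}
#'   \item{\code{"ratio"}}{IP/input enrichment ratio per bin
#'     (see \code{\link{ratio_track}}).}
#'   \item{\code{"difference"}}{bin-wise difference of two scaled tracks;
#'     the only flavour allowed to be negative
#'     (see \code{\link{subtract_tracks}}).}
#' }
#'
#' @param values named list of numeric vectors, one per chromosome, each of
#'   length \code{n_bins(genome)} for that chromosome; or a single numeric
#'   vector if the genome has one chromosome.
#' @param genome a \code{\link{genome_model}}.
#' @param label free-text sample tag (age/genotype/replicate).
#' @param units one of \code{"raw"}, \code{"scaled"}, \code{"ratio"},
#'   \code{"difference"}.
#' @return An object of class \code{coverage_track}.
#' @export
coverage_track <- function(values, genome,
                           label = "track",
                           units = c("raw", "scaled", "ratio", "difference")) {
  stopifnot(inherits(genome, "genome_model"))
  units <- match.arg(units)
  if (is.numeric(values)) {
    if (length(genome$chrom_names) != 1L)
      stop("bare numeric values only allowed for single-chromosome genomes")
    values <- stats::setNames(list(values), genome$chrom_names)
  }
  if (!is.list(values) || !setequal(names(values), genome$chrom_names))
    stop("values must be a list named by the genome's chromosomes")
  values <- values[genome$chrom_names]
  nb <- n_bins(genome)
  for (i in seq_along(values)) {
    v <- as.numeric(values[[i]])
    if (length(v) != nb[i])
      stop(sprintf("chromosome '%s': expected %d bins, got %d",
                   genome$chrom_names[i], nb[i], length(v)))
    if (any(!is.finite(v)))
      stop(sprintf("chromosome '%s': non-finite bin values",
                   genome$chrom_names[i]))
    if (units != "difference" && any(v < 0))
      stop(sprintf("chromosome '%s': negative values in a '%s' track",
                   genome$chrom_names[i], units))
    values[[i]] <- v
  }
  structure(
    list(genome = genome, values = values, label = label, units = units),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> '%s' [%s], %d chromosome(s), %d bins, total mass %.4g\n",
              x$label, x$units, length(x$values),
              sum(lengths(x$values)), track_mass(x)))
  invisible(x)
}

#' Total signal mass of a track
#'
#' Sum over all bins of bin value times bin width in base pairs.  For raw
#' tracks whose bin value is a read count this is (reads x bin width); for
#' rasterized bedGraph input it equals the integral of the piecewise
#' constant signal over the genome.
#'
#' @param track a \code{coverage_track}.
#' @return numeric scalar.
#' @export
track_mass <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  tot <- 0
  for (chrom in track$genome$chrom_names)
    tot <- tot + sum(track$values[[chrom]] * bin_widths(track$genome, chrom))
  tot
}

# total of bin values (used as a read-count proxy for raw tracks)
track_sum <- function(track) sum(vapply(track$values, sum, numeric(1)))

# apply a function bin-wise over the chromosomes of one or two tracks
map_bins <- function(f, a, b = NULL) {
  out <- vector("list", length(a$values))
  names(out) <- names(a$values)
  for (chrom in names(a$values)) {
    out[[chrom]] <- if (is.null(b)) f(a$values[[chrom]])
                    else f(a$values[[chrom]], b$values[[chrom]])
  }
  out
}
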