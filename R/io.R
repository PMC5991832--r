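#' Read a bedGraph file onto a fixed-bin genome
#'
#' Rasterizes the piecewise-constant bedGraph signal onto the genome's fixed
#' bins.  When a bin's bases are covered by intervals with different values
#' the bin receives the length-weighted per-base mean; uncovered bases
#' contribute 0.  Intervals are 0-based half-open as the format prescribes.
#'
#' @param path path to a 4-column bedGraph file (track/comment lines are
#'   skipped).
#' @param genome a \code{\link{genome_model}}.
#' @param label sample tag for the resulting track.
#' @param units units flag for the resulting track, default \code{"raw"}.
#' @return A \code{\link{coverage_track}}.
#' @seealso \code{\link{write_bedgraph}}
#' @export
read_bedgraph <- function(path, genome, label = basename(path),
                          units = "raw") {
  stopifnot(inherits(genome, "genome_model"))
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  nb <- stats::setNames(n_bins(genome), genome$chrom_names)
  vals <- lapply(genome$chrom_names,
                 function(ch) numeric(nb[[ch]]))
  names(vals) <- genome$chrom_names
  if (length(lines) == 0L)
    return(coverage_track(vals, genome, label = label, units = units))

  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop(sprintf("bedGraph format error at line %d: fewer than 4 columns",
                 which(nf < 4L)[1]))
  rec <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L))),
    end   = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L))),
    value = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L))),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(rec$start) | is.na(rec$end) | is.na(rec$value))
  if (length(bad))
    stop(sprintf("bedGraph format error at line %d: non-numeric field", bad[1]))
  unknown <- setdiff(unique(rec$chrom), genome$chrom_names)
  if (length(unknown))
    stop(sprintf("bedGraph format error: unknown chromosome '%s'", unknown[1]))
  if (any(rec$start < 0) || any(rec$start >= rec$end))
    stop("bedGraph format error: require 0 <= start < end")
  over <- rec$end > genome$chrom_lengths[rec$chrom]
  if (any(over))
    stop(sprintf("bedGraph format error: interval beyond chromosome end (%s)",
                 rec$chrom[which(over)[1]]))

  B <- genome$bin_size
  for (ch in unique(rec$chrom)) {
    r <- rec[rec$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)]))
      stop(sprintf("bedGraph format error: overlapping intervals on %s", ch))
    b0 <- r$start %/% B
    b1 <- (r$end - 1) %/% B
    nper <- b1 - b0 + 1
    bin <- rep(b0, nper) + sequence(nper) - 1
    s <- rep(r$start, nper)
    e <- rep(r$end, nper)
    v <- rep(r$value, nper)
    w <- bin_widths(genome, ch)
    ovl <- pmin(e, bin * B + B) - pmax(s, bin * B)
    # weight is exactly 1 for fully covered bins, keeping round trips
    # bit-exact; partial coverage contributes its per-base fraction
    contrib <- rowsum(v * (ovl / w[bin + 1]), bin)
    idx <- as.numeric(rownames(contrib)) + 1
    vals[[ch]][idx] <- vals[[ch]][idx] + contrib[, 1L]
  }
  coverage_track(vals, genome, label = label, units = units)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-valued bins are run-length merged into single records.
#' Values are written with 17 significant digits so that
#' \code{read_bedgraph(write_bedgraph(t))} reproduces \code{t} bin-exactly.
#'
#' @param track a \code{\link{coverage_track}}.
#' @param path output file path.
#' @param drop_zero if \code{TRUE} (default) zero-valued runs are omitted;
#'   if \code{FALSE} they are written explicitly.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  stopifnot(inherits(track, "coverage_track"))
  genome <- track$genome
  B <- genome$bin_size
  out <- character(0)
  for (ch in genome$chrom_names) {
    v <- track$values[[ch]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts <- (ends_bin - r$lengths) * B
    ends <- pmin(ends_bin * B, genome$chrom_lengths[[ch]])
    keep <- if (drop_zero) r$values != 0 else rep(TRUE, length(r$values))
    if (any(keep))
      out <- c(out, sprintf("%s\t%.0f\t%.0f\t%.17g",
                            ch, starts[keep], ends[keep], r$values[keep]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Two dialects are supported.  \code{format = "bed"}: headerless BED6
#' (chrom, start, end, gene_id, score, strand) with 0-based half-open
#' coordinates, kept as-is.  \code{format = "tsv"}: a headered TSV with
#' columns \code{gene_id, chrom, start, end, strand} in the 1-based
#' inclusive convention common to GFF-derived tables; coordinates are
#' converted to 0-based half-open at this boundary (start-1, end unchanged)
#' so that a single convention holds everywhere downstream.
#'
#' @param path input file.
#' @param format \code{"bed"} (default) or \code{"tsv"}.
#' @return A data.frame of class \code{gene_annotation} with columns
#'   \code{gene_id, chrom, start, end, strand}, 0-based half-open.
#' @export
read_gene_table <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- utils::read.table(path, sep = "", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end",
                                          "gene_id", "score", "strand"))
    genes <- df[, c("gene_id", "chrom", "start", "end", "strand")]
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(df)))
      stop("gene TSV must have columns gene_id, chrom, start, end, strand")
    genes <- df[, need]
    genes$start <- genes$start - 1   # 1-based inclusive -> 0-based half-open
  }
  gene_annotation(genes)
}

#' Construct / validate a gene annotation table
#'
#' @param genes data.frame with columns \code{gene_id, chrom, start, end,
#'   strand}; coordinates 0-based half-open.
#' @param genome optional \code{\link{genome_model}}; when given, genes are
#'   checked to lie within chromosome bounds.
#' @return The validated data.frame, classed \code{gene_annotation}.
#' @export
gene_annotation <- function(genes, genome = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes)))
    stop("gene table must have columns gene_id, chrom, start, end, strand")
  genes <- as.data.frame(genes)[, need]
  bad <- which(!is.finite(genes$start) | !is.finite(genes$end) |
                 genes$start < 0 | genes$start >= genes$end)
  if (length(bad))
    stop(sprintf("gene table parse error at row %d: require 0 <= start < end",
                 bad[1]))
  if (anyDuplicated(genes$gene_id))
    stop(sprintf("duplicate gene_id '%s'",
                 genes$gene_id[anyDuplicated(genes$gene_id)]))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!is.null(genome)) {
    stopifnot(inherits(genome, "genome_model"))
    unknown <- setdiff(unique(genes$chrom), genome$chrom_names)
    if (length(unknown))
      stop(sprintf("gene on unknown chromosome '%s'", unknown[1]))
    if (any(genes$end > genome$chrom_lengths[genes$chrom]))
      stop("gene extends beyond chromosome end")
  }
  class(genes) <- c("gene_annotation", "data.frame")
  genes
}

#' Read an alignment summary table
#'
#' Expects a headered TSV with columns \code{sample_id, role,
#' reads_experimental, reads_spikein, total_reads}, read counts in millions.
#'
#' @param path input TSV.
#' @return Named list of \code{\link{alignment_summary}} objects, keyed by
#'   sample id.
#' @export
read_alignment_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "role", "reads_experimental", "reads_spikein",
            "total_reads")
  if (!all(need %in% names(df)))
    stop("alignment table must have columns ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    alignment_summary(df$sample_id[i], df$role[i],
                      reads_experimental_millions = df$reads_experimental[i],
                      reads_spikein_millions = df$reads_spikein[i],
                      total_reads_millions = df$total_reads[i]))
  names(out) <- df$sample_id
  out
}
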