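#' Metabolite intensity table
#'
#' Holds a metabolite-by-sample matrix of non-negative LC-MS intensities
#' with a group label (genotype/age) per sample.
#'
#' @param intensities numeric matrix, metabolites in rows (rownames = ids),
#'   samples in columns (colnames = sample ids); no negative values.
#' @param groups character/factor vector of group labels, one per sample.
#' @param normalized logical flag: has \code{\link{normalize_table}} been
#'   applied?
#' @return Object of class \code{metabolite_table}.
#' @export
metabolite_table <- function(intensities, groups, normalized = FALSE) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)))
    stop("intensity matrix needs metabolite ids as rownames")
  if (anyDuplicated(rownames(intensities)))
    stop("duplicate metabolite ids")
  if (ncol(intensities) != length(groups))
    stop("one group label per sample is required")
  if (!normalized && any(intensities < 0))
    stop("negative intensities")
  if (any(!is.finite(intensities)))
    stop("non-finite intensities")
  structure(
    list(intensities = intensities,
         groups = stats::setNames(as.character(groups),
                                  colnames(intensities)),
         normalized = normalized),
    class = "metabolite_table"
  )
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("<metabolite_table> %d metabolite(s) x %d sample(s)%s; groups: %s\n",
              nrow(x$intensities), ncol(x$intensities),
              if (x$normalized) " (normalized)" else "",
              paste(unique(x$groups), collapse = ", ")))
  invisible(x)
}

#' Read a metabolite table and its group map
#'
#' @param path TSV with a \code{metabolite_id} column and one column per
#'   sample.
#' @param group_path 2-column TSV (\code{sample_id}, \code{group}).
#' @return A \code{\link{metabolite_table}}.
#' @export
read_metabolite_table <- function(path, group_path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"metabolite_id" %in% names(df))
    stop("metabolite table must have a metabolite_id column")
  m <- as.matrix(df[, setdiff(names(df), "metabolite_id"), drop = FALSE])
  rownames(m) <- df$metabolite_id
  gm <- utils::read.table(group_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(gm)))
    stop("group map must have columns sample_id, group")
  miss <- setdiff(colnames(m), gm$sample_id)
  if (length(miss))
    stop(sprintf("sample '%s' has no group label", miss[1]))
  metabolite_table(m, gm$group[match(colnames(m), gm$sample_id)])
}

#' Read pathway definitions
#'
#' @param path 2-column TSV (\code{pathway_id}, \code{metabolite_id}).
#' @return Named list of character vectors of member metabolite ids.
#' @export
read_pathway_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "metabolite_id") %in% names(df)))
    stop("pathway table must have columns pathway_id, metabolite_id")
  split(df$metabolite_id, df$pathway_id)
}

# population (divisor-n) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Normalize one metabolite's intensities by the population SD
#'
#' Each value is divided by the population (divisor-n) standard deviation
#' of that metabolite across all samples, giving a column whose population
#' SD is exactly 1.  The values are not centered.
#'
#' @param column numeric vector of one metabolite's intensities across at
#'   least two samples.
#' @return Normalized numeric vector.
#' @examples
#' normalize_intensity(c(2, 4, 6))  # / sqrt(8/3)
#' @export
normalize_intensity <- function(column) {
  column <- as.numeric(column)
  if (length(column) < 2L) stop("need at least two samples")
  s <- sd_pop(column)
  if (s == 0)
    stop("degenerate metabolite: zero population standard deviation")
  column / s
}

#' Normalize a whole metabolite table
#'
#' Applies \code{\link{normalize_intensity}} metabolite-wise.  Metabolites
#' with zero population SD (constant across samples) cannot be normalized;
#' they are flagged with a warning and excluded from the result.
#'
#' @param table a raw \code{\link{metabolite_table}}.
#' @return A normalized \code{metabolite_table}; excluded metabolite ids
#'   are recorded in the \code{excluded} attribute.
#' @export
normalize_table <- function(table) {
  stopifnot(inherits(table, "metabolite_table"))
  if (table$normalized) stop("table is already normalized")
  sds <- apply(table$intensities, 1, sd_pop)
  degen <- sds == 0
  if (any(degen))
    warning(sprintf("excluding %d degenerate metabolite(s): %s",
                    sum(degen),
                    paste(rownames(table$intensities)[degen],
                          collapse = ", ")))
  out <- metabolite_table(table$intensities[!degen, , drop = FALSE] /
                            sds[!degen],
                          table$groups, normalized = TRUE)
  attr(out, "excluded") <- rownames(table$intensities)[degen]
  out
}

#' Pathway intensity score
#'
#' Sum of the detected member metabolites' normalized intensities per
#' sample, averaged within the requested group.  Members absent from the
#' table are skipped silently but reported in the \code{detected}
#' attribute (\code{k} of \code{m}).
#'
#' @param table a normalized \code{\link{metabolite_table}}.
#' @param members character vector of the pathway's metabolite ids.
#' @param group group label to average over.
#' @return Numeric pathway intensity with attribute
#'   \code{detected = c(k, m)}.
#' @export
pathway_intensity <- function(table, members, group) {
  stopifnot(inherits(table, "metabolite_table"))
  if (!table$normalized)
    stop("pathway_intensity expects a normalized table (see normalize_table)")
  if (length(members) == 0L) stop("empty pathway definition")
  if (!group %in% table$groups)
    stop(sprintf("unknown group '%s'", group))
  present <- intersect(members, rownames(table$intensities))
  if (length(present) == 0L)
    stop("no pathway member detected in the table")
  cols <- table$groups == group
  per_sample <- colSums(table$intensities[present, cols, drop = FALSE])
  out <- mean(per_sample)
  attr(out, "detected") <- c(k = length(present), m = length(members))
  out
}

#' Median-based fold change per metabolite
#'
#' For each metabolite, the ratio of the group medians:
#' \code{median(group_b) / median(group_a)}.  Medians are robust to the
#' occasional outlier replicate typical of LC-MS intensities.
#'
#' @param table a \code{\link{metabolite_table}} (raw or normalized).
#' @param group_a reference group label (denominator).
#' @param group_b comparison group label (numerator).
#' @return Named numeric vector of fold changes; metabolites whose
#'   reference median is 0 get \code{NA} and are listed in the
#'   \code{undefined} attribute.
#' @export
median_fold_change <- function(table, group_a, group_b) {
  stopifnot(inherits(table, "metabolite_table"))
  for (g in c(group_a, group_b))
    if (!g %in% table$groups) stop(sprintf("unknown group '%s'", g))
  ma <- apply(table$intensities[, table$groups == group_a, drop = FALSE],
              1, stats::median)
  mb <- apply(table$intensities[, table$groups == group_b, drop = FALSE],
              1, stats::median)
  fc <- mb / ma
  undef <- ma == 0
  fc[undef] <- NA_real_
  attr(fc, "undefined") <- names(fc)[undef]
  fc
}

#' Isotopologue intensity table
#'
#' Long-format container for stable-isotope (13C) tracer data: for each
#' metabolite, the intensity of each isotopologue (M+0 ... M+k) in each
#' sample.
#'
#' @param df data.frame with columns \code{metabolite_id},
#'   \code{isotopologue} (integer >= 0: number of heavy carbons) and one
#'   numeric column per sample.
#' @param carbon_counts optional named integer vector of carbon counts per
#'   metabolite; when given, \code{isotopologue <= carbons} is enforced.
#' @return Object of class \code{isotopologue_table}.
#' @export
isotopologue_table <- function(df, carbon_counts = NULL) {
  if (!all(c("metabolite_id", "isotopologue") %in% names(df)))
    stop("need columns metabolite_id and isotopologue")
  samples <- setdiff(names(df), c("metabolite_id", "isotopologue"))
  if (length(samples) == 0L) stop("no sample columns")
  if (any(df$isotopologue < 0 | df$isotopologue != round(df$isotopologue)))
    stop("isotopologue indices must be non-negative integers")
  if (any(as.matrix(df[, samples]) < 0)) stop("negative intensities")
  if (anyDuplicated(df[, c("metabolite_id", "isotopologue")]))
    stop("duplicate (metabolite, isotopologue) rows")
  if (!is.null(carbon_counts)) {
    cc <- carbon_counts[df$metabolite_id]
    if (any(!is.na(cc) & df$isotopologue > cc))
      stop("isotopologue index exceeds the metabolite's carbon count")
  }
  structure(list(data = as.data.frame(df), samples = samples),
            class = "isotopologue_table")
}

#' Read an isotopologue table
#'
#' @param path TSV with columns \code{metabolite_id, isotopologue} and one
#'   column per sample.
#' @return An \code{\link{isotopologue_table}}.
#' @export
read_isotopologue_table <- function(path) {
  isotopologue_table(utils::read.table(path, sep = "\t", header = TRUE,
                                       stringsAsFactors = FALSE,
                                       check.names = FALSE))
}

#' Per-sample isotopologue sum for one metabolite
#'
#' Sums intensities over isotopologue indices — all of them, or only the
#' labeled species (M+1 and above) when \code{labeled_only = TRUE}.
#'
#' @param iso an \code{\link{isotopologue_table}}.
#' @param metabolite metabolite id.
#' @param labeled_only exclude M+0? Default \code{FALSE}.
#' @return Named numeric vector, one sum per sample.
#' @export
isotopologue_sum <- function(iso, metabolite, labeled_only = FALSE) {
  stopifnot(inherits(iso, "isotopologue_table"))
  d <- iso$data[iso$data$metabolite_id == metabolite, , drop = FALSE]
  if (nrow(d) == 0L) stop(sprintf("metabolite '%s' not present", metabolite))
  if (labeled_only) d <- d[d$isotopologue >= 1, , drop = FALSE]
  if (nrow(d) == 0L)
    return(stats::setNames(numeric(length(iso$samples)), iso$samples))
  colSums(as.matrix(d[, iso$samples, drop = FALSE]))
}

#' Fraction of a metabolite pool that is isotope-labeled
#'
#' \code{100 * labeled / total} per sample, where labeled is the M+1..M+k
#' sum.  Near-100\% labeling of the tracer substrate itself (e.g. dietary
#' glucose) indicates the pool has been fully replaced by the labeled diet.
#'
#' @param iso an \code{\link{isotopologue_table}}.
#' @param metabolite metabolite id.
#' @return Named numeric vector of percentages per sample.
#' @export
labeling_fraction <- function(iso, metabolite) {
  total <- isotopologue_sum(iso, metabolite, labeled_only = FALSE)
  if (any(total <= 0)) stop("zero total pool in at least one sample")
  100 * isotopologue_sum(iso, metabolite, labeled_only = TRUE) / total
}

#' Percent of a pathway's labeled flux remaining with age
#'
#' Summarizes tracer data into a single pathway-level retention figure.
#' For each pathway member, the labeled isotopologue sum is computed per
#' sample and reduced to the group median (consistent with the
#' median-based metabolite statistics used throughout); the pathway level
#' is the sum of those medians, and the statistic is
#' \code{100 * aged level / young level}.  No natural-abundance isotope
#' correction is applied, mirroring vendor-software extraction of
#' qualitative flux experiments.
#'
#' @param iso_young,iso_aged \code{\link{isotopologue_table}}s for the two
#'   conditions.
#' @param members character vector of pathway metabolite ids, present in
#'   both tables.
#' @param aggregate \code{"sum_of_medians"} (default) or
#'   \code{"median_of_sums"}: how per-metabolite labeled sums are folded
#'   into the pathway level.
#' @return Percent of the pathway's labeled level remaining in the aged
#'   condition.
#' @export
pathway_remaining_pct <- function(iso_young, iso_aged, members,
                                  aggregate = c("sum_of_medians",
                                                "median_of_sums")) {
  aggregate <- match.arg(aggregate)
  if (length(members) == 0L) stop("empty pathway definition")
  level <- function(iso) {
    per_met <- vapply(members, function(m)
      stats::median(isotopologue_sum(iso, m, labeled_only = TRUE)),
      numeric(1))
    if (aggregate == "sum_of_medians") sum(per_met)
    else {
      per_sample <- Reduce(`+`, lapply(members, isotopologue_sum,
                                       iso = iso, labeled_only = TRUE))
      stats::median(per_sample)
    }
  }
  young <- level(iso_young)
  if (young <= 0) stop("young pathway level is zero")
  100 * level(iso_aged) / young
}
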