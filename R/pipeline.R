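#' Joint bootstrap of peak-gene vs inter-peak-gene selectivity
#'
#' Resamples the two gene sets jointly: each draw takes
#' \code{subsample_n} values with replacement from each set and records the
#' selectivity \code{100 * (mean_peak / mean_interpeak - 1)} of the draw.
#' The percentile interval of those draws is the bootstrap CI of the
#' selectivity statistic.
#'
#' @param peak_values,interpeak_values per-gene signal (or per-gene
#'   late-onset gain) of the two sets.
#' @param draws,subsample_n,seed as in \code{\link{bootstrap_mean}}.
#' @return List with \code{point} (full-set selectivity), \code{ci_low},
#'   \code{ci_high}, \code{boot}.
#' @export
bootstrap_selectivity <- function(peak_values, interpeak_values,
                                  draws = 10000, subsample_n = 500,
                                  seed = 1L) {
  pk <- as.numeric(peak_values); ik <- as.numeric(interpeak_values)
  if (!length(pk) || !length(ik)) stop("both gene sets must be non-empty")
  boot <- with_seed(seed, {
    ip <- sample.int(length(pk), draws * subsample_n, replace = TRUE)
    ii <- sample.int(length(ik), draws * subsample_n, replace = TRUE)
    mp <- .colMeans(pk[ip], subsample_n, draws)
    mi <- .colMeans(ik[ii], subsample_n, draws)
    100 * (mp / mi - 1)
  })
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  list(point = 100 * (mean(pk) / mean(ik) - 1),
       ci_low = ci[1], ci_high = ci[2], boot = boot)
}

# mean of a list of same-genome tracks, preserving units
mean_tracks <- function(tracks) {
  g <- tracks[[1]]$genome
  vals <- lapply(g$chrom_names, function(ch)
    Reduce(`+`, lapply(tracks, function(t) t$values[[ch]])) / length(tracks))
  names(vals) <- g$chrom_names
  coverage_track(vals, g, label = "replicate mean",
                 units = tracks[[1]]$units)
}

#' Run the full drift pipeline on a simulated (or assembled) experiment
#'
#' Executes the published analysis end to end: per-replicate spike-in
#' scale factors and reference-adjusted tracks; IP/input ratio tracks and
#' broad-domain peak calling per baseline replicate; replicate
#' reconciliation; gene partition; per-age gene-body signal from the
#' replicate-mean scaled tracks; late-onset (older minus baseline)
#' difference tracks; and bootstrap drift statistics.
#'
#' @param sim an \code{\link{epigenome_sim}} (or an equivalently shaped
#'   list built from real data).
#' @param pseudocount RPM pseudocount for ratio tracks, default 1.
#' @param ratio_threshold,min_span,merge_dist peak-calling parameters (see
#'   \code{\link{call_peaks}}).
#' @param draws,subsample_n bootstrap parameters, defaults 10000 and 500.
#' @param seed master seed for all resampling; per-operation seeds are
#'   derived deterministically from it.
#' @param log2,offset summarize gene signal on the log2 scale? Default
#'   linear.
#' @return List of class \code{drift_report}: \code{scale_factors},
#'   \code{peaks} (reconciled \code{peak_set}), \code{partition},
#'   \code{signal} (gene-by-age data.frame), \code{set_means},
#'   \code{boot} (per age and gene set \code{\link{bootstrap_mean}}
#'   results), \code{selectivity} (baseline and per-older-age late-onset
#'   \code{\link{bootstrap_selectivity}} results), and \code{drift}
#'   (per-older-age \code{\link{drift_summary}} objects).
#' @export
drift_pipeline <- function(sim, pseudocount = 1,
                           ratio_threshold = 2, min_span = 3000,
                           merge_dist = 5000,
                           draws = 10000, subsample_n = 500,
                           seed = 1L, log2 = FALSE, offset = 1) {
  age_names <- names(sim$tracks)
  baseline <- age_names[1]

  # scale factors + replicate-mean reference-adjusted track per age
  sfs <- list(); scaled <- list()
  for (a in age_names) {
    reps <- seq_along(sim$tracks[[a]]$ip)
    sf_a <- lapply(reps, function(r)
      compute_scale_factor(sim$summaries[[a]][[r]]$ip,
                           sim$summaries[[a]][[r]]$input))
    sc_a <- lapply(reps, function(r)
      scale_track(sim$tracks[[a]]$ip[[r]], sf_a[[r]]))
    sfs[[a]] <- sf_a
    scaled[[a]] <- mean_tracks(sc_a)
  }

  # peaks from the baseline age, reconciled across replicates
  peaksets <- lapply(seq_along(sim$tracks[[baseline]]$ip), function(r) {
    su <- sim$summaries[[baseline]][[r]]
    rt <- ratio_track(sim$tracks[[baseline]]$ip[[r]],
                      sim$tracks[[baseline]]$input[[r]],
                      pseudocount = pseudocount,
                      ip_total_millions = su$ip$reads_experimental_millions,
                      input_total_millions =
                        su$input$reads_experimental_millions)
    call_peaks(rt, ratio_threshold = ratio_threshold,
               min_span = min_span, merge_dist = merge_dist)
  })
  common <- merge_replicate_peaks(peaksets)
  part <- partition_genes(sim$genes, common)

  sig <- gene_signal_table(scaled, sim$genes, log2 = log2, offset = offset)
  pk_idx <- rownames(sig) %in% part$peak_genes

  set_means <- data.frame(
    age = age_names,
    peak_mean = vapply(sig[pk_idx, , drop = FALSE], mean, numeric(1)),
    interpeak_mean = vapply(sig[!pk_idx, , drop = FALSE], mean, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  boot <- list(); selectivity <- list(); drift <- list()
  for (a in age_names) {
    boot[[a]] <- list(
      peak = bootstrap_mean(sig[pk_idx, a], draws, subsample_n,
                            seed = derive_seed(seed, paste0("peak_", a))),
      interpeak = bootstrap_mean(sig[!pk_idx, a], draws, subsample_n,
                                 seed = derive_seed(seed,
                                                    paste0("inter_", a))))
  }
  selectivity$baseline <- bootstrap_selectivity(
    sig[pk_idx, baseline], sig[!pk_idx, baseline],
    draws, subsample_n, seed = derive_seed(seed, "sel_baseline"))
  for (a in age_names[-1]) {
    diff_tr <- subtract_tracks(scaled[[a]], scaled[[baseline]])
    gains <- gene_body_signal(diff_tr, sim$genes)
    selectivity[[paste0("lateonset_", a)]] <- bootstrap_selectivity(
      gains[pk_idx], gains[!pk_idx],
      draws, subsample_n, seed = derive_seed(seed, paste0("sel_", a)))
    drift[[a]] <- drift_summary(
      peak_younger = set_means$peak_mean[set_means$age == baseline],
      peak_older = set_means$peak_mean[set_means$age == a],
      interpeak_younger =
        set_means$interpeak_mean[set_means$age == baseline],
      interpeak_older = set_means$interpeak_mean[set_means$age == a],
      labels = c(baseline, a))
  }

  structure(
    list(scale_factors = sfs, peaks = common, partition = part,
         signal = sig, set_means = set_means, boot = boot,
         selectivity = selectivity, drift = drift,
         params = list(pseudocount = pseudocount,
                       ratio_threshold = ratio_threshold,
                       min_span = min_span, merge_dist = merge_dist,
                       draws = draws, subsample_n = subsample_n,
                       seed = seed, log2 = log2)),
    class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("<drift_report> %d age(s); %d reproducible peak region(s) covering %.3g Mb\n",
              nrow(x$set_means), nrow(x$peaks),
              peak_coverage_bp(x$peaks) / 1e6))
  cat(sprintf("  %d peak gene(s) / %d inter-peak gene(s)\n",
              length(x$partition$peak_genes),
              length(x$partition$interpeak_genes)))
  print(x$set_means)
  sb <- x$selectivity$baseline
  cat(sprintf("  baseline selectivity %.1f%% [%.1f, %.1f]\n",
              sb$point, sb$ci_low, sb$ci_high))
  for (nm in setdiff(names(x$selectivity), "baseline")) {
    s <- x$selectivity[[nm]]
    cat(sprintf("  %s selectivity %.1f%% [%.1f, %.1f]\n",
                sub("lateonset_", "late-onset gain to ", nm),
                s$point, s$ci_low, s$ci_high))
  }
  invisible(x)
}
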