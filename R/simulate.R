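#' Configuration for the synthetic epigenome generator
#'
#' States the world the generator emulates: a small multi-chromosome genome
#' carrying broad enriched domains of a repressive mark over a low
#' inter-domain baseline; an age series in which the mark gains signal
#' globally while the \emph{selectivity} of that gain for the domains
#' decays (epigenetic drift); a fixed fraction of exogenous spike-in
#' chromatin; and Poisson sequencing noise.
#'
#' The per-base expected signal at age \eqn{t} is
#' \deqn{\mu_t(x) = baseline + enrichment \cdot 1_{dom}(x)
#'   + gain_t \cdot [ s_t / \phi \; if \; x \in dom;\;
#'                    (1 - s_t)/(1 - \phi) \; otherwise ]}
#' where \eqn{\phi} is the realized fraction of the genome inside domains.
#' The allocation \eqn{s_t \in [0,1]} sends a fraction \eqn{s_t} of the
#' gained mass into the domains: \eqn{s_t = 1} concentrates all late-onset
#' gain at pre-existing domains (no drift), while \eqn{s_t = \phi} spreads
#' it uniformly per base (complete drift, late-onset selectivity 0).
#'
#' Defaults state a desk-scale aging regime that mirrors the published fly
#' numbers: inter-peak baseline 1 signal unit, domain enrichment +3
#' (baseline selectivity about 300\%), per-base gains of 0.36 and 0.48
#' signal units at the two older ages (the printed net gains of inter-peak
#' genes at 15d/30d relative to a baseline near 1), allocations chosen so
#' the late-onset gain is only about 9\% more concentrated at domains, and
#' a 5\% spike-in fraction.
#'
#' @param chrom_lengths named vector of chromosome lengths (default 2
#'   chromosomes of 2 Mb).
#' @param bin_size bin width in bp, default 100 (tests' speed setting; real
#'   tracks commonly use 10).
#' @param n_domains number of planted domains, default 8.
#' @param domain_span_bp length-2 range of domain spans, default 20-50 kb.
#' @param baseline_rate inter-domain signal level per base, default 1.
#' @param domain_enrichment added signal level inside domains, default 3.
#' @param ages data.frame with columns \code{age} (label), \code{gain}
#'   (per-base mean signal gained relative to the first age) and
#'   \code{selectivity} (allocation \eqn{s_t}; ignored where gain = 0).
#'   Default: 3d/15d/30d with gains 0, 0.36, 0.48 and allocations targeting
#'   about 9\% late-onset selectivity.
#' @param spikein_fraction true fraction of spike-in chromatin, default
#'   0.05.
#' @param reads_per_sample experimental-genome mapped reads per library,
#'   default 1e6.
#' @param replicates biological replicates per age, default 2.
#' @param n_genes number of annotated genes tiled over the genome, default
#'   200.
#' @param gene_span_bp length-2 range of gene body lengths, default
#'   4-12 kb.
#' @param dispersion optional over-dispersion parameter; when \code{NULL}
#'   (default) bin counts are Poisson, otherwise negative binomial with
#'   variance \code{mu + dispersion * mu^2}.
#' @param seed integer master seed.
#' @return A list of class \code{epigenome_sim_config}.
#' @seealso \code{\link{simulate_epigenome}},
#'   \code{\link{gain_allocation}}
#' @export
epigenome_sim_config <- function(chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                                 bin_size = 100,
                                 n_domains = 8,
                                 domain_span_bp = c(20000, 50000),
                                 baseline_rate = 1,
                                 domain_enrichment = 3,
                                 ages = NULL,
                                 spikein_fraction = 0.05,
                                 reads_per_sample = 1e6,
                                 replicates = 2,
                                 n_genes = 200,
                                 gene_span_bp = c(4000, 12000),
                                 dispersion = NULL,
                                 seed = 1L) {
  if (spikein_fraction <= 0 || spikein_fraction >= 1)
    stop("spikein_fraction must be in (0, 1)")
  if (!is.null(dispersion) && dispersion <= 0)
    stop("dispersion must be positive (or NULL for Poisson noise)")
  if (baseline_rate <= 0 || domain_enrichment < 0)
    stop("rates must be positive")
  phi_expected <- n_domains * mean(domain_span_bp) / sum(chrom_lengths)
  if (phi_expected >= 0.5)
    stop("infeasible config: domains would cover half the genome or more")
  if (is.null(ages)) {
    s9 <- gain_allocation(9, phi_expected)
    ages <- data.frame(age = c("3d", "15d", "30d"),
                       gain = c(0, 0.36, 0.48),
                       selectivity = c(NA, s9, s9),
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("age", "gain", "selectivity") %in% names(ages)))
  s <- ages$selectivity[ages$gain > 0]
  if (any(!is.na(s) & (s < 0 | s > 1)))
    stop("selectivity allocations must lie in [0, 1]")
  structure(
    list(chrom_lengths = chrom_lengths, bin_size = bin_size,
         n_domains = n_domains, domain_span_bp = domain_span_bp,
         baseline_rate = baseline_rate,
         domain_enrichment = domain_enrichment,
         ages = ages, spikein_fraction = spikein_fraction,
         reads_per_sample = reads_per_sample, replicates = replicates,
         n_genes = n_genes, gene_span_bp = gene_span_bp,
         dispersion = dispersion, seed = as.integer(seed)),
    class = "epigenome_sim_config"
  )
}

#' Gain allocation for a target late-onset selectivity
#'
#' Inverts the generator's gain model: returns the allocation
#' \eqn{s \in [0,1]} for which the per-base gain inside domains exceeds the
#' per-base gain outside by \code{target_pct} percent, given the domain
#' fraction \eqn{\phi} of the genome.
#'
#' @param target_pct target late-onset selectivity in percent.
#' @param domain_fraction fraction of the genome inside domains.
#' @return Allocation \eqn{s}.
#' @export
gain_allocation <- function(target_pct, domain_fraction) {
  r <- 1 + target_pct / 100
  phi <- domain_fraction
  if (phi <= 0 || phi >= 1) stop("domain_fraction must be in (0, 1)")
  r * phi / (1 - phi + r * phi)
}

# late-onset selectivity (%) implied by allocation s and domain fraction phi
allocation_selectivity <- function(s, phi) {
  100 * ((s / phi) / ((1 - s) / (1 - phi)) - 1)
}

# non-overlapping domain placement: slot the chromosome and jitter
place_domains <- function(genome, n_domains, span_range) {
  lens <- genome$chrom_lengths
  per <- diff(c(0, round(cumsum(lens) / sum(lens) * n_domains)))
  out <- list()
  for (i in seq_along(lens)) {
    k <- per[i]
    if (k == 0) next
    L <- lens[[i]]
    slot <- L / k
    if (slot < span_range[2] + 20000)
      stop("infeasible config: domains too large/numerous for the genome")
    span <- round(stats::runif(k, span_range[1], span_range[2]))
    start <- round((seq_len(k) - 1) * slot +
                     stats::runif(k, 10000, slot - span - 10000))
    out[[names(lens)[i]]] <- data.frame(chrom = names(lens)[i],
                                        start = start, end = start + span,
                                        stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# Poisson (or, with over-dispersion, negative binomial) bin counts
draw_counts <- function(lambda, dispersion = NULL) {
  if (is.null(dispersion)) stats::rpois(length(lambda), lambda)
  else stats::rnbinom(length(lambda), mu = lambda, size = 1 / dispersion)
}

# per-bin fraction covered by domains, per chromosome
domain_bin_fraction <- function(genome, domains) {
  lapply(genome$chrom_names, function(ch) {
    w <- bin_widths(genome, ch)
    frac <- numeric(length(w))
    d <- domains[domains$chrom == ch, , drop = FALSE]
    B <- genome$bin_size
    for (j in seq_len(nrow(d))) {
      b0 <- d$start[j] %/% B
      b1 <- (d$end[j] - 1) %/% B
      bins <- b0:b1
      ovl <- pmin(d$end[j], bins * B + B) - pmax(d$start[j], bins * B)
      frac[bins + 1] <- frac[bins + 1] + ovl / w[bins + 1]
    }
    pmin(frac, 1)
  })
}

#' Simulate a spike-in ChIP experiment across an age series
#'
#' Draws Poisson read counts per bin for IP and input libraries at every
#' age and replicate of the configuration, generates the paired alignment
#' summaries so that the input's spike-in percentage \emph{d} and each IP's
#' spike-in read count \emph{c} reproduce the configured spike-in world,
#' tiles genes over the genome, and returns closed-form ground truth for
#' every downstream statistic.  Deterministic given \code{config$seed}.
#'
#' Spike-in reads are simulated at the read-count book-keeping level (the
#' scale factor consumes only counts), with the reference epigenome's
#' IP-able mass held constant across samples — the defining assumption of
#' spike-in normalization.
#'
#' @param config an \code{\link{epigenome_sim_config}}.
#' @return A list of class \code{epigenome_sim} with elements
#'   \code{genome}, \code{genes} (a \code{gene_annotation}),
#'   \code{tracks} (per age: lists \code{ip} and \code{input} of raw
#'   replicate \code{coverage_track}s), \code{summaries} (per age: lists of
#'   paired \code{alignment_summary} objects), and \code{truth} (planted
#'   domains, realized domain fraction, per-age true peak/inter-peak gene
#'   means and selectivities, true scale factors).
#' @export
simulate_epigenome <- function(config) {
  stopifnot(inherits(config, "epigenome_sim_config"))
  with_seed(config$seed, .simulate_epigenome_impl(config))
}

.simulate_epigenome_impl <- function(config) {
  genome <- genome_model(names(config$chrom_lengths),
                         config$chrom_lengths, config$bin_size)
  domains <- place_domains(genome, config$n_domains, config$domain_span_bp)
  dom_frac <- domain_bin_fraction(genome, domains)
  names(dom_frac) <- genome$chrom_names
  L_tot <- sum(genome$chrom_lengths)
  phi <- sum((domains$end - domains$start)) / L_tot

  # genes: uniform placement, lengths from the configured range
  glen <- round(stats::runif(config$n_genes, config$gene_span_bp[1],
                             config$gene_span_bp[2]))
  gchrom <- sample(genome$chrom_names, config$n_genes, replace = TRUE,
                   prob = genome$chrom_lengths / L_tot)
  gstart <- floor(stats::runif(config$n_genes) *
                    (genome$chrom_lengths[gchrom] - glen))
  genes <- gene_annotation(data.frame(
    gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
    chrom = gchrom, start = gstart, end = gstart + glen,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    stringsAsFactors = FALSE), genome)
  genes <- genes[order(match(genes$chrom, genome$chrom_names), genes$start), ]
  class(genes) <- c("gene_annotation", "data.frame")

  xi <- config$spikein_fraction
  # reference (spike-in) epigenome IP-able mass; the constant that makes
  # reference-adjusted bin values land on the mu scale at any depth
  G_ref <- 1e8 * (1 - xi) * genome$bin_size

  ages <- config$ages
  mu <- list(); tracks <- list(); summaries <- list(); sfs <- list()
  true_means <- data.frame()
  for (a in seq_len(nrow(ages))) {
    gain <- ages$gain[a]; s <- ages$selectivity[a]
    mu_a <- lapply(genome$chrom_names, function(ch) {
      f <- dom_frac[[ch]]
      base <- config$baseline_rate + config$domain_enrichment * f
      if (gain > 0)
        base <- base + gain * (s / phi * f + (1 - s) / (1 - phi) * (1 - f))
      base
    })
    names(mu_a) <- genome$chrom_names
    mu[[ages$age[a]]] <- mu_a
    G_t <- sum(mapply(function(v, ch) sum(v * bin_widths(genome, ch)),
                      mu_a, genome$chrom_names))
    p_ip <- lapply(genome$chrom_names, function(ch)
      mu_a[[ch]] * bin_widths(genome, ch) / G_t)
    names(p_ip) <- genome$chrom_names

    ip_reps <- list(); input_reps <- list(); sum_reps <- list()
    sf_reps <- list()
    for (r in seq_len(config$replicates)) {
      tag <- sprintf("%s_rep%d", ages$age[a], r)
      ip_vals <- lapply(p_ip, function(p)
        draw_counts(config$reads_per_sample * p, config$dispersion))
      input_vals <- lapply(genome$chrom_names, function(ch)
        draw_counts(config$reads_per_sample *
                      bin_widths(genome, ch) / L_tot,
                    config$dispersion))
      names(input_vals) <- genome$chrom_names
      ip_tr <- coverage_track(ip_vals, genome,
                              label = paste0("IP_", tag), units = "raw")
      in_tr <- coverage_track(input_vals, genome,
                              label = paste0("input_", tag), units = "raw")
      N_ip <- track_sum(ip_tr); N_in <- track_sum(in_tr)
      # spike-in bookkeeping (reads, then Poisson realization)
      c_exp <- N_ip * xi * G_ref / ((1 - xi) * G_t)
      spike_ip <- stats::rpois(1, c_exp)
      spike_in <- stats::rpois(1, N_in * xi / (1 - xi))
      ip_sum <- alignment_summary(paste0("IP_", tag), "IP",
                                  N_ip / 1e6, spike_ip / 1e6,
                                  (N_ip + spike_ip) / 1e6)
      in_sum <- alignment_summary(paste0("input_", tag), "input",
                                  N_in / 1e6, spike_in / 1e6,
                                  (N_in + spike_in) / 1e6)
      ip_reps[[r]] <- ip_tr; input_reps[[r]] <- in_tr
      sum_reps[[r]] <- list(ip = ip_sum, input = in_sum)
      sf_reps[[r]] <- compute_scale_factor(ip_sum, in_sum)
    }
    tracks[[ages$age[a]]] <- list(ip = ip_reps, input = input_reps)
    summaries[[ages$age[a]]] <- sum_reps
    sfs[[ages$age[a]]] <- sf_reps

    # closed-form truth: gene means over the noise-free expected track
    mu_track <- coverage_track(mu_a, genome,
                               label = paste0("mu_", ages$age[a]),
                               units = "scaled")
    gsig <- gene_body_signal(mu_track, genes)
    dompk <- peak_set(data.frame(chrom = domains$chrom,
                                 start = domains$start, end = domains$end,
                                 span_bp = domains$end - domains$start,
                                 mean_ratio = NA_real_), genome)
    part <- partition_genes(genes, dompk)
    true_means <- rbind(true_means, data.frame(
      age = ages$age[a],
      peak_mean = mean(gsig[part$peak_genes]),
      interpeak_mean = mean(gsig[part$interpeak_genes]),
      stringsAsFactors = FALSE))
  }

  base_row <- true_means[1, ]
  sel_base <- 100 * (true_means$peak_mean / true_means$interpeak_mean - 1)
  sel_late <- ifelse(
    ages$gain > 0,
    100 * ((true_means$peak_mean - base_row$peak_mean) /
             (true_means$interpeak_mean - base_row$interpeak_mean) - 1),
    NA_real_)
  truth <- list(
    domains = domains, domain_fraction = phi,
    gene_partition = partition_genes(
      genes, peak_set(data.frame(chrom = domains$chrom,
                                 start = domains$start, end = domains$end,
                                 span_bp = domains$end - domains$start,
                                 mean_ratio = NA_real_), genome)),
    true_means = cbind(true_means,
                       selectivity_pct_baseline = sel_base,
                       selectivity_pct_lateonset = sel_late),
    scale_factors = sfs,
    expected_signal = mu)
  structure(list(genome = genome, genes = genes, tracks = tracks,
                 summaries = summaries, truth = truth, config = config),
            class = "epigenome_sim")
}

#' @export
print.epigenome_sim <- function(x, ...) {
  cat(sprintf("<epigenome_sim> %d age(s) x %d replicate(s), %d gene(s), %d planted domain(s) (%.1f%% of %.3g Mb)\n",
              length(x$tracks), x$config$replicates, nrow(x$genes),
              nrow(x$truth$domains), 100 * x$truth$domain_fraction,
              sum(x$genome$chrom_lengths) / 1e6))
  invisible(x)
}

#' Simulate a pathway-structured metabolome with tracer data
#'
#' Generates log-normal metabolite intensities with multiplicative
#' pathway-wide group effects (the planted fold changes), plus matched
#' isotopologue tables in which a fixed fraction of each metabolite's pool
#' carries heavy carbons.  Emulates an aging series in which one pathway's
#' labeled flux declines, partially rescued in a mutant.
#'
#' @param n_metabolites total metabolites, default 30.
#' @param pathways named list of member metabolite ids; default: three
#'   pathways (\code{glycolysis}: met01-met06, \code{tca}: met07-met12,
#'   \code{other}: the rest).
#' @param group_effects named list (one element per group) of named
#'   numeric vectors (one multiplier per pathway).  Default groups
#'   \code{young}, \code{aged}, \code{aged_mutant} with glycolysis
#'   multipliers 1, 0.5 and 0.78 and all others 1 — an age-associated
#'   halving of glycolytic flux partially rescued in the mutant.
#' @param replicates biological replicates per group, default 8.
#' @param cv replicate coefficient of variation, default 0.1.
#' @param labeled_fraction fraction of each pool carrying at least one
#'   heavy carbon, default 0.93.
#' @param seed integer seed.
#' @return List of class \code{metabolome_sim}: \code{table} (a raw
#'   \code{\link{metabolite_table}}), \code{iso} (named list of
#'   \code{\link{isotopologue_table}}s, one per group), \code{pathways},
#'   and \code{truth} (planted effects, labeled fraction, carbon counts).
#' @export
simulate_metabolome <- function(n_metabolites = 30,
                                pathways = NULL,
                                group_effects = NULL,
                                replicates = 8,
                                cv = 0.1,
                                labeled_fraction = 0.93,
                                seed = 1L) {
  if (cv <= 0) stop("cv must be positive")
  if (labeled_fraction < 0 || labeled_fraction > 1)
    stop("labeled_fraction must be in [0, 1]")
  mets <- sprintf("met%02d", seq_len(n_metabolites))
  if (is.null(pathways)) {
    if (n_metabolites < 13) stop("default pathways need >= 13 metabolites")
    pathways <- list(glycolysis = mets[1:6], tca = mets[7:12],
                     other = mets[13:n_metabolites])
  }
  if (is.null(group_effects))
    group_effects <- list(
      young       = c(glycolysis = 1,    tca = 1, other = 1),
      aged        = c(glycolysis = 0.5,  tca = 1, other = 1),
      aged_mutant = c(glycolysis = 0.78, tca = 1, other = 1))
  path_of <- rep(NA_character_, n_metabolites)
  for (p in names(pathways))
    path_of[match(pathways[[p]], mets)] <- p

  with_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    base <- stats::rlnorm(n_metabolites, meanlog = log(1e5), sdlog = 1)
    carbons <- sample(3:6, n_metabolites, replace = TRUE)
    groups <- names(group_effects)
    cols <- list(); glab <- character(0)
    iso_tabs <- list()
    for (g in groups) {
      eff <- group_effects[[g]][path_of]
      eff[is.na(eff)] <- 1
      m <- matrix(0, n_metabolites, replicates)
      for (r in seq_len(replicates))
        m[, r] <- base * eff *
          stats::rlnorm(n_metabolites, -sdlog^2 / 2, sdlog)
      colnames(m) <- sprintf("%s_rep%d", g, seq_len(replicates))
      cols[[g]] <- m
      glab <- c(glab, rep(g, replicates))
      # isotopologue split: M+0 gets (1 - labeled_fraction); labeled mass
      # spread over M+1..M+k with weights proportional to the index
      rows <- list()
      for (i in seq_len(n_metabolites)) {
        k <- carbons[i]
        w <- c(1 - labeled_fraction,
               labeled_fraction * (1:k) / sum(1:k))
        rows[[i]] <- data.frame(metabolite_id = mets[i],
                                isotopologue = 0:k,
                                outer(w, m[i, ]),
                                check.names = FALSE,
                                stringsAsFactors = FALSE)
        names(rows[[i]])[-(1:2)] <- colnames(m)
      }
      iso_tabs[[g]] <- isotopologue_table(
        do.call(rbind, rows),
        carbon_counts = stats::setNames(carbons, mets))
    }
    intens <- do.call(cbind, cols)
    rownames(intens) <- mets
    structure(
      list(table = metabolite_table(intens, glab),
           iso = iso_tabs, pathways = pathways,
           truth = list(group_effects = group_effects,
                        labeled_fraction = labeled_fraction,
                        carbons = stats::setNames(carbons, mets),
                        base = stats::setNames(base, mets))),
      class = "metabolome_sim")
  })
}

#' Study-scale aging regime for drift recovery
#'
#' A configuration at realistic fly-epigenome scale: a 40 Mb
#' two-chromosome genome, 70 fixed-span 40 kb domains (domain fraction
#' exactly 7\%), about 15,000 genes of 1-3 kb (so roughly 1,000 peak genes
#' and 14,000 inter-peak genes), four biological replicates, deep
#' coverage, baseline selectivity about 300\% and a late-onset gain
#' allocated for about 9\% selectivity.  Gene-set sizes at
#' least comparable to the bootstrap resample size (n = 500) are what make
#' CI-based parameter recovery meaningful; the desk-scale default of
#' \code{\link{epigenome_sim_config}} is too small for that and is meant
#' for fast mechanical tests.
#'
#' @param seed integer master seed.
#' @param ages optional ages data.frame overriding the default 3d/30d
#'   pair (gains 0 and 0.48).
#' @return An \code{\link{epigenome_sim_config}}.
#' @export
drift_regime_config <- function(seed = 1L, ages = NULL) {
  phi <- 70 * 40000 / 4e7
  if (is.null(ages))
    ages <- data.frame(age = c("3d", "30d"), gain = c(0, 0.48),
                       selectivity = c(NA, gain_allocation(9, phi)),
                       stringsAsFactors = FALSE)
  epigenome_sim_config(
    chrom_lengths = c(chr2L = 2e7, chr3R = 2e7), bin_size = 100,
    n_domains = 70, domain_span_bp = c(40000, 40000),
    baseline_rate = 1, domain_enrichment = 3, ages = ages,
    spikein_fraction = 0.05, reads_per_sample = 2e7, replicates = 4,
    n_genes = 15000, gene_span_bp = c(1000, 3000), seed = seed)
}
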