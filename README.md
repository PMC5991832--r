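# epidrift

Quantifying epigenetic drift of broad repressive histone marks from
spike-in-normalized ChIP-seq, with companion metabolomics and
¹³C-tracer summaries.

## The problem

Repressive chromatin marks such as H3K27me3 rise globally with age in many
animals. Depth normalization (reads per million) erases exactly that kind of
global change, so quantitative comparisons across ages or genotypes require
an exogenous spike-in reference (ChIP-Rx): a fixed amount of foreign
chromatin added to every sample before immunoprecipitation. Beyond the
global trend, the scientifically interesting question is *where* the
age-acquired signal lands. If a young epigenome concentrates the mark in
broad peak domains but the signal gained during aging is spread almost
uniformly across the genome, the mark is *drifting* — losing targeting
fidelity — with downstream consequences for the genes (for example,
glycolytic genes) that sit outside the ancestral domains.

`epidrift` implements that analysis end to end for users with binned
coverage tracks (bedGraph), alignment read-count summaries and gene
annotations:

- **Spike-in scale factor.** With `c` the IP sample's spike-in-aligned
  reads (millions) and `d` the percentage of spike-in reads in the paired
  input, the reference signal `b = a·c/d` is constant across samples, so
  setting `b = 1` gives the scale factor `â = d/c`. Multiplying a raw
  track by `â` yields reference-adjusted signal; `â ×` (mapped reads in
  millions) is the sample's RRPM total.
- **Broad-domain peaks.** Maximal runs of bins with IP/input ratio ≥ 2,
  merged across gaps < 5 kb, kept when spanning ≥ 3 kb; reproducible
  regions are those overlapped by every replicate; genes are partitioned
  into peak genes and inter-peak genes by ≥ 1 bp overlap.
- **Bootstrap drift statistics.** Gene-body means (TSS to TTS) per age;
  percentile bootstrap (10,000 draws of n = 500) of gene-set means; net
  gain, relative gain (%), and selectivity (%) — the percent excess of
  peak-gene over inter-peak-gene signal — for both baseline signal and the
  late-onset signal obtained by subtracting the young track from an old
  one.
- **Metabolomics.** Per-metabolite normalization by the population
  standard deviation (`x/σ`), pathway intensity as the sum of detected
  members' normalized intensities, median-based fold changes,
  isotopologue sums, labeling fractions, and percent-pathway-remaining
  for ¹³C-tracer flux comparisons.
- **Synthetic data.** A generator with closed-form ground truth (planted
  domains, known gains and gain selectivity, known spike-in fraction,
  Poisson or negative-binomial noise) so every stage is testable without
  external data.

## Worked example

Reference bootstrap 95% CI bounds for gene-set means (fly muscle and head,
shipped in `inst/extdata/`) drive the drift statistics directly, using CI
midpoints as point estimates:

```r
library(epidrift)
ci <- reference_bootstrap_cis()
m <- function(tissue, cond, set)
  ci$mid[ci$tissue == tissue & ci$condition == cond & ci$gene_set == set]

drift_summary(peak_younger = m("muscle", "3d", "peak"),
              peak_older = m("muscle", "15d", "peak"),
              interpeak_younger = m("muscle", "3d", "interpeak"),
              interpeak_older = m("muscle", "15d", "interpeak"),
              labels = c("3d", "15d"))
#> <drift_summary> 3d -> 15d
#>   net gain: peak +0.334 (9.4%), inter-peak +0.325 (36.6%)
#>   selectivity: baseline about 299%, late-onset about 3%
```

Peak genes gained 9.4% signal from day 3 to day 15 while inter-peak genes
gained 36.6% — the relative gains of the aging series. Baseline signal is
about 299% more concentrated at peak genes; computed instead from the
late-onset CI midpoints, the age-acquired signal is only about 9% more
concentrated at peaks (`m("muscle", "lateonset_15d", ...)`), the drift
signature. Wild-type vs PRC2-mutant reductions follow the same pattern:

```r
signal_reduction_pct(m("head", "WT_30d", "interpeak"),
                     m("head", "PRC2mut_30d", "interpeak"))  # 38.9
signal_reduction_pct(m("head", "WT_30d", "peak"),
                     m("head", "PRC2mut_30d", "peak"))       # 18.3
```

The same statistics run end to end on synthetic data with known truth:

```r
sim <- simulate_epigenome(drift_regime_config(seed = 1))
report <- drift_pipeline(sim, seed = 1)
report
#> <drift_report> 2 age(s); 70 reproducible peak region(s) covering 2.8 Mb
#>   1172 peak gene(s) / 13828 inter-peak gene(s)
#>   age peak_mean interpeak_mean
#> 1  3d  3.860314      0.9998219
#> 2 30d  4.386460      1.4784902
#>   baseline selectivity 286.1% [281.7, 290.2]
#>   late-onset gain to 30d selectivity 9.9% [8.7, 11.1]
sim$truth$true_means   # planted values: baseline 286.4%, late-onset 8.6%
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the four
worked-example drift percentages from the reference CI midpoints, a full
synthetic drift-pipeline run at study scale (spike-in normalization →
peak calling → replicate reconciliation → gene partition → bootstrap
selectivities, compared with the generator's planted truth), and the
synthetic metabolome's pathway-remaining flux summaries, then writes its
JSON report to `--out`.

See the vignette in `vignettes/` for the model, its assumptions, the
numerical choices and the limitations of the synthetic world.
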