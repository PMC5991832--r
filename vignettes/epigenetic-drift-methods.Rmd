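---
title: "Quantifying epigenetic drift from spike-in ChIP-seq: models, choices and limits"
author: "epidrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epigenetic drift from spike-in ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidrift)
```

## 1. The measurement model

### Spike-in normalization

A ChIP-Rx experiment adds a constant amount of exogenous reference
chromatin (here, a mouse spike-in into fly samples) before
immunoprecipitation. Reads then split between the experimental genome and
the reference genome in proportion to the IP-able material of each. Write
`b` for the reference signal recovered from the spike-in, `c` for the
sample's spike-in-aligned reads in millions, and `d` for the percentage of
spike-in reads in the paired *input* library. Because the input samples
total chromatin, `d` estimates the (constant) spike-in mass fraction;
because `b` is the same physical material in every sample, `b = a·c/d` is
constant, so the per-sample normalization factor satisfies `a ∝ d/c` and,
fixing `b = 1`, is estimated as

> `â = d / c`.

`compute_scale_factor()` takes `c` from the IP sample and `d` from the
paired input, per these definitions. When the input has no spike-in reads
the pipeline fails loudly rather than imputing: the estimator mixes the
two libraries and a silently guessed `d` would corrupt every downstream
number. Multiplying a raw track by `â` gives reference-adjusted signal
(`scale_track()`); `â ×` raw mapped-read millions is the RRPM total
(`rrpm_total()`). The key property — checked as an invariant — is that
reference-adjusted signal is invariant to sequencing depth: doubling reads
doubles `c`, halves `â`, and leaves the product unchanged in expectation.

Inputs are displayed and used un-scaled; only IP tracks are
reference-adjusted. Whether browser-view inputs should themselves be
scaled is ambiguous in practice; scaling IP only is the conservative
choice and scale factors cancel in IP/input ratios anyway (an exact
algebraic identity, also under test).

### Tracks, bins and coordinates

All coverage lives on fixed-width bins over a declared genome
(`genome_model()`); 10 bp is the conventional production bin size, and the
synthetic tests use 100 bp for speed. All coordinates are 0-based
half-open (BED convention); 1-based inclusive gene tables are converted at
the I/O boundary (`read_gene_table(format = "tsv")`) so a single
convention holds internally. bedGraph rasterization length-weights
intervals onto bins (uncovered bases count as zero), and the writer
run-length merges equal bins and prints 17 significant digits so
read-after-write is bit-exact. Strand is stored but ignored by
summarization: gene-body signal of a chromatin mark is strand-agnostic.

### Ratio tracks and a resolved ambiguity

`ratio_track()` forms per-bin `(ip_rpm + p) / (input_rpm + p)` after
normalizing each track to reads per million. The RPM totals default to the
track's own bin sum but can be supplied explicitly (mapped experimental
reads only — spike-in reads are normalization cargo, not signal). The
pseudocount `p` (default 1 RPM-unit) prevents infinities in broad
low-coverage domains; no production value is prescribed anywhere, so it is
a documented, configurable default. Note one internal tension in the
contract this function implements: "IP = 2× input gives ratio 2" holds
only at equal sequencing depth, since internal depth normalization cancels
any global multiple. We keep the depth normalization (it is what makes
ratios comparable across samples) and expose explicit totals for the
equal-depth reading.

## 2. Broad-domain peaks and the gene partition

Detection is deliberately simple and citable: maximal runs of consecutive
bins with ratio ≥ 2 are candidates; candidates on a chromosome closer than
5 kb are merged, gap included; merged candidates spanning < 3 kb are
dropped. The span threshold is inclusive and evaluated *after* merging.
The per-bin threshold defines detection; a region's mean ratio is reported
but never filtered on. These text criteria are not identical to what a
histone-mode peak caller with a 3 kb window and 5 kb minimum distance
does internally; where the two diverge we follow the text criteria, which
are the definition a reader can check. No statistical significance model
(local Poisson background, blacklists) is attempted — that is out of
scope by design.

Replicate reconciliation (`merge_replicate_peaks()`) requires ≥ 1 bp of
overlap in *all* replicates by default — the strictest reading of
"reproducibly identified" — and reports the union extent of the
overlapping replicate regions; `min_replicates` relaxes this. Genes
overlap-partition into peak genes and inter-peak genes by ≥ 1 bp against
the reconciled set; under the half-open convention a gene ending exactly
where a peak starts does not overlap it. Interval algebra goes through
IRanges, the field-standard container; the caller itself is authored here
because its exact criteria are the point, and it is verified
region-for-region against a brute-force enumerator on a thousand random
tracks.

## 3. Bootstrap drift statistics

Per-gene signal is the exact per-base mean of the piecewise-constant
track over the gene body (TSS to TTS), computed by prefix sums; it is
linear in the track, so the late-onset signal of a gene equals its signal
in the difference track (`subtract_tracks()`, old minus young), which may
legitimately be negative.

Gene-set means are bootstrapped with the percentile method: 10,000 draws
with replacement of n = 500, 95% interval from the 2.5/97.5 percentiles.
Percentile (not BCa) is the minimal-assumption choice matching how such
intervals are conventionally reported. Whether to bootstrap linear or
log2 per-gene means is genuinely ambiguous in the field's figure
conventions (scatter axes log2, violin legends linear); the statistics
here are scale-agnostic — `bootstrap_mean()` operates on whatever column
it is given, and the pipeline default is linear with a `log2`/`offset`
option.

The drift statistics themselves are subtractions and ratios of the four
set means (`drift_summary()`):

* net gain per set: old − young;
* relative gain (%): 100 × net gain / young;
* selectivity (%): 100 × (peak − inter-peak) / inter-peak, computed for
  baseline signal and for the late-onset gains;
* reduction (%): 100 × (WT − mutant) / WT (`signal_reduction_pct()`).

Percentages are rounded only at report time (one decimal; "about"
selectivities to integers). The packaged reference intervals
(`reference_bootstrap_cis()`) reproduce four legend-style percentages at
printed precision from CI midpoints (9.4, ~9, 38.9, 18.3); others (e.g. a
13.3% or a 323% figure) do not follow exactly from midpoint arithmetic,
so only the four that do are asserted.

Two statistical caveats are worth stating. First, a resample size fixed
at n = 500 yields an interval for "the mean of 500 draws from this gene
set", which matches the estimator's own uncertainty only when the gene
set is at least comparable in size to 500; with a 15-gene set the interval
is far too narrow to cover anything. Recovery tests therefore run at
realistic gene counts (about 1,000 peak and 14,000 inter-peak genes).
Second, gene resampling cannot see noise shared by all genes of a sample
— most notably scale-factor estimation noise — so empirical coverage of
planted truths sits slightly below nominal. Both effects are properties of
the published procedure, reproduced faithfully rather than repaired.

`track_correlation()` aggregates bins to 1 kb windows (mean) and reports
genome-wide Pearson correlation, the conventional occupancy-similarity
summary.

## 4. Metabolomics and tracer flux

Normalized intensity is `x/σ` where `σ` is the *population* (divisor-n)
standard deviation of the metabolite across all samples — so each
normalized row has population SD exactly 1. Constant metabolites cannot
be normalized; they are flagged and excluded, never imputed. Pathway
intensity is the sum of *detected* members' normalized intensities per
sample, averaged within a group, with a "detected k of m" report; missing
members are skipped, not imputed. Fold changes use group medians, robust
to the occasional outlier replicate typical of LC-MS.

For ¹³C-tracer data, isotopologue sums (optionally excluding M+0) and
labeling fractions are plain bookkeeping. The pathway-level retention
statistic aggregates per-metabolite labeled sums to the group median and
sums medians across the pathway ("sum of medians"); the aggregation
behind "the pathway as a whole" is not uniquely determined by convention,
so the alternative ("median of sums") is available behind a flag and the
default is consistent with the median-based fold changes used elsewhere.
No natural-abundance isotope correction is applied — the qualitative
flux workflow this mirrors extracts isotopologues with vendor software
without stated correction — so absolute labeling fractions carry a small
upward bias chemically; comparisons between conditions are unaffected.

## 5. The synthetic world

`simulate_epigenome()` draws per-bin read counts from a Poisson model
(negative binomial behind a `dispersion` option) with per-base expected
signal

```
mu_t(x) = baseline + enrichment·1_dom(x)
          + gain_t · [ s_t/phi inside domains ; (1−s_t)/(1−phi) outside ]
```

where `phi` is the realized domain fraction of the genome. The
allocation `s_t` sends a fraction of the gained mass into domains:
`s_t = 1` is perfectly targeted gain, `s_t = phi` is per-base-uniform gain
(complete drift, selectivity 0); `gain_allocation()` inverts the model
for a target gain selectivity. Spike-in material is simulated at the
read-count bookkeeping level only — the scale factor consumes nothing
else — with the reference epigenome's IP-able mass held constant across
samples (the defining ChIP-Rx assumption). That constant also fixes the
output units so that reference-adjusted bin values land on the `mu`
scale; it inflates the nominal spike-in read counts of IP libraries,
which is cosmetic (every statistic is invariant to it). Ground truth —
planted domains, realized `phi`, per-age gene-set means and
selectivities from the noise-free expected track, and the realized scale
factors — is returned alongside the data.

Defaults state the world once. The desk-scale default (two 2 Mb
chromosomes, 100 bp bins, 8 domains of 20–50 kb, 200 genes, 1e6 reads,
2 replicates, 5% spike-in) mirrors the published aging regime's numbers:
baseline +3 enrichment over a baseline of 1 (≈300% baseline
selectivity), per-base gains of 0.36/0.48 at the older ages (the printed
inter-peak net gains against a baseline near 1), allocation targeting
≈9% late-onset selectivity. `drift_regime_config()` scales that world to
realistic fly-epigenome proportions — 40 Mb, 70 fixed 40 kb domains
(`phi` exactly 7%), ~15,000 small genes giving ≈1,100 peak genes, four
biological replicates, 2e7 reads — because CI-based parameter recovery is
only meaningful at study-like gene counts (Section 3).

What the generator does **not** emulate: read-level artifacts (fragment
lengths, GC and mappability bias, duplicates), inter-replicate biological
variability beyond counting noise, genes with structured placement
relative to domains, and a genuine second genome for the spike-in. A
green recovery test therefore establishes the correctness of the
estimators and their calibration under counting noise — not robustness to
alignment artifacts, which are upstream of this package's inputs.

`simulate_metabolome()` plants multiplicative pathway-wide group effects
on log-normal intensities (default: glycolysis halved with age, partially
rescued at 0.78 in a mutant; CV 10%; 8 replicates; labeled fraction 0.93
bookkept exactly in the isotopologue split).

## 6. Numerical and degenerate-input choices

* Rasterization weights are computed as overlap/width so fully covered
  bins reproduce values bit-exactly on round trip.
* Zero-valued runs are omitted from bedGraph output by default
  (`drop_zero = FALSE` writes them explicitly).
* Bootstrap RNG: one master seed; per-operation seeds derived
  deterministically by operation name, so every printed interval is
  reproducible; the caller's RNG state is restored.
* Degenerate inputs error rather than guess: zero spike-in in IP or
  input, double scaling, ratio-calling on non-ratio tracks, constant
  tracks in correlations, zero denominators in percentages, constant
  metabolites, zero pools, empty gene sets.
* Ties at thresholds: bin ratio exactly at the threshold counts as
  enriched; a region spanning exactly the minimum span is kept; a gap of
  exactly the merge distance is *not* merged.

## 7. Known limitations

* Peak criteria are the citable text rules; counts of regions from any
  specific historical dataset depend on raw data and exact caller
  internals and are not reproduced here.
* The bootstrap interval inherits the two caveats of Section 3
  (fixed-n resampling; blindness to sample-global noise).
* Metabolite tables are taken as identified and batch-normalized
  upstream; feature detection, RT alignment and enrichment p-values are
  out of scope.
* The CLI-style workflow is exposed as R functions and the acceptance
  script rather than a shell tool.
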