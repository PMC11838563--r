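---
title: "Allele-resolved replication timing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-resolved replication timing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelert)
```

## The problem

In an F1-hybrid mouse embryonic stem cell line (129 x castaneus), dense
diagnostic SNPs — roughly one every 150 bp — allow sequencing reads to be
assigned to their parental allele. When a reporter construct is inserted
into one allele, the untouched homolog in the same nuclei is a perfectly
matched internal control, which makes small changes in replication timing
(RT) detectable. `allelert` implements the computational side of such an
experiment: two-fraction (early/late S phase) Repli-Seq profiles per
allele, a domain-level "RT advance" statistic normalized to the natural
allelic baseline, per-window significance calls, nascent-RNA and reporter
barcode quantification, and the association between RT advance and
transcription rate across inducer doses or time points.

Because the package is exercised entirely on simulated data, it ships a
generator that emulates the experimental design with full ground truth.

## The generative model

The simulator assigns every position a latent RT value in $[-1, +1]$
(+1 = earliest). The landscape is built from domain annotations —
constitutive-early (level $+0.8$), constitutive-late ($-0.8$), and
"switching" domains that are late in the primary state and early in an
alternative state — with linear interpolation between domain midpoints, so
transition slopes provide a continuum of intermediate latent values, as in
real RT data. Two allele-asymmetric terms act on allele 1 inside a target
domain:

* a natural allelic offset (default $0.1$ latent units), emulating the
  129 allele's slightly earlier replication, which baseline normalization
  must remove; and
* an engineered advance $\Delta \ge 0$, the quantity the pipeline
  estimates.

Sequencing is modeled per 50-kb bin. The total read count is Poisson; a
read is allele-assignable with probability
$1 - e^{-\ell/s}$ ($\ell$ = read length, $s$ = mean SNP spacing; about
0.49 for 100-bp reads and 150-bp spacing), derived from Poisson SNP
coverage of a read rather than per-base simulation so it is testable in
closed form. Assignable reads split symmetrically between alleles, and
each allele's reads fall into the early fraction with probability
$p = \sigma(k \cdot \mathrm{rt})$ — a logistic link (default $k = 2$)
chosen as the simplest monotone map from a bounded latent to a
probability; $k$ controls how sharply timing separates the fractions.
Unassignable reads are emitted under their own label so that read totals
are conserved exactly. A useful consequence of the logistic link is that
the noiseless log2 early/late ratio is linear in the latent:
$\log_2(p/(1-p)) = k\,\mathrm{rt}/\ln 2$.

The default depth (62 reads per fraction per 50-kb bin) yields ~30
allele-assignable reads per fraction per bin, a deliberately modest,
realistic coverage for allele-split Repli-Seq; it is a free parameter.

Nascent transcription is Poisson in rate x gene length x library scale,
with optional "read-through" leaking a configurable fraction of a
reporter's rate into a downstream interval. Barcoded reporter reads embed
exact 16-nt barcodes at multinomial frequencies; all background sequence
is rejection-sampled against the barcode manifest, so exact-substring
counting has a deterministic truth table.

What the generator does **not** model: alignment artifacts, mappability,
PCR duplicates, GC bias, copy-number variation, or cell-cycle sorting
impurity. Passing tests therefore demonstrate correctness of the
estimators under clean sampling noise, not robustness to real-data
artifacts.

## The RT profiling path

1. **Binning** — each read is assigned to the bin containing its 5' start
   (0-based half-open, BED convention); 50-kb bins for statistics, 5-kb
   for display.
2. **Raw RT** — per allele and replicate, each fraction library is scaled
   to counts per million and
   $\mathrm{rt} = \log_2\frac{E_{cpm} + c}{L_{cpm} + c}$ with pseudocount
   $c = 0.1$ CPM (no value is standard; 0.1 CPM prevents infinities while
   leaving high-coverage bins essentially untouched). Bins with fewer
   than 10 raw reads (E+L) are masked.
3. **Quantile normalization** — every (allele, replicate) track is mapped
   rank-for-rank onto the pooled unmasked values of the wild-type
   reference, making samples comparable. Ties receive the average of the
   tied reference quantiles; with equal unmasked-bin counts the output
   multiset equals the reference multiset exactly.
4. **Display only: smoothing and scaling** — a centered 300-kb sliding
   mean over 5-kb bins, then a linear map putting the 99.5th percentile
   of |rt| at 3.0 (compressing the raw ~±7 dynamic range to ~±3). A
   normalization-state machine (`raw -> quantile_normalized -> smoothed
   -> scaled`, forward-only) enforces that scaled values can never enter
   the statistics path; the scaling constant is therefore free to be any
   monotone linear map. The sliding mean was chosen over loess because a
   span is the only parameter the procedure needs.

## The advance statistic

Per bin and replicate, the allelic delta is
$\delta_r(w) = \mathrm{rt}_{a1,r}(w) - \mathrm{rt}_{a2,r}(w)$, masked if
either allele is. The wild-type allelic baseline is the per-bin mean of
the WT deltas. The domain advance per mutant replicate is the mean over
unmasked domain bins of $\delta_r(w) - \mathrm{baseline}(w)$, and the
reported advance is the mean over replicates. The error bar is the min
and max over replicate-pair estimates — every pairing of a mutant
replicate experiment with a WT replicate experiment — which is the
spread actually attributable to replicate experiments and remains stable
with the 2–3 replicates typical of these designs.

Under the logistic link, an engineered latent advance $\Delta$ should
shift the noiseless statistic by $k\Delta/\ln 2$; at finite depth the
expectation is computed by exact enumeration over the Poisson-binomial
sampling model (`expected_log2_ratio()`, `expected_rt_advance()`), which
the tests use as an independent oracle.

**Known limitation.** Quantile normalization onto a fixed wild-type
reference compresses genuine differences: when ~10% of bins truly
advance, their ranks displace and the mapped values under-shoot by
roughly 5–15% of the true shift at the default design (2-Mb domain on a
20-Mb genome). The estimate is therefore mildly conservative; the
recovery tests budget for this.

## Per-window significance

RT changes per 50-kb window are tested by permutation. The effect size is
the raw difference `mean(mutant delta) - mean(WT delta)`; the test
statistic standardizes it by the replicate-based standard error plus a
moderation constant (the median SE across windows, as in SAM-style
moderated statistics). Standardization matters because sampling noise of
a log2 ratio is several-fold larger in extreme-RT windows than in
mid-range windows; without it, pooled nulls are anticonservative exactly
where the interesting domains are.

Replicate group labels are permuted, and the permuted statistics of
windows outside annotated switching domains are pooled into a
genome-wide null. With 2–3 replicates per group there are at most 20
distinct label splits, so within-window permutations alone cannot resolve
p-values below 0.1; pooling borrows strength genome-wide and is valid
because the standardized statistics of null windows share a common
distribution (the generator's uniform depth satisfies this; for real
data it is an assumption worth checking). Two-sided p-values use the
add-one rule, Benjamini–Hochberg controls FDR across windows, and
windows with `q < 0.05` are flagged. Calibration (false-positive rate at
most a few percent under the null across 10^4 windows) and near-uniform
null p-values are asserted by the test suite.

Domains are classified across two reference cell states by the sign of
their mean RT: constitutive early/late when the sign agrees,
developmental early/late (named by the second state) when it flips.

## Transcription and barcodes

Nascent reads are counted into BED6 intervals by their 5' end,
strand-aware (default reverse-stranded, matching directional nascent-RNA
protocols; configurable). RPM and RPKM follow the standard definitions.
Read-through is the downstream-to-reporter RPKM ratio, with the silent
reporter + active downstream case flagged as undefined rather than
returning a misleading 0 or infinity.

The differential test is deliberately simple and transparent: library-
size-normalized means, log2 fold change with pseudocount 1, a two-sided
exact Poisson rate test on summed counts with library totals as exposure,
and BH correction. It detects rate differences and is calibrated under
the null; it does not attempt negative-binomial dispersion shrinkage, so
it will be anticonservative for strongly overdispersed real replicates —
it is the re-specified stand-in for a full differential-expression
framework, not a replacement.

Barcode counting is exact 16-mer substring matching, forward-only by
default (reverse-complement scanning behind a flag); a read matching two
or more distinct barcodes is counted for none and logged, since
attribution is ambiguous.

## Association across conditions

Across an ordered condition series (dose or time), the package reports
the Spearman rank correlation between the domain advance and the target
gene's nascent RPKM — Spearman rather than Pearson because dose-response
curves that plateau are monotone but not linear. Plateau detection is
descriptive: the smallest covariate from which successive advances change
by less than 10% of the maximum advance. A withdrawal experiment is
flagged "reversible" when the withdrawn arm's replicate range overlaps
the never-induced baseline's and its count of significant domain windows
has returned to at most the baseline's.

## Numerical and design choices

* All coordinates are 0-based half-open; bins are keyed by start.
* Quantile normalization interpolates reference quantiles linearly when
  unmasked-bin counts differ; with equal counts it is an exact
  permutation of the reference values.
* Randomness flows from one root seed through named per-stage substreams;
  identical configuration and seed reproduce every output file byte for
  byte (the run manifest records md5 checksums and a configuration hash,
  with no timestamps).
* Degenerate inputs fail loudly: fewer than 2 unmasked bins for
  normalization, all-masked profiles for scaling, silent reporter with
  active downstream for read-through, fewer than 100 permutations, fewer
  than 3 conditions for association.
* Problem sizes in the test suite: a 20-Mb chromosome (400 statistics
  windows) for parameter recovery with 3 replicates; a 500-Mb chromosome
  (10^4 windows, 10^3 permutations) for null calibration; 100 simulation
  seeds for the reversibility property; these sizes give stable
  properties while keeping the suite quick to run.

## A worked example

```{r example, eval = FALSE}
cfg <- yaml::read_yaml(system.file("extdata", "demo_config.yaml",
                                   package = "allelert"))
cfg$outdir <- tempfile("allelert_demo")
res <- run_pipeline(cfg)
res$series          # per-condition advance and target expression
res$association$spearman
```

On the shipped demo configuration (a 10-Mb chromosome, 2-Mb inducible
domain, four inducer doses) the advance rises with dose and the
advance–expression Spearman correlation is 1.
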