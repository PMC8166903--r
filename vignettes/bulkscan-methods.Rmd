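---
title: "Methods: bulked-segregant QTL mapping and its calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked-segregant QTL mapping and its calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkscan)
```

## The mapping model

Bulked segregant analysis (BSA) maps a quantitative trait by comparing
pooled allele frequencies between the two phenotypic extremes of a
segregating panel. The design `bulkscan` targets is a recombinant inbred
line (RIL) panel from a two-parent cross (N2 × CB4856 in the motivating
system, scored for seam cell number): every line is a homozygous mosaic
of the two parental genomes, so a bulk of pooled lines has, at every
locus, a true CB4856 allele *count* between 0 and the number of pooled
lines, and pooled sequencing reads estimate the corresponding frequency.

For each bulk $b$ and SNP, the CB4856 frequency is the CB4856-supporting
read count over the total read count. Frequencies are averaged —
unweighted — over the SNPs inside non-overlapping 300-kb windows tiled
from position 1 of each chromosome, and rescaled to line-equivalents
$l = \bar l\, n_l$, $h = \bar h\, n_h$ with $n_l = 22$, $n_h = 24$ pooled
lines. The window statistic is

$$\mathrm{log\text{-}odds} =
  \log_{10}\!\left(\frac{h/(n_h - h)}{l/(n_l - l)}\right),$$

the $\log_{10}$ odds ratio of the high bulk's CB4856 line-equivalents
against the low bulk's: positive where the high bulk is CB4856-enriched,
negative where the low bulk is. Windowing assumes SNPs within 300 kb are
in near-complete linkage within a RIL (true for this cross's marker
density), so the window mean estimates the bulk's line fraction rather
than anything allele-specific.

### Null distribution and genome-wide thresholds

Under no association, each pooled line carries the CB4856 allele with
probability 1/2 independently, so $l \sim \mathrm{Binomial}(n_l, 1/2)$
and $h \sim \mathrm{Binomial}(n_h, 1/2)$ independently — one Bernoulli
trial per pooled line. `null_threshold_mc()` simulates this (default
$10^6$ trials) and takes the two-tailed empirical $\alpha = 0.05$
thresholds; `null_threshold_exact()` enumerates the full
$(n_l+1)(n_h+1)$-outcome pmf and returns the conservative thresholds
exactly (smallest value whose strict upper tail mass is $\le \alpha/2$,
mirrored below). A window is significant when its statistic exceeds a
threshold; runs of adjacent same-sign significant windows merge into one
QTL interval (`call_qtls()`).

Two readings of this null were open and we fixed them as follows.

* **Sampling unit.** The Bernoulli trials could model pooled *lines* or
  individual *reads*. We model lines: the statistic itself scales window
  frequencies by line counts, which is only coherent if the latent
  variable is a line count; the read-level reading would make the null
  depend on depth and would narrow it considerably. The choice makes the
  thresholds conservative with respect to read-sampling noise, which
  adds a small extra variance on top of the line-count signal.
* **"Genome-wide".** The threshold pair is the unadjusted two-tailed
  $\alpha$ quantile of the null distribution of a single window
  statistic, with no per-window multiplicity correction — this matches
  the procedure as practised. A Bonferroni-style correction can be had
  by passing `alpha / n_windows`, but it is not the default.

### Numerical choices

* **Boundary clamp.** The statistic is infinite at $l \in \{0, n_l\}$ or
  $h \in \{0, n_h\}$. Both observed and null statistics clamp $l$ and
  $h$ to 0.5 line-equivalents inside the boundary before evaluation;
  interior values are untouched, so the statistic equals the raw formula
  wherever that is finite. Under the null the boundary has probability
  $2^{-21}$ per tail, so thresholds are insensitive to the clamp value.
* **Quantile rule.** Monte-Carlo thresholds are the order statistics
  $\lceil \alpha/2 \cdot \mathrm{trials} \rceil$ from each tail, so the
  empirical mass strictly beyond each threshold never exceeds
  $\alpha/2$, matching the exact version's guarantee. For the 22/24
  design the null pmf's atoms near the 2.5% tail are far enough apart
  that $10^5$- and $10^6$-trial thresholds coincide with the exact atom
  ($\pm 0.544$, two-sided exact tail mass 0.0481).
* **Window anchor and empty windows.** Windows tile from the chromosome
  start; windows with no surviving SNP are omitted (not emitted as
  missing), and omitted windows never break a run during interval
  merging. A non-significant emitted window does break a run
  (configurable via `gap`).
* **Ties and degenerate input.** Peak ties inside an interval go to the
  leftmost window. Bulk selection breaks phenotype ties by ascending
  line id. An empty (header-only) VCF flows through the whole pipeline
  and yields empty tables, not errors; a zero total read count in a
  bulk at any SNP is an error, because it means the depth filter was
  skipped.

### Filters

SNPs are discarded when GQ < 40 in *either* bulk (the most conservative
reading of a jointly stated quality rule) or when read depth is below 22
in the low bulk or 24 in the high bulk — one read per pooled line.
Equality passes all cutoffs. Depth here is the per-sample sum of the AD
(allelic depth) entries, not the DP field: the AD sum is the denominator
of the frequency itself, so filtering on it is self-consistent; DP is
still written for interoperability. Records missing GQ are read as
GQ = 0 and therefore filtered, with a logged count.

### LOESS curves

`loess_curve()` (span 0.1, local linear, tricube weights — delegated to
`stats::loess` with `surface = "direct"`) smooths the per-SNP frequency
tracks for display. It is deliberately decoupled from inference: QTL
calls come only from the windowed statistic and thresholds.

## The simulator

`sim_bsa_cross()` generates the entire experiment so every stage of the
pipeline is testable without sequencing data. Its defaults *are* the
study conditions: 116 RILs, bulks of 22 and 24, 25× mean pooled depth,
four planted QTLs. Components:

* **Genome.** Six chromosomes of 15.1, 15.3, 13.8, 17.5, 20.9 and
  17.7 Mb (I, II, III, IV, V, X — approximate *C. elegans* sizes), 50 cM
  each, one diagnostic SNP per 10 kb. All configurable.
* **Meiosis.** No-interference crossover model: crossover count per
  chromosome Poisson with mean cM/100, breakpoints uniform on the
  genetic map projected to physical coordinates (uniform in bp under
  the default uniform map). The simplest standard model; nothing in the
  procedure depends on interference.
* **RIL derivation.** Each line descends from its own F1 heterozygote
  through `selfing_generations = 10` single-individual selfing meioses
  (the first producing the F2), leaving an expected fraction
  $(1/2)^{G}$ of the genome heterozygous; residual heterozygous
  intervals are then fixed by a fair coin per interval. The panel's real
  derivation involved marker-assisted steps; their genotypic footprint
  is reproduced instead by **forced regions** — tracts overwritten to one
  ancestry in every line (defaults: I:0–3 Mb, IV:0–5 Mb and V:5–15 Mb
  all N2, standing for an incompatibility element, the introgressed
  scored mutation, and the scoring transgene; coordinates are
  placeholders, configurable). Forced regions are invisible to mapping
  by construction: both bulks are flat N2 there.
* **Phenotype.** Line mean = 12 (baseline, arbitrary anchor) + effects
  of carried CB4856 QTL alleles (II +0.8, III +0.8, X +0.4, V −0.5
  cells) + the mean of 80 per-animal N(0, 1.5) noise draws. The three
  positive effects sum to the ~2-cell parental gap the cross exhibits;
  only that gap and the QTL signs are anchored, so the split across
  II/III/X and the V magnitude are package choices, fixed once.
* **Pooled reads.** Per SNP and bulk: depth ~ Poisson(25) (a standard
  dispersion-free choice for target coverage; only the mean is
  specified by the design), CB4856 read count ~ Binomial(depth,
  $q(1-e) + (1-q)e$) with $q$ the bulk's true CB4856 line fraction and
  base error $e = 0.001$ (Illumina-like Q30; a package choice). GQ is
  constant 60 with an optional low-GQ contamination fraction to
  exercise the quality filter.

What the simulator does **not** emulate: sequence-level reads and
alignment/calling artefacts (mapping bias, indel edge effects,
multi-mapping), depth overdispersion beyond Poisson, correlated
genotyping error along the genome, segregation distortion other than the
forced regions, and the marker-selection bookkeeping of the real
two-step crosses. Passing tests therefore certify the mapping arithmetic
and its calibration under the stated generative model — not robustness
to real-data artefacts upstream of the SNP table.

## Calibration properties and test scale

The suite verifies, at the study's own scale (116 lines, 22/24 bulks,
~10,000 SNPs, 336 windows; 10 seeds where an ensemble is needed):

* the achieved two-tailed level of the Monte-Carlo thresholds on fresh
  null draws is ≤ 0.05 and matches the exact tail mass within
  Monte-Carlo error ($10^6$ threshold trials, $10^5$ fresh draws);
* Monte-Carlo and exact thresholds agree (they coincide on the default
  design);
* the planted QTL architecture is recovered — at least three of four
  QTLs with correct signs including the negative-sign V QTL, peaks
  within 2 Mb — in at least eight of ten seeds;
* on a null genome (all effects zero) the per-window flag rate matches
  the exact tail mass within the ensemble's standard error;
* heterozygosity decay, filter arithmetic against a brute-force oracle,
  antisymmetry under bulk relabelling, and byte-identical reruns per
  seed.

## Known limitations

* **Windows are strongly dependent.** On a 50-cM chromosome, adjacent
  300-kb windows are ~2 cM apart on the RIL-expanded map, so their
  ancestry (hence their statistics) correlate at ~0.95+. The thresholds
  control the *per-window* false-flag rate, not the geometry of
  excursions: on a null genome a chance exceedance typically extends
  over many consecutive windows, and called intervals spanning 1–6 Mb
  arise with appreciable probability. Interval *length* therefore
  carries no significance; the peak window is the localisation signal,
  and single-window intervals deserve no more trust than their margin
  over the threshold.
* The per-window level is slightly anti-conservative in practice
  because read-sampling noise adds variance on top of the line-count
  null; at 25× over ~30 SNPs per window the inflation is at the percent
  level of the standard deviation and is absorbed by the thresholds'
  discreteness slack.
* Real-mode input must arrive polarised (ALT = CB4856 allele); the
  reader does not auto-detect polarity.
* The simulator's forced-region coordinates and QTL positions are
  placeholders at realistic magnitudes, not measured coordinates.
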