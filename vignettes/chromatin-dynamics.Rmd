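---
title: "Spike-in calibrated chromatin dynamics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in calibrated chromatin dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromexch)
```

chromexch analyses four related questions about chromatin in budding
yeast: has a mutation changed histone occupancy globally (spike-in
calibration), has it changed replication-independent histone exchange and
where along genes (Flag/Myc turnover scoring), how does signal distribute
relative to gene anchors (metagene profiling), and has chromatin
accessibility shifted (subnucleosomal ATAC classification). This vignette
explains each model, the parameters that matter, and the choices made
where conventions in the field genuinely diverge.

## Coordinates and coverage

All coordinates are 0-based half-open, matching BED and bedGraph. The TSS
of a `+` strand gene is `start`; of a `-` strand gene, `end - 1`.

Coverage assigns each fragment to the single bin containing its midpoint.
The alternative — spreading a fragment over every bin it overlaps — is
offered (`method = "overlap"`), but midpoint assignment is the default
and the tested convention because it conserves totals exactly (the sum of
all bins equals the number of fragments), which in turn makes the
rpm-conservation and depth-cancellation properties of downstream ratios
exact rather than approximate.

Defaults with units:

* `bin_width = 50` bp. Yeast genes are short (median ≈ 1.4 kb); 50 bp
  gives ≈ 20–100 bins per gene body, enough resolution for TSS-proximal
  structure without noisy bins at typical depths.
* Single-end reads are extended to `length = 150` bp (about one
  nucleosome plus linker) symmetrically about their midpoint before
  coverage. BED3 input carries no strand, so directional 3′ extension is
  not possible; symmetric extension keeps the midpoint — and therefore
  the binned coverage — unchanged, making the choice of extension length
  nearly inert under the midpoint convention.

## Spike-in calibration

Libraries prepared from a fixed-proportion mix of target (*S. cerevisiae*)
and spike-in (*S. pombe*) chromatin are calibrated by the enrichment
ratio, computed from whole-library mapped fragment counts:

$$E^{IP} = \frac{IP_{target}/input_{target}}{IP_{spike}/input_{spike}}$$

and the mutant-versus-wild-type scale factor defined by the proportion
$N \cdot c_{mut} : c_{wt} = E^{IP}_{mut} : E^{IP}_{wt}$, where $c$ are the
target-genome mapped counts of the two IP libraries; `compare_tracks()`
then computes $\log_2((N a_i + p)/(b_i + p))$ per bin with the mutant
scaled and the wild type unscaled (the "N : 1" convention).

Choices and rationale:

* $E^{IP}$ uses **raw whole-library counts**, not per-bin signal and not
  deduplicated counts: the defining equations are stated at library
  level, and any within-genome reweighting would re-introduce the
  composition dependence the spike-in exists to remove.
* **Pseudocount `p = 1` raw count per bin.** It bounds the log ratio on
  empty bins; at the depths where calibration is meaningful (hundreds of
  counts per bin) its bias is < 0.01 log2 units. Configurable.
* The cell-mixing ratio (default 5 : 1 target : spike) is experimental
  metadata: the calibration math never uses it, and the simulator records
  it purely as ground truth.
* Comparisons compose: a mutant-over-wild-type comparison of two
  per-genotype modification-over-H3 ratio tracks is just
  `compare_tracks()` applied to `compare_tracks()` outputs.

## Metagene conventions

`tss_anchored_matrix()` samples each gene 5′→3′ from its TSS on a common
distance grid (default `extent = 2000` bp, in track-width bins). Three
conventions are load-bearing:

* **Beyond-TES masking.** Every matrix entry at distance ≥ gene length is
  exactly 0 — short genes contribute zeros, not downstream intergenic
  signal. The masking is bitwise (`0`, not "small"), and it is the only
  truncation applied: the TSS and TES windows of a short gene may
  overlap, and both report the (masked) signal rather than being cut at
  the gene midpoint.
* **Bin-center sampling.** Column $j$ holds the track value at distance
  $(j - \tfrac12)\,\mathrm{bin\_width}$; a bin straddling the TES is
  zeroed when its *center* is beyond the TES, consistent with the
  midpoint coverage convention.
* **Fixed-distance anchoring.** Average profiles use two fixed-distance
  panels (one from the TSS, one ending at the TES) rather than rescaling
  gene bodies to a common length; with masking, the TSS panel is exactly
  the column-mean of the heatmap matrix, so heatmap and average plot can
  never disagree.

Row order is ascending gene length (the heatmap convention that makes the
TES mask a visible diagonal) or descending mean gene-body signal.

## Histone exchange (turnover)

The exchange assay induces a Flag-tagged histone and chases it against a
constitutive Myc-tagged one; more Flag relative to Myc means faster
replication-independent exchange. Two estimators are provided:

* **Track-based:** `log2((mean Flag + p)/(mean Myc + p))` over a region
  of rpm tracks (`pseudocount = 0.1` rpm), used per-gene for boxplots and
  per-bin (`turnover_track()`) for heatmaps — per-bin for display, per-
  gene for statistics, since a per-gene score from a per-bin average of
  logs would be biased low in noisy bins.
* **Count-based RPKM at gene centers:** fragments whose midpoints fall in
  the center window are counted and converted with
  RPKM = reads × 1e9 / (window length × total mapped). This is the
  default for the stratified center-of-gene comparison because it uses
  the printed formula directly and is independent of bin width.

The center window excludes `exclude_fraction = 0.25` of the gene length
per end. Exchange is dominated by promoter-proximal deposition;
excluding a quarter from each end removes the 5′ peak and 3′ effects for
genes of every length while keeping half the gene, and the fraction is
configurable because the analysis region is inherently schematic.

Gene-length clusters are `>2 kb`, `1–2 kb`, `0.5–1 kb`, with boundaries
left-open/right-closed (a 2000 bp gene is `1–2 kb`, since ">2 kb" reads
as strict) and genes ≤ 0.5 kb excluded from cluster analyses
(`unassigned`); cut points are configurable.

`group_compare()` is a two-sided Mann–Whitney rank-sum test. Below
`choose(n_a + n_b, n_a) = 1e5` it enumerates the exact permutation null of
the rank sum with average ranks — necessary because the classical exact
distribution is unavailable under ties — defining the two-sided p-value
as $P(|W - \mu| \ge |w_{obs} - \mu|)$ (the tied null need not be
symmetric). Larger samples use the standard normal approximation with tie
correction via `stats::wilcox.test()`.

## ATAC accessibility

Fragments strictly shorter than `cutoff = 100` bp — below a nucleosome
footprint — report accessible DNA. Fragment length is the interval span;
no Tn5 +4/−5 offset is applied. Per-gene log2 fold change uses the whole
transcribed region (not the center window), and the three-way
classification uses open intervals at ±`threshold` (default 0.2):
a gene at exactly ±0.2 is `steady`. Open intervals make
threshold-monotonicity clean (raising the threshold never shrinks the
steady class) and leave boundary behaviour explicit rather than
accidental.

## The synthetic-data generator

The generator emulates the *statistical structure* the pipeline assumes,
with recorded ground truth:

* **Genomes:** genes laid head-to-tail with 200 bp intergenic gaps over
  two chromosomes; lengths log-uniform on [600, 6000] bp (default) so all
  three length clusters are populated, or drawn equally per stratum
  (`law = "stratified"`) for balanced designs; a spike genome one fifth
  the gene count mirrors the 5 : 1 mixing design.
* **ChIP:** fixed-size multinomial sampling over genes of both genomes.
  IP weights are per-gene enrichment × length (enrichment log-normal,
  σ = 0.5, unless supplied); input weights are flat per bp; the mutant IP
  carries a global occupancy scale *s* on the target genome only, and
  spike rates never differ between conditions. Fixed-*n* sampling
  deliberately preserves the compositional distortion that real
  sequencing imposes — that distortion is precisely what the spike-in
  calibration corrects, and the scale-recovery test shows it does so
  exactly in expectation.
* **Turnover:** Myc is flat over genes; Flag density at offset $x$ from
  the TSS is $2^{b + t e^{-x/\lambda} + \delta}$ with baseline $b = 0$,
  TSS boost $t = 1$, decay $\lambda = 300$ bp, and $\delta$
  (`longgene_delta`) applied only to genes > 2 kb under the mutant
  condition. Counts are Poisson per 25 bp lattice site with *absolute*
  (per-cell) rates calibrated so the expected wild-type library is
  `n_fragments_per_sample`; analyses then normalize by that design depth.
  This models libraries sequenced to a calibrated common scale. Under
  fixed-size sampling the mutant's loss of long-gene signal would inflate
  short-gene densities by composition alone, and no normalization
  computed from the mutant library itself could remove it — the absolute-
  rate design is what makes "short-gene clusters unchanged" a true null.
* **ATAC:** a two-component length mixture — subnucleosomal, normal
  (60 ± 15 bp, floored at 20 bp) with weight `sub_frac = 0.35`, and
  nucleosomal (160 ± 20 bp, floored at 100 bp so the components cannot
  cross the classification cutoff). Subnucleosomal per-gene Poisson rates
  scale with gene length and, in the mutant, a per-gene accessibility
  multiplier; nucleosomal rates are length-only. Absolute rates with
  design-depth normalization, as for turnover.
* **Determinism:** every operation derives its own RNG stream from
  (seed, operation, condition, role) via a 32-bit FNV-1a hash, so adding
  a sample never perturbs an existing one and a fixed seed reproduces
  every fragment byte for byte.

What the generator does **not** model: GC or mappability bias, duplicate
reads, alignment error, nucleosome positioning, the galactose-induction
time course behind the exchange assay, or realistic intergenic signal.
Passing recovery tests therefore demonstrates that the estimators are
correct and well-calibrated under idealized sampling noise — not that
they are robust to the artifacts real libraries add.

## Problem sizes used by the tests

The recovery analyses are run at desk scale, chosen so that sampling
noise sits well inside each tolerance: spike-in scale recovery at
s ∈ {0.5, 1, 2} with 100 genes and 10⁶ fragments per library (median
log2 ratio within ±0.1 of log2 s); turnover recovery with 600 stratified
genes (200 per cluster) and an expected 150 fragments per gene per
library (cluster medians within ±0.2); ATAC recovery with 200 genes, 10%
designated at multiplier $2^{0.5}$, and ≈ 1500 subnucleosomal fragments
per gene, where the per-gene Poisson sd of the log2 fold change
(≈ 0.05–0.1 depending on length) is comfortably inside the ±0.2 steady
band.

## Limitations

* The calibration implements exactly the two library-level equations; no
  per-locus spike-in regression or ChIP-Rx-style variants.
* Metagene profiles are fixed-distance; gene bodies are not rescaled, so
  compartment-level comparisons across very different length
  distributions should use the length clusters instead.
* The count-based center RPKM and the track-based score answer slightly
  different questions at low depth (counts vs binned means); both are
  exposed, and the count-based path is the default for stratified
  comparisons.
* BAM input is out of scope; fragments enter as BED intervals.
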