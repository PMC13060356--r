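---
title: "Inferring ancestrally conserved recombination landscapes"
author: "ancestralRecomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ancestrally conserved recombination landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestralRecomb)
```

## The problem

Recombination is unevenly distributed along mammalian chromosomes: rates
tend to be elevated near the ends of long chromosomes, depressed toward
their middles, and uniformly high on short chromosomes. Parts of this
landscape appear to be evolutionarily stable — syntenic regions that have
remained in the lowest or highest recombination-rate classes across
distantly related placental mammals. We call these ancestrally
low-recombining regions (ALR) and ancestrally high-recombining regions
(AHR). This package implements the comparative pipeline that identifies
them from per-species recombination maps, projects them onto a
reconstructed ancestral karyotype, and quantifies two downstream
consequences: how many genes each lineage has retained in these regions,
and whether biological pathways are skewed toward the high- or
low-recombining class.

Recombination-rate estimation itself (e.g. from population resequencing),
ancestral karyotype reconstruction, synteny-block detection, orthology
inference and maximum-likelihood tree estimation are upstream of this
package; their outputs — bedGraph rate tracks, synteny TSVs, GFF3 gene
annotations, orthogroup tables, GMT gene sets, FASTA alignments and newick
trees — are its inputs.

## The procedure

Per species, the raw rate track is smoothed by **sliding-block averaging**
(2 Mb blocks placed every 50 kb; `slidingAverage()`), mapped onto fixed
**1.5 Mb analysis windows** (`makeWindows()`, `mapRatesToWindows()`), and
the windows are ranked genome-wide from highest to lowest rate and split
into four **quartile categories**, Q1 lowest (`assignQuartiles()`).
Data-free windows inside known recombination deserts (notably the middle
of the X chromosome) can be set to zero with `fillDesertZero()`; windows
without data are otherwise treated as missing and carry no category.

Collinear regions are then classified per species
(`classifyRegion()`): the low set is {Q1, Q2} — the extreme and the next
category above — and the high set {Q3, Q4}. A region containing only one
set takes that class; a mixture takes the class covering at least 50% of
its windows; an exact tie is ambiguous and yields no class. A region
becomes a conserved call when at least 3 of 4 species agree
(`consensusCall()`): low consensus is an ALR, high an AHR. Same-class
calls within 1 Mb are merged (`mergeCalls()`), and any residual ALR/AHR
overlap is cut at the midpoint of the overlapped interval, dropping fully
contained calls (`resolveOverlaps()`). `callConservedRegions()`
orchestrates this: maximal runs of reference windows in the low (or high)
set define candidate regions, which are lifted into every other species
through synteny and classified there.

Coordinates move between species, reference and ancestor by **linear
interpolation within syntenic fragments** (`projectCoordinate()`): a
position at a given fraction of its source fragment maps to the same
fraction of the destination fragment, reversed on inverted fragments,
rounded half-up to integer bp. `projectRegions()` clips regions to
fragments and reports inter-fragment gaps explicitly rather than dropping
them. The printed form of this interpolation formula in the source
literature is typeset ambiguously; the implementation follows the
linear-interpolation reading implied by the surrounding fragment
definitions, and the inverted-fragment extension is this package's own
convention, flagged in output provenance.

For gene-level analysis, unnamed LOC symbols are resolved through
orthogroups (`resolveLocSymbols()`): a LOC takes a proper symbol carried
by an anchor species (human, dog or mouse by default) or by at least two
species, with conflicts left unresolved. Genes take the majority quartile
of the windows they overlap, with exact ties resolved by a seeded uniform
choice (`assignGeneCategories()`); `retentionSummary()` reports, per
species, the fraction of ALR/AHR genes still in the corresponding
two-quartile sets, plus the genes remaining in the single extreme quartile
across all species. Pathway skew is a per-pathway 2×2 chi-squared test
(pathway vs rest × high vs low, Pearson statistic without continuity
correction) with Benjamini–Hochberg correction (`pathwaySkew()`).

The phylogenomic comparison steps are alignment-column filtering at
greater-than-10% missingness (a column at exactly 10% is kept), seeded
random subsampling of 100,000 columns, paired branch-length and
node-height comparison of trees fitted to the two region classes
(`compareTrees()`, matching branches by the taxon set they subtend), and
aggregation of per-base conservation scores over region coordinates
(`scoresInRegions()`, positive = conserved).

## The synthetic-data generator

Real inputs for this analysis are genome-scale and partly manual, so the
package ships a first-class simulator with planted ground truth
(`simConfig()`, `simulateStudy()`). Its default configuration is the
reference study condition used throughout the tests: four species of
roughly 200 Mb each, derived from a five-chromosome ancestor (60, 55, 45,
35 Mb plus a 15 Mb short chromosome), with 15 planted cold and 15 planted
hot regions of nominally two 1.5 Mb windows.

Design choices that matter, and why:

* **The base landscape lives on the ancestor.** The deterministic base
  rate is `1 + boost * exp(-d / (L/10))` at distance `d` from the nearest
  end of an ancestral chromosome of length `L` (uniformly `1 + boost` on
  chromosomes below the short-chromosome threshold, 20 Mb by default),
  and every species inherits it through its synteny before species-level
  noise is applied. That conservation of the landscape is precisely the
  hypothesis the caller is meant to detect. New telomeres created by
  simulated fissions do not acquire their own boost; this is a known
  simplification.
* **Noise** is multiplicative log-normal per 50 kb tile (sd 0.2 on the
  log scale by default). The upstream rate-estimation error of real maps
  is not quantified in the literature this emulates; the noise level is a
  free knob, not an estimate.
* **Planted regions form alternating cold/hot chains** anchored at
  chromosome tips, separated by single transition windows, on
  karyotypically stable chromosomes. Two facts force this geometry. The
  quartile low/high sets {Q1,Q2}/{Q3,Q4} tile the entire genome, so every
  window belongs to a candidate run and an isolated planted region simply
  extends into whatever background surrounds it. And 2 Mb sliding blocks
  smear a planted anomaly roughly one window beyond each edge. A region
  is therefore cleanly delimited only where both sides meet either an
  opposite-class neighbour or a chromosome end — which is also how ALR
  and AHR loci actually interleave along real chromosomes. A chain that
  must stop mid-chromosome ends with a hot region, because the U-shaped
  background in mid-chromosome is low-ranked and terminates a high run
  but would absorb a trailing cold one.
* **Rearrangements are confined to planted-free chromosomes.** The
  regions of interest are, by the premise of the analysis, on
  chromosomes that have remained karyotypically stable; fissions, fusions
  and inversions are drawn on the remaining chromosomes (the 35 Mb and
  15 Mb ancestral chromosomes under the defaults). Configurations whose
  rearrangement counts cannot be satisfied there are rejected.
* **Planted rates** are drawn per species from the extremes of that
  species' own rate distribution: cold tiles uniformly in
  (0.3, 0.9) × the 10th percentile, hot in (1.1, 1.7) × the 90th. With
  noise disabled, every cold tile ranks strictly below every hot tile.
* **Genes** (1,000 by default, 10 kb) are placed uniformly on the
  ancestor and projected into each species as one-to-one orthologs; a
  configurable fraction of per-species symbols is replaced by LOC
  placeholders ("LOC" + integer). Pathways draw a configurable fraction
  of members from genes resident in planted hot regions and the rest from
  genes outside all planted regions.
* **Toy alignments** evolve sites independently under an equal-rates
  four-state (Jukes–Cantor-like) substitution process — the simplest
  model sufficient to test branch-length recovery — with dataset B's
  branch lengths scaled by a rate multiplier and missing cells injected
  per-site.

What passing tests on these data do *not* show: robustness to
non-conserved landscape components (PRDM9-driven hotspot turnover),
linkage-disequilibrium structure, estimation error correlated along the
genome, assembly or annotation error, or regions whose contrast with the
local background is weaker than the planted extremes. The simulator
plants signal that the method should find; it cannot certify behaviour on
signals it does not model.

## Numerical and procedural choices

* Coordinates are 0-based half-open in every on-disk format and in
  synteny block tables (matching BED conventions and the interpolation
  formula); in-memory GRanges follow the usual 1-based closed convention.
* Truncated terminal windows are retained and ranked.
* Window means are unweighted means of overlapping source-interval values
  (the common interval-tool default); an overlap-length-weighted mean is
  available behind a flag (`weighted = TRUE`), and the two differ
  whenever source intervals overlap a window unevenly.
* Quartiling is genome-wide per species, not per chromosome; remainders
  go to the higher categories first, so category sizes differ by at most
  one. Rate ties are broken by genomic coordinate, which makes the
  all-equal track well-defined (and flagged with a degeneracy warning).
* The mixture rule counts windows, not base pairs (a bp-weighted mode
  exists via `weights`); an exact 50/50 tie gives no class, since both
  classes would satisfy "50% or more".
* Projection rounding is half-up, and a projected interval keeps at least
  1 bp so that no region silently vanishes.
* Merged-call support is the maximum of its constituents.
* The chi-squared design is pathway-vs-rest (pathway size enters the
  expected counts), Pearson without continuity correction, α = 0.05 on
  the BH-adjusted p; all three are parameters.
* The by-hand curation present in the original workflow is replaced by
  deterministic rules plus an explicit curation override (forced
  inclusion/exclusion intervals), so every formerly manual decision is
  auditable in the run log.
* Tie-breaking randomness (gene category assignment, column subsampling)
  runs on seeded streams isolated from the caller's RNG state.

## Problem sizes

The full-scale validation uses the default four-species, ~200 Mb
configuration (about 140 analysis windows per species; 30 planted
regions), 20 label-permutation replicates for the empirical null, 100
replicates of the planted-pathway experiment, 1,000 simulated null
pathways for calibration, 1,000 random merge inputs and 1,000 projected
coordinates; toy alignments use 8 taxa and 4,000 columns with
neighbour-joining trees fitted from Jukes–Cantor distances. Unit tests
run the same code on smaller configurations.

## Known limitations

* The consensus caller's resolution is the analysis window; calls can
  over- or under-shoot a true boundary by about one window, more where
  block smoothing and window grids disagree after rearrangement.
* Exact 50/50 classification ties in individual species reduce support
  and can drop a true region when two of four species tie; this is the
  conservative reading of the mixture rule.
* The species-label permutation null destroys the species-to-assembly
  correspondence entirely; it bounds false calls from pipeline structure,
  not from subtler rate correlations.
* Reproducing the original study's locus and gene counts requires the
  real maps, assemblies and curation decisions, and is out of scope by
  design; validation is property- and planted-recovery-based.
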