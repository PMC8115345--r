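---
title: "Methods: single-cell methylome and accessibility analysis in scnome"
author: "scnome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell methylome and accessibility analysis in scnome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models behind each stage, the assumptions they make, the tunable
parameters and their defaults, what the synthetic-data generator does
and does not emulate, and the design choices made where the underlying
protocol left the design open.

## The measurement model

scBS-seq reports, per cytosine, counts of methylated and unmethylated
reads after bisulfite conversion. scCOOL-seq (NOMe-seq-style) first
exposes chromatin to a GpC methyltransferase that can only methylate
accessible DNA, then bisulfite-converts; one library therefore carries
two signals separable by trinucleotide context. WCG sites (ACG/TCG) are
CpGs with no adjacent G, so their methylation is purely endogenous; GCH
sites (GCA/GCC/GCT) are GpCs with no adjacent CpG, so their
"methylation" is purely the enzymatic accessibility label. GCG sites
confound the two and are excluded from both analyses — the package
classifies them explicitly rather than leaving the exclusion implicit.
Both strands are kept as independent records throughout; a plus-strand
cytosine is classified by its trinucleotide `(i-1, i, i+1)` and a
minus-strand cytosine (genomic G) by the reverse complement. Any N in
the trinucleotide, and chromosome-edge cytosines, fall into `other`, so
the four classes partition all cytosines — a property the test suite
asserts by brute force over all 64 trinucleotides on both strands.

The level of a covered site is `m / (m + u)`. Single-cell bisulfite
data is dominated by depth-1 sites; the package interprets "1×" usage
as *use every site with ≥ 1 read at whatever depth it has*, which
coincides with binarization at depth 1 and avoids discarding reads at
the rare deeper sites. Region and global levels are unweighted means of
per-site levels over covered sites of the class, which keeps deep sites
from dominating sparse single-cell profiles.

## Coordinates and boundary conventions

Intervals are 0-based half-open internally and in BED output; call
tables on disk are 1-based (bismark-coverage dialect), converted on
read. Thresholds are applied exactly as the protocol prints them:
"more than" is strict (`>` 70% tile cell-coverage, `>` 10% DMR
eligibility, `>` 40% differential-open coverage, `>` 30% variance
cell-coverage, `>` 3 CpG / `>` 5 GCH per-cell window gates, NDR length
`>` 140 bp), while "at least"/"no more than" are inclusive (mapping
rate ≥ 20%, conversion ≥ 99%, FGC global methylation ≤ 0.2, ≥ 3 CpG
per tile, ≥ 5 GCH per NDR, NDR p ≤ 1e-20, DMR q ≤ 0.05). Every
threshold lives in `analysis_config()` and each pipeline run logs the
resolved configuration, so a run is reproducible from its log.

## NDR detection

Cells of a group are pooled site-by-site to gain coverage before any
region calling. Windows of 100 bp advanced by 20 bp are scored with a
one-sided chi-square: the 2×2 table contrasts the window's pooled
(C, T) with the genome-wide totals. Three numerical choices matter:

* The background *includes* the window. The window is a negligible
  fraction of the genome, so inclusion is immaterial statistically, and
  fixing one convention keeps results deterministic.
* One-sidedness is a pre-gate — a window whose rate does not exceed the
  background gets p = 1 — because only *elevated* GCH labeling is
  evidence of openness.
* P-values are computed in log10 space
  (`pchisq(..., log.p = TRUE)`), since true signals at pooled coverage
  routinely fall below 1e-300 and would underflow.

Windows with zero covered reads are skipped, not scored: an untestable
window is not evidence of closed chromatin. Significant windows that
overlap or book-end are merged by union; the component filters (length
strictly greater than 140 bp, at least 5 covered GCH sites) are applied
to the merged span. Union merging makes the caller monotone: relaxing
the p threshold can only grow called spans, never remove them (each
strict-threshold NDR is contained in a loose-threshold NDR), and the
suite asserts this containment. NDR centers within 2 kb of a TSS
(inclusive) are proximal; 2001 bp away is distal.

Differential openness between two groups evaluates the union of their
NDRs: per-cell region levels (mean of per-site levels over GCH sites,
≥ 1 site to count as covered), coverage in more than 40% of cells of
*both* groups, |Δ mean| > 0.2, and an exclusivity rule — more than half
of covered cells open (level ≥ 0.5) in exactly one group. Cells between
0.3 and 0.5 count toward coverage but toward neither state; this
deliberate dead zone keeps ambiguous cells from deciding calls.

## Differential methylation

Tiles are fixed 500-bp windows from coordinate 0. For two groups, tiles
covered in more than 10% of cells of each group (against that group's
post-QC cell count) are compared. The protocol names only the FDR
adjustment ("fdr" = Benjamini–Hochberg), not the test statistic; the
package uses the Wilcoxon rank-sum over per-cell tile levels — robust
at small n with no distributional assumption on levels that are means
of few binary site calls. Because tied levels are ubiquitous at low
site counts, the classical exact Wilcoxon is unavailable; when the
smaller group has fewer than 8 covered cells the package instead
enumerates all label permutations of the rank-sum statistic (exact even
under ties); otherwise it uses the normal approximation with tie
correction. A Welch t-test is selectable via `dmr_test = "ttest"` for
sensitivity analysis. Calls then require the printed level gates: a
*demethylated* tile has former mean > 0.75, latter mean < 0.25 and
q ≤ 0.05; *de novo* is the mirror; everything else is *stable*. The
level gates dominate specificity — groups drawn from an identical
Beta(2, 8) tile distribution essentially never cross both 0.75 and
0.25, which is why null calibration is comfortably below 5%.

The residual-methylation screen keeps tiles whose group-mean level is
at least 0.4 at *every* stage, restricted to tiles eligible at all
stages. Hypergeometric enrichment of a candidate tile set against a
background set uses any-bp overlap with merged annotation intervals and
the exact upper tail `P(X ≥ k)`; the suite verifies it against direct
factorial summation for every parameter set with N ≤ 60.

## Promoter classes and three-omics integration

The HCP/ICP/LCP promoter terminology is used without numeric criteria
in the source protocol; the package adopts the field-standard
Weber-style definition and exposes the numbers in the configuration: a
promoter (`[TSS−1000, TSS+500)`, strand-oriented) is HCP if any 500-bp
subwindow has CpG observed/expected `> 0.75` *and* GC fraction
`> 0.55`; LCP if no subwindow exceeds observed/expected `0.48`; ICP
otherwise. Subwindows slide by 1 bp (cumulative sums make this cheap),
and observed/expected is `nCpG / (nC · nG / L)`.

Promoter signals are means of per-site pooled levels over
`[TSS−1000, TSS+500)` for WCG and `[TSS−200, TSS+100)` for GCH,
oriented by gene strand (for minus-strand genes the upstream window
lies above the TSS). Per promoter class, Spearman correlations are
computed among expression, promoter methylation and promoter
accessibility across genes with all three values.

The phase-specific gene screen aggregates cells of each phase as a bulk
sample, computes each proximal NDR's pooled GCH level per phase, and
correlates that phase vector (Pearson) with the expression vector of
the NDR's gene. NDRs map to the nearest TSS within 2 kb of their
center, ties broken to the lexicographically smaller gene id (the
protocol does not state its mapping; nearest-TSS is the conventional
choice and the tie-break makes it deterministic). Screening is at the
region level — a gene can appear through several proximal NDRs, which
matches how such heat maps display region rows. Pairs with r strictly
above 0.6 are selected; NDRs with accessibility missing in any phase
are skipped rather than imputed.

## Cell-to-cell variance

Heterogeneity is measured in sliding windows (3000 bp / 600 bp for
methylation; 200 bp / 100 bp for accessibility; both grids start at
coordinate 0). A cell contributes a window only when it covers more
than 3 CpG (respectively more than 5 GCH) sites there; its statistic is
the mean of its site levels in the window — consistent with the
package's region-level definition (pooled C/(C+T) per cell is the other
defensible reading; at depth 1 with equal site counts they coincide).
Windows covered in more than 30% of the group's cells are retained, and
groups with fewer than 10 cells are skipped entirely. The reported
summary is the lower endpoint of the two-sided 95% chi-squared
confidence interval of the sample variance,
`(n−1)s² / qchisq(0.975, n−1)` — a deliberately conservative statistic
that shrinks toward zero when few cells are observed, so sparsely
covered windows cannot fake heterogeneity. The plain `s²` is emitted
alongside, since the accessibility-side convention in prior work is
under-specified; applying the same lower bound to both modalities keeps
them comparable. Element-level summaries assign each window by its
center and report quartiles of the lower bounds.

## The synthetic-data generator

The source study is observational: it defines no generative model. The
generator is therefore the package's own construction, built to emulate
the *statistical structure* the study reports, so that every stage has
planted ground truth to be scored against:

* **Sparse coverage at ~1×**: each context site is covered with
  probability `site_coverage_prob` (default 0.12, matching the reported
  ~10–15% of sites per cell); covered sites draw depth
  `1 + Poisson(mean_read_depth − 1)`, so the default regime is exactly
  depth 1.
* **Phase-dependent methylation**: per (tile, phase) a true level is
  drawn from a Beta centered on the phase mean with dispersion 0.05;
  per-cell site counts are Binomial at the tile's true level. Default
  phases mirror a male time course — soma at 67.4% global CpG
  methylation, FGCs at 14.5% (week 6), 4.9% (week 17) and 7.2%
  (week 24). Because planted demethylating tiles (0.85 → 0.05 across
  the first FGC transition), residual tiles (0.6 in all FGC stages) and
  ICR-like intervals (0.5 in soma) would otherwise bias the global
  mean, the background-tile mean is solved so the *global* per-cell
  level matches the configured phase mean; the acceptance script
  reports these global levels and they land on the configured values to
  within sampling error.
* **Two-state accessibility**: planted NDRs (one per open promoter,
  default 300 bp centered on the TSS) emit GCH methylation at
  `enzyme_efficiency` (0.85); everywhere else at `background_gch`
  (0.02). Bisulfite non-conversion and nonspecific labeling are folded
  into the single background rate — they are indistinguishable in call
  tables. A warning fires if efficiency does not exceed background,
  since planted truth is then unrecoverable. The two-state model is the
  simplest structure under which NDR recall and precision are well
  defined; it does not emulate continuous occupancy, nucleosome
  phasing, or footprint-size effects.
* **Promoter sequence classes**: every third promoter receives a
  CpG-island-like segment (GC ≈ 0.7) and the next a CpG-depleted
  neighborhood retaining ~10% of CpGs, so HCP/ICP/LCP all exist and
  the CGI annotation is real sequence, not a label. TSS positions are
  jittered (±250 bp) against the regular spacing — without jitter,
  annotation intervals can alias systematically against the fixed
  tile and window grids and silently vanish from element summaries.
* **Expression**: genes open in a phase are ~10× baseline there, with
  mild lognormal noise, making the r > 0.6 screen's expected output
  derivable from truth; genes open in no phase are negative controls.

What passing tests on this generator do *not* show: robustness to
mapping bias, PCR duplicates, conversion-efficiency gradients,
copy-number variation, continuous occupancy profiles, or real repeat
sequence (repeat "families" are planted intervals, not transposon
sequence). Results on real data depend on upstream alignment and
deduplication, which are out of scope here.

## Problem sizes and determinism

The shipped analyses and tests run on deliberately small cohorts — a
two-chromosome 300-kb genome with 60 genes and 12 cells per group for
the workflow scripts, a 200-kb genome with 30 cells for NDR recovery,
50 replicates for differential-methylation calibration and power, 100
background-only tracks for null calibration, and 1000 windows for
variance-CI coverage. These sizes were chosen so each statistical
property is measured with comfortable margin while the whole suite
stays interactive; all of them scale up by configuration only. Every
stochastic step is seeded: the same seed reproduces cohorts, pipeline
outputs and acceptance quantities byte-for-byte.

## Known limitations

* The NDR caller reports merged significant-window unions; it does not
  trim spans back to significant cores, so called regions can exceed
  planted regions by up to one window less one step on each side.
* The tile p-value choice (Wilcoxon over per-cell levels) is one of two
  defensible readings of the protocol; a pooled-count Fisher test is
  the other. The per-cell reading matches the plural "cells … used for
  comparison" and is robust to per-cell coverage imbalance.
* ICR profiling reports group means only; allele-specific
  (parent-of-origin) analysis is out of scope.
* QC count thresholds (2 M CpG etc.) assume a mammalian-scale genome;
  on synthetic genomes they must be rescaled via the configuration, as
  the analysis scripts do.
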