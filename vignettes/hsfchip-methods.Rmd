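---
title: "Methods: tiling-array ChIP peak, motif and expression analysis for the heat shock regulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiling-array ChIP peak, motif and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Heat shock factor (HSF) trimerizes under proteotoxic stress and binds heat
shock elements (HSEs) — canonically three inverted-repeat nGAAn units,
`nGAAnnTTCnnGAAn`, 15 bp in total — to drive the heat shock regulon. A
genome-wide picture of where HSF sits, what kind of genomic real estate it
occupies (promoters, introns, intergenic space), and how binding relates to
heat-induced transcription, comes from combining three data modalities:

* **ChIP-chip tiling arrays**: probe-level enrichment ratios of
  immunoprecipitated chromatin versus whole-cell extract (WCE), with a
  per-probe error-model probability `P[Xbar]` that the difference is
  non-biological;
* **expression microarrays** in two systems (a cultured cell line and whole
  larvae), reduced to per-gene fold changes and FDR-adjusted p-values;
* **polytene cytology**: a coarse band-level map of HSF immunostaining.

`hsfchip` implements the downstream analysis of such a study as a tested,
reusable pipeline, together with a seeded synthetic-study generator so that
every stage can be exercised — and its statistical behaviour verified —
without any external download.

# Pipeline stages and their models

## Segment calling (`call_segments`, `assign_peak`)

The array vendor's error and neighbourhood models are not reproduced here;
bound segments are consumed downstream as given, so the caller only needs to
produce the same data shape and recover planted truth. The substitute is a
thresholded run-joiner: maximal runs of probes with
`pxbar < pxbar_threshold` (default `1e-3`), tolerating up to
`max_gap_probes = 1` interior non-significant probes, retained with at least
`min_probes = 2` significant members. The segment peak is the centre of the
member probe with the lowest `P[Xbar]`; ties break toward the higher fold
change, then leftmost — on clean signal this is also the highest-fold probe,
matching the behaviour expected of real segments.

Mock-ChIP filtering drops a segment only when it is completely contained in
the union of overlapping mock segments *and* its minimum `P[Xbar]` is not at
least `pxbar_ratio_keep = 100`-fold smaller than the best overlapping mock's.
"Much stronger" is not defined quantitatively in the field's usage; the
printed example of a retained segment differs by seven orders of magnitude,
so any factor between ~10 and ~10^6 gives identical decisions there. Every
decision carries a human-readable reason.

HS-versus-RT comparison (`compare_conditions`) counts any base-pair
intersection as overlap and computes per-pair fold ratios on the
representative peak probes.

## PWM scanning with exact p-values (`pwm`, `score_distribution`, `scan_pwm`)

Motif matches are scored by natural-log odds against a background base
model, with a per-position pseudocount defaulting to 1% of the position's
count total (applied as `pseudocount * background(b)`); this avoids `-Inf`
scores for well-populated matrices while being immaterial to
threshold-crossing at the match cut-offs used (1e-4, 1e-5, 5e-4). The match
p-value is the *exact* upper-tail probability of the log-odds score of a
background-generated sequence, computed by position-wise convolution over
scores discretized to 1e-3 natural-log units — the convention of classic
pattern matchers, i.e. single position, single strand, no per-scan
multiple-testing adjustment (library-level Bonferroni correction lives in
the screen, below). Scanning and the distribution share the same integer
discretization, so a reported p-value is exactly the tail of the reported
score's bin; the test suite verifies tails against exhaustive enumeration of
all `4^w` sequences for widths up to 6.

Both strands are scanned (minus-strand scores via the reverse-complemented
matrix); windows containing `N` are skipped silently and counted. The
background defaults to uniform 0.25; if a zero count meets a zero
pseudocount the cell scores `-Inf` and is floored 50 log-units below the
matrix minimum during binning, far past any usable threshold.

## Positional enrichment (`match_histogram`, `center_flank_test`, `orientation_scan`, `group_screen`)

Matches around each peak (±2500 bp, truncated at chromosome ends with
coverage bookkeeping) are binned by the offset of the match *start* from
the peak centre into 50-bp windows; a match straddling a boundary is not
split. Enrichment at the peak is tested by a 1-df goodness-of-fit chi-square
(no continuity correction) of the counts in the centre (−500..+500) versus
local background (−1000..−550 and +550..+1000) intervals. The expected split
is proportional to the available interval lengths — 1001 : 902 bp per fully
covered peak, with truncated peaks contributing their covered lengths — the
defensible null when none is otherwise specified. When no match falls in
either interval the test is undefined and reported as `p = 1` with a
`degenerate` flag. A simulation helper (`center_flank_null_sim`) confirms
the test holds its nominal size under uniform match placement.

`orientation_scan` builds all 8 triplet arrangements of the 5-bp units
{GAA, TTC} and ranks them by centre enrichment at each threshold;
reverse-complement arrangement pairs necessarily produce identical two-strand
histograms, which the tests assert.

`group_screen` runs the centre-versus-flank test for every matrix in a
user-supplied library against two disjoint peak groups (HSF-bound promoters
and HSF-bound introns), Bonferroni-corrects the per-matrix test p-value by
the library size against `alpha = 5.6e-2`, and re-tests every passing matrix
with a seeded column permutation of itself (`scramble_columns`): a matrix
whose scrambled version also passes is flagged as a base-composition
artifact and excluded. The published cut-off phrasing is ambiguous between
correcting match p-values and test p-values; this package corrects the
*test* p-value and keeps the per-match scan cut-off at its stated value,
which keeps match thresholds comparable across analyses. A
promoter-versus-intron two-sample chi-square on (centre, flank) counts asks
whether near-peak enrichment differs between the groups.

## Site annotation (`nearest_tss`, `classify_site`, `genome_composition`)

Distances to transcription start sites are signed in transcription
direction: positive downstream, negative upstream. Ties break toward a gene
whose body contains the peak, then lexicographically. The promoter is
*bidirectional*: within `promoter_radius = 1250` bp of any isoform TSS on
either side — the published per-site distances include both signs, and this
choice reproduces their membership most consistently; an upstream-only rule
can be emulated by post-filtering on the sign. Classification applies, over
the union of isoforms: intragenic sites are sub-labelled `ExonK`/`IntronK`
by the containing isoform closest by TSS (`promoter_intragenic` when also
within the promoter radius); non-intragenic sites are `promoter_intergenic`
within the radius, `downstream` within 1250 bp past a 3′ end (the published
"downstream" label carries no radius; the promoter radius is reused), else
`intergenic`. Genome composition backgrounds (intragenic, promoter,
intronic base-pair fractions) are interval-union computations verified
against a per-base brute-force oracle in the tests.

Cytological analysis maps peaks into a band partition (left-closed
intervals) and tests band-level independence of ChIP hits and polytene loci
with the same uncorrected 2×2 chi-square, optionally widening ChIP hits by
one band index (never across a chromosome). The test universe is all bands
in the map; restricting the universe is a caller-side subset of the band
table.

## Expression integration

Differential calls use the published rule exactly: `|fold| >= 2` (inclusive)
and FDR-adjusted `p < 0.01` (strict), on signed-ratio fold changes
(−1.5 means 1.5-fold down). FDR adjustment is Benjamini–Hochberg
(`stats::p.adjust`), the standard stand-in when a vendor's method is
unstated. Gene–site association follows the published two-rule definition:
a peak inside the transcribed span (isoform union), or a TSS within 1250 bp
of a peak. The three-set Venn reports all 7 regions plus the
exactly-one-system count, using `exclusive = |A| + |B| − 2|A∩B|` over
`union = |A| + |B| − |A∩B|`. The motif/binding-by-induction contingency
analysis uses Pearson's chi-square without continuity correction
throughout — validated by recovering the published `p = 0.0198` from the
printed table; "induced" means up-calls in the cell system (the one
repressed gene is thereby excluded from the induced column). Expression
profiles are clustered with Manhattan distance and unweighted average
linkage (`stats::hclust`), exported as Newick via `ape`. Term enrichment is
a generic one-sided hypergeometric against a user-supplied background (for
intron-gene analyses, all genes with introns), BH-adjusted — deliberately
*not* a reimplementation of any annotation service.

# The synthetic study generator

`sim_config()` holds the generative knobs; its defaults *are* the study
conditions the pipeline targets and are not tuned per analysis:

| knob | default | what it encodes |
|---|---|---|
| `probe_spacing`, `probe_length` | 233, 60 | tiling grid of the arrays |
| `masked_gap_fraction` | 0.02 | repeat-masked probe-free gaps; one super-gap ≥ 10× spacing is always planted so the "nearest site beyond a probe desert" phenomenon is exercisable |
| `n_segments`, `fold_model` | 120, lognormal(log 15, 0.8) clamped to [5, 100] | bound segments, spans ~1–1.8 kb (mean ≈ 1.4 kb) |
| `category_mix` | 0.27 / 0.35 / 0.22 / 0.16 | promoter / intron / exon / intergenic placements, mirroring the published 57% intragenic, 27% promoter, 35% intron breakdown |
| `hse_window` | −400..+300 | planted HSE offsets relative to the peak |
| `rt_retained_fraction`, `rt_attenuation` | 0.81, 5 | RT ChIP coincidence and fold attenuation |
| `de_fraction_per_system`, `de_overlap_fraction` | 0.08/0.09, 0.08 | responsive genes per system; shared fraction of the union |
| `promoter_induced_fraction` | 11/115 | bound promoters induced in the cell system |
| `beaf_plant_prob_induced` / `_noninduced` | 0.27 / 0.66 | BEAF-motif planting in bound promoters |

Design choices a user should know:

* **Coordinates** are 1-based inclusive in memory (the Bioconductor
  convention); emitted GFF3 and BED go through `rtracklayer` and therefore
  follow each format's own convention exactly.
* **Noise** is multiplicative log-normal on probe folds (`noise_sd`, log-sd
  0.15) — the conventional model for ratio data; `P[Xbar]` is generated as a
  monotone transform of the underlying signal profile
  (`10^-(3.2 + 9s + noise)` for profile height `s` in (0,1]), so
  significance decreases monotonically with fold on average. Null probes
  draw `P[Xbar]` from U(0.01, 1): significant background probes arise *only*
  through the configured `fp_rate`, which makes the noise-free limit exactly
  recoverable and puts the false-positive rate under a single explicit knob.
* **Planted peaks are snapped to the nearest probe centre.** A real
  segment's peak is by definition a probe centre; snapping makes noise-free
  recovery exact rather than approximate.
* **The BEAF-style matrix** (`make_beaf_pwm`) uses a 7-bp informative core.
  At the 5e-4 occurrence cut-off under a uniform background only the exact
  core matches (the next score step has tail 1.3e-3), keeping chance
  matches over a promoter-sized region rare (~0.06 per kb per strand).
  Chance hits still inflate measured presence rates above the planted
  Bernoulli probabilities by a few points; the recovery tests account for
  this by estimating the background rate from segments where nothing was
  planted.
* **Base composition** defaults to uniform 0.25 and is configurable for
  AT-rich genomes.

What the generator does *not* emulate: scanner images, dye bias, array
normalization, amplification bias, correlated probe noise, isoform-specific
expression, or real genomic sequence composition (repeats, CpG/AT structure,
codon bias). Passing recovery tests therefore demonstrate that the
algorithms are correct and calibrated on data obeying the stated generative
contract — not that the biological conclusions of any particular study
would be re-derived from raw arrays.

# Numerical choices

* Score discretization `bin_width = 1e-3` natural-log units; the exact-p
  oracle tests agree to 1e-9 on the shared grid.
* Chi-square tests are 1-df and never continuity-corrected (this is what
  reproduces the published contingency p-value from its printed counts).
* Degenerate inputs are flagged, not guessed at: empty centre+flank counts
  give `p = 1` with a flag, zero-marginal 2×2 tables raise an error that
  report-level callers convert into an explicit "undefined" entry, empty
  peak groups are skipped and named in the screen output.
* `hclust` average linkage resolves merge ties by its deterministic
  smallest-index rule; leaf order is emitted alongside the tree.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic data
sized for a workstation: unit tests on 0.4–0.5 Mb genomes with 40–50
segments, and study-scale checks on a 4-Mb genome with 400 segments and
~520 genes (roughly the published segment count, at ~1/30 of the fly genome
length). Statistical recovery assertions use binomial confidence intervals
at those sizes.

# Known limitations

* The vendor error model behind `P[Xbar]` is not reimplemented; calling
  thresholds are stipulated, not derived from an FDR target.
* Match p-values assume a fixed background model per matrix; scanning with
  sequence-estimated backgrounds is supported by constructing the `pwm`
  with different `background`, but per-window local backgrounds are not.
* UTR sub-labels require CDS annotation, which the generator does not emit;
  the classifier labels such sites by exon/intron rank instead.
* Detection power for the promoter-motif contingency at the published group
  sizes (11 vs 104) is intrinsically limited by the small induced group;
  exact enumeration puts the uncorrected chi-square's power at ≈0.75 for
  the planted rates, so single-study non-significance is an expected
  outcome rather than a pipeline failure.

# A worked example

```{r example}
library(hsfchip)

cfg <- sim_config(seed = 1)
sim <- sim_study(cfg)

hs <- call_segments(sim$chip$hs)
hs <- filter_against_mock(hs, call_segments(sim$chip$mock))$kept
rt <- call_segments(sim$chip$rt)
compare_conditions(hs, rt)

h <- match_histogram(hs, sim$genome, make_triplet_pwm(), 1e-4)
center_flank_test(h)
plot(h)

ann <- annotate_sites(hs, sim$models)
category_breakdown(ann)

calls <- differential_calls(sim$expression)
bound <- gene_site_association(sim$models, hs)
intersect_lists(bound,
                calls[calls$system == "cells", ],
                calls[calls$system == "larvae", ])
```
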