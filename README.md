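# hsfchip

Downstream analysis of genome-wide **HSF ChIP-chip** and heat-shock
expression data, as a tested R pipeline.

Heat shock factor (HSF) binds heat shock elements (HSEs) — three
inverted-repeat nGAAn units, `nGAAnnTTCnnGAAn` — to drive the stress
regulon. Studies of this system combine tiling-array ChIP (probe-level
enrichment ratios versus whole-cell extract, with an error-model
probability `P[Xbar]` per probe), expression microarrays in multiple
systems, and polytene-chromosome cytology. `hsfchip` implements the
downstream analysis of such a study for computational biologists who want
the published logic as reusable, tested functions:

* **Segment calling** — probe runs with `P[Xbar]` below threshold (gap- and
  minimum-probe rules), peak assignment at the lowest-`P[Xbar]` probe,
  mock-ChIP filtering, and HS-versus-RT condition comparison.
* **Motif model** — TRANSFAC-dialect PWM parsing, log-odds scoring, *exact*
  score-distribution match p-values
  (P(score ≥ s) by position-wise convolution), two-strand scanning at
  p-value cut-offs, scrambled-matrix controls, and constructors for all
  nGAAn-unit HSE orientations.
* **Positional enrichment** — 50-bp windowed match histograms around peaks,
  the centre (−500..+500) versus flank (±550..1000) chi-square with
  length-proportional expectation (1001 : 902), orientation comparison, and
  a Bonferroni-corrected library screen with scrambled controls
  (promoter versus intron groups).
* **Genome annotation** — nearest-TSS distances with strand-aware signs,
  the promoter(1250 bp)/exon/intron/downstream/intergenic partition over
  multi-isoform gene models, genome composition backgrounds, cytological
  band mapping and polytene overlap chi-square tests.
* **Expression integration** — the ≥2-fold, FDR < 0.01 differential filter,
  Benjamini–Hochberg adjustment, bound/regulated Venn intersections,
  distance-to-nearest-site summaries, 2×2 contingency tests without
  continuity correction, Manhattan/average-linkage clustering with Newick
  export, and generic hypergeometric term enrichment.
* **Synthetic study generator** — a seeded simulator of genome, annotation,
  233-bp probe tiling with repeat-masked gaps, HS/RT/mock ChIP signal,
  two-system expression and cytology, with planted ground truth, so the
  whole pipeline is testable offline.

## Worked example

```r
library(hsfchip)

cfg <- sim_config(seed = 1)      # the study conditions: 233-bp tiling,
sim <- sim_study(cfg)            # 120 segments, 81% RT retention, ...

hs <- call_segments(sim$chip$hs)
hs <- filter_against_mock(hs, call_segments(sim$chip$mock))$kept
rt <- call_segments(sim$chip$rt)
compare_conditions(hs, rt)
#> <condition_comparison> 100.0% of RT segments overlap HS; 76.9% of HS
#>   segments have RT signal; mean HS/RT peak fold ratio 5.13 (93 pairs)

h <- match_histogram(hs, sim$genome, make_triplet_pwm(), 1e-4)
center_flank_test(h)
#> <center_flank_test> center 123 vs flank 0 (expected 64.7 : 58.3),
#>   chi2 = 110.84, p = 6.43e-26

ann <- annotate_sites(hs, sim$models)
round(category_breakdown(ann)$aggregates, 3)
#>   intragenic promoter_any
#>        0.570        0.281

calls <- differential_calls(sim$expression)
bound <- gene_site_association(sim$models, hs)
intersect_lists(bound,
                calls[calls$system == "cells", ],
                calls[calls$system == "larvae", ])
#> <binding_venn> regions:
#> bound_only     a_only     b_only    bound_a    bound_b        a_b  bound_a_b
#>         86         12         11          5          9          1          2
#> one-system: 37 (92.5% of regulated); triple overlap: 2
```

Reading the numbers: the caller recovered every planted segment; RT binding
coincides with HS binding at close to the planted 81% retention and 5-fold
attenuation; HSE matches pile up in the −400..+300 window around peaks
(flank count 0), making the centre-versus-flank chi-square decisive; the
annotated site categories recover the planted mix (57% intragenic, 27%
intergenic promoters); and most differentially expressed genes are
responsive in only one system and not HSF-bound.

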