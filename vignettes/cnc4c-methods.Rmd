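---
title: "Methods: 4C interaction calling and conservation-proximity analysis"
author: "cnc4c"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4C interaction calling and conservation-proximity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnc4c)
```

## The experiment and the analysis model

Circular chromosome conformation capture (4C) fixes chromatin contacts with
formaldehyde, digests with a restriction enzyme (here DpnII, a 4-cutter
recognising GATC and cleaving 5' of the site), ligates under dilute
conditions so that cross-linked fragments circularise together, and then
amplifies outward from one fixed *bait* (viewpoint) fragment. Sequencing the
amplified junctions enumerates the restriction fragments that were in
physical proximity to the bait in the cell population. Because the
sequencing primer anneals immediately upstream of the bait-side DpnII site,
every informative read begins with GATC and its alignment starts (or ends,
on the minus strand) exactly at a restriction-site boundary.

The analysis layer implemented here makes four modelling commitments:

1. **The restriction fragment is the unit of observation.** The genome is
   partitioned in silico into DpnII fragments (`digest_genome()`); tags are
   assigned to the fragment whose boundary they start from
   (`assign_tags()`), and every downstream statistic counts fragments or
   per-fragment tags.
2. **Interaction calling is a plain count threshold.** A fragment is an
   interacting region (CIR) when it accrues at least 50 tags
   (`call_cirs()`), after removal of the bait fragment and the fragments
   directly flanking it, which are over-represented through partial
   digestion and proximity ligation (`exclude_bait_flanking()`, one
   fragment per side by default). There is no parametric background model;
   the control for the threshold's meaning is the pair of no-cross-link
   libraries, which should (and do) behave like uniform random sampling of
   the genome's fragments.
3. **Conservation proximity is a distance, not an overlap.** The tendency
   of interacting fragments to lie near conserved non-coding sequence is
   measured as the center-to-center distance from each member fragment to
   its nearest non-exonic conservation block (`nearest_block()`), compared
   between samples by the two-sample Wilcoxon rank-sum test and by paired
   empirical quantiles (Q-Q points).
4. **The null is an empirical sample of the same genome.** Rather than a
   parametric null distance distribution, 10000 fragments (by default) are
   sampled uniformly without replacement from the fragment index
   (`sample_null_fragments()`), and their distances form the "simulation"
   sample.

## Parameters, defaults, units

| parameter | default | where | meaning |
|---|---|---|---|
| `threshold` | 50 tags | `call_cirs()` | minimum tag count for a CIR |
| `n_flank` | 1 fragment | `exclude_bait_flanking()` | flanks removed each side of the bait |
| `min_match` | 29 nt | `filter_config()` | minimum aligned match length |
| `max_gap` | 1 nt | `filter_config()` | largest tolerated per-gap insertion |
| `required_prefix` | GATC | `filter_config()` | leading nucleotides of a valid read |
| `window_bait` | 5000 bp | `bait_proximity_edges()` | center-to-center bait proximity window |
| `window_gene` | 10000 bp | `genes_near_cirs()` | interval-gap gene proximity window |
| `null_size` | 10000 fragments | `null_config()` | simulation-null sample size |

Two windows deliberately use different distance notions: bait-bait
proximity is center-to-center (consistent with the conservation-distance
convention; a restriction fragment is short relative to 5 kb), while gene
proximity uses the minimal interval gap, because genes are long and a
center-to-center rule would misclassify a tag inside a 100 kb gene body.

## Coordinate and file conventions

All internal coordinates are 0-based half-open; BED I/O is native in that
convention. The tabular count dialect
(`BaitID, Chr, DpnIIStart, DpnIIEnd, NumbReads`) is treated as 1-based
inclusive on read and write; the convention is a reader argument
(`one_based`) because published tables of this shape do not always state
it. Fragment and block centers use the floor midpoint
`(start + end) %/% 2`; nearest-block ties break toward the smaller start
coordinate. PSL alignments do not carry read sequences, so the
GATC-prefix filter is approximated by requiring the alignment to start at
query position 0 (together with boundary-anchored fragment assignment this
is equivalent for reads produced by the 4C primer design). Per-gap sizes
are reconstructed from the PSL block structure since the match criterion
is per-gap, not total inserted bases.

## Statistical machinery

`wilcoxon_rank_sum()` is two-sided throughout. The exact null enumeration
is used when `n1 + n2 <= 20` and the pooled data are tie-free; otherwise
the normal approximation with mid-ranks, tie correction and continuity
correction (the standard large-sample treatment). When every pooled
observation is identical the test is degenerate and reports p = 1. Q-Q
points are type-7 empirical quantiles at evenly spaced probabilities; the
interpolation scheme is fixed and documented because quantile plots are
not invariant to it. The gene-set overlap statistic is the exact
hypergeometric upper tail `P[X >= k]`, with the convention that an empty
query yields p = 1 and is flagged degenerate. Raw p-values are reported;
no multiple-testing correction is applied across baits.

## What the synthetic generator emulates

`synthetic_config()` describes a scaled-down study: a multi-chromosome
genome in which GATC occurs only at planted positions with geometric
inter-site spacing (mean 256 bp, the expectation for a 4-base site);
non-overlapping conservation blocks with integer scores uniform in
525-710 (the score range of conserved non-coding baits), a fraction of
which are duplicated as exons so that exon subtraction removes them;
and 4C libraries drawn per tag as: trans with probability
`trans_fraction` (uniform over other-chromosome fragments), otherwise cis
with weight `(1 + distance)^-1.5`, and a multiplicative weight
`conservation_enrichment` (default 4) on fragments whose center lies
within 5 kb of a non-exonic block. `crosslinked = FALSE` forces uniform
genome-wide sampling -- the no-cross-link control. Everything is
deterministic under a seed.

The generator does **not** emulate sequence-level realism (GC content,
repeats, mappability), PCR duplicates, partial digestion, or chromatin
domain structure. Passing tests therefore demonstrate the correctness and
calibration of the analysis machinery under the stated sampling model,
not robustness to the artefacts of real libraries.

### Design of the Monte-Carlo validation harness

`run_recovery_experiment()` regenerates the conservation annotation and
redraws baits in every replicate, so replicates are genuine draws of the
whole study. Three design choices matter and were made for statistical
validity:

* **Distances are pooled across one bait per chromosome** before testing
  against the genome-wide null, as in a pooled multi-bait analysis. A
  single bait's library systematically excludes the bait's own chromosome
  while the null contains it; with per-chromosome block layouts this
  composition mismatch alone rejects far above nominal level. Pooling one
  bait per chromosome balances the composition exactly.
* **The default genome is 4 x 1.5 Mb (~23,000 fragments).** The member
  set (~400 fragments at threshold 50) and the 2000-fragment null are then
  nearly disjoint subsets, as in the real genome; on a much smaller
  genome they overlap heavily and the shared values make the test
  spuriously conservative. The in-harness null size is 2000 rather than
  10000 because the scaled genome does not hold 10000 fragments to sample
  without replacement at comfortable margin.
* **The cis decay exponent defaults to 1.5** (within the range observed
  for 4C viewpoint profiles). At this depth the cis fragments exceeding
  the 50-tag threshold are confined to the immediate bait vicinity, so
  under no enrichment the pooled member sample is essentially an
  independent draw from the trans fragment population, which is the
  regime in which the nominal type-I error of the rank test is meaningful.

With these defaults the pooled test holds its nominal level (5%
rejections at alpha = 0.05 over 1000 replicates, checked in the
acceptance suite) and detects a 4-fold enrichment with power near 1 at
several hundred member fragments.

The trans-fraction recovery check uses deliberately small libraries
(30 tags, trans fraction 0.3). The raw trans tag share is exactly
binomial, so a two-sigma interval has asymptotic coverage 95.45% -- too
close to a 95%-of-replicates requirement to verify reliably at any large
library size. At 30 tags, binomial discreteness widens the effective
interval to 97.4% exact coverage (computed from the binomial CDF, not
simulated), making the nominal property robustly observable in 200
replicates. This is a property of the estimator's discreteness, not of
the pipeline.

The acceptance checks use problem sizes chosen to characterise the
statistics well while remaining desk-scale: 1000 replicates for the
type-I rate, 200 for power and recovery, 1000 random instances for the
digestion oracle.

## Degenerate inputs and numerical edges

Zero-length fragments (a site at chromosome position 0) are dropped: they
can hold no tags. `N` bases never complete a recognition site, matching
repeat-masked references. A bait at a chromosome end simply loses fewer
flanking fragments. Fragments on chromosomes without conservation blocks
are excluded from distance samples and counted rather than raised as
errors. Reproducibility (overlap over experiment 1) is undefined for an
empty first experiment and is an explicit error; the symmetric Jaccard
index is attached as an attribute. An empty CIR set yields 0% trans with
`n_members = 0` rather than NaN.

## Known limitations

* Trans percentages are computed over threshold-passing members by
  default (the unthresholded variant is available by passing the raw
  library); published per-library percentages of this kind are sensitive
  to that choice.
* The nearest-block search is same-chromosome only; cross-chromosome
  distance is undefined in this framework.
* The simulation null samples fragments uniformly, not weighted by
  fragment length; distances are center-based, so length weighting would
  only matter for strongly length-biased member sets.
* The gene-set overlap universe defaults to the supplied gene models;
  enrichment p-values depend on that universe choice and are not
  comparable across universes.
* Directed bait-bait edges are reported without a reciprocity
  requirement; a reciprocal-edge filter is a trivial post-processing step
  left to the user.
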