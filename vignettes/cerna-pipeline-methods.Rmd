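---
title: "Methods: ceRNA network inference from two-group microarray panels"
author: "cernaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference from two-group microarray panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernaflow)
```

## The scientific problem

Long non-coding RNAs can act as competing endogenous RNAs (ceRNAs): by
carrying microRNA response elements they sequester ("sponge") miRNAs and so
relieve the repression those miRNAs exert on their mRNA targets. In a
two-group expression study this hypothesis has an observable signature: if a
lncRNA sponges a miRNA that represses an mRNA, the miRNA's differential
direction between groups should be *opposite* to that of both the lncRNA and
the mRNA. `cernaflow` implements the complete inference chain from raw
microarray intensity panels (mRNA, lncRNA, miRNA) to sponge-consistent
(lncRNA, miRNA, mRNA) triads, for designs such as hippocampal profiling of
mice colonized with microbiota from depressed versus healthy donors — three
pooled samples per group, one array per sample.

## Differential expression

**Normalization.** Each cell is background-subtracted and scaled by its
sample's median: `(foreground − background) / median_s`, where `median_s` is
the per-sample median of `foreground − background` over the analyzed
features. Every sample's median normalized value is therefore 1. Fold change
is the ratio of group means of these values on the linear scale (depression
over healthy by convention, so "up" means up in the depression-microbiota
group); absolute fold change is `max(r, 1/r)`.

**Filters.** Features must carry Present or Marginal detection flags in at
least 3 of 6 samples. miRNA features must additionally reach a mean raw
foreground intensity of at least 30 (boundary inclusive, averaged over all
samples — the rule could also be read per-sample; the mean reading is the
less brittle one and is the package's documented choice). Replicated probe
ids are mean-collapsed before filtering.

**Test.** Normalized values are floored at `1e-6` and log2-transformed, and
each feature gets a two-sample t-test. The default pools the group variances
(`var_equal = TRUE`). This was a genuinely open choice: the Welch form is
also available (`var_equal = FALSE`), but with three arrays per group the
Satterthwaite degrees of freedom drop to 2–4 and the power loss is severe —
under the recovery conditions used in the test suite (fold 2.5, CV 0.1,
3 vs 3, 5% differential), Welch + BH recovers roughly 60% of planted
effects while the pooled test recovers above 90% at an empirical
false-discovery proportion well under 0.10. Identically processed one-color
arrays justify the equal-variance assumption; both forms are exposed.

**Detection-aware weighting.** A cell flagged Absent carries a
background-only measurement; feeding its floored value (log2 ≈ −20) into a
3-vs-3 test destroys the variance estimate of an otherwise clean feature.
Such cells therefore receive zero weight — the same convention as spot
quality weights in array linear-model practice — and both the fold change
and the test use detected cells only. A feature with fewer than two detected
cells in either group is below the design's information limit and gets
`p = 1` by convention.

**Multiple testing and calls.** BH step-up FDR across the tested features of
each panel; a feature is significant when absolute fold change ≥ 1.5 and
FDR < 0.05 (strict). An optional raw-p rescue (`rescue_raw_p`) retains
features that pass the fold-change threshold and have raw `p` below the
rescue cutoff despite `FDR ≥ 0.05`, marked `rescued = TRUE`. It is off by
default; it exists to represent, transparently rather than by silently
widening the FDR threshold, the common practice of carrying a
near-threshold miRNA forward — the packaged fixture tables contain exactly
one such miRNA (FDR 0.066, raw p < 0.05).

**Degenerate inputs.** Two constant groups with equal means give `p = 1`
(with unequal means, `p = 0`); a nonpositive per-sample median aborts
normalization naming the sample; unknown flag symbols are rejected at panel
construction.

## Positional classification and cis targets

lncRNAs are classified against protein-coding gene bodies with precedence
sense_overlap > antisense_overlap > bidirectional > intergenic:

* **sense_overlap** — interval overlap with a coding gene on the same strand;
* **antisense_overlap** — overlap on the opposite strand only;
* **bidirectional** — no overlap, but a coding gene's 5′ start lies
  head-to-head (divergent, opposite strand) within 1 kb of the lncRNA's 5′
  start. The 1-kb window is the conventional bidirectional-promoter
  distance; it is a configurable parameter because no standard fixes it.
* **intergenic** — none of the above. Gene-body (not exon-level) overlap is
  used throughout; exon structure is not modeled.

Intergenic lncRNAs (lincRNAs) get *cis* candidate targets: every coding gene
whose locus lies within 300 kb of the lincRNA locus, measured edge-to-edge
between gene bodies (overlap counts as distance 0), symmetric upstream/
downstream and strand-agnostic. Coordinates are 0-based half-open
internally, BED dialect at the I/O boundary; interval work is delegated to
`GenomicRanges`/`IRanges`.

## Target intersection

Predicted miRNA→mRNA and miRNA→lncRNA relations are inputs (database-export
style tables), not predictions made here — seed matching and binding
energetics are out of scope by design. Intersection with the differential
sets is at the *transcript accession* level, not the gene symbol: one gene
can appear as two transcripts with opposite directions, and accession-level
identity is what makes the packaged tables' distinct-target counts exact.

## Network, modules, hubs

The tripartite network holds only differential features. Edges are typed:
miRNA–mRNA and miRNA–lncRNA target relations, plus mRNA–mRNA edges from a
scored interaction table kept when `score > 0.4` (strict). Symbol-level
interaction edges are expanded onto the mRNA transcript nodes carrying those
symbols. The graph is simple; duplicate rows collapse.

Dense modules are mined with an MCODE-style procedure authored in the
package: each vertex is weighted by the product of its closed neighborhood's
highest k-core number and that core's edge density (vertices under the
degree cutoff score 0); complexes grow greedily outward from the
highest-weight unassigned seed, admitting neighbors whose weight is at least
`(1 − node_score_cutoff)` of the seed weight; complexes without a 2-core are
discarded and haircut trims singly-connected fringes. Defaults are the
algorithm's canonical parameters (degree cutoff 2, node score cutoff 0.2,
k-core 2, haircut on, fluff off). Modules are ranked by density × size.
Hubs are the maximum-degree nodes, ties broken lexicographically.

## ceRNA triads

For every miRNA node, each pair of a lncRNA target and an mRNA target whose
differential directions are both opposite to the miRNA's yields one triad.
"Negative regulation" is deliberately the *sign rule* on differential
directions, not an expression correlation: with three samples per group a
correlation estimate is unstable, and the sign pattern is exactly what a
sponge predicts for a two-group contrast. An optional restriction to a
user-supplied functional gene set (by mRNA symbol) reproduces
function-guided sub-network selection; the package does not attempt to
automate that biological judgement, because no algorithmic criterion is
recoverable for it.

## Enrichment

Term over-representation is the standard upper-tail hypergeometric test: the
probability of at least the observed overlap when drawing `|query|` genes
from the universe, BH-corrected across terms. The default universe is all
annotated coding genes of the bundle. This module is a generic, documented
stand-in for black-box online annotation tools; its term lists depend
entirely on the annotation supplied.

## The synthetic-data generator

`generate_bundle()` emulates the full study input surface with planted
ground truth. What it models:

* **Intensities.** Per-feature baseline `2^N(10, 1.5)` (arbitrary
  fluorescence units); signal is multiplied by log-normal noise with
  coefficient of variation `noise_cv` (mean-corrected); foreground =
  background + signal with background uniform on [10, 30]. Differential
  features have their depression-group signal multiplied (up) or divided
  (down) by `effect_fold`.
* **Flags.** Each cell is Absent with probability `frac_absent` (default
  0.02); Absent cells carry background-only signal, so the flag filter and
  detection weighting have real work to do. The default is read as the
  absence rate among *expressed* probes: wholly undetected probes, the bulk
  of absent calls on a real array, would only be deleted by the flag filter
  and are not simulated. 5% of detected cells are Marginal.
* **Genome.** Each locus sits in its own 3-Mb slot cycling over 19
  autosomes. Overlap-class lncRNAs are placed against dedicated host genes;
  bidirectional lncRNAs sit head-to-head 100–900 bp from a host promoter;
  planted cis lincRNAs sit 50–250 kb from their partner gene; all other
  loci are megabases apart, so planted positional classes and cis pairs are
  exactly recoverable. The class mix defaults to 50% intergenic, 26%
  antisense, 12% sense, 12% bidirectional — the composition reported for
  mouse array lncRNA annotations of this kind.
* **Targets and triads.** Random miRNA target maps (Poisson out-degree,
  mean `targets_per_mirna` for mRNAs, half for lncRNAs) plus one planted
  triad per differential miRNA with distinct partners; a fraction
  `frac_coupled_triads` of them is wired sponge-consistently by
  `plant_sponge_signal()`, which rescales partner group means and updates
  the ground truth. Cis-pair members are pushed into the differential set
  first (budget permitting, i.e. when `round(frac_de·n)` covers them), so
  planted cis pairs are recoverable end to end.
* **Interactions and terms.** Gene–gene edges are sampled at
  `interaction_density` (default 0.002) with Uniform(0,1) confidence
  scores; 25 synthetic terms of 10–60 genes cover the five standard
  categories.

All randomness flows from a single seeded generator; identical
configuration and seed give byte-identical bundles. What the generator does
**not** model: probe-level sequence effects, spatial array artifacts,
dye/batch effects, correlated pooling variance (the three animals pooled per
sample are represented as plain per-sample noise, since the pooling variance
structure is unknowable), exon structure, and real miRNA seed biology.
Passing recovery tests therefore demonstrate that the pipeline's logic is
correct under its stated noise model — not that the thresholds are optimal
for any particular real array platform.

## Problem sizes and numerical choices

The test suite and the acceptance script run the recovery studies at 2000
mRNA features for differential sensitivity (20 seeds, 5% planted, fold 2.5,
CV 0.1) and 600/200/60 features for triad recovery (20 seeds, fold 4, CV
0.05) — sizes chosen so each study exercises the full pipeline while a
complete run stays in the tens of seconds on a laptop. The normalized-value
floor is `1e-6`; BH ties are stable; triad and hub orderings are
lexicographic so all outputs are deterministic given the inputs.

## Known limitations

* Significance calls at n = 3 per group lean on the equal-variance
  assumption; strongly heteroscedastic features are better served by
  `var_equal = FALSE` (at a power cost) or by moderated-variance methods
  outside this package's scope.
* The sign rule cannot distinguish direct sponging from co-regulation; it
  is a screening criterion, as in the ceRNA literature, not causal evidence.
* Enrichment results are only as good as the supplied term annotation; no
  live database access is attempted.
* Features absent in all but one group-cell are reported with `p = 1`
  rather than imputed — a deliberate refusal to manufacture information at
  the design's detection limit.
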