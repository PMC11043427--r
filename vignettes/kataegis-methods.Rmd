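---
title: "Detecting and characterizing kataegis in somatic SBS catalogs"
author: "katascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing kataegis in somatic SBS catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(katascan)
```

## The phenomenon and the detection model

Kataegis is localized somatic hypermutation: a short genomic region in
which a tumor accumulates a dense cluster of single base substitutions
(SBSs), typically strand-coordinated C>T and C>G changes in a TpC context.
The mechanism is attributed to APOBEC cytidine deaminases acting
processively on transiently single-stranded DNA, which is why member
substitutions of one cluster tend to share a strand and why pooled cluster
spectra are dominated by the C>T/C>G classes (the signature SBS2/SBS13
pattern).

The operational definition is a run rule on the intermutation distance
(IMD), the genomic distance between consecutive SBSs of one sample on one
chromosome. Two variants circulate in the literature and both are
implemented:

* **max rule** (default): a locus is a maximal run of at least `minSbs`
  (default 6) consecutive SBSs in which *every* adjacent IMD is at most
  `imdThreshold` (default 1000 bp). This is the rule detection tools apply
  in practice, and the default here for that reason.
* **mean rule**: every window of at least `minSbs` consecutive SBSs whose
  *mean* adjacent IMD is at most the threshold qualifies; since adjacent
  gaps telescope, the mean is `(pos_last - pos_first) / (n - 1)`.
  Overlapping qualifying windows are merged by union into maximal disjoint
  loci, which makes the output deterministic and partition-like without
  tie-breaking.

The two rules differ exactly on catalogs where a long internal gap is
averaged away: positions `0, 100, 200, 300, 5300, 5400, 5500` contain no
6-run with all gaps below 1000 bp, but the full 7-SBS window has mean IMD
`5500/6 ~ 917` and is one locus under the mean rule. The test suite checks
both rules against brute-force window enumeration, exhaustively at small
catalog sizes and on a thousand random catalogs.

IMDs are never computed across chromosome or sample boundaries.
Same-position records with different alternate alleles (multi-allelic
sites) are kept and contribute an IMD of zero; exact duplicate records are
removed at read time with a logged count, since those are pipeline
artifacts rather than biology.

### Confidence tiers

Published analyses filter loci at "confidence >= 1" of the upstream
detection tool, whose scoring formula is not public. `katascan` therefore
defines an explicit, deterministic surrogate documented here: tier 1 =
passes detection; tier 2 = at least 70% of member substitutions are
pyrimidine C>N after normalization (APOBEC-consistent); tier 3 = tier 2
with at least 10 members. With the default filter (`minConfidence = 1`)
the surrogate is a no-op for headline analyses, which keeps results
comparable while making stricter filtering reproducible.

### Coordinates, chromosomes, and conventions

Variant positions are 1-based inclusive (VCF convention); annotation
tracks and genome bins are 0-based half-open (BED convention). Conversion
happens exactly once, at comparison time: an SBS at 1-based position *p*
is inside a BED interval `[s, e)` iff `p - 1` is. Chromosome names are
harmonized against the genome build (a `chr` prefix on either side is
tolerated). Canonical ordinals map X to 23 and Y to 24: the binary status
rule counts events on ordinals 1-23, per-chromosome and bin-recurrence
views default to 1-22, and Y loci are always filtered. Trinucleotide
context is optional throughout; without a sequence source, spectra are
reported at 6-class resolution, which is the resolution the headline
spectrum figures use.

## Characterization

* **Merged spectra** pool every member SBS of every locus of a subgroup
  into one set before tabulating the 6 pyrimidine-normalized classes;
  spectra are additive over disjoint locus sets and proportions sum to 1.
* **Locus sizes** are reported as raw spans (bp) and member counts with
  quantiles; kernel smoothing seen in figures is a plotting device and is
  deliberately not part of the computation.
* **Bin recurrence** tiles the genome into half-open bins of constant
  width (default 2 Mb; the last bin of each chromosome is truncated, never
  dropped, so every base belongs to exactly one bin). Each locus maps to
  exactly one bin by its midpoint, `floor((start - 1 + end) / 2)` in
  0-based coordinates — the mapping point is not specified in the
  literature, and the midpoint is the unambiguous choice given that locus
  spans (typically a few kb) are far below the bin width. Event frequency
  divides bin counts by *all* tumors of the group, kataegis-negative
  included. Multiple loci of one tumor in one bin count as multiple
  events.

## Context enrichment

For an annotation track (open chromatin, DHS, repeats, chromatin states,
...), three SBS pools are compared per subgroup: kataegis-associated SBSs
of kataegis-positive tumors, all SBSs of kataegis-positive tumors, and all
SBSs of kataegis-negative tumors. SBSs are pooled across tumors with equal
weight per SBS (not per tumor), matching how subgroup context bars are
built. The enrichment ratio is the kataegis proportion divided by the
all-SBS proportion of the positive tumors; tracks are treated
independently (an SBS may belong to many), and no hypothesis test is
attached — the quantity is descriptive. Note that because kataegis SBSs
are part of the positive tumors' all-SBS pool, an injected placement
enrichment of *E* is recovered as slightly below *E*; the effect is
negligible when clustered SBSs are a small fraction of the total burden,
as they are in real cohorts.

## Cohort statistics

Binary kataegis status is positive when the event count on ordinals 1-23
reaches the cut-off (default 1); frequency-vs-cut-off curves are monotone
non-increasing by construction. TMB is `(SBS + indel) / Mb`; the
denominator defaults to the sum of the genome build's chromosome lengths
and is configurable because "callable genome" definitions vary.

Metagene rank scores are single-sample statistics: all measured genes are
ranked ascending within the sample (average ranks for ties) and a module's
score is the mean member rank divided by the gene count, in (0, 1], with
no cross-sample centering. This is a documented reconstruction of the
cited scoring approach; the orientation is higher expression, higher
score.

Association tests delegate to R's reference implementations behind stable
wrappers: Wilcoxon rank-sum (exact only when both groups have at most 8
tie-free observations, otherwise normal approximation with tie and
continuity corrections), tie-corrected Kruskal-Wallis, and Pearson
chi-square with the continuity correction OFF by default for every table
size — one consistent rule, with Yates correction available by flag, since
published analyses rarely state which variant their tooling applied.
Driver-gene association uses per-gene 2x2 chi-square against binary
status with Benjamini-Hochberg adjustment per subgroup panel; genes with a
zero marginal are flagged degenerate and excluded from the BH family with
a logged count. All p-values are two-sided. Type-I error of all three
tests is verified at the 5% level to within one percentage point over
10,000 null replicates.

## The synthetic cohort generator

Real WGS breast cancer cohorts are controlled-access, so every stage is
validated on a seeded simulator whose defaults are the study conditions:

* **Genome**: 23 chromosomes totaling ~300 Mb (a tenth of human scale, so
  hundred-sample cohorts simulate in seconds). All rates are per Mb and
  transfer across genome sizes; experiments that need realistic
  per-sample SBS totals (e.g. enrichment recovery) pass a ~3 Gb
  chromosome set instead.
* **Background**: uniform per-chromosome SBS positions at 1 per Mb per
  sample by default, with a +25% rate in kataegis-positive samples to
  emulate the reported TMB association (the direction is reported; the
  magnitude is a modeling choice made once).
* **Subgroups**: positivity probabilities TNBC 0.38, ERpHER2n 0.48,
  ERpHER2p 0.94, ERnHER2p 0.89 — the reported binary frequencies, used as
  *inputs to recover*, never as reproduction targets — with subgroup
  sizes 60/80/12/8 mirroring the relative cohort sizes.
* **Clusters**: per positive sample 1 + Geometric(0.5) loci (mean 2);
  cluster sizes uniform 6-25; adjacent spacing uniform 10-300 bp; member
  classes C>T 0.45, C>G 0.40, remainder split evenly; one strand per
  cluster (processive deamination), which pyrimidine normalization must
  erase in 6-class spectra — itself a test.
* **Tracks and hotspots**: each track covers a configured fraction of
  every chromosome; one track may carry a placement enrichment factor
  *E*, steering cluster placement into it with probability
  `E x coverage`. An optional hotspot window captures recurrence
  structure.
* **Drivers and expression**: per-gene alteration flags follow a logistic
  model in true status (default one gene at odds ratio 4 among nulls);
  expression is log-scale Gaussian with status-conditional mean shifts on
  metagene members.

What the simulator does *not* emulate — replication-timing and
chromatin-covariate mutation-rate variation, rearrangement co-location,
96-channel signature realism — bounds what passing tests show: they
validate the detection, counting, and statistical machinery, not the
biological fidelity of any particular cohort.

`truthMatch()` scores detection against ground truth: a truth locus is
recovered when a detected locus overlaps it reciprocally by at least 50%
or contains all member positions; detected loci matching no truth locus
are false calls. Under the max rule, a cluster isolated from background by
more than the IMD threshold is recovered with exact boundaries; under the
mean rule the absorption radius scales with cluster size (a window may
average a distant background SBS into a large cluster), so exactness is
only guaranteed at isolation beyond roughly `threshold x nSbs`.

## Numerical and degenerate-input choices

Empty catalogs, empty subgroups, and empty pools return explicitly flagged
empty results rather than errors (`defined = FALSE`, `NA` proportions).
Zero-marginal contingency tables and all-equal Kruskal-Wallis inputs are
flagged degenerate. Threshold comparisons use `<=` on exact integer
positions, so integer thresholds involve no floating-point ambiguity.
Locus member indexing references the catalog's canonical sort (sample,
chromosome order, position, ref, alt), making every result invariant to
input row order. The pipeline writes no timestamps, so identical inputs
produce byte-identical outputs.

## Problem sizes used in validation

The shipped validation uses: 1000 random catalogs of up to 500 SBSs for
detector-oracle equivalence; 100-sample cohorts for injection recovery
(clusters of 8-20 SBSs over 1 SBS/Mb background) and null calibration
(2 SBS/Mb, zero positivity); 200 samples per subgroup for positivity
recovery; ~5700 clustered SBSs for spectrum recovery; and a ~3 Gb genome
with 200 positive tumors of ~6000 SBSs each (clustered SBSs under 2% of
the burden, as in real cohorts) for enrichment recovery, where the
expected ratio is 2 x (1 - K/(B+K)) ~ 1.96 for K clustered among B+K
total SBSs. These sizes were chosen by error propagation so that each
recovered quantity sits several standard errors inside its acceptance
band.

## Limitations

The confidence tiering is a surrogate, not the unpublished original
score. The mean-rule locus definition (union of overlapping qualifying
windows) is one of several defensible conventions; it was chosen for
determinism and disjointness. Promoter/intron/intergenic-style locus
annotation is supported only through user-supplied BED tracks — no gene
model is bundled, and no priority scheme between overlapping annotations
is imposed. Survival analysis, signature fitting, differential expression,
and subtype classification are out of scope; their outputs are consumed as
metadata where relevant.
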