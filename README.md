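# katascan

Kataegis detection and cohort-level analysis for somatic single base
substitution (SBS) catalogs.

Kataegis is localized somatic hypermutation: a cluster of closely spaced
SBSs — typically strand-coordinated C>T and C>G changes in a TpC context,
attributed to APOBEC cytidine deaminases — observed in many cancers and at
high frequency in breast cancer. Cohort studies ask how often tumors carry
such events, where in the genome they recur, whether the SBSs inside them
prefer particular genomic contexts (open chromatin, repeats, chromatin
states), and how a tumor's binary kataegis status associates with clinical
subgroup, mutational burden, driver alterations, and expression programs.
`katascan` implements that analysis as a tested, reusable pipeline for
anyone with per-sample SBS calls (VCF, MAF-like, or plain TSV) and a
genome description.

## The core rule

A kataegis locus is a run of at least *m* consecutive SBSs of one sample on
one chromosome whose intermutation distances (IMD; distance between
consecutive SBSs) satisfy a threshold rule. With defaults *m* = 6 and
*t* = 1000 bp:

* **max rule** (default): every adjacent IMD in the run is ≤ *t*; loci are
  the maximal such runs.
* **mean rule**: a window of *n* ≥ *m* SBSs qualifies when
  (pos_last − pos_first)/(n − 1) ≤ *t*; overlapping qualifying windows are
  merged into maximal disjoint loci.

Each locus carries span, member count, mean/max IMD, a 6-class
substitution spectrum, and a deterministic APOBEC-consistency confidence
tier. Downstream: binary status per tumor (≥1 event on chromosomes 1–23),
frequency-vs-cut-off curves, merged subgroup spectra, per-chromosome
counts, 2-Mb bin recurrence, annotation-track enrichment ratios
(kataegis SBS proportion / all-SBS proportion), TMB, single-sample
metagene rank scores, and Wilcoxon / Kruskal–Wallis / chi-square
association tests with Benjamini–Hochberg adjustment.

A seeded simulator (`simulateCohort`) generates cohorts with known ground
truth — uniform background SBSs, injected APOBEC-like clusters,
subgroup-dependent positivity, enriched annotation tracks, driver flags,
metagene-structured expression — so every stage is testable without
controlled-access tumor data.

## Worked example

```r
library(katascan)

sim <- simulateCohort(simulationConfig(seed = 42))
sim$catalog
#> SbsCatalog: 57792 SBS records, 160 sample(s), genome 'synthetic'

loci <- filterLoci(detectKataegis(sim$catalog), genome = sim$genome)
length(loci)
#> [1] 215
head(lociTable(loci), 3)
#>   sample chromosome   start     end n_sbs span_bp mean_imd max_imd confidence
#> 2  S0001      chr19  685001  686023     8    1023 146.0000     265          2
#> 1  S0001       chr2 1247143 1249159    11    2017 201.6000     283          1
#> 3  S0002       chr8  693836  697087    23    3252 147.7727     267          3
```

215 loci are detected across 160 tumors. Binary kataegis frequency per
simulated clinical subgroup (positivity parameters 0.38 / 0.48 / 0.94 /
0.89 went into the simulation):

```r
status <- classifyBinary(loci, sim$metadata$sample, genome = sim$genome)
tapply(status, sim$metadata$subgroup, mean)
#>  ERnHER2p  ERpHER2n  ERpHER2p      TNBC
#> 1.0000000 0.5750000 0.9166667 0.4833333
```

The merged spectrum of all member SBSs recovers the injected APOBEC-like
class distribution (C>T 0.45, C>G 0.40):

```r
round(mergedSpectrum(loci)$proportions, 3)
#>   C>A   C>G   C>T   T>A   T>C   T>G
#> 0.041 0.399 0.451 0.035 0.035 0.039
```

Enrichment of kataegis SBSs in the simulated open-chromatin track (10% of
the genome, placement enrichment 2): 16.5% of kataegis SBSs fall in the
track versus 10.5% of all SBSs in kataegis-positive tumors — an
enrichment ratio of 1.57 at this desk-scale cohort, where clustered SBSs
make up ~9% of the positive tumors' burden and therefore inflate the
denominator (see the methods vignette for the exact expectation):

```r
cp <- contextProportions(sim$catalog, loci, sim$tracks$ATAC)
enrichmentRatio(cp)
#>      ratio p_kataegis p_all_positive defined
#> 1 1.567162  0.1648999       0.105222    TRUE
```

`runPipeline()` executes all stages on a cohort and writes one TSV per
result table plus a JSON manifest; `inst/scripts/katascan.R` wraps
`simulate`, `detect`, and `run` for shell use.

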