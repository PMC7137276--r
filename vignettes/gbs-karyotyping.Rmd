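---
title: "Read-depth karyotyping from GBS tag counts: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth karyotyping from GBS tag counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbskaryo)
```

## The estimator

Genotyping-by-sequencing reduces a genome to the neighborhoods of
restriction-enzyme cut sites. For a large-genome polyploid like bread
wheat, the set of uniquely mapped GBS tags is dense enough (hundreds of
thousands of anchored tags genome-wide) that the tag count in a large
genomic window is, to first order, proportional to

* the number of tag sites in the window (a fixed genome property),
* the sample's overall sequencing depth, and
* the copy number of the window in that sample.

The first two factors are nuisances; the method removes them with two
normalizations and reads the copy number off what remains.

With `c(b, s)` the retained-tag count of sample `s` in window `b`:

1. **Across-sample total normalization** rescales each sample's counts so
   all samples have the same total. The common target is the *median* of
   the per-sample totals. The data this emulates have heavily skewed,
   multi-modal per-sample totals (different flowcells and library plates),
   so a robust target is the natural choice — but the choice is provably
   immaterial: any common target cancels in step 2. The package asserts
   this as a test (multiplying one sample's raw counts by an arbitrary
   constant leaves every final value unchanged).
2. **Per-bin median normalization** divides each bin by its median across
   samples. The median plays the role of the "2-copy reference panel":
   whatever the local site density or mappability, most samples are
   disomic there, so the median is the 2x level and the normalized value
   `v(b, s)` estimates copy number / 2.

`v` is then classified with fixed, lower-inclusive thresholds:

| interval | class |
|---|---|
| [0, 0.25) | 0x |
| [0.25, 0.75) | 1x |
| [0.75, 1.25) | 2x |
| [1.25, 1.75) | 3x |
| [1.75, 2.25) | 4x |
| [2.25, 2.75) | 5x |
| [2.75, ∞) | 6x+ |

### Key assumption: disomic majority

The per-bin median is only a 2x reference if, at every bin, more than half
the cohort is disomic. A deletion or duplication shared by the majority of
samples is invisible (the median shifts with it) or, if every sample has
zero counts, the bin is *masked* (no-call) rather than divided by zero.
Masked bins propagate as no-calls; they never silently become dosage 0.
The simulator warns when a generated cohort violates the majority
assumption.

### A second-order effect worth knowing

The total normalization uses the sample's *genome-wide* tag total, which
itself shifts when the sample carries large aberrations. A sample
tetrasomic for a chromosome holding fraction `f` of the genome's tag sites
has `1 + f` times the expected total, so its normalized values are
attenuated by that factor: the tetrasomic chromosome sits near
`2 / (1 + f)` rather than 2.0. For wheat (21 chromosomes, `f ≈ 0.05`) the
attenuation is a few percent and harmless against the ±0.25-wide class
intervals; on toy genomes with very few chromosomes it can move a value
across a class boundary. The test suite computes expected values with this
factor included, and the bundled simulation genome keeps 21 chromosomes so
the fraction stays realistic.

## Window geometry

Windows are `bin_size` wide (default 100 Mb) and slide by `step_size`
(default 50 Mb), so interior positions are covered by exactly two windows;
a tag in an overlap region counts in both. Windows are truncated at
chromosome ends and the short terminal windows are *kept*: the per-bin
median normalization cancels their smaller expected counts, and dropping
them would blind the method to precisely the terminal deletions it is best
at detecting. All internal coordinates are 0-based half-open; 1-based SAM
positions are converted once at ingest.

Because analysis windows overlap, any per-window quantity must be reduced
to a disjoint track for reporting and plotting. Both the ideogram renderer
and the event caller use the *step grid*: each window represents its
`[start, start + step)` interval (the window starting at each step
boundary wins; a max-dosage reduction is available as an option). This
makes plotted segments tile each chromosome exactly and keeps event calls
non-overlapping. The cost is that an event boundary is resolved no finer
than one step.

## Ingest filters

A SAM record becomes a tag iff it is mapped, primary (neither secondary
nor supplementary), carries **no `XS:i` optional field**, maps to a
chromosome listed in the genome definition, and has a valid position.
Absence of `XS:i` — the aligner's second-best score — is the operational
definition of "uniquely mapped" here; MAPQ is deliberately not thresholded
(a MAPQ filter is a different, stricter definition and would change the
retained set; the equivalence oracle in the tests is a literal grep-style
reimplementation of the rule). Records on scaffolds absent from the genome
definition are dropped silently but counted: each ingest returns an
accounting vector (unmapped/non-primary, multimapped, unanchored, invalid
position) and the CLI writes it to the run log, so a cohort's raw →
retained funnel is always auditable.

One retained record counts as one tag: the upstream tag pipeline has
already collapsed reads into unique tags. For SAM files that instead carry
per-read records with a tag-depth annotation, `weight_by_depth = TRUE`
reads an integer `dp` tag as the record weight (a package convention —
there is no standard SAM tag for tag depth).

## QC, classification and event calling

* `min_tags` (default **10,000** retained tags) gates samples: below it a
  karyotype is mostly noise. The motivating dataset's failures carried
  1,868 and 14 tags against a cohort median around 205k; the default sits
  well between failure and typical scale and is configurable.
* Threshold boundaries are half-open so classification is a total,
  monotone partition of `[0, ∞)`; the boundary convention only matters on
  a measure-zero set.
* `call_events` merges maximal runs of equal non-2x class within a
  chromosome. No-call bins are transparent: they bridge two runs of equal
  class (but do not count toward run length). Runs shorter than
  `min_run_length` (default **2** bins, i.e. one full window of evidence)
  are suppressed. The default exists because centromeric windows are
  systematically undersampled — methylation-sensitive GBS enzymes rarely
  cut in centromeric heterochromatin — so isolated flips around
  centromeres are expected noise, and single-bin events are not trustable
  without corroboration. Setting `min_run_length = 1` reproduces the pure
  per-bin classification.
* Labels: whole-chromosome runs get aneuploidy names (nullisomic /
  monosomic / trisomic / tetrasomic / pentasomic, "polysomic" beyond);
  runs of class 0 or 1 touching one chromosome end are "terminal
  deletion" (class 1 annotated heterozygous/single-copy); everything else
  is "segmental". If a centromere is annotated and a terminal run's
  interior boundary falls within one bin of it, the label gains
  "[arm-level]" — the signature of a ditelosomic stock. There is no
  dedicated ditelosomic genotype model.
* No HMM, no smoothing, no significance statistics: classification is per
  bin, runs are deterministic. This mirrors the method's origin as a
  visual-inspection aid; an HMM over bins is an obvious extension but out
  of scope here, and the hard thresholds make every call exactly
  reproducible.

## The simulator

The simulator is the package's test and acceptance surface: it generates
tag positions with known copy-number truth.

* **Sites** are placed uniformly per chromosome at `site_density` sites/Mb
  and thinned near annotated centromeres (retention probability
  `1 − centromere_depletion` within `centromere_radius_bp`). Defaults:
  **32 sites/Mb**, matching roughly 450k anchored tags over a ~14 Gb
  hexaploid genome; **depletion 0.8** within a **25 Mb** radius, a
  deliberately strong depletion so the centromeric-noise behaviour of the
  caller is exercised. The site list is a genome property, shared by all
  samples — exactly like real restriction sites.
* **Samples** observe each site independently with probability
  `min(1, base_rate · depth · m)`, where `base_rate = mean_tags / n_sites`
  calibrates a depth-1 euploid sample to `mean_tags` expected tags,
  `depth` is log-normal with `sd = dispersion` (default **0.5**, mean 1),
  and `m` is the copy-number multiplier from the sample's aberration spec
  (1 = disomic, 0.5 = monosomic, 2 = tetrasomic, ...). The log-normal
  emulates the heavy skew of real per-sample totals across sequencing
  batches; at the default rates the `min(1, ·)` cap is essentially
  inactive below 4x.
* **Truth** is `2 × m` per bin; bins straddling a region boundary take the
  length-weighted majority multiplier.
* Everything is seeded: one master seed derives per-sample seeds, and
  identical seeds give byte-identical tag tables (asserted in tests).

What the simulator does **not** emulate — and therefore what passing tests
do not certify about real data: non-uniform restriction-site spacing and
fragment-size selection, PCR amplification bias correlated with sequence
content, batch structure beyond a scalar depth factor (no flowcell/plate
covariates), multi-mapping ambiguity beyond simple `XS:i`-tagged decoys,
and any sequence-level artifacts (no reads are simulated at all, only
positions). Real cohorts can produce hard-to-interpret karyotypes — e.g.
genome-wide apparent 1x from uneven coverage — that the simulator will not
reproduce; the QC gate catches only the low-total part of that space.

The toy genome (`toy_wheat_genome()`) has 21 chromosomes named like
hexaploid wheat with realistic relative lengths; `scale = 0.1` gives a
1:10 genome used throughout the tests with 10 Mb / 5 Mb windows (same bin
count as full scale with 100/50 Mb — windows are parameters everywhere,
never hard-coded). Test and acceptance cohorts use 10–20 samples at a mean
of 20k–100k tags, sizes at which per-bin counts are a few hundred to a few
thousand and class boundaries sit several standard deviations from
expected values; the end-to-end recovery suite runs ten seeds at 20
samples × 100k tags and requires ≥ 99% of unmasked, non-centromeric bins
to match truth.

## Numerical conventions

* Median with an even number of samples is the mean of the two central
  order statistics (R's default); the per-bin median of normalized values
  is then *exactly* 1 for unmasked bins, asserted at 1e-9.
* Zero-median bins are masked, zero-total samples are a hard error
  directing the caller to QC exclusion (they cannot be depth-normalized).
* Modal per-chromosome dosage breaks ties toward the class nearest 2 —
  prefer the least surprising karyotype.
* Plot geometry is computed in data coordinates and unit-tested without
  rendering; images are a deterministic function of the track, the genome
  and the palette (2x is neutral grey so aberrations pop; deletions warm,
  gains cool; no-call white).

## Known limitations

* Aberrations shared by more than half the cohort are misread or masked
  (median-reference assumption).
* Breakpoints are resolved to one step (50 Mb at defaults, 5 Mb on the
  1:10 toy genome); no sub-bin refinement.
* Centromeric bins are noisy by construction of GBS; single-bin variation
  there should not be trusted unless it continues into a terminal
  aberration — the `min_run_length` default implements exactly that
  caveat.
* Interior ("segmental") calls and dosage classes above 4x are reported
  but were not the method's design target; treat them as screening
  output.
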