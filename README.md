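# gbskaryo

Read-depth karyotyping of aneuploidy and chromosomal deletions from
genotyping-by-sequencing (GBS) data.

## The problem

Wheat tolerates whole-chromosome aneuploidy and large deletions, and
collections of such aneuploid and deletion stocks (nullisomic, monosomic,
trisomic, tetrasomic, ditelosomic and terminal-deletion lines) are a core
resource for locating genes on chromosomes. Curating these stocks has
traditionally required cytogenetics (C-banding, FISH/GISH), which is slow
and low-throughput. Because GBS samples a reproducible set of
restriction-site tags across the genome, the *number of uniquely mapped
tags per genomic window* is proportional to the copy number of that window
— so a cheap GBS assay doubles as a karyotype. `gbskaryo` implements that
read-depth karyotyping for whole cohorts: SAM in, dosage calls and
karyotype ideograms out. It is aimed at genetic-stock curators and anyone
using shallow reduced-representation sequencing to screen for dosage
variants in large-genome crops.

## The method

For sample *s* and genomic window *b* (100 Mb wide, sliding by 50 Mb by
default), let *c(b,s)* be the number of retained tags (uniquely mapped:
no `XS:i` secondary-score field; anchored to a real chromosome). Two
normalizations put all samples on a common dosage scale:

1. **Depth**: every sample is rescaled to the cohort's median tag total,
   `c'(b,s) = c(b,s) · T/T(s)`.
2. **Per-bin median**: `v(b,s) = c'(b,s) / median_s c'(b,s)`.

Since most samples are disomic (2x) at any given bin, the per-bin median is
the 2-copy reference and *v* estimates half the copy number: v ≈ 0.5 at 1x,
1.0 at 2x, 1.5 at 3x, 2.0 at 4x. Values are classified with fixed
thresholds (`[0, 0.25) → 0x`, `[0.25, 0.75) → 1x`, `[0.75, 1.25) → 2x`,
`[1.25, 1.75) → 3x`, `[1.75, 2.25) → 4x`, `[2.25, 2.75) → 5x`,
`≥ 2.75 → 6x+`), runs of aberrant bins are merged into whole-chromosome
aneuploidy and terminal/segmental deletion calls, and each sample is drawn
as a color-coded ideogram with centromere markers. A seeded simulator with
known copy-number truth makes the whole pipeline testable without any
sequencing data.

## Worked example

Simulate a 12-sample cohort on a wheat-like 21-chromosome genome at 1:10
scale, with one complex stock lacking both copies of 1A, carrying four
copies of 1B, and monosomic for 4A — then karyotype it:

```r
library(gbskaryo)

g <- toy_wheat_genome(scale = 0.1)
specs <- c(lapply(1:11, function(i) aberration_spec(sprintf("euploid%02d", i))),
           list(aberration_spec("stock278", regions = data.frame(
             chrom = c("1A", "1B", "4A"), start = NA, end = NA,
             multiplier = c(0, 2.0, 0.5)), genome = g)))
sim <- simulate_cohort(g, specs, bins = make_bins(g, 10e6, 5e6),
                       site_density = 320, centromere_radius_bp = 2.5e6,
                       mean_tags = 1e5, seed = 11)
fit <- gbs_karyotype(sim$tags, g, bin_size = 10e6, step_size = 5e6)
fit
```

```
GBS read-depth karyotype fit
  genome:     21 chromosomes, 1,405,500,000 bp
  bins:       291 windows of 10 Mb, step 5 Mb; 0 masked
  samples:    12 ( 0 QC-failed at min_tags = 10,000 )
  events:     3 aberration call(s) in 1 sample(s)
```

```r
subset(fit$events, sample == "stock278")
```

```
   sample chrom start      end dosage      label n_bins terminal whole_chromosome
 stock278    1A     0 59400000      0 nullisomic     12     TRUE             TRUE
 stock278    1B     0 68900000      4 tetrasomic     14     TRUE             TRUE
 stock278    4A     0 74400000      1  monosomic     15     TRUE             TRUE
```

All three engineered aberrations are called, each spanning its whole
chromosome: `dosage` is the copy-number class (0 = no copies, 1 =
monosomic, 4 = tetrasomic), `n_bins` the number of aberrant windows
supporting the call. `plot(fit, sample = "stock278")` draws the ideogram
(1A in the deletion color, 1B in the 4x color, 4A in the 1x color;
centromeres as line-plus-diamond). `modal_dosage(fit, "stock278", "1B")`
returns `4`.

The same pipeline runs from the shell on SAM files via the bundled script:

```sh
inst/scripts/gbskaryo pipeline --genome genome.tsv --sam-map samples.tsv --out run/
```

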