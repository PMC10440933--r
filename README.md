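# rohscan

Runs of homozygosity (ROH), genomic inbreeding and ROH islands from
multi-sample diploid genotypes.

A ROH is a contiguous genomic stretch where an individual's two
inherited haplotypes are identical, the footprint of autozygosity.
`rohscan` is aimed at population geneticists working with small
multi-population WGS cohorts (livestock, wildlife, companion species)
who want, from one VCF:

* per-individual ROH segments from a sliding-window scan
  (PLINK `--homozyg`-style semantics: a window of 50 consecutive
  variants is homozygous iff it has ≤ 3 heterozygous and ≤ 1 missing
  calls; eligible runs are gap-split at 500 kb, end-trimmed, and kept
  at ≥ 15 variants, ≥ 100 kb, ≤ 50 kb/variant spacing);
* the genomic inbreeding coefficient
  **F_ROH = L_ROH / L_aut** — the fraction of the autosomal genome
  covered by ROH;
* **ROH islands**: regions where ≥ 70% of a population carries a ROH,
  a standard screen for selection signatures, annotated with the genes
  (BED/GFF3) they overlap;
* per-species summary tables (short 100–500 kb and long > 500 kb
  classes) with one-way ANOVA across species;
* population structure from identity-by-state distances and classical
  MDS;
* QC on the way in: sample call-rate ≥ 99%, PI-HAT ≥ 0.5 relatedness
  removal, and (for the structure branch only) MAF ≥ 5% and
  `--indep-pairwise`-style LD pruning — the ROH branch deliberately
  stays unpruned.

Everything is tidyverse-shaped: results are tibbles, fitted objects
have `tidy()`/`glance()` methods, and `autoplot()`/`plot_*()` give
ggplot2 figures. A built-in simulator (Balding–Nichols population
divergence, planted autozygous tracts, genotyping error, missingness,
admixed individuals) provides ground truth for validation.

## Worked example

Simulate a 3-species cohort (18 samples, 2 × 4 Mb chromosomes, 1,200
variants each) with one tract shared by 90% of species 1, then run the
whole pipeline:

```r
library(rohscan)
library(dplyr)

cfg <- sim_config(
  n_populations = 3, n_per_population = 6, n_chromosomes = 2,
  chrom_length_bp = 4e6, n_variants_per_chrom = 1200, fst = 0.1,
  shared_roh = data.frame(population = 1, carrier_fraction = 0.9,
                          chrom = 1, start_bp = 1e6, end_bp = 1.5e6),
  n_random_roh = 1, random_roh_min_bp = 2e5, random_roh_max_bp = 5e5,
  het_error_rate = 0.002, missing_rate = 0.005, seed = 42)

res <- run_pipeline(tempfile("rohscan_demo_"), sim = cfg,
                    ld_window = 300, ld_step = 100)

res$segments |> count(length_class)
#> 1 100-500         15
#> 2 >500             8

res$froh |> group_by(species) |> summarise(mean_froh = mean(f_roh))
#> 1 pop1       0.106
#> 2 pop2       0.0549
#> 3 pop3       0.0486

res$islands |> select(species, chrom, start_bp, end_bp,
                      pct_population, n_variants, genes_label)
#> 1 pop1    chr1    967568 1508078             83        172 GENE_SHARED_1
```

The island table reads like a selection-signature report: 83% of
species 1 (5 of 6 samples) share a ROH over the planted 1.0–1.5 Mb
tract on chr1, spanning 172 analysis-set variants and overlapping the
synthetic gene placed inside it. Species 1 also shows elevated
inbreeding (mean F_ROH 0.106 vs ~0.05), driven by the shared tract,
and the cross-species ANOVA flags the difference:

```r
res$anova
#> 1 n_segments      25        2    15 0.0000167
#> 2 mean_segment_kb  1.51     2    15 0.252
#> 3 f_roh           22.8      2    15 0.0000285
```

`run_pipeline()` also writes every table (segments, F_ROH, summaries,
islands, MDS coordinates, QC reports, a JSON run manifest) as TSV into
the output directory; reruns with the same configuration are
byte-identical.

For real data, pass files instead of a simulation config:

```r
run_pipeline("out/", vcf = "cohort.vcf", sample_map = "samples.tsv",
             chrom_lengths = "chroms.tsv", genes = "genes.gff3")
```

## Documentation

The methods vignette (`vignettes/roh-methods.Rmd`) describes the
model and algorithm choices in detail: window-scan semantics, QC
boundaries, the island sweep, what the simulator does and does not
emulate, and known numerical edge cases.
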