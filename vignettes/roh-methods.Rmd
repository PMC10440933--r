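---
title: "Detecting runs of homozygosity, genomic inbreeding and ROH islands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting runs of homozygosity, genomic inbreeding and ROH islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
library(dplyr)
```

## The problem

A run of homozygosity (ROH) is a contiguous stretch of the genome in
which the two haplotypes an individual inherited are identical —
typically because both descend from a single recent common ancestor
(autozygosity). The length distribution of ROH carries demographic
information: many short ROH point to ancient bottlenecks or founder
effects, while long ROH indicate recent inbreeding. Two population-level
statistics are built on top of the per-individual segments:

* the **genomic inbreeding coefficient**
  \(F_{ROH} = L_{ROH} / L_{aut}\), the fraction of the autosomal genome
  covered by an individual's ROH, and
* **ROH islands**: genomic regions where a large fraction of a
  population (here, at least 70%) carries a ROH. Because drift alone
  rarely pushes the same haplotype to homozygosity in most of a
  population, such islands are interpreted as candidate signatures of
  selection and are annotated with the genes they overlap.

`rohscan` implements this pipeline for diploid, biallelic genotype data
read from a multi-sample VCF: quality control (call-rate filtering,
relatedness pruning via PI-HAT, minor-allele-frequency and
linkage-disequilibrium filters for the structure branch), a
sliding-window ROH caller, \(F_{ROH}\), per-species summary tables with
one-way ANOVA comparisons, island detection with gene annotation, and
population structure via identity-by-state (IBS) distances and
classical multidimensional scaling (MDS). A genotype simulator with
planted autozygous tracts provides ground truth for every stage.

## The ROH caller

The caller follows the widely used sliding-window semantics of PLINK's
`--homozyg` scan.

1. **Window scan.** A window of `window_snp` consecutive variants
   (default 50) slides along each chromosome of each sample. A window
   is *homozygous* iff it contains at most `window_het` heterozygous
   calls (default 3) and at most `window_missing` missing calls
   (default 1). A variant is *ROH-eligible* iff at least
   `window_threshold` (default 0.05) of the windows containing it are
   homozygous. Chromosomes with fewer than `window_snp` variants are
   scanned with a single window spanning all variants.
2. **Run assembly.** Maximal runs of consecutive eligible variants are
   split wherever the gap between adjacent variants exceeds
   `max_gap_kb` (default 500 kb), then trimmed so that the first and
   last variant of each run is a homozygous non-missing call.
3. **Filters.** A run becomes a segment iff it carries at least
   `min_snp` non-missing variants (default 15), spans at least
   `min_kb` (default 100 kb, computed as
   \((\mathrm{end} - \mathrm{start} + 1)/1000\) from the first and
   last variant positions, 1-based inclusive), and its average spacing
   `length_kb / n_variants` does not exceed `density_kb_per_snp`
   (default 50 kb per variant).

The five thresholds that matter most — 100 kb minimum length, 15
variants, 500 kb maximum gap, 1 missing and 3 heterozygous calls per
window — are a parameterization commonly used for livestock data,
where WGS variant density is high and genotyping error makes a small
heterozygote allowance inside true autozygous tracts necessary. The
remaining knobs (`window_snp` 50, `window_threshold` 0.05, density
50 kb/variant) are the scanner's conventional defaults; all are
exposed through `roh_params()`.

Two decisions the scan itself does not dictate were fixed as follows:
missing calls inside a run do not break it (the window limits already
police them) but do not count toward `n_variants`; and segments are
binned into a `[100, 500]` kb class (closed at both ends — a segment of
exactly 500.000 kb is a "short" segment) and a strictly `> 500` kb
class, matching how short and long ROH are conventionally tabulated.

Every rule above is cross-checked in the test suite against a
brute-force oracle that enumerates all windows and candidate runs
directly; on 200 randomized instances of up to 300 variants the two
implementations agree segment-for-segment.

## QC decisions

* **Call rate.** Samples with genotyping rate below 99% are removed;
  the boundary is kept (a rate of exactly 0.99 survives).
* **Relatedness.** PI-HAT
  \(= P(\mathrm{IBD}{=}2) + \tfrac12 P(\mathrm{IBD}{=}1)\) is estimated
  per pair by the method of moments from IBS counts, with expected
  IBS-state probabilities computed from sample allele frequencies;
  negative moment estimates are clamped to zero before
  renormalization. Pairs at PI-HAT ≥ 0.5 are broken by removing the
  member with the lower call rate (ties: the lexicographically larger
  ID), iterating from the worst pair. Pairs with fewer than 50 jointly
  observed variants are flagged unreliable.
* **Branching.** The ROH branch uses the call-rate- and
  relatedness-filtered but otherwise *unpruned* matrix: MAF and LD
  filters would preferentially delete the monomorphic stretches that
  constitute ROH. The structure branch (IBS/MDS) additionally applies
  MAF < 5% removal and greedy windowed LD pruning
  (window 1500 variants, step 150, prune at \(r^2 > 0.1\); the later
  variant of a high-LD pair is dropped).

## Islands

Per species, segments are swept with a ±1 event queue over their
endpoints, giving maximal intervals of constant carrier count (each
sample counts once, however many segments it has). An island is a
maximal interval whose count stays at or above
\(\lceil 0.7 \cdot N \rceil\); its carrier number is the minimum count
over the interval, and the displayed percentage rounds half up
(5 of 7 prints as 71%, 16 of 18 as 89%). Contiguous eligible intervals
with different counts form one island; intervals separated by any
sub-threshold gap stay separate. Genes (BED, 0-based half-open, or
GFF3, 1-based inclusive — both normalized internally to 1-based
inclusive) are attached on ≥ 1 bp overlap; islands without genes are
labelled `---`.

## The simulator and what it does (not) emulate

`sim_config()` + `simulate_genotypes()` generate a multi-population
cohort:

* **Divergence.** Population allele frequencies follow the
  Balding–Nichols model: around an ancestral frequency
  \(p \sim U(0.05, 0.95)\), each population draws
  \(\mathrm{Beta}\!\big(p(1-F)/F,\ (1-p)(1-F)/F\big)\), so
  \(E[\tilde p] = p\) and \(\mathrm{Var}[\tilde p] = F p (1-p)\).
  \(F = 0\) is the no-drift limit and \(F = 1\) is rejected.
* **Genotypes.** Outside planted tracts, Hardy–Weinberg draws from the
  individual's population frequencies; admixed individuals draw each
  variant's population of origin independently with their source
  weights (tract-based admixture is deliberately not modelled — the
  per-variant mixture is sufficient to place hybrids between their
  sources in MDS space).
* **Planted autozygosity.** Inside a planted tract both haplotypes are
  one population haplotype, so every call is homozygous, except
  heterozygous miscalls planted at `het_error_rate` — emulating the
  genotyping error that makes real ROH imperfectly homozygous.
  Missingness hits every call at `missing_rate`. Shared tracts are
  assigned to a random subset of a population at a configured carrier
  fraction; per-individual random tracts are placed uniformly.
* **Positions.** Uniform random, deduplicated, sorted — so the caller's
  gap and density rules are exercised by natural density fluctuation.
  Ploidy is fixed at 2 and no sex chromosome is simulated.

What the simulator does *not* reproduce: linkage disequilibrium and
recombination structure (variants are independent given the
frequencies), mutation/coalescent realism, allele-frequency spectra
from real site-frequency data, and background *identity-by-descent*
segments — so passing recovery tests demonstrate the caller's
window/gap/length logic and the island arithmetic, not robustness to
LD-induced homozygosity runs, which in real data are controlled by the
length and variant-count floors.

## Validation design and problem sizes

The synthetic study used by the acceptance checks mirrors a small
multi-species WGS cohort: 4 populations × 8 samples, 2 chromosomes ×
5,000 variants over 20 Mb each (1 variant per 4 kb), 0.5% heterozygous
miscalls inside tracts, 1% missingness, two random 200–600 kb tracts
per individual, one tract shared by 80% of population 1 and one by 50%
of population 2. Between-population divergence is set to
\(F_{ST} = 0.1\) for this design: strong enough to separate the
populations in MDS, mild enough that within-population heterozygosity
stays realistic for WGS data — at much higher divergence the
Balding–Nichols model fixes so many variants per population that long
genuinely homozygous (non-autozygous) stretches appear and the notion
of a "false positive" segment stops being meaningful. The MDS
demonstration, which only needs separation, uses \(F_{ST} = 0.3\).

At these sizes the whole validation (simulation, calling, islands,
MDS) completes in seconds on one core. Expected outcomes, all computed
by the tests and the acceptance script at run time: ≥ 90% of planted
tracts ≥ 200 kb are recovered with both boundaries within one window
span (50 variants ≈ 200 kb at design density); per-sample \(F_{ROH}\)
is within ±0.01 of the planted autozygous fraction; the 80%-shared
tract is detected as an island at threshold 0.7 while the 50%-shared
tract is rejected; tract-free cohorts yield segments in ≤ 5% of
samples.

A known, quantified bias: eligibility extends a handful of variants
past a true tract boundary (windows straddling the edge still pass the
heterozygote allowance), so called segments slightly overshoot planted
tracts — by roughly 5–15 variants per side, i.e. tens of kb at the
design density. This is inherent to windowed scanning, shrinks with
marker density and background heterozygosity, and is well inside the
one-window-span boundary tolerance.

## Numerical and degenerate-input choices

* `anova_one_way()` uses the closed-form F statistic; all-equal groups
  return \(F = 0, p = 1\); zero within-group variance with unequal
  means returns \(F = \infty, p = 0\) with a `degenerate` flag.
  Two-group fits equal the squared pooled t statistic and match
  `stats::aov` to numerical precision (checked in the tests).
* `classical_mds()` wraps the standard double-centering
  eigendecomposition; axes are ordered by descending eigenvalue,
  negative eigenvalues are reported but never used for scaling, and
  each axis is sign-fixed so its first nonzero loading (taking samples
  in ID order, which makes the result invariant to row permutation) is
  positive.
* PI-HAT moment estimates are clamped to \([0, 1]\) and renormalized;
  a pair with no informative variants degrades to
  \((P_0, P_1, P_2) = (1, 0, 0)\).
* All boundary comparisons are inclusive where the upstream filter
  removes strictly-below values: call rate, MAF and the two segment
  floors keep exact-boundary cases.
* Percentages round half away from zero (`round_half_up()`), not to
  even.

## Limitations

* The caller reproduces PLINK-style semantics but is not a bit-exact
  PLINK clone; agreement is proven against this package's own
  brute-force enumeration, not against PLINK binaries.
* Island boundaries are defined at variant-position resolution by the
  sweep; consensus-run or pool-based definitions would differ at the
  margins.
* The PI-HAT estimator assumes a homogeneous population for its allele
  frequencies; applied across strongly diverged species it overstates
  within-species relatedness (as any frequency-based moment estimator
  does). In the pipeline it is used as the original filter was — to
  drop near-duplicates and first-degree pairs, which are far above the
  0.5 bound either way.
* Admixture-proportion estimation and enrichment analysis of island
  genes are out of scope.
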