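# Sample- and variant-level quality control: call-rate filter, MAF
# filter and linkage-disequilibrium pruning.  Each filter returns the
# filtered matrix plus a tidy report so counts always reconcile
# (input = retained + removed).

#' Remove samples with low genotyping rate
#'
#' A sample's call rate is its fraction of non-missing calls; samples
#' with rate below `min_rate` are dropped (rate exactly equal to
#' `min_rate` is retained).
#'
#' @param geno A [genotype_matrix()].
#' @param min_rate Minimum call rate, default 0.99.
#' @return List with `genotype` and `report` (tibble: `sample_id`,
#'   `call_rate`, `removed`).
#' @export
filter_sample_call_rate <- function(geno, min_rate = 0.99) {
  stopifnot(min_rate > 0, min_rate <= 1)
  cr <- sample_call_rate(geno)
  removed <- cr$call_rate < min_rate
  if (all(removed)) abort_rohscan("call-rate filter removed every sample")
  list(
    genotype = subset_genotypes(geno, samples = !removed),
    report = dplyr::mutate(cr, removed = removed)
  )
}

#' Remove variants with low minor allele frequency
#'
#' MAF is computed from non-missing calls over all samples; variants
#' with MAF below `min_maf` are dropped (MAF exactly equal to `min_maf`
#' is retained).  Variants with every call missing are removed and
#' counted separately.
#'
#' @param geno A [genotype_matrix()].
#' @param min_maf Minimum MAF in `[0, 0.5]`, default 0.05.
#' @return List with `genotype` and `report` (tibble: `n_input`,
#'   `n_removed_maf`, `n_removed_all_missing`, `n_retained`).
#' @export
filter_maf <- function(geno, min_maf = 0.05) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  maf <- minor_allele_freq(geno)
  all_missing <- is.nan(maf)
  low <- !all_missing & maf < min_maf
  keep <- !all_missing & !low
  list(
    genotype = subset_genotypes(geno, variants = keep),
    report = tibble::tibble(
      n_input = n_variants(geno),
      n_removed_maf = sum(low),
      n_removed_all_missing = sum(all_missing),
      n_retained = sum(keep)
    )
  )
}

#' Prune variants in high linkage disequilibrium
#'
#' Greedy windowed pruning in the style of PLINK's
#' `--indep-pairwise`: within a sliding window of `window_n_variants`
#' consecutive variants (per chromosome), pairs are scanned
#' left-to-right and the later variant of any pair with `r^2 >`
#' `r2_threshold` is marked pruned; the window then slides by `step`
#' variants.  `r^2` is the squared Pearson correlation of allele
#' dosages over samples non-missing in both variants.
#'
#' @param geno A [genotype_matrix()].
#' @param window_n_variants Window size in variants, default 1500.
#' @param step Window slide in variants, default 150.
#' @param r2_threshold Pruning threshold, default 0.1.
#' @return List with `genotype` and `report` (tibble: `n_input`,
#'   `n_pruned`, `n_retained`).
#' @export
ld_prune <- function(geno, window_n_variants = 1500, step = 150,
                     r2_threshold = 0.1) {
  if (window_n_variants < 2) abort_rohscan("window must span at least 2 variants")
  stopifnot(step >= 1)
  m <- n_variants(geno)
  pruned <- logical(m)
  for (ch in unique(geno$variants$chrom)) {
    idx <- which(geno$variants$chrom == ch)
    nc <- length(idx)
    starts <- seq(1, max(1, nc - 1), by = step)
    for (s in starts) {
      w <- idx[s:min(s + window_n_variants - 1, nc)]
      w <- w[!pruned[w]]
      if (length(w) < 2) next
      dos <- geno$calls[, w, drop = FALSE]
      r2 <- suppressWarnings(stats::cor(dos, use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      for (a in seq_len(length(w) - 1)) {
        if (pruned[w[a]]) next
        hits <- which(r2[a, ] > r2_threshold)
        hits <- hits[hits > a & !pruned[w[hits]]]
        pruned[w[hits]] <- TRUE
      }
      if (s + window_n_variants - 1 >= nc) break
    }
  }
  list(
    genotype = subset_genotypes(geno, variants = !pruned),
    report = tibble::tibble(
      n_input = m, n_pruned = sum(pruned), n_retained = sum(!pruned)
    )
  )
}
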