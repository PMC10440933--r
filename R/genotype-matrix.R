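#' Genotype matrix container
#'
#' Holds diploid genotype calls as an integer dosage matrix (samples in
#' rows, variants in columns; values 0 = hom-ref, 1 = het, 2 = hom-alt,
#' `NA` = missing) together with tidy variant and sample metadata.
#'
#' @param calls Integer matrix, samples x variants, values in
#'   `{0, 1, 2, NA}`.
#' @param variants Tibble with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`; positions strictly increasing within a chromosome.
#' @param samples Tibble with columns `sample_id` and optionally
#'   `species`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  stopifnot(
    nrow(calls) == nrow(samples),
    ncol(calls) == nrow(variants),
    all(c("chrom", "pos") %in% names(variants)),
    "sample_id" %in% names(samples)
  )
  bad <- !(calls %in% c(0L, 1L, 2L)) & !is.na(calls)
  if (any(bad)) abort_rohscan("calls must be 0, 1, 2 or NA")
  ord_ok <- all(tapply(variants$pos, variants$chrom,
                       function(p) all(diff(p) > 0)))
  if (!isTRUE(ord_ok)) {
    abort_rohscan("variant positions must be strictly increasing within a chromosome")
  }
  if (anyDuplicated(samples$sample_id)) {
    abort_rohscan("duplicate sample ids")
  }
  rownames(calls) <- samples$sample_id
  structure(
    list(calls = calls, variants = variants, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d variants on %d chromosome(s); %.2f%% missing\n",
    n_samples(x), n_variants(x),
    length(unique(x$variants$chrom)),
    100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Number of samples / variants
#' @param x A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$calls)

#' @rdname n_samples
#' @export
n_variants <- function(x) ncol(x$calls)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param samples Logical or integer index over samples (default all).
#' @param variants Logical or integer index over variants (default all).
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(x)) else samples
  vi <- if (is.null(variants)) seq_len(n_variants(x)) else variants
  genotype_matrix(
    x$calls[si, vi, drop = FALSE],
    x$variants[vi, , drop = FALSE],
    x$samples[si, , drop = FALSE]
  )
}

#' Per-variant alternate-allele frequency
#'
#' Frequency of the ALT allele computed from non-missing calls over all
#' samples (mean dosage / 2).
#'
#' @param x A `genotype_matrix`.
#' @return Numeric vector, one value per variant (`NaN` when every call
#'   is missing).
#' @export
alt_allele_freq <- function(x) {
  colMeans(x$calls, na.rm = TRUE) / 2
}

#' Per-variant minor allele frequency
#'
#' @param x A `genotype_matrix`.
#' @return Numeric vector of MAF values in `[0, 0.5]` (`NaN` when every
#'   call is missing).
#' @export
minor_allele_freq <- function(x) {
  p <- alt_allele_freq(x)
  pmin(p, 1 - p)
}

#' Per-sample call rate
#'
#' Fraction of variants with a non-missing genotype for each sample.
#'
#' @param x A `genotype_matrix`.
#' @return Tibble with `sample_id` and `call_rate`.
#' @export
sample_call_rate <- function(x) {
  tibble::tibble(
    sample_id = x$samples$sample_id,
    call_rate = unname(rowMeans(!is.na(x$calls)))
  )
}
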