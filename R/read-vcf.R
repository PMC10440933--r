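#' Read genotypes from a multi-sample VCF
#'
#' Parses a sorted VCF into a [genotype_matrix()].  Only biallelic
#' records are kept (multi-allelic records are skipped and counted).
#' Half-calls and non-diploid genotypes are treated as missing, as is
#' `./.`.  Phased separators (`|`) are accepted.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param sample_map Tibble/data.frame mapping `sample_id` to `species`;
#'   every sample in the VCF must appear in it.
#' @return List with `genotype` (a [genotype_matrix()]) and `report`
#'   (tibble: one row per skip reason with a count).
#' @export
read_vcf <- function(path, sample_map) {
  sample_map <- tibble::as_tibble(sample_map)
  stopifnot(all(c("sample_id", "species") %in% names(sample_map)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  n_multi <- sum(multi)

  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- !multi
  chrom <- chrom[keep]; pos <- pos[keep]
  ref <- fix[keep, "REF"]; alt <- alt[keep]
  gt <- gt[keep, , drop = FALSE]

  # sortedness within chromosomes
  for (ch in unique(chrom)) {
    if (is.unsorted(pos[chrom == ch], strictly = TRUE)) {
      abort_rohscan("VCF not sorted (or duplicate positions) on ", ch)
    }
  }
  vcf_samples <- colnames(gt)
  missing_from_map <- setdiff(vcf_samples, sample_map$sample_id)
  if (length(missing_from_map) > 0) {
    abort_rohscan("VCF sample(s) absent from sample map: ",
                  paste(missing_from_map, collapse = ", "))
  }

  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    out
  }
  tg <- t(gt)                      # samples x variants
  calls <- matrix(code(tg), nrow = nrow(tg), ncol = ncol(tg))

  samples <- dplyr::left_join(tibble::tibble(sample_id = vcf_samples),
                              sample_map, by = "sample_id")
  geno <- genotype_matrix(
    calls,
    tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt),
    samples
  )
  list(
    genotype = geno,
    report = tibble::tibble(
      reason = "multiallelic_skipped",
      n = n_multi
    )
  )
}
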