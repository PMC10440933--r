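# Small construction helpers used across the suite.

# genotype_matrix from a samples x variants dosage matrix
make_geno <- function(calls, pos = NULL, chrom = "chr1", ids = NULL,
                      species = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(calls)))
  if (is.null(species)) species <- rep("sp1", nrow(calls))
  genotype_matrix(
    calls,
    tibble::tibble(chrom = rep_len(chrom, m), pos = pos,
                   ref = rep("A", m), alt = rep("G", m)),
    tibble::tibble(sample_id = ids, species = species)
  )
}

# single-sample, single-chromosome genotype matrix from a call vector
make_geno1 <- function(calls, pos = NULL) {
  make_geno(matrix(calls, nrow = 1), pos = pos)
}
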