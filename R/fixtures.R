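# Plain-text fixture emission: VCF, sample map, chromosome lengths,
# per-sample truth BED and a named gene BED.

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCFv4.2 with GT-only FORMAT, one ALT allele per
#' record and `./.` for missing calls.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output file path.
#' @param chrom_lengths Optional tibble (`chrom`, `length_bp`) for
#'   contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path, chrom_lengths = NULL) {
  gt_code <- c("0/0", "0/1", "1/1")
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(chrom_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          chrom_lengths$chrom, as.integer(chrom_lengths$length_bp)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT",
                        geno$samples$sample_id), collapse = "\t"))
  gt <- matrix("./.", n_samples(geno), n_variants(geno))
  ok <- !is.na(geno$calls)
  gt[ok] <- gt_code[geno$calls[ok] + 1L]
  body <- paste(
    geno$variants$chrom, geno$variants$pos,
    paste0("v", seq_len(n_variants(geno))),
    geno$variants$ref, geno$variants$alt,
    ".", "PASS", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a full synthetic fixture set
#'
#' Simulates a cohort and writes every file a downstream run needs:
#' multi-sample VCF, sample-to-species map TSV, chromosome-length TSV,
#' one truth BED per sample (0-based half-open planted intervals) and a
#' named gene BED.  One synthetic gene is placed inside every planted
#' shared tract (named `GENE_SHARED_<i>`), flanked by decoy genes that
#' overlap nothing.
#'
#' @param config A [sim_config()].
#' @param out_dir Writable output directory (created if absent).
#' @return List of file paths (`vcf`, `sample_map`, `chrom_lengths`,
#'   `genes`, `truth_beds`) plus the in-memory `genotype` and `truth`.
#' @export
write_fixture_set <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genotypes(config)
  geno <- sim$genotype

  vcf <- file.path(out_dir, "cohort.vcf")
  write_vcf(geno, vcf, sim$truth$chrom_lengths)

  sample_map <- file.path(out_dir, "sample_map.tsv")
  utils::write.table(sim$truth$population_of, sample_map, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  chrom_lengths <- file.path(out_dir, "chrom_lengths.tsv")
  utils::write.table(sim$truth$chrom_lengths, chrom_lengths, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth_beds <- character()
  pl <- sim$truth$planted_intervals
  if (nrow(pl) > 0) {
    for (sid in unique(pl$sample_id)) {
      p <- file.path(out_dir, paste0("truth_", sid, ".bed"))
      d <- dplyr::filter(pl, .data$sample_id == sid)
      writeLines(sprintf("%s\t%d\t%d\t%s", d$chrom,
                         as.integer(d$start_bp - 1), as.integer(d$end_bp),
                         sid), p)
      truth_beds <- c(truth_beds, p)
    }
  }

  genes <- file.path(out_dir, "genes.bed")
  gene_rows <- character()
  if (!is.null(config$shared_roh) && nrow(config$shared_roh) > 0) {
    sr <- config$shared_roh
    for (i in seq_len(nrow(sr))) {
      mid <- floor((sr$start_bp[i] + sr$end_bp[i]) / 2)
      half <- max(1, floor((sr$end_bp[i] - sr$start_bp[i]) / 10))
      gene_rows <- c(gene_rows, sprintf(
        "chr%d\t%d\t%d\tGENE_SHARED_%d",
        sr$chrom[i], as.integer(mid - half - 1), as.integer(mid + half), i))
    }
  }
  # decoy genes near the chromosome starts, away from any planted tract
  for (ch in seq_len(config$n_chromosomes)) {
    gene_rows <- c(gene_rows,
                   sprintf("chr%d\t%d\t%d\tGENE_DECOY_%d", ch, 99L, 1099L, ch))
  }
  writeLines(gene_rows, genes)

  list(vcf = vcf, sample_map = sample_map, chrom_lengths = chrom_lengths,
       genes = genes, truth_beds = truth_beds,
       genotype = geno, truth = sim$truth)
}

#' Read a chromosome-length TSV
#'
#' Two columns, `chrom` and `length_bp` (FASTA-index style).
#'
#' @param path TSV path.
#' @return Tibble with `chrom` and `length_bp`.
#' @export
read_chrom_lengths <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length_bp") %in% names(d)))
  tibble::as_tibble(d)
}
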