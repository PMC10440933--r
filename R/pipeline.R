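# End-to-end orchestration: simulate/read -> QC -> ROH -> F_ROH ->
# islands -> gene annotation -> IBS/MDS, with tidy TSV reports and a
# machine-readable manifest.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort_rohscan("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full ROH analysis pipeline
#'
#' Either reads a cohort from files (`vcf`, `sample_map`,
#' `chrom_lengths`, optionally `genes`) or simulates one from a
#' [sim_config()] (in which case a complete plain-text fixture set is
#' written under `out_dir/fixtures` and read back, so a rerun with the
#' same configuration is byte-identical).  Stages: sample call-rate
#' filter; PI-HAT relatedness removal (estimated on a MAF-filtered
#' view); ROH calling on the unpruned matrix with length-class
#' stratification; per-sample F_ROH; per-species summaries and
#' cross-species ANOVA; ROH islands with gene annotation; MAF filter +
#' LD pruning + IBS distance + classical MDS.
#'
#' @param out_dir Output directory (created).
#' @param vcf,sample_map,chrom_lengths,genes Input file paths; or
#' @param sim A [sim_config()] (exactly one of `vcf`/`sim`).
#' @param min_call_rate Sample call-rate floor, default 0.99.
#' @param max_pi_hat Relatedness removal bound, default 0.5.
#' @param min_maf MAF floor for the structure branch, default 0.05.
#' @param ld_window,ld_step,ld_r2 LD-pruning parameters, defaults
#'   1500 / 150 / 0.1.
#' @param roh A [roh_params()].
#' @param island_threshold Carrier fraction defining islands, 0.70.
#' @param mds_dims MDS dimensions, default 2.
#' @return Invisibly, a list with every intermediate result
#'   (`qc`, `segments`, `froh`, `summaries`, `anova`, `islands`,
#'   `mds`, `manifest`, `genotype`) and the written file paths.
#' @export
run_pipeline <- function(out_dir,
                         vcf = NULL, sample_map = NULL,
                         chrom_lengths = NULL, genes = NULL,
                         sim = NULL,
                         min_call_rate = 0.99, max_pi_hat = 0.5,
                         min_maf = 0.05, ld_window = 1500, ld_step = 150,
                         ld_r2 = 0.1,
                         roh = roh_params(), island_threshold = 0.70,
                         mds_dims = 2) {
  if (is.null(vcf) == is.null(sim)) {
    abort_rohscan("provide exactly one of `vcf` or `sim`")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(sim)) {
    fx <- .stage("simulate", write_fixture_set(sim, file.path(out_dir, "fixtures")))
    vcf <- fx$vcf; sample_map <- fx$sample_map
    chrom_lengths <- fx$chrom_lengths; genes <- fx$genes
  }
  smap <- .stage("read_sample_map",
                 tibble::as_tibble(utils::read.delim(sample_map)))
  clen <- .stage("read_chrom_lengths", read_chrom_lengths(chrom_lengths))
  rv <- .stage("read_vcf", read_vcf(vcf, smap))
  geno <- rv$genotype

  qc_cr <- .stage("call_rate_filter",
                  filter_sample_call_rate(geno, min_call_rate))
  geno <- qc_cr$genotype

  rel_view <- .stage("maf_view_for_relatedness", filter_maf(geno, min_maf))
  rel <- .stage("pi_hat", pi_hat(rel_view$genotype))
  qc_rel <- .stage("remove_related", remove_related(geno, rel, max_pi_hat))
  geno <- qc_rel$genotype

  segs <- .stage("roh_caller", call_roh_cohort(geno, roh))
  autosome_bp <- sum(clen$length_bp)
  froh <- .stage("f_roh", f_roh(segs, autosome_bp, geno$samples))

  nvar_by_species <- geno$samples |>
    dplyr::count(.data$species) |>
    dplyr::mutate(n_variants = n_variants(geno)) |>
    dplyr::select("species", "n_variants")
  summaries <- .stage("summaries", {
    lapply(split(segs, segs$length_class), function(d) {
      summarize_roh(f_roh(d, autosome_bp, geno$samples), nvar_by_species)
    })
  })
  anova_tbl <- .stage("anova", tryCatch(
    compare_species(froh),
    error = function(e) tibble::tibble(statistic = character(),
                                       f = numeric(), df1 = integer(),
                                       df2 = integer(), p_value = numeric())
  ))

  isl <- .stage("islands", {
    i <- roh_islands(segs, geno$samples, island_threshold)
    i <- count_island_variants(i, geno)
    if (!is.null(genes)) {
      annotate_islands(i, read_gene_intervals(genes))
    } else {
      dplyr::mutate(i, genes = list(character(0)), genes_label = "---")
    }
  })

  struct_geno <- .stage("maf_filter", filter_maf(geno, min_maf))
  pruned <- .stage("ld_prune",
                   ld_prune(struct_geno$genotype, ld_window, ld_step, ld_r2))
  mds <- .stage("mds", classical_mds(ibs_distance(pruned$genotype),
                                     mds_dims, geno$samples))

  manifest <- list(
    package = "rohscan",
    version = as.character(utils::packageVersion("rohscan")),
    seed = if (!is.null(sim)) sim$seed else NA_integer_,
    parameters = list(
      min_call_rate = min_call_rate, max_pi_hat = max_pi_hat,
      min_maf = min_maf, ld_window = ld_window, ld_step = ld_step,
      ld_r2 = ld_r2, roh = unclass(roh),
      island_threshold = island_threshold, mds_dims = mds_dims
    ),
    n_samples_final = n_samples(geno),
    n_variants = n_variants(geno)
  )

  wt <- function(d, f) {
    p <- file.path(out_dir, f)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- list(
    qc_call_rate = wt(qc_cr$report, "qc_call_rate.tsv"),
    relatedness = wt(rel, "relatedness.tsv"),
    qc_related_removed = wt(qc_rel$report, "qc_related_removed.tsv"),
    segments = wt(dplyr::select(segs, "sample_id", "chrom", "start_bp",
                                "end_bp", "length_kb", "n_variants",
                                "length_class"),
                  "roh_segments.tsv"),
    segments_bed = {
      p <- file.path(out_dir, "roh_segments.bed")
      writeLines(sprintf("%s\t%d\t%d\t%s", segs$chrom,
                         as.integer(segs$start_bp - 1),
                         as.integer(segs$end_bp), segs$sample_id), p)
      p
    },
    froh = wt(froh, "froh.tsv"),
    anova = wt(anova_tbl, "anova.tsv"),
    islands = wt(dplyr::select(isl, -"genes"), "islands.tsv"),
    mds = wt(mds$coordinates, "mds_coordinates.tsv"),
    manifest = {
      p <- file.path(out_dir, "manifest.json")
      writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                  pretty = TRUE, digits = NA, na = "null"), p)
      p
    }
  )
  for (cl in names(summaries)) {
    paths[[paste0("summary_", cl)]] <-
      wt(summaries[[cl]], paste0("summary_", gsub("[^0-9A-Za-z]+", "_", cl),
                                 ".tsv"))
  }

  invisible(list(
    qc = list(call_rate = qc_cr$report, relatedness = rel,
              related_removed = qc_rel$report,
              vcf_read = rv$report, maf = struct_geno$report,
              ld = pruned$report),
    segments = segs, froh = froh, summaries = summaries,
    anova = anova_tbl, islands = isl, mds = mds,
    manifest = manifest, genotype = geno, paths = paths
  ))
}
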