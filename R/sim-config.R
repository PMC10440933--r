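#' Simulation configuration
#'
#' Parameters for the multi-population genotype simulator.  Populations
#' diverge from a common ancestral allele-frequency pool under the
#' Balding-Nichols model; each individual can carry planted autozygous
#' segments (fully homozygous tracts standing in for runs of
#' homozygosity), genotyping error that miscalls variants inside a true
#' tract as heterozygous, and missing calls.
#'
#' @param n_populations Number of populations.
#' @param n_per_population Diploid individuals per population.
#' @param n_chromosomes Number of autosomes.
#' @param chrom_length_bp Length of every chromosome, bp.
#' @param n_variants_per_chrom Biallelic variants per chromosome;
#'   positions are drawn uniformly, deduplicated and sorted.
#' @param fst Balding-Nichols divergence in `[0, 1)`; scalar or one
#'   value per population.
#' @param shared_roh Planted shared tracts: a tibble/data.frame with
#'   columns `population` (1-based index), `carrier_fraction` in
#'   `(0, 1]`, `chrom` (1-based index), `start_bp`, `end_bp`; or `NULL`.
#' @param n_random_roh Random autozygous tracts planted per individual.
#' @param random_roh_min_bp,random_roh_max_bp Length bounds (uniform)
#'   for random tracts.
#' @param het_error_rate Probability that a call inside a true tract is
#'   miscalled heterozygous.
#' @param missing_rate Probability that any call is missing.
#' @param n_admixed Number of extra admixed (hybrid) individuals.
#' @param admix_sources Two population indices the admixed individuals
#'   draw from.
#' @param seed Integer seed; fully determines the output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 4,
                       n_per_population = 8,
                       n_chromosomes = 2,
                       chrom_length_bp = 2e7,
                       n_variants_per_chrom = 5000,
                       fst = 0.3,
                       shared_roh = NULL,
                       n_random_roh = 0,
                       random_roh_min_bp = 1e5,
                       random_roh_max_bp = 1e7,
                       het_error_rate = 0.005,
                       missing_rate = 0.01,
                       n_admixed = 0,
                       admix_sources = c(1L, 2L),
                       seed = 1L) {
  cfg <- list(
    n_populations = as.integer(n_populations),
    n_per_population = as.integer(n_per_population),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_variants_per_chrom = as.integer(n_variants_per_chrom),
    fst = rep_len(as.numeric(fst), n_populations),
    shared_roh = if (is.null(shared_roh)) NULL else tibble::as_tibble(shared_roh),
    n_random_roh = as.integer(n_random_roh),
    random_roh_min_bp = as.numeric(random_roh_min_bp),
    random_roh_max_bp = as.numeric(random_roh_max_bp),
    het_error_rate = as.numeric(het_error_rate),
    missing_rate = as.numeric(missing_rate),
    n_admixed = as.integer(n_admixed),
    admix_sources = as.integer(admix_sources),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (any(fst < 0) || any(fst >= 1)) {
      abort_rohscan("fst must lie in [0, 1): fst = 1 gives a degenerate Beta")
    }
    rates <- c(het_error_rate, missing_rate)
    if (any(rates < 0) || any(rates > 1)) abort_rohscan("rates must lie in [0, 1]")
    if (n_populations < 1 || n_per_population < 1) abort_rohscan("need at least one sample")
    if (random_roh_min_bp > random_roh_max_bp) abort_rohscan("random ROH length bounds reversed")
  })
  if (!is.null(cfg$shared_roh)) {
    sr <- cfg$shared_roh
    need <- c("population", "carrier_fraction", "chrom", "start_bp", "end_bp")
    if (!all(need %in% names(sr))) {
      abort_rohscan("shared_roh needs columns: ", paste(need, collapse = ", "))
    }
    if (any(sr$start_bp < 1) || any(sr$end_bp > cfg$chrom_length_bp) ||
        any(sr$start_bp > sr$end_bp)) {
      abort_rohscan("planted interval outside chromosome bounds")
    }
    carriers <- round_half_up(sr$carrier_fraction * cfg$n_per_population)
    if (any(carriers < 1)) {
      abort_rohscan("carrier_fraction x n_per_population < 1 for a planted tract")
    }
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d pops x %d ind, %d chrom x %d variants (%.1f Mb), fst %s, seed %d\n",
    x$n_populations, x$n_per_population, x$n_chromosomes,
    x$n_variants_per_chrom, x$chrom_length_bp / 1e6,
    paste(unique(x$fst), collapse = "/"), x$seed
  ))
  invisible(x)
}
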