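# Multi-population genotype simulator with planted autozygous tracts.
#
# Population allele frequencies follow the Balding-Nichols model: for a
# variant with ancestral frequency p and divergence F, each population's
# frequency is Beta(p(1-F)/F, (1-p)(1-F)/F), so E[freq] = p and
# Var[freq] = F p(1-p).  F = 0 is the no-drift limit (frequency == p).

# draw positions/frequencies; assumes the RNG is already seeded
.sim_freqs <- function(config) {
  K <- config$n_populations
  purrr::map(seq_len(config$n_chromosomes), function(ch) {
    pos <- sort(sample.int(config$chrom_length_bp, config$n_variants_per_chrom))
    p_anc <- stats::runif(length(pos), 0.05, 0.95)
    freq <- matrix(NA_real_, length(pos), K)
    for (k in seq_len(K)) {
      f <- config$fst[k]
      freq[, k] <- if (f == 0) p_anc else {
        stats::rbeta(length(pos), p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
      }
    }
    # keep frequencies strictly inside (0, 1)
    freq <- pmin(pmax(freq, 1e-9), 1 - 1e-9)
    list(chrom = paste0("chr", ch), pos = pos, p_anc = p_anc, freq = freq)
  })
}

#' Simulate per-population allele frequencies
#'
#' Draws variant positions and Balding-Nichols population allele
#' frequencies around uniform ancestral frequencies on `[0.05, 0.95]`.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `chrom`, `pos`, `p_anc` and one `pop_<k>`
#'   frequency column per population.
#' @export
simulate_allele_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- .sim_freqs(config)
  purrr::map_dfr(chroms, function(cc) {
    out <- tibble::tibble(chrom = cc$chrom, pos = cc$pos, p_anc = cc$p_anc)
    for (k in seq_len(ncol(cc$freq))) out[[paste0("pop_", k)]] <- cc$freq[, k]
    out
  })
}

# merge overlapping/adjacent intervals on one chromosome
.merge_intervals <- function(start, end) {
  if (length(start) == 0) return(list(start = numeric(), end = numeric()))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Simulate a multi-population genotype cohort with planted tracts
#'
#' Outside planted intervals genotypes are Hardy-Weinberg draws from the
#' individual's population allele frequencies (admixed individuals draw
#' each variant's population of origin independently with their source
#' weights).  Inside planted intervals both haplotypes are copies of one
#' population haplotype, so every call is homozygous except
#' heterozygous miscalls introduced at `het_error_rate`.  Any call is
#' missing with probability `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return List with elements `genotype` (a [genotype_matrix()]) and
#'   `truth` (list of tibbles: `population_of`, `planted_intervals`,
#'   `admixture_fractions`, plus `chrom_lengths`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- .sim_freqs(config)
  K <- config$n_populations
  n_pp <- config$n_per_population

  sample_id <- character(); population <- integer()
  for (k in seq_len(K)) {
    sample_id <- c(sample_id, sprintf("pop%d_ind%02d", k, seq_len(n_pp)))
    population <- c(population, rep(k, n_pp))
  }
  admix <- NULL
  if (config$n_admixed > 0) {
    aid <- sprintf("admix_ind%02d", seq_len(config$n_admixed))
    sample_id <- c(sample_id, aid)
    population <- c(population, rep(NA_integer_, config$n_admixed))
    w1 <- stats::runif(config$n_admixed, 0.3, 0.7)
    admix <- tibble::tibble(
      sample_id = rep(aid, each = 2),
      source_population = rep(config$admix_sources, times = config$n_admixed),
      weight = as.vector(rbind(w1, 1 - w1))
    )
  }
  n <- length(sample_id)
  species <- ifelse(is.na(population), "admixed", paste0("pop", population))

  # planted intervals per sample: shared tracts first, then random ones
  plant <- vector("list", n)
  names(plant) <- sample_id
  for (i in seq_len(n)) {
    plant[[i]] <- lapply(seq_len(config$n_chromosomes),
                         function(ch) list(start = numeric(), end = numeric()))
  }
  if (!is.null(config$shared_roh)) {
    sr <- config$shared_roh
    for (r in seq_len(nrow(sr))) {
      members <- which(population == sr$population[r])
      n_car <- round_half_up(sr$carrier_fraction[r] * length(members))
      carriers <- sample(members, n_car)
      for (i in carriers) {
        ch <- sr$chrom[r]
        plant[[i]][[ch]]$start <- c(plant[[i]][[ch]]$start, sr$start_bp[r])
        plant[[i]][[ch]]$end <- c(plant[[i]][[ch]]$end, sr$end_bp[r])
      }
    }
  }
  if (config$n_random_roh > 0) {
    for (i in seq_len(n)) {
      for (j in seq_len(config$n_random_roh)) {
        len <- stats::runif(1, config$random_roh_min_bp, config$random_roh_max_bp)
        len <- min(len, config$chrom_length_bp)
        ch <- sample.int(config$n_chromosomes, 1)
        s <- floor(stats::runif(1, 1, config$chrom_length_bp - len + 1))
        plant[[i]][[ch]]$start <- c(plant[[i]][[ch]]$start, s)
        plant[[i]][[ch]]$end <- c(plant[[i]][[ch]]$end, s + len - 1)
      }
    }
  }
  for (i in seq_len(n)) {
    for (ch in seq_len(config$n_chromosomes)) {
      plant[[i]][[ch]] <- .merge_intervals(plant[[i]][[ch]]$start,
                                           plant[[i]][[ch]]$end)
    }
  }

  # draw genotypes chromosome by chromosome
  calls <- matrix(NA_integer_, n, 0)
  variants <- list()
  bases <- c("A", "C", "G", "T")
  for (ch in seq_len(config$n_chromosomes)) {
    cc <- chroms[[ch]]
    m <- length(cc$pos)
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    g <- matrix(NA_integer_, n, m)
    for (i in seq_len(n)) {
      if (is.na(population[i])) {
        wi <- admix$weight[admix$sample_id == sample_id[i]]
        z <- sample(config$admix_sources, m, replace = TRUE, prob = wi)
        p <- cc$freq[cbind(seq_len(m), z)]
      } else {
        p <- cc$freq[, population[i]]
      }
      gi <- stats::rbinom(m, 2L, p)
      pl <- plant[[i]][[ch]]
      if (length(pl$start) > 0) {
        for (t in seq_along(pl$start)) {
          inside <- which(cc$pos >= pl$start[t] & cc$pos <= pl$end[t])
          if (length(inside) > 0) {
            # one haplotype copied onto both: homozygous at the allele freq
            gi[inside] <- 2L * stats::rbinom(length(inside), 1L, p[inside])
            if (config$het_error_rate > 0) {
              err <- stats::runif(length(inside)) < config$het_error_rate
              gi[inside][err] <- 1L
            }
          }
        }
      }
      if (config$missing_rate > 0) {
        gi[stats::runif(m) < config$missing_rate] <- NA_integer_
      }
      g[i, ] <- gi
    }
    calls <- cbind(calls, g)
    variants[[ch]] <- tibble::tibble(chrom = cc$chrom, pos = cc$pos,
                                     ref = ref, alt = alt)
  }

  planted <- purrr::map_dfr(seq_len(n), function(i) {
    purrr::map_dfr(seq_len(config$n_chromosomes), function(ch) {
      pl <- plant[[i]][[ch]]
      if (length(pl$start) == 0) return(NULL)
      tibble::tibble(sample_id = sample_id[i], chrom = paste0("chr", ch),
                     start_bp = pl$start, end_bp = pl$end)
    })
  })
  truth <- list(
    population_of = tibble::tibble(sample_id = sample_id, species = species),
    planted_intervals = planted,
    admixture_fractions = admix,
    chrom_lengths = tibble::tibble(
      chrom = paste0("chr", seq_len(config$n_chromosomes)),
      length_bp = config$chrom_length_bp
    )
  )
  geno <- genotype_matrix(
    calls,
    dplyr::bind_rows(variants),
    tibble::tibble(sample_id = sample_id, species = species)
  )
  list(genotype = geno, truth = truth)
}

#' Duplicate one sample under a new ID
#'
#' Copies an individual's genotype row verbatim, e.g. to exercise
#' relatedness filtering (the pair's PI-HAT is ~1).
#'
#' @param geno A [genotype_matrix()].
#' @param sample_id ID of the sample to copy.
#' @param new_id ID for the copy.
#' @return A [genotype_matrix()] with one extra sample.
#' @export
duplicate_sample <- function(geno, sample_id, new_id) {
  i <- match(sample_id, geno$samples$sample_id)
  if (is.na(i)) abort_rohscan("unknown sample: ", sample_id)
  genotype_matrix(
    rbind(geno$calls, geno$calls[i, , drop = FALSE]),
    geno$variants,
    dplyr::bind_rows(geno$samples,
                     dplyr::mutate(geno$samples[i, ], sample_id = new_id))
  )
}
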