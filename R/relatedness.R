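# Method-of-moments IBD relatedness (PI-HAT) from identity-by-state
# counts, and iterative removal of one member of each related pair.

#' Pairwise PI-HAT relatedness
#'
#' For every sample pair, counts IBS states 0/1/2 over jointly
#' non-missing variants and solves the method-of-moments system for the
#' IBD-state probabilities P(Z=0), P(Z=1), P(Z=2), using expected
#' IBS-state probabilities under each IBD state given the sample allele
#' frequencies.  Negative estimates are clamped to zero and the triple
#' renormalized.  `PI_HAT = P(Z=2) + 0.5 P(Z=1)`.
#'
#' Frequencies should be away from 0/1 (run [filter_maf()] first):
#' monomorphic variants carry no IBD information and near-fixed ones
#' destabilise the moments.
#'
#' @param geno A [genotype_matrix()], ideally MAF-filtered.
#' @param min_joint Minimum jointly observed variants before a pair is
#'   flagged unreliable, default 50.
#' @return Tibble with `sample_1`, `sample_2`, `n_joint`, `z0`, `z1`,
#'   `z2`, `pi_hat`, `unreliable`.
#' @export
pi_hat <- function(geno, min_joint = 50) {
  n <- n_samples(geno)
  if (n < 2) abort_rohscan("need at least two samples")
  p <- alt_allele_freq(geno)
  q <- 1 - p
  # expected IBS-state probabilities per variant given IBD state
  e0_ibs0 <- 2 * p^2 * q^2
  e0_ibs1 <- 4 * p^3 * q + 4 * p * q^3
  e0_ibs2 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibs1 <- 2 * p^2 * q + 2 * p * q^2
  e1_ibs2 <- p^3 + q^3 + p^2 * q + p * q^2

  ids <- geno$samples$sample_id
  calls <- geno$calls
  out <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    di <- calls[i, ]
    for (j in seq(i + 1, n)) {
      dj <- calls[j, ]
      ok <- !is.na(di) & !is.na(dj) & !is.na(p)
      ibs <- 2L - abs(di[ok] - dj[ok])
      nj <- length(ibs)
      n0 <- sum(ibs == 0L); n1 <- sum(ibs == 1L); n2 <- nj - n0 - n1
      if (nj == 0) {
        z0 <- z1 <- z2 <- NA_real_; ph <- NA_real_
      } else {
        s0_0 <- sum(e0_ibs0[ok]); s0_1 <- sum(e0_ibs1[ok]); s0_2 <- sum(e0_ibs2[ok])
        s1_1 <- sum(e1_ibs1[ok]); s1_2 <- sum(e1_ibs2[ok])
        z0 <- if (s0_0 > 0) n0 / s0_0 else 0
        z1 <- if (s1_1 > 0) (n1 - z0 * s0_1) / s1_1 else 0
        z2 <- (n2 - z0 * s0_2 - z1 * s1_2) / nj
        z <- pmin(pmax(c(z0, z1, z2), 0), 1)
        if (sum(z) == 0) z <- c(1, 0, 0) else z <- z / sum(z)
        z0 <- z[1]; z1 <- z[2]; z2 <- z[3]
        ph <- z2 + 0.5 * z1
      }
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        sample_1 = ids[i], sample_2 = ids[j], n_joint = nj,
        z0 = z0, z1 = z1, z2 = z2, pi_hat = ph,
        unreliable = nj < min_joint
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Remove one member of each highly related pair
#'
#' Iteratively takes the pair with the largest PI-HAT at or above
#' `pi_hat_max` and removes the member with the lower call rate (tie:
#' the lexicographically larger sample ID), until no pair remains at or
#' above the bound.
#'
#' @param geno A [genotype_matrix()].
#' @param relatedness Output of [pi_hat()] (computed on this matrix or
#'   on a pruned view with the same samples).
#' @param pi_hat_max Removal threshold, default 0.5 (removal at
#'   `PI_HAT >= pi_hat_max`).
#' @return List with `genotype` and `report` (tibble: `sample_id`,
#'   `partner`, `pi_hat` for each removed sample).
#' @export
remove_related <- function(geno, relatedness, pi_hat_max = 0.5) {
  cr <- sample_call_rate(geno)
  rate_of <- stats::setNames(cr$call_rate, cr$sample_id)
  rel <- dplyr::filter(relatedness, !is.na(.data$pi_hat))
  removed <- tibble::tibble(sample_id = character(), partner = character(),
                            pi_hat = numeric())
  repeat {
    live <- dplyr::filter(rel, .data$pi_hat >= pi_hat_max)
    if (nrow(live) == 0) break
    worst <- live[which.max(live$pi_hat), ]
    a <- worst$sample_1; b <- worst$sample_2
    drop <- if (rate_of[a] < rate_of[b]) a
            else if (rate_of[b] < rate_of[a]) b
            else max(a, b)
    keep_partner <- if (drop == a) b else a
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      sample_id = drop, partner = keep_partner, pi_hat = worst$pi_hat))
    rel <- dplyr::filter(rel, .data$sample_1 != drop, .data$sample_2 != drop)
  }
  keep <- !(geno$samples$sample_id %in% removed$sample_id)
  list(genotype = subset_genotypes(geno, samples = keep), report = removed)
}
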