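# Brute-force oracles, written as direct enumerations independent of
# the package's rolling-sum / sweep implementations.

# direct window enumeration: per-variant eligibility flags
oracle_window_scan <- function(calls, p) {
  m <- length(calls)
  if (m == 0) return(logical(0))
  w <- p$window_snp
  windows <- if (m < w) list(seq_len(m)) else {
    lapply(seq_len(m - w + 1), function(j) j:(j + w - 1))
  }
  hits <- integer(m); denom <- integer(m)
  for (ix in windows) {
    hom <- sum(calls[ix] == 1, na.rm = TRUE) <= p$window_het &&
      sum(is.na(calls[ix])) <= p$window_missing
    denom[ix] <- denom[ix] + 1L
    if (hom) hits[ix] <- hits[ix] + 1L
  }
  hits / denom >= p$window_threshold
}

# direct run enumeration: eligible runs -> gap split -> trim -> filters
oracle_call_roh <- function(calls, pos, p) {
  elig <- oracle_window_scan(calls, p)
  m <- length(calls)
  segs <- list()
  i <- 1
  while (i <= m) {
    if (!elig[i]) { i <- i + 1; next }
    j <- i
    while (j < m && elig[j + 1]) j <- j + 1
    pieces <- list(); s <- i
    if (j > i) {
      for (k in i:(j - 1)) {
        if (pos[k + 1] - pos[k] > p$max_gap_kb * 1000) {
          pieces <- c(pieces, list(s:k)); s <- k + 1
        }
      }
    }
    pieces <- c(pieces, list(s:j))
    for (run in pieces) {
      while (length(run) > 0 &&
             (is.na(calls[run[1]]) || calls[run[1]] == 1)) run <- run[-1]
      while (length(run) > 0 &&
             (is.na(calls[run[length(run)]]) ||
                calls[run[length(run)]] == 1)) run <- run[-length(run)]
      if (length(run) == 0) next
      nv <- sum(!is.na(calls[run]))
      lk <- (pos[run[length(run)]] - pos[run[1]] + 1) / 1000
      if (nv >= p$min_snp && lk >= p$min_kb &&
          lk / nv <= p$density_kb_per_snp) {
        segs[[length(segs) + 1]] <- tibble::tibble(
          start_bp = pos[run[1]], end_bp = pos[run[length(run)]],
          n_variants = nv, length_kb = lk)
      }
    }
    i <- j + 1
  }
  if (length(segs) == 0) {
    tibble::tibble(start_bp = numeric(), end_bp = numeric(),
                   n_variants = integer(), length_kb = numeric())
  } else {
    dplyr::bind_rows(segs)
  }
}

# random single-sample instance + parameter set for oracle comparison
random_roh_instance <- function() {
  m <- sample(20:300, 1)
  pos <- sort(sample.int(2e6, m))
  p_het <- stats::runif(1, 0.1, 0.5)
  calls <- sample(c(0L, 1L, 2L, NA), m, replace = TRUE,
                  prob = c((1 - p_het) / 2, p_het, (1 - p_het) / 2, 0.03))
  # plant a homozygous stretch in half the instances
  if (stats::runif(1) < 0.5 && m > 60) {
    a <- sample(1:(m - 50), 1)
    calls[a:(a + 49)] <- sample(c(0L, 2L), 50, replace = TRUE)
  }
  params <- roh_params(
    min_kb = sample(c(20, 50, 100), 1),
    min_snp = sample(c(5, 10, 15), 1),
    max_gap_kb = sample(c(50, 200, 500), 1),
    window_missing = sample(0:2, 1),
    window_het = sample(0:3, 1),
    window_snp = sample(c(10, 25, 50), 1),
    window_threshold = 0.05,
    density_kb_per_snp = sample(c(20, 50), 1)
  )
  list(calls = calls, pos = pos, params = params)
}

# per-base brute-force carrier count over a toy chromosome
oracle_coverage_counts <- function(segments, chrom_len) {
  cover <- matrix(FALSE, nrow = length(unique(segments$sample_id)),
                  ncol = chrom_len,
                  dimnames = list(unique(segments$sample_id), NULL))
  for (r in seq_len(nrow(segments))) {
    cover[segments$sample_id[r],
          segments$start_bp[r]:segments$end_bp[r]] <- TRUE
  }
  colSums(cover)
}

# brute-force windowed LD pruning: all pairs within each window,
# left-to-right, later variant of a high-r2 pair pruned
oracle_ld_prune <- function(dosages, window, step, r2_max) {
  m <- ncol(dosages)
  pruned <- logical(m)
  s <- 1
  repeat {
    w <- s:min(s + window - 1, m)
    for (a in w) {
      if (pruned[a]) next
      for (b in w[w > a]) {
        if (pruned[b]) next
        ok <- !is.na(dosages[, a]) & !is.na(dosages[, b])
        if (sum(ok) < 2) next
        if (stats::sd(dosages[ok, a]) == 0 || stats::sd(dosages[ok, b]) == 0) next
        if (stats::cor(dosages[ok, a], dosages[ok, b])^2 > r2_max) pruned[b] <- TRUE
      }
    }
    if (s + window - 1 >= m) break
    s <- s + step
  }
  pruned
}

# Hudson's FST estimator from two dosage matrices (samples x variants)
hudson_fst <- function(d1, d2) {
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  n1 <- 2 * colSums(!is.na(d1))
  n2 <- 2 * colSums(!is.na(d2))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
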