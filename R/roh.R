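# Sliding-window detection of runs of homozygosity (ROH), following the
# PLINK --homozyg semantics: a window of consecutive variants is
# "homozygous" if it carries at most `window_het` heterozygous and
# `window_missing` missing calls; a variant is ROH-eligible when a
# sufficient fraction of the windows spanning it are homozygous; maximal
# eligible runs are gap-split, end-trimmed and filtered on length,
# variant count and density.

#' ROH caller parameters
#'
#' Defaults follow a common livestock parameterization: minimum segment
#' length 100 kb, at least 15 variants per segment, maximum 500 kb
#' between consecutive variants of a segment, at most 1 missing and 3
#' heterozygous calls per 50-variant scanning window, eligibility
#' threshold 0.05 and a maximum average spacing of 50 kb per variant.
#'
#' @param min_kb Minimum segment length, kb.
#' @param min_snp Minimum number of (non-missing) variants per segment.
#' @param max_gap_kb Maximum gap between consecutive variants within a
#'   segment, kb.
#' @param window_missing Maximum missing calls per scanning window.
#' @param window_het Maximum heterozygous calls per scanning window.
#' @param window_snp Scanning window size in variants.
#' @param window_threshold Minimum fraction of spanning windows that
#'   must be homozygous for a variant to be ROH-eligible.
#' @param density_kb_per_snp Maximum average spacing (segment kb per
#'   variant).
#' @return A validated list of class `roh_params`.
#' @export
roh_params <- function(min_kb = 100, min_snp = 15, max_gap_kb = 500,
                       window_missing = 1, window_het = 3,
                       window_snp = 50, window_threshold = 0.05,
                       density_kb_per_snp = 50) {
  p <- list(min_kb = min_kb, min_snp = as.integer(min_snp),
            max_gap_kb = max_gap_kb,
            window_missing = as.integer(window_missing),
            window_het = as.integer(window_het),
            window_snp = as.integer(window_snp),
            window_threshold = window_threshold,
            density_kb_per_snp = density_kb_per_snp)
  stopifnot(p$window_het < p$window_snp, p$window_missing < p$window_snp,
            p$window_het >= 0, p$window_missing >= 0, p$window_snp >= 2,
            p$min_kb > 0, p$min_snp > 0, p$max_gap_kb > 0,
            p$density_kb_per_snp > 0,
            p$window_threshold > 0, p$window_threshold <= 1)
  structure(p, class = "roh_params")
}

#' Per-variant ROH eligibility from the sliding-window scan
#'
#' Slides a window of `window_snp` consecutive variants along one
#' sample's calls on one chromosome.  A window is homozygous iff it
#' contains at most `window_het` heterozygous and `window_missing`
#' missing calls.  A variant is eligible iff at least
#' `window_threshold` of the windows containing it are homozygous.
#' Chromosomes with fewer than `window_snp` variants are scanned with a
#' single window spanning all variants.
#'
#' @param calls Integer vector of one sample's calls on one chromosome
#'   (0/1/2, `NA` missing), ordered by position.
#' @param params A [roh_params()].
#' @return Logical vector of per-variant eligibility flags.
#' @export
window_scan <- function(calls, params = roh_params()) {
  m <- length(calls)
  if (m == 0) return(logical(0))
  het <- !is.na(calls) & calls == 1L
  mis <- is.na(calls)
  w <- params$window_snp
  if (m < w) {
    hom <- sum(het) <= params$window_het && sum(mis) <= params$window_missing
    frac <- as.numeric(hom)
    return(rep(frac >= params$window_threshold, m))
  }
  # rolling window counts via cumulative sums
  ch <- c(0, cumsum(het)); cm <- c(0, cumsum(mis))
  j <- seq_len(m - w + 1)
  hom <- (ch[j + w] - ch[j]) <= params$window_het &
         (cm[j + w] - cm[j]) <= params$window_missing
  chom <- c(0, cumsum(hom))
  nW <- length(hom)
  i <- seq_len(m)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nW)
  hits <- chom[hi + 1] - chom[lo]
  hits / (hi - lo + 1) >= params$window_threshold
}

# segments for one sample on one chromosome
.call_roh_chrom <- function(calls, pos, params) {
  elig <- window_scan(calls, params)
  if (!any(elig)) return(NULL)
  r <- rle(elig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- Map(function(s, e) s:e, starts[r$values], ends[r$values])

  # split runs at inter-variant gaps larger than max_gap_kb
  max_gap <- params$max_gap_kb * 1000
  runs <- unlist(lapply(runs, function(run) {
    if (length(run) < 2) return(list(run))
    gaps <- diff(pos[run]) > max_gap
    unname(split(run, c(0, cumsum(gaps))))
  }), recursive = FALSE)

  out <- list()
  for (run in runs) {
    # trim ends to homozygous non-missing calls
    hom_ok <- !is.na(calls[run]) & calls[run] != 1L
    if (!any(hom_ok)) next
    run <- run[min(which(hom_ok)):max(which(hom_ok))]
    n_var <- sum(!is.na(calls[run]))
    len_kb <- segment_length_kb(pos[run[1]], pos[run[length(run)]])
    if (n_var >= params$min_snp && len_kb >= params$min_kb &&
        len_kb / n_var <= params$density_kb_per_snp) {
      out[[length(out) + 1]] <- tibble::tibble(
        start_bp = pos[run[1]], end_bp = pos[run[length(run)]],
        n_variants = n_var, length_kb = len_kb
      )
    }
  }
  if (length(out) == 0) NULL else dplyr::bind_rows(out)
}

#' Call runs of homozygosity for every sample
#'
#' Runs the sliding-window scan and segment assembly per sample and
#' chromosome.  Segments are maximal runs of consecutive eligible
#' variants, split at gaps above `max_gap_kb`, trimmed so both ends are
#' homozygous non-missing calls, and kept when they satisfy the
#' `min_snp`, `min_kb` and density conditions.  Coordinates are the
#' positions of the first and last variant of the run (1-based,
#' inclusive); `n_variants` counts the spanned variants with
#' non-missing calls.
#'
#' @param geno A [genotype_matrix()] (QC-complete; the ROH branch is
#'   not MAF-filtered or LD-pruned).
#' @param params A [roh_params()].
#' @return Tibble of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_variants`, `length_kb`, sorted and non-overlapping
#'   within sample and chromosome.
#' @export
call_roh <- function(geno, params = roh_params()) {
  chroms <- unique(geno$variants$chrom)
  out <- list()
  for (sid in geno$samples$sample_id) {
    i <- match(sid, geno$samples$sample_id)
    for (ch in chroms) {
      vi <- which(geno$variants$chrom == ch)
      segs <- .call_roh_chrom(geno$calls[i, vi], geno$variants$pos[vi], params)
      if (!is.null(segs)) {
        out[[length(out) + 1]] <- dplyr::mutate(segs, sample_id = sid,
                                                chrom = ch, .before = 1)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start_bp = numeric(), end_bp = numeric(),
                          n_variants = integer(), length_kb = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Call ROH and stratify segments into length classes
#'
#' Runs [call_roh()] once at the short-segment floor (default
#' `min_kb = 100`) and bins segments into the `[100, 500]` kb and
#' `> 500` kb classes (the 100-500 class is closed at both ends; a
#' segment of exactly 500 kb falls in it).
#'
#' @param geno A [genotype_matrix()].
#' @param params A [roh_params()].
#' @param class_boundary_kb Boundary between the two classes, default
#'   500.
#' @return Segment tibble as [call_roh()] plus a `length_class` factor
#'   (`"100-500"`, `">500"`, labelled from the actual bounds).
#' @export
call_roh_cohort <- function(geno, params = roh_params(),
                            class_boundary_kb = 500) {
  segs <- call_roh(geno, params)
  lab_short <- paste0(params$min_kb, "-", class_boundary_kb)
  lab_long <- paste0(">", class_boundary_kb)
  dplyr::mutate(segs, length_class = factor(
    ifelse(.data$length_kb <= class_boundary_kb, lab_short, lab_long),
    levels = c(lab_short, lab_long)
  ))
}
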