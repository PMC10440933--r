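# ROH islands: regions whose ROH carrier count reaches a threshold
# fraction of a population, found by an event sweep over segment
# endpoints, then annotated with overlapping genes.

#' Carrier-count coverage profile of ROH segments
#'
#' Event sweep over segment endpoints (+1 at `start_bp`, -1 at
#' `end_bp + 1`) giving, per chromosome, the maximal intervals of
#' constant carrier count.  Each sample contributes at most 1 at any
#' position (its segments are merged first), so the count is a number
#' of carriers, not of segments.
#'
#' @param segments Segment tibble (one species' samples) with
#'   `sample_id`, `chrom`, `start_bp`, `end_bp`.
#' @return Tibble: `chrom`, `start_bp`, `end_bp` (1-based inclusive),
#'   `n_carriers` (> 0 intervals only).
#' @export
coverage_profile <- function(segments) {
  if (nrow(segments) == 0) {
    return(tibble::tibble(chrom = character(), start_bp = numeric(),
                          end_bp = numeric(), n_carriers = integer()))
  }
  merged <- segments |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::group_modify(function(d, key) {
      m <- .merge_intervals(d$start_bp, d$end_bp)
      tibble::tibble(start_bp = m$start, end_bp = m$end)
    }) |>
    dplyr::ungroup()
  merged |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      ev <- tibble::tibble(
        pos = c(d$start_bp, d$end_bp + 1),
        delta = rep(c(1L, -1L), each = nrow(d))
      ) |>
        dplyr::group_by(.data$pos) |>
        dplyr::summarise(delta = sum(.data$delta), .groups = "drop") |>
        dplyr::arrange(.data$pos)
      count <- cumsum(ev$delta)
      k <- nrow(ev)
      tibble::tibble(
        start_bp = ev$pos[-k],
        end_bp = ev$pos[-1] - 1,
        n_carriers = count[-k]
      ) |>
        dplyr::filter(.data$n_carriers > 0)
    }) |>
    dplyr::ungroup()
}

#' Find ROH islands from a coverage profile
#'
#' An island is a maximal interval whose carrier count stays at or
#' above `ceiling(threshold * n_population)`.  Its `n_carriers` is the
#' minimum count over the interval and `pct_population` is
#' `round(100 * n_carriers / n_population)` (half up).
#'
#' @param profile Output of [coverage_profile()].
#' @param n_population Number of samples in the population.
#' @param threshold Carrier fraction defining an island, default 0.70.
#' @return Tibble: `chrom`, `start_bp`, `end_bp`, `n_carriers`,
#'   `pct_population`, `length_kb`.
#' @export
find_islands <- function(profile, n_population, threshold = 0.70) {
  if (n_population < 1) abort_rohscan("empty population")
  min_carriers <- ceiling(threshold * n_population)
  elig <- dplyr::filter(profile, .data$n_carriers >= min_carriers)
  if (nrow(elig) == 0) {
    return(tibble::tibble(chrom = character(), start_bp = numeric(),
                          end_bp = numeric(), n_carriers = integer(),
                          pct_population = numeric(), length_kb = numeric()))
  }
  elig |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start_bp, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      new_island <- c(TRUE, d$start_bp[-1] != d$end_bp[-nrow(d)] + 1)
      d |>
        dplyr::mutate(island = cumsum(new_island)) |>
        dplyr::group_by(.data$island) |>
        dplyr::summarise(start_bp = min(.data$start_bp),
                         end_bp = max(.data$end_bp),
                         n_carriers = min(.data$n_carriers),
                         .groups = "drop") |>
        dplyr::select(-"island")
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      pct_population = round_half_up(100 * .data$n_carriers / n_population),
      length_kb = segment_length_kb(.data$start_bp, .data$end_bp)
    )
}

#' Count analysis-set variants inside each island
#'
#' @param islands Island tibble with `chrom`, `start_bp`, `end_bp`.
#' @param geno The [genotype_matrix()] whose variants define the
#'   analysis set.
#' @return `islands` with an added `n_variants` column.
#' @export
count_island_variants <- function(islands, geno) {
  known <- unique(geno$variants$chrom)
  bad <- setdiff(unique(islands$chrom), known)
  if (length(bad) > 0) abort_rohscan("unknown chromosome: ",
                                     paste(bad, collapse = ", "))
  nv <- purrr::pmap_int(
    list(islands$chrom, islands$start_bp, islands$end_bp),
    function(ch, s, e) {
      sum(geno$variants$chrom == ch & geno$variants$pos >= s &
            geno$variants$pos <= e)
    }
  )
  dplyr::mutate(islands, n_variants = nv)
}

#' Read gene annotation intervals (BED or GFF3)
#'
#' BED input (0-based half-open) and GFF3 input (1-based inclusive) are
#' both returned as 1-based inclusive intervals.  Malformed BED lines
#' (fewer than 3 fields) are skipped with a warning.  For GFF3, only
#' `gene` features are kept when the file types its records.
#'
#' @param path Annotation file; format chosen by extension
#'   (`.bed` vs `.gff`/`.gff3`).
#' @return Tibble: `chrom`, `start_bp`, `end_bp`, `gene`.
#' @export
read_gene_intervals <- function(path) {
  is_bed <- grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)
  if (is_bed) {
    lines <- readLines(path)
    nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
    bad <- nf < 3 | !nzchar(lines)
    if (any(bad)) {
      warning(sum(bad), " malformed BED line(s) skipped")
      lines <- lines[!bad]
    }
    tmp <- tempfile(fileext = ".bed")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(lines, tmp)
    gr <- rtracklayer::import(tmp, format = "bed")
    name <- if (!is.null(gr$name)) gr$name else paste0("interval_", seq_along(gr))
  } else {
    gr <- rtracklayer::import(path)
    if (!is.null(gr$type) && any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    name <- gr$Name
    if (is.null(name)) name <- gr$ID
    if (is.null(name)) name <- paste0("interval_", seq_along(gr))
    name <- ifelse(is.na(name), paste0("interval_", seq_along(gr)), name)
  }
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr),
    end_bp = GenomicRanges::end(gr),
    gene = name
  )
}

#' Annotate islands with overlapping genes
#'
#' A gene is listed for an island iff its interval overlaps the island
#' by at least 1 bp.  Islands without any overlap get an empty gene
#' list and the display label `"---"`.
#'
#' @param islands Island tibble with `chrom`, `start_bp`, `end_bp`.
#' @param genes Gene tibble from [read_gene_intervals()] (1-based
#'   inclusive).
#' @return `islands` with `genes` (list-column of character vectors)
#'   and `genes_label` (comma-separated or `"---"`).
#' @export
annotate_islands <- function(islands, genes) {
  if (nrow(islands) == 0) {
    return(dplyr::mutate(islands, genes = list(), genes_label = character()))
  }
  ir <- GenomicRanges::GRanges(
    islands$chrom, IRanges::IRanges(islands$start_bp, islands$end_bp))
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start_bp, genes$end_bp))
  hits <- GenomicRanges::findOverlaps(ir, gr)
  gl <- vector("list", nrow(islands))
  for (i in seq_len(nrow(islands))) gl[[i]] <- character(0)
  for (h in seq_along(hits)) {
    qi <- S4Vectors::queryHits(hits)[h]
    gl[[qi]] <- c(gl[[qi]], genes$gene[S4Vectors::subjectHits(hits)[h]])
  }
  gl <- lapply(gl, unique)
  dplyr::mutate(
    islands,
    genes = gl,
    genes_label = purrr::map_chr(gl, function(g) {
      if (length(g) == 0) "---" else paste(g, collapse = ", ")
    })
  )
}

#' Per-species ROH islands
#'
#' Convenience wrapper: computes each species' coverage profile and
#' islands at the shared-carrier threshold.
#'
#' @param segments Cohort segment tibble from [call_roh()].
#' @param samples Tibble with `sample_id` and `species`.
#' @param threshold Carrier fraction defining an island, default 0.70.
#' @return Island tibble with a leading `species` column.
#' @export
roh_islands <- function(segments, samples, threshold = 0.70) {
  samples <- tibble::as_tibble(samples)
  purrr::map_dfr(split(samples, samples$species), function(sp) {
    segs <- dplyr::filter(segments, .data$sample_id %in% sp$sample_id)
    isl <- find_islands(coverage_profile(segs), nrow(sp), threshold)
    if (nrow(isl) == 0) return(NULL)
    dplyr::mutate(isl, species = sp$species[1], .before = 1)
  })
}
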