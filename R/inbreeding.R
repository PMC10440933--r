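# Genomic inbreeding from ROH: F_ROH = L_ROH / L_aut, the fraction of
# the autosomal genome covered by an individual's ROH segments, plus
# per-species summary tables and one-way ANOVA across species.

#' Per-sample genomic inbreeding coefficient F_ROH
#'
#' `F_ROH = L_ROH / L_aut`, where `L_ROH` is the summed length of all of
#' a sample's ROH segments and `L_aut` the autosomal genome length.
#' Samples listed in `samples` but carrying no segment get
#' `f_roh = 0`.
#'
#' @param segments Segment tibble from [call_roh()] (the
#'   `min_kb = 100` run; segments per sample/chromosome must be
#'   disjoint).
#' @param autosome_length_bp Total autosome length in bp (e.g. the sum
#'   of the chromosome-length TSV).
#' @param samples Optional tibble with `sample_id` (and `species`) to
#'   include segment-free samples and attach species labels.
#' @return Tibble: `sample_id`, (`species`,) `n_segments`, `total_kb`,
#'   `f_roh`.
#' @export
f_roh <- function(segments, autosome_length_bp, samples = NULL) {
  stopifnot(autosome_length_bp > 0)
  if (nrow(segments) > 0) {
    overlap <- segments |>
      dplyr::group_by(.data$sample_id, .data$chrom) |>
      dplyr::arrange(.data$start_bp, .by_group = TRUE) |>
      dplyr::summarise(
        bad = dplyr::n() > 1 && any(utils::head(.data$end_bp, -1) >=
                                      utils::tail(.data$start_bp, -1)),
        .groups = "drop")
    if (any(overlap$bad)) abort_rohscan("overlapping segments for one sample")
  }
  per <- segments |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      total_kb = sum(.data$end_bp - .data$start_bp + 1) / 1000,
      .groups = "drop"
    )
  if (!is.null(samples)) {
    per <- dplyr::left_join(tibble::as_tibble(samples), per,
                            by = "sample_id") |>
      dplyr::mutate(n_segments = dplyr::coalesce(.data$n_segments, 0L),
                    total_kb = dplyr::coalesce(.data$total_kb, 0))
  }
  dplyr::mutate(per, f_roh = .data$total_kb * 1000 / autosome_length_bp)
}

#' Per-species ROH summary
#'
#' Mean, sample standard deviation (n-1 denominator), minimum and
#' maximum of segment count, total kb, F_ROH and per-sample mean
#' segment size, for each species.  A species with a single sample
#' reports `sd = 0` with `sd_degenerate = TRUE`.
#'
#' @param records Output of [f_roh()] with a `species` column.
#' @param n_variants_by_species Optional tibble (`species`,
#'   `n_variants`) with the variant count entering the ROH caller.
#' @return Long tibble: `species`, `n`, `statistic`, `mean`, `sd`,
#'   `min`, `max`, `sd_degenerate` (and `n_variants` when supplied).
#' @export
summarize_roh <- function(records, n_variants_by_species = NULL) {
  stopifnot("species" %in% names(records))
  long <- records |>
    dplyr::mutate(mean_segment_kb = ifelse(.data$n_segments > 0,
                                           .data$total_kb / .data$n_segments,
                                           NA_real_)) |>
    tidyr::pivot_longer(c("n_segments", "total_kb", "f_roh",
                          "mean_segment_kb"),
                        names_to = "statistic", values_to = "value")
  out <- long |>
    dplyr::group_by(.data$species, .data$statistic) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = if (any(!is.na(.data$value)))
               mean(.data$value, na.rm = TRUE) else NA_real_,
      sd = if (sum(!is.na(.data$value)) > 1)
             stats::sd(.data$value, na.rm = TRUE) else 0,
      min = if (any(!is.na(.data$value)))
              min(.data$value, na.rm = TRUE) else NA_real_,
      max = if (any(!is.na(.data$value)))
              max(.data$value, na.rm = TRUE) else NA_real_,
      sd_degenerate = sum(!is.na(.data$value)) <= 1,
      .groups = "drop"
    ) |>
    dplyr::relocate("n", .after = "species")
  if (!is.null(n_variants_by_species)) {
    out <- dplyr::left_join(out, tibble::as_tibble(n_variants_by_species),
                            by = "species")
  }
  out
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance:
#' `F = (SSB / (k-1)) / (SSW / (n-k))` with the p-value from the upper
#' tail of `F(k-1, n-k)`.  Zero within-group variance with unequal
#' means yields `F = Inf`, `p = 0`, flagged `degenerate`.
#'
#' @param data Data frame of observations.
#' @param value Column with the response (tidy-eval).
#' @param group Column with the group label (tidy-eval).
#' @return Object of class `roh_anova`: list with `f`, `df1`, `df2`,
#'   `p_value`, `group_means`, `degenerate`.
#' @export
anova_one_way <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- g[ok]
  sizes <- table(g)
  k <- length(sizes)
  n <- length(v)
  if (k < 2) abort_rohscan("need at least two groups")
  if (any(sizes < 2)) abort_rohscan("every group needs at least two values")
  grand <- mean(v)
  gm <- tapply(v, g, mean)
  ssb <- sum(sizes * (gm - grand)^2)
  ssw <- sum((v - gm[g])^2)
  df1 <- k - 1; df2 <- n - k
  degenerate <- FALSE
  if (ssb == 0) {
    f <- 0; p <- 1
  } else if (ssw == 0) {
    f <- Inf; p <- 0; degenerate <- TRUE
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(
    list(f = f, df1 = df1, df2 = df2, p_value = p,
         group_means = tibble::tibble(group = names(gm),
                                      n = as.integer(sizes[names(gm)]),
                                      mean = as.numeric(gm)),
         degenerate = degenerate),
    class = "roh_anova"
  )
}

#' @export
print.roh_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df1, x$df2, x$f, x$p_value,
              if (x$degenerate) " [degenerate: zero within-group variance]" else ""))
  invisible(x)
}

#' Tidy a one-way ANOVA fit
#' @param x A `roh_anova` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df1`, `df2`, `p.value`.
#' @method tidy roh_anova
#' @export
tidy.roh_anova <- function(x, ...) {
  tibble::tibble(statistic = x$f, df1 = x$df1, df2 = x$df2,
                 p.value = x$p_value)
}

#' @rdname tidy.roh_anova
#' @return For `glance`: one-row tibble adding `n_groups` and `n_obs`.
#' @method glance roh_anova
#' @export
glance.roh_anova <- function(x, ...) {
  tibble::tibble(statistic = x$f, p.value = x$p_value,
                 n_groups = x$df1 + 1L, n_obs = x$df1 + x$df2 + 1L,
                 degenerate = x$degenerate)
}

#' Cross-species ANOVA on ROH statistics
#'
#' Applies [anova_one_way()] across species to segment count, mean
#' segment length and F_ROH, mirroring the three comparisons usually
#' reported alongside Table-1-style ROH summaries.
#'
#' @param records Output of [f_roh()] with a `species` column.
#' @return Tibble: `statistic`, `f`, `df1`, `df2`, `p_value`.
#' @export
compare_species <- function(records) {
  recs <- dplyr::mutate(records, mean_segment_kb = ifelse(
    .data$n_segments > 0, .data$total_kb / .data$n_segments, NA_real_))
  purrr::map_dfr(c("n_segments", "mean_segment_kb", "f_roh"), function(st) {
    d <- dplyr::filter(recs, !is.na(.data[[st]]))
    fit <- anova_one_way(d, .data[[st]], .data$species)
    tibble::tibble(statistic = st, f = fit$f, df1 = fit$df1,
                   df2 = fit$df2, p_value = fit$p_value)
  })
}
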