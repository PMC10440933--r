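seg <- function(id, s, e, chrom = "chr1") {
  tibble::tibble(sample_id = id, chrom = chrom, start_bp = s, end_bp = e)
}

test_that("coverage profile counts carriers, not segments", {
  one <- seg("a", 100, 200)
  pr <- coverage_profile(one)
  expect_equal(pr$start_bp, 100)
  expect_equal(pr$end_bp, 200)
  expect_equal(pr$n_carriers, 1)

  two <- dplyr::bind_rows(seg("a", 100, 200), seg("b", 100, 200))
  expect_equal(coverage_profile(two)$n_carriers, 2)

  # two abutting segments of the same sample still count once
  same <- dplyr::bind_rows(seg("a", 100, 150), seg("a", 151, 200),
                           seg("b", 120, 180))
  pr3 <- coverage_profile(same)
  expect_true(all(pr3$n_carriers <= 2))
  expect_equal(max(pr3$n_carriers), 2)
})

test_that("sweep profile equals a per-base brute-force count on a toy chromosome", {
  withr::local_seed(41)
  L <- 1e5
  segs <- purrr::map_dfr(1:50, function(i) {
    s <- sample.int(L - 1000, 1)
    seg(sprintf("s%02d", sample(1:10, 1)), s, s + sample(200:5000, 1))
  })
  segs$end_bp <- pmin(segs$end_bp, L)
  pr <- coverage_profile(segs)
  base_counts <- oracle_coverage_counts(segs, L)
  # compare at every breakpoint interval
  for (r in seq_len(nrow(pr))) {
    expect_true(all(base_counts[pr$start_bp[r]:pr$end_bp[r]] ==
                      pr$n_carriers[r]))
  }
  # positions outside reported intervals carry zero
  covered <- unlist(purrr::map2(pr$start_bp, pr$end_bp, seq))
  expect_true(all(base_counts[setdiff(seq_len(L), covered)] == 0))
})

test_that("interval length weighted by carrier count conserves total segment length", {
  withr::local_seed(43)
  segs <- purrr::map_dfr(1:30, function(i) {
    s <- sample.int(5e4, 1)
    seg(sprintf("s%02d", sample(1:6, 1)), s, s + sample(100:3000, 1))
  })
  # merge per sample first so overlaps within a sample are not double-counted
  merged_len <- segs |>
    dplyr::group_by(sample_id) |>
    dplyr::group_modify(function(d, k) {
      o <- d[order(d$start_bp), ]
      tot <- 0; cur_s <- o$start_bp[1]; cur_e <- o$end_bp[1]
      for (i in seq_len(nrow(o))[-1]) {
        if (o$start_bp[i] <= cur_e + 1) cur_e <- max(cur_e, o$end_bp[i])
        else { tot <- tot + cur_e - cur_s + 1; cur_s <- o$start_bp[i]; cur_e <- o$end_bp[i] }
      }
      tibble::tibble(len = tot + cur_e - cur_s + 1)
    }) |> dplyr::ungroup()
  pr <- coverage_profile(segs)
  expect_equal(sum((pr$end_bp - pr$start_bp + 1) * pr$n_carriers),
               sum(merged_len$len))
})

test_that("island carrier minima follow the ceiling rule", {
  expect_equal(ceiling(0.7 * 7), 5)
  pr7 <- coverage_profile(purrr::map_dfr(1:5, function(i)
    seg(paste0("s", i), 1000, 2000)))
  isl7 <- find_islands(pr7, n_population = 7)
  expect_equal(isl7$n_carriers, 5)
  expect_equal(isl7$pct_population, 71)
  # 4 carriers of 6 (67%) are below the bar; 5 of 6 (83%) pass
  pr4 <- coverage_profile(purrr::map_dfr(1:4, function(i)
    seg(paste0("s", i), 1000, 2000)))
  expect_equal(nrow(find_islands(pr4, n_population = 6)), 0)
  pr5 <- coverage_profile(purrr::map_dfr(1:5, function(i)
    seg(paste0("s", i), 1000, 2000)))
  expect_equal(find_islands(pr5, n_population = 6)$pct_population, 83)
})

test_that("an island spans contiguous eligible intervals with varying counts", {
  # N = 18: counts 12,12,13,14,13,12 along one chromosome; ceil(.7*18) = 13
  counts <- c(12, 12, 13, 14, 13, 12)
  bounds <- seq(1000, by = 1000, length.out = 7)
  segs <- purrr::map_dfr(seq_along(counts), function(b) {
    purrr::map_dfr(seq_len(counts[b]), function(i)
      seg(sprintf("s%02d", i), bounds[b], bounds[b + 1] - 1))
  })
  isl <- find_islands(coverage_profile(segs), n_population = 18)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start_bp, 3000)
  expect_equal(isl$end_bp, 5999)
  expect_equal(isl$n_carriers, 13)
  expect_equal(isl$pct_population, 72)
})

test_that("raising the threshold never increases total island length", {
  withr::local_seed(47)
  segs <- purrr::map_dfr(1:40, function(i) {
    s <- sample.int(8e4, 1)
    seg(sprintf("s%02d", sample(1:10, 1)), s, s + sample(500:8000, 1))
  })
  pr <- coverage_profile(segs)
  lens <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
    isl <- find_islands(pr, 10, th)
    if (nrow(isl) == 0) 0 else sum(isl$end_bp - isl$start_bp + 1)
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("variant counting inside islands matches a direct position scan", {
  g <- make_geno(matrix(0L, 2, 100), pos = seq(500, 50000, by = 500))
  isl <- tibble::tibble(chrom = "chr1", start_bp = c(1, 1, 10001),
                        end_bp = c(400, 50000, 20000))
  out <- count_island_variants(isl, g)
  expect_equal(out$n_variants, c(0L, 100L,
                                 sum(g$variants$pos >= 10001 &
                                       g$variants$pos <= 20000)))
  expect_error(count_island_variants(
    tibble::tibble(chrom = "chrX", start_bp = 1, end_bp = 2), g),
    "unknown chromosome")
})

test_that("gene annotation respects 1 bp overlap and boundary conventions", {
  genes <- tibble::tibble(
    chrom = "chr1",
    start_bp = c(5001, 900, 2000),
    end_bp = c(6000, 980, 4000),
    gene = c("ABUT", "LEFT", "INSIDE")
  )
  isl <- tibble::tibble(chrom = "chr1", start_bp = 1000, end_bp = 5000)
  ann <- annotate_islands(isl, genes)
  expect_setequal(ann$genes[[1]], "INSIDE")      # ABUT starts at end+1
  expect_equal(annotate_islands(
    tibble::tibble(chrom = "chr1", start_bp = 2500, end_bp = 2600),
    genes)$genes[[1]], "INSIDE")                  # containing gene reported
  none <- annotate_islands(
    tibble::tibble(chrom = "chr1", start_bp = 7000, end_bp = 8000), genes)
  expect_equal(none$genes_label, "---")
})

test_that("BED genes are shifted to 1-based inclusive and malformed lines skipped", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tG1", "malformed", "chr2\t0\t100\tG2"), bed)
  expect_warning(genes <- read_gene_intervals(bed), "malformed")
  expect_equal(genes$start_bp, c(1000, 1))
  expect_equal(genes$end_bp, c(2000, 100))
  expect_equal(genes$gene, c("G1", "G2"))
})

test_that("GFF3 genes read as 1-based inclusive, gene features only", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=g1;Name=FGF5",
    "chr1\tsrc\texon\t1000\t1200\t.\t+\t.\tID=e1;Parent=g1"
  ), gff)
  genes <- read_gene_intervals(gff)
  expect_equal(nrow(genes), 1)
  expect_equal(genes$start_bp, 1000)
  expect_equal(genes$end_bp, 2000)
  expect_equal(genes$gene, "FGF5")
})

test_that("tracts shared by 80% of a species become islands; 50% do not", {
  cfg <- sim_config(
    n_populations = 2, n_per_population = 8, n_chromosomes = 1,
    chrom_length_bp = 5e6, n_variants_per_chrom = 2500,
    shared_roh = data.frame(
      population = c(1, 2), carrier_fraction = c(0.8, 0.5),
      chrom = 1, start_bp = c(1e6, 3e6), end_bp = c(1.6e6, 3.6e6)),
    het_error_rate = 0.002, missing_rate = 0.01, seed = 53)
  sim <- simulate_genotypes(cfg)
  segs <- call_roh(sim$genotype)
  isl <- roh_islands(segs, sim$genotype$samples, threshold = 0.7)
  hit1 <- dplyr::filter(isl, species == "pop1",
                        start_bp <= 1.6e6, end_bp >= 1e6)
  expect_gte(nrow(hit1), 1)
  hit2 <- dplyr::filter(isl, species == "pop2",
                        start_bp <= 3.6e6, end_bp >= 3e6)
  expect_equal(nrow(hit2), 0)
})
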