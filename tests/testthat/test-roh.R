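test_that("window scan: all-homozygous eligible, all-heterozygous not", {
  p <- roh_params()
  hom <- rep(c(0L, 2L), 100)
  expect_true(all(window_scan(hom, p)))
  het <- rep(1L, 200)
  expect_false(any(window_scan(het, p)))
  expect_identical(window_scan(integer(0), p), logical(0))
})

test_that("short chromosomes fall back to a single all-variants window", {
  p <- roh_params(window_snp = 50)
  calls <- c(rep(0L, 20), 1L, 1L, 1L, rep(2L, 17))   # 40 < 50, 3 hets
  expect_true(all(window_scan(calls, p)))
  calls[5] <- 1L                                      # 4 hets
  expect_false(any(window_scan(calls, p)))
})

test_that("eligibility flags equal a direct window enumeration on a planted tract", {
  withr::local_seed(81)
  m <- 200
  calls <- sample(c(0L, 1L, 2L), m, replace = TRUE,
                  prob = c(0.3, 0.4, 0.3))
  calls[61:140] <- sample(c(0L, 2L), 80, replace = TRUE)   # 80-variant tract
  calls[c(80, 120)] <- 1L                                  # 2 hets inside
  p <- roh_params()
  expect_identical(window_scan(calls, p), oracle_window_scan(calls, p))
})

test_that("a planted 300 kb fully homozygous tract yields one covering segment", {
  # 60 variants spaced 5 kb on a homozygous tract within a het background
  pos_bg1 <- seq(1e4, 2e5, by = 4e3)
  pos_tr <- seq(3e5, 3e5 + 59 * 5000, by = 5000)   # ~295 kb span
  pos_bg2 <- seq(7e5, 9e5, by = 4e3)
  pos <- c(pos_bg1, pos_tr, pos_bg2)
  calls <- c(rep(1L, length(pos_bg1)),
             rep(c(0L, 2L), 30),
             rep(1L, length(pos_bg2)))
  g <- make_geno1(calls, pos)
  segs <- call_roh(g, roh_params(min_kb = 100))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_bp, pos_tr[1])
  expect_equal(segs$end_bp, pos_tr[60])
  expect_equal(segs$n_variants, 60)
  expect_equal(segs$length_kb, (pos_tr[60] - pos_tr[1] + 1) / 1000)
})

test_that("tracts below the length floor are not called", {
  pos_tr <- seq(1e5, 1e5 + 79000, by = 1000)   # 80 kb, 80 variants
  calls <- rep(c(0L, 2L), 40)
  g <- make_geno1(calls, pos_tr)
  expect_equal(nrow(call_roh(g, roh_params(min_kb = 100))), 0)
  expect_equal(nrow(call_roh(g, roh_params(min_kb = 50))), 1)
})

test_that("a long internal gap splits a run and both halves face the filters again", {
  # 20 homozygous variants; 600 kb gap between variants 10 and 11
  pos <- c(seq(1e5, 1e5 + 9 * 20000, by = 20000),
           seq(9e5, 9e5 + 9 * 20000, by = 20000))
  calls <- rep(c(0L, 2L), 10)
  p <- roh_params(min_kb = 100, min_snp = 15, max_gap_kb = 500,
                  window_snp = 10, density_kb_per_snp = 50)
  g <- make_geno1(calls, pos)
  expect_equal(nrow(call_roh(g, p)), 0)   # each half has 10 < 15 variants
  p2 <- roh_params(min_kb = 100, min_snp = 10, max_gap_kb = 500,
                   window_snp = 10, density_kb_per_snp = 50)
  expect_equal(nrow(call_roh(g, p2)), 2)
})

test_that("caller output is identical to the brute-force oracle on random instances", {
  withr::local_seed(91)
  for (rep in 1:40) {
    inst <- random_roh_instance()
    g <- make_geno1(inst$calls, inst$pos)
    got <- call_roh(g, inst$params)
    want <- oracle_call_roh(inst$calls, inst$pos, inst$params)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$end_bp, want$end_bp)
      expect_equal(got$n_variants, want$n_variants)
    }
  }
})

test_that("raising min_kb or min_snp never increases the segment count", {
  withr::local_seed(92)
  for (rep in 1:10) {
    inst <- random_roh_instance()
    g <- make_geno1(inst$calls, inst$pos)
    base <- inst$params
    n0 <- nrow(call_roh(g, base))
    up_kb <- roh_params(min_kb = base$min_kb * 2, min_snp = base$min_snp,
                        max_gap_kb = base$max_gap_kb,
                        window_missing = base$window_missing,
                        window_het = base$window_het,
                        window_snp = base$window_snp,
                        window_threshold = base$window_threshold,
                        density_kb_per_snp = base$density_kb_per_snp)
    up_snp <- roh_params(min_kb = base$min_kb, min_snp = base$min_snp + 5,
                         max_gap_kb = base$max_gap_kb,
                         window_missing = base$window_missing,
                         window_het = base$window_het,
                         window_snp = base$window_snp,
                         window_threshold = base$window_threshold,
                         density_kb_per_snp = base$density_kb_per_snp)
    expect_lte(nrow(call_roh(g, up_kb)), n0)
    expect_lte(nrow(call_roh(g, up_snp)), n0)
  }
})

test_that("length classes are closed at the 500 kb boundary", {
  # tract spanning exactly 500.000 kb: first variant 100001, last 600000
  pos <- seq(100001, 600000, length.out = 100)
  pos <- round(pos); pos[100] <- 600000; pos[1] <- 100001
  calls <- rep(c(0L, 2L), 50)
  g <- make_geno1(calls, pos)
  segs <- call_roh_cohort(g, roh_params())
  expect_equal(segs$length_kb, 500)
  expect_equal(as.character(segs$length_class), "100-500")

  # one short and one long tract land in different classes
  pos2 <- c(seq(1e5, 3e5, by = 4e3), seq(2e6, 2.9e6, by = 4e3))
  calls2 <- rep(c(0L, 2L), length.out = length(pos2))
  g2 <- make_geno1(calls2, pos2)
  p <- roh_params(max_gap_kb = 500)
  segs2 <- call_roh_cohort(g2, p)
  expect_equal(sort(as.character(segs2$length_class)), c("100-500", ">500"))
})

test_that("high background heterozygosity yields zero segments", {
  cfg <- sim_config(n_populations = 1, n_per_population = 5,
                    n_chromosomes = 1, chrom_length_bp = 5e6,
                    n_variants_per_chrom = 2000, fst = 0.05,
                    het_error_rate = 0, missing_rate = 0.01, seed = 15)
  g <- simulate_genotypes(cfg)$genotype
  expect_equal(nrow(call_roh(g)), 0)
})
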