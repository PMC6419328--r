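# Synthetic-cohort generator: construction guarantees, Hardy-Weinberg
# calibration, planted-tract semantics, reproducibility.

test_that("simulated genotypes follow Hardy-Weinberg proportions", {
  cfg <- sim_config(n_cases = 1000L, n_controls = 1000L, n_chromosomes = 1L,
                    snps_per_chr = 1L, maf_range = c(0.3, 0.3),
                    missing_rate = 0, seed = 11L)
  co <- simulate_cohort(cfg)
  g <- co$genotypes$geno
  # het frequency within 4 SD of 2 p (1 - p) = 0.42 (binomial, n = 2000)
  p_het <- mean(g == 1L)
  expect_lt(abs(p_het - 0.42), 4 * sqrt(0.42 * 0.58 / 2000))

  # with no structure and no planted tracts, the exact HWE test rarely
  # rejects at alpha = 1e-3 (conservative exact test)
  cfg2 <- sim_config(n_cases = 150L, n_controls = 150L, n_chromosomes = 2L,
                     snps_per_chr = 1000L, missing_rate = 0, seed = 12L)
  g2 <- simulate_cohort(cfg2)$genotypes$geno
  p <- hwe_exact_test(colSums(g2 == 0L), colSums(g2 == 1L),
                      colSums(g2 == 2L))
  expect_gte(mean(p >= 1e-3), 0.99)
})

test_that("planted tracts force homozygosity in carriers and only carriers", {
  tr <- planted_tract("chr1", 101L, 150L, p_case = 1, p_control = 0)
  cfg <- sim_config(n_cases = 40L, n_controls = 40L, n_chromosomes = 2L,
                    snps_per_chr = 400L, planted_tracts = list(tr),
                    missing_rate = 0, seed = 3L)
  co <- simulate_cohort(cfg)
  g <- co$genotypes$geno
  span <- 101:250
  pheno <- co$genotypes$samples$phenotype
  expect_true(all(co$truth_tracts[[1]]$carrier == (pheno == 1L)))
  # every case: 150 consecutive non-het, non-missing calls
  expect_true(all(g[pheno == 1L, span] != 1L))
  expect_false(anyNA(g[pheno == 1L, span]))
  # carriers share the same homozygous call at every tract SNP
  expect_true(all(apply(g[pheno == 1L, span, drop = FALSE], 2,
                        function(x) length(unique(x)) == 1L)))
  # controls keep a Hardy-Weinberg-looking het fraction inside the span
  expect_gt(mean(g[pheno == 0L, span] == 1L), 0.15)
})

test_that("planted carrier fractions match their binomial expectation", {
  for (seed in 1:5) {
    tr <- planted_tract("chr1", 1L, 50L, p_case = 0.3, p_control = 0.1)
    cfg <- sim_config(n_cases = 200L, n_controls = 200L, n_chromosomes = 1L,
                      snps_per_chr = 60L, planted_tracts = list(tr),
                      seed = seed)
    co <- simulate_cohort(cfg)
    carrier <- co$truth_tracts[[1]]$carrier
    pheno <- co$genotypes$samples$phenotype
    expect_lt(abs(sum(carrier[pheno == 1L]) - 200 * 0.3),
              4 * sqrt(200 * 0.3 * 0.7) + 1e-9)
    expect_lt(abs(sum(carrier[pheno == 0L]) - 200 * 0.1),
              4 * sqrt(200 * 0.1 * 0.9) + 1e-9)
  }
})

test_that("identical configurations reproduce bit-identical cohorts", {
  cfg <- sim_config(n_cases = 30L, n_controls = 30L, n_chromosomes = 2L,
                    snps_per_chr = 300L, fst = 0.05,
                    planted_tracts = list(planted_tract(1, 10L, 100L, .5, .1)),
                    seed = 99L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$genotypes$map, b$genotypes$map)
  expect_identical(a$truth_tracts, b$truth_tracts)
  expect_identical(a$subpop, b$subpop)
})

test_that("degenerate and invalid configurations are handled", {
  empty <- simulate_cohort(sim_config(n_cases = 3L, n_controls = 3L,
                                      snps_per_chr = 0L, seed = 1L))
  expect_identical(dim(empty$genotypes$geno), c(6L, 0L))
  expect_error(sim_config(snps_per_chr = 100L, planted_tracts =
    list(planted_tract("chr1", 90L, 20L, .5, .5))), "does not fit")
  expect_error(sim_config(planted_tracts =
    list(planted_tract("chr9", 1L, 10L, .5, .5))), "unknown chromosome")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(planted_tract("chr1", 1L, 0L, .5, .5), "n_snps")
})

test_that("implied_odds_ratio matches direct arithmetic and its symmetry", {
  expect_identical(implied_odds_ratio(0.2, 0.2), 1)
  expect_equal(implied_odds_ratio(0.3, 0.1), (0.3 * 0.9) / (0.1 * 0.7))
  expect_equal(implied_odds_ratio(0.1, 0.3),
               1 / implied_odds_ratio(0.3, 0.1))
  expect_error(implied_odds_ratio(0, 0.5), "undefined")
  expect_error(implied_odds_ratio(0.5, 1), "undefined")
})

test_that("exome simulation respects configured length bounds", {
  regions <- data.frame(region_id = "ctoh_001", chrom = "chr1",
                        start_idx = 1L, end_idx = 100L,
                        start_bp = 50000L, end_bp = 850000L, n_snps = 100L,
                        bp_length = 800001L, min_cov = 12L, max_cov = 20L)
  cfg <- exome_config(n_samples = 8L, indels_per_sample = 1250L,
                      n_repeats = 500L, background_in_genes = TRUE,
                      n_planted = 0L, n_decoys = 0L, n_genes = 5L, seed = 5L)
  ex <- simulate_exome_features(cfg, regions)
  expect_gte(nrow(ex$indels), 9000)           # 10,000 requested draws
  expect_gte(min(ex$indels$length), 1)
  expect_lte(max(ex$indels$length), 191)
  rlen <- ex$repeats$end - ex$repeats$start
  expect_gte(min(rlen), 39 - 1)               # floor() on the end coordinate
  expect_lte(max(rlen), 21947)

  expect_identical(nrow(simulate_exome_features(
    exome_config(n_samples = 0L, n_planted = 0L, seed = 2L),
    regions)$indels), 0L)
  expect_error(simulate_exome_features(exome_config(seed = 3L),
                                       regions[0, ]), "no cTOH regions")
})
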