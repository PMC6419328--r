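# Coverage track, cTOH region construction and carrier assignment.

make_toh_df <- function(sample_id, start, end, map) {
  data.frame(sample_id = sample_id, chrom = map$chrom[start],
             start_idx = start, end_idx = end,
             start_bp = map$bp[start], end_bp = map$bp[end],
             n_snps = end - start + 1L, n_hom = end - start + 1L,
             n_het = 0L, n_missing = 0L)
}

test_that("toh_coverage counts distinct individuals per SNP", {
  gm <- toy_gm(matrix(0L, 1, 50))
  map <- gm$map
  empty <- data.frame(sample_id = character(), chrom = character(),
                      start_idx = integer(), end_idx = integer(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_hom = integer(),
                      n_het = integer(), n_missing = integer())
  expect_identical(toh_coverage(empty, map), integer(50))

  one <- make_toh_df("s1", 5L, 10L, map)
  cov <- toh_coverage(one, map)
  expect_identical(cov[5:10], rep(1L, 6))
  expect_identical(sum(cov), 6L)

  # overlapping tracts of the same individual count once
  two <- rbind(make_toh_df("s1", 5L, 10L, map), make_toh_df("s1", 8L, 15L, map))
  expect_identical(max(toh_coverage(two, map)), 1L)

  # brute-force per-position membership oracle on random tracts
  set.seed(41)
  for (rep in 1:10) {
    n <- 80L
    gm2 <- toy_gm(matrix(0L, 1, n),
                  chrom = rep(c("chr1", "chr2"), each = n / 2))
    starts <- sample.int(n - 5L, 60, replace = TRUE)
    ends <- pmin(starts + sample.int(10L, 60, replace = TRUE),
                 ifelse(starts <= n / 2, n / 2, n))
    starts <- pmax(starts, ifelse(ends > n / 2, n / 2 + 1L, 1L))
    tohs <- make_toh_df(sample(sprintf("s%02d", 1:12), 60, replace = TRUE),
                        starts, ends, gm2$map)
    want <- vapply(seq_len(n), function(j)
      length(unique(tohs$sample_id[tohs$start_idx <= j & tohs$end_idx >= j])),
      0L)
    expect_identical(toh_coverage(tohs, gm2$map), want)
  }
})

test_that("define_ctohs keeps maximal qualifying runs only", {
  gm <- toy_gm(matrix(0L, 1, 300))
  map <- gm$map
  # 99 consecutive SNPs at coverage 10: below the 100-SNP rule
  cov <- integer(300); cov[101:199] <- 10L
  expect_identical(nrow(define_ctohs(cov, map, 10L, 100L)), 0L)
  # exactly 100 at coverage 12: one region of 100 SNPs
  cov2 <- integer(300); cov2[101:200] <- 12L
  r <- define_ctohs(cov2, map, 10L, 100L)
  expect_identical(nrow(r), 1L)
  expect_identical(r$n_snps, 100L)
  expect_identical(r$start_idx, 101L)
  expect_identical(r$min_cov, 12L)

  # random coverage tracks vs the brute-force maximal-run oracle
  set.seed(43)
  for (rep in 1:25) {
    cov3 <- sample(0:15, 300, replace = TRUE)
    got <- define_ctohs(cov3, map, 9L, 4L)
    want <- oracle_coverage_runs(cov3, 9L, 4L)
    expect_identical(cbind(start = got$start_idx, end = got$end_idx), want)
  }

  # runs reset at chromosome boundaries
  gm2 <- toy_gm(matrix(0L, 1, 40), chrom = rep(c("chr1", "chr2"), each = 20))
  cov4 <- rep(10L, 40)
  r2 <- define_ctohs(cov4, gm2$map, 5L, 10L)
  expect_identical(nrow(r2), 2L)
  expect_identical(r2$chrom, c("chr1", "chr2"))
})

test_that("regions are disjoint, sorted and never mergeable", {
  set.seed(47)
  gm <- toy_gm(matrix(0L, 1, 500))
  for (rep in 1:10) {
    cov <- sample(0:12, 500, replace = TRUE)
    r <- define_ctohs(cov, gm$map, 8L, 3L)
    if (nrow(r) < 2L) next
    expect_true(all(diff(r$start_idx) > 0))
    expect_true(all(r$start_idx[-1] > r$end_idx[-nrow(r)] + 1L))
  }
})

test_that("assign_carriers applies the exact covered-SNP threshold", {
  gm <- toy_gm(matrix(0L, 1, 200))
  map <- gm$map
  cov <- integer(200); cov[51:150] <- 10L
  regions <- define_ctohs(cov, map, 10L, 100L)
  ids <- sprintf("s%02d", 1:5)
  # full cover, no tract, and fractional covers right at the 0.9 boundary
  tohs <- rbind(
    make_toh_df("s01", 51L, 150L, map),   # covers 100/100
    make_toh_df("s03", 61L, 150L, map),   # covers 90/100  -> carrier at 0.9
    make_toh_df("s04", 62L, 150L, map),   # covers 89/100  -> not a carrier
    make_toh_df("s05", 40L, 100L, map))   # covers 50/100
  carriers <- assign_carriers(regions, tohs, ids, min_cover_frac = 0.9)
  expect_identical(as.integer(carriers[, 1]), c(1L, 0L, 1L, 0L, 0L))

  # per-SNP counting oracle across random fractions
  set.seed(49)
  for (rep in 1:10) {
    st <- sample(30:70, 8); en <- pmin(st + sample(60:130, 8), 200L)
    tohs2 <- make_toh_df(sprintf("s%02d", 1:8), st, en, map)
    got <- assign_carriers(regions, tohs2, sprintf("s%02d", 1:8), 0.75)
    covered <- vapply(seq_len(8), function(i)
      sum(seq(st[i], en[i]) %in% 51:150), 0L)
    expect_identical(as.integer(got[, 1]),
                     as.integer(covered >= ceiling(0.75 * 100 - 1e-9)))
  }
  expect_error(assign_carriers(regions, tohs, ids, 0), "min_cover_frac")
  expect_error(assign_carriers(regions, tohs, ids, 1.2), "min_cover_frac")
})

test_that("a planted tract is recovered as a single intersecting region", {
  # one seed here; the replicated recovery experiment lives in the
  # acceptance suite
  cfg <- sim_config(planted_tracts = list(
    planted_tract("chr3", 400L, 150L, p_case = 0.3, p_control = 0.1)),
    seed = 53L)
  co <- simulate_cohort(cfg)
  tohs <- call_tohs(co$genotypes)
  cov <- toh_coverage(tohs, co$genotypes$map)
  regions <- define_ctohs(cov, co$genotypes$map)
  span <- co$truth_tracts[[1]]$snp_index
  hit <- regions$end_idx >= span[1] & regions$start_idx <= span[2] &
    regions$chrom == "chr3"
  expect_identical(sum(hit), 1L)
})
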