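# Interval intersection, indel clustering, the recurrence + repeat
# filter, gene shortlisting and per-chromosome repeat summaries.

test_that("intersect_intervals matches the all-pairs oracle", {
  a <- genomic_intervals("chr1", 0, 10, name = "X")
  b <- genomic_intervals("chr1", 10, 20, name = "Y")
  expect_identical(nrow(intersect_intervals(a, b)), 0L)   # abutting, no base
  expect_identical(intersect_intervals(a, a),
                   data.frame(query = 1L, subject = 1L))

  set.seed(73)
  for (rep in 1:8) {
    q <- random_intervals(120)
    s <- random_intervals(150)
    got <- intersect_intervals(q, s)
    want <- oracle_intersect(q, s)
    expect_identical(got[order(got$query, got$subject), ],
                     want[order(want$query, want$subject), ],
                     ignore_attr = TRUE)
    # symmetry: pair set of (A,B) is the transpose of (B,A)
    rev <- intersect_intervals(s, q)
    expect_identical(got[order(got$query, got$subject), c("query", "subject")],
                     stats::setNames(rev[order(rev$subject, rev$query),
                                         c("subject", "query")],
                                     c("query", "subject")),
                     ignore_attr = TRUE)
  }
  expect_error(genomic_intervals("chr1", 5, 5), "malformed")
  expect_error(genomic_intervals("chr1", -1, 5), "malformed")
  expect_error(genomic_intervals("", 0, 5), "malformed")
})

test_that("cluster_indels matches the union-find oracle", {
  one <- data.frame(sample = "s1", chrom = "chr1", pos = 100, length = 5,
                    type = "deletion")
  cl1 <- cluster_indels(one)
  expect_identical(nrow(cl1$clusters), 1L)
  expect_identical(cl1$clusters$n_samples, 1L)

  # identical positions in 3 of 8 samples: one cluster, sample count 3
  three <- data.frame(sample = c("s1", "s4", "s7"), chrom = "chr2",
                      pos = 500, length = 12, type = "insertion")
  cl3 <- cluster_indels(three)
  expect_identical(nrow(cl3$clusters), 1L)
  expect_identical(cl3$clusters$n_samples, 3L)
  expect_identical(cl3$clusters$samples, "s1,s4,s7")

  set.seed(79)
  for (mw in c(0, 5, 25)) for (rep in 1:6) {
    n <- 60L
    ind <- data.frame(sample = sample(sprintf("s%d", 1:6), n, replace = TRUE),
                      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                      pos = sample.int(400, n, replace = TRUE),
                      length = sample.int(30, n, replace = TRUE),
                      type = "deletion")
    got <- cluster_indels(ind, mw)$calls$cluster_id
    want <- oracle_cluster(ind, mw)
    # same partition: cluster labels must be a bijection
    expect_identical(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(x) length(unique(x)) == 1L)))
  }
  expect_error(cluster_indels(one, -1), "merge_window")
})

test_that("merge_window = 0 clusters exactly the overlapping calls and widening never splits", {
  a <- data.frame(sample = c("s1", "s2"), chrom = "chr1", pos = c(100, 110),
                  length = c(10, 10), type = "deletion")
  # spans [99,109) and [109,119): abutting, not overlapping
  expect_identical(nrow(cluster_indels(a, 0)$clusters), 2L)
  expect_identical(nrow(cluster_indels(a, 1)$clusters), 1L)

  set.seed(83)
  ind <- data.frame(sample = sample(sprintf("s%d", 1:5), 40, replace = TRUE),
                    chrom = "chr1", pos = sample.int(300, 40, replace = TRUE),
                    length = sample.int(20, 40, replace = TRUE),
                    type = "insertion")
  narrow <- cluster_indels(ind, 2)$calls$cluster_id
  wide <- cluster_indels(ind, 40)$calls$cluster_id
  # every narrow cluster sits inside one wide cluster
  expect_true(all(tapply(wide, narrow, function(x) length(unique(x)) == 1L)))
})

test_that("recurrent_indels enforces both conjuncts of the filter", {
  repeats <- genomic_intervals("chr1", 480, 600, name = "IR1",
                               class = "inverted")
  # 3-sample cluster with no repeat overlap: excluded
  far <- cluster_indels(data.frame(sample = c("s1", "s2", "s3"),
                                   chrom = "chr1", pos = 2000, length = 5,
                                   type = "deletion"))
  expect_identical(nrow(recurrent_indels(far, repeats, 3L)), 0L)
  # 2-sample cluster inside a repeat: excluded
  two <- cluster_indels(data.frame(sample = c("s1", "s2"), chrom = "chr1",
                                   pos = 500, length = 5, type = "deletion"))
  expect_identical(nrow(recurrent_indels(two, repeats, 3L)), 0L)
  # 3-sample cluster inside a repeat: retained with its repeat label
  good <- cluster_indels(data.frame(sample = c("s1", "s2", "s5"),
                                    chrom = "chr1", pos = 500, length = 5,
                                    type = "deletion"))
  kept <- recurrent_indels(good, repeats, 3L)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$repeat_names, "IR1")
})

test_that("shortlist_genes applies the spatial and support conjuncts", {
  regions <- data.frame(region_id = "ctoh_001", chrom = "chr1",
                        start_idx = 1L, end_idx = 100L, start_bp = 10001L,
                        end_bp = 60000L, n_snps = 100L, bp_length = 50000L,
                        min_cov = 10L, max_cov = 15L)
  genes <- genomic_intervals(c("chr1", "chr1", "chr2"),
                             c(20000, 70000, 20000),
                             c(30000, 80000, 30000),
                             name = c("IN_REGION", "OUTSIDE", "OTHER_CHR"),
                             class = "gene")
  repeats <- genomic_intervals("chr1", 24000, 26000, name = "IRX",
                               class = "simple")
  indels <- data.frame(sample = c("s1", "s2", "s3", "s4"), chrom = "chr1",
                       pos = c(25000, 25003, 25006, 75000),
                       length = c(4, 4, 4, 4), type = "deletion")
  kept <- recurrent_indels(cluster_indels(indels), repeats, 3L)
  sl <- shortlist_genes(genes, regions, kept)
  expect_identical(sl$gene, "IN_REGION")
  expect_identical(sl$n_samples, 3L)
  expect_identical(sl$samples, "s1,s2,s3")
  expect_identical(sl$region_ids, "ctoh_001")

  # order invariance of every input
  set.seed(89)
  sl2 <- shortlist_genes(genes[sample(3), ], regions, kept)
  expect_identical(sl, sl2)
})

test_that("ir_summary restricts to in-region repeats and counts genes", {
  regions <- data.frame(region_id = c("ctoh_001", "ctoh_002"),
                        chrom = c("chr1", "chr2"),
                        start_idx = c(1L, 1L), end_idx = c(10L, 10L),
                        start_bp = c(1001L, 1001L), end_bp = c(50000L, 50000L),
                        n_snps = c(10L, 10L), bp_length = c(49000L, 49000L),
                        min_cov = c(10L, 10L), max_cov = c(10L, 10L))
  repeats <- genomic_intervals(
    c("chr1", "chr1", "chr2", "chr3"),
    c(2000, 100000, 10000, 5000),
    c(2500, 100400, 12000, 5600),
    name = c("in1", "out1", "in2", "nochr"),
    class = c("inverted", "inverted", "simple", "simple"))
  genes <- genomic_intervals(c("chr1", "chr2"), c(2100, 40000),
                             c(2400, 45000), name = c("G1", "G2"),
                             class = "gene")
  s <- ir_summary(repeats, regions, genes)
  expect_identical(s$chrom, c("chr1", "chr2"))
  expect_identical(s$n_irs, c(1L, 1L))
  expect_identical(s$n_genes_with_irs, c(1L, 0L))
  expect_identical(s$min_bp[1], 500)
  expect_identical(s$mean_bp[2], 2000)

  # singleton: min = max = mean
  s1 <- ir_summary(repeats[1, ], regions, genes[0, ])
  expect_identical(c(s1$min_bp, s1$max_bp, s1$mean_bp), rep(500, 3))

  # hand-rolled counting oracle on a random annotation set
  set.seed(97)
  rr <- random_intervals(100, max_pos = 60000, max_len = 3000)
  gg <- random_intervals(30, max_pos = 60000, max_len = 4000)
  s2 <- ir_summary(rr, regions, gg)
  ov <- function(x, ch, s, e) x$chrom == ch & x$start < e & s < x$end
  for (i in seq_len(nrow(s2))) {
    ch <- s2$chrom[i]
    reg <- regions[regions$chrom == ch, ]
    insel <- ov(rr, ch, reg$start_bp - 1, reg$end_bp)
    expect_identical(s2$n_irs[i], sum(insel))
    expect_equal(s2$mean_bp[i], mean(rr$end[insel] - rr$start[insel]))
    ghits <- vapply(which(gg$chrom == ch), function(gi)
      any(insel & rr$start < gg$end[gi] & gg$start[gi] < rr$end &
            rr$chrom == ch), TRUE)
    expect_identical(s2$n_genes_with_irs[i], sum(ghits))
  }
})

test_that("planted exome truth survives the full integration filter exactly", {
  regions <- data.frame(region_id = c("ctoh_001", "ctoh_002"),
                        chrom = c("chr1", "chr2"),
                        start_idx = c(1L, 1L), end_idx = c(150L, 150L),
                        start_bp = c(100001L, 200001L),
                        end_bp = c(900000L, 1100000L),
                        n_snps = c(150L, 150L),
                        bp_length = c(800000L, 900000L),
                        min_cov = c(11L, 12L), max_cov = c(20L, 25L))
  for (seed in 1:6) {
    ex <- simulate_exome_features(exome_config(seed = seed), regions)
    cl <- cluster_indels(ex$indels, 10)
    kept <- recurrent_indels(cl, ex$repeats, 3L)
    sl <- shortlist_genes(ex$genes, regions, kept)
    expect_identical(sl$gene, ex$truth_shortlist)
    expect_length(intersect(sl$gene, ex$decoy_genes), 0)
  }
})
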