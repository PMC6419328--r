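# Independent brute-force oracles used to cross-check the implementation.
# Each oracle recomputes the quantity from first principles along a code
# path disjoint from the package's own.

# All maximal homozygous windows of a genotype vector, by exhaustive
# O(n^2) enumeration with prefix sums: a window [l, r] is valid when it
# starts and ends on a homozygous call, holds >= min_snps homozygous
# calls and at most max_het het / max_missing missing calls; it is
# maximal when no valid window strictly contains it.
oracle_maximal_windows <- function(g, min_snps, max_het, max_missing) {
  n <- length(g)
  hom <- !is.na(g) & g != 1L
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  ch <- c(0L, cumsum(hom)); ct <- c(0L, cumsum(het)); cm <- c(0L, cumsum(mis))
  valid <- NULL
  for (l in seq_len(n)) {
    if (!hom[l]) next
    r <- l:n
    ok <- hom[r] &
      (ch[r + 1L] - ch[l]) >= min_snps &
      (ct[r + 1L] - ct[l]) <= max_het &
      (cm[r + 1L] - cm[l]) <= max_missing
    if (any(ok)) valid <- rbind(valid, cbind(l, r[ok]))
  }
  if (is.null(valid)) return(cbind(start = integer(), end = integer()))
  # containment filter: sorted by start, a window is maximal iff its end
  # strictly exceeds every earlier (equal-or-smaller start) window's end
  best_end <- tapply(valid[, 2], valid[, 1], max)
  starts <- as.integer(names(best_end))
  o <- order(starts)
  starts <- starts[o]; ends <- as.integer(best_end)[o]
  keep <- ends > cummax(c(-1L, ends[-length(ends)]))
  cbind(start = starts[keep], end = ends[keep])
}

# Exact Hardy-Weinberg p-value via the direct log-factorial formula:
# P(h | nA, n) = n! / (nAA! h! nBB!) * 2^h * nA! nB! / (2n)!
oracle_hwe <- function(n_hom_a, n_het, n_hom_b) {
  n <- n_hom_a + n_het + n_hom_b
  na <- 2 * n_hom_a + n_het
  nb <- 2 * n - na
  hs <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  lp <- vapply(hs, function(h) {
    naa <- (na - h) / 2; nbb <- (nb - h) / 2
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, 0)
  pr <- exp(lp)
  obs <- pr[match(n_het, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Maximal coverage runs by double loop.
oracle_coverage_runs <- function(coverage, min_subjects, min_snps) {
  n <- length(coverage)
  runs <- NULL
  i <- 1L
  while (i <= n) {
    if (coverage[i] >= min_subjects) {
      j <- i
      while (j < n && coverage[j + 1L] >= min_subjects) j <- j + 1L
      if (j - i + 1L >= min_snps) runs <- rbind(runs, c(i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(runs)) cbind(start = integer(), end = integer())
  else cbind(start = runs[, 1], end = runs[, 2])
}

# All-pairs interval intersection.
oracle_intersect <- function(query, subject) {
  pairs <- NULL
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chrom[i] == subject$chrom[j] &&
        query$start[i] < subject$end[j] && subject$start[j] < query$end[i])
      pairs <- rbind(pairs, c(i, j))
  }
  if (is.null(pairs)) return(data.frame(query = integer(), subject = integer()))
  data.frame(query = pairs[, 1], subject = pairs[, 2])
}

# Transitive-closure indel clustering by union-find over all linked pairs.
oracle_cluster <- function(indels, merge_window) {
  n <- nrow(indels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  s <- indels$pos - 1
  e <- s + indels$length
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && indels$chrom[i] == indels$chrom[j] &&
        s[i] < e[j] + merge_window && s[j] < e[i] + merge_window) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, 0L)
}

# Naive Benjamini-Hochberg with an explicit min-over-tail.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- i:m
    q[o[i]] <- min(1, min(m * p[o[j]] / j))
  }
  q
}

# Closed-form 2x2 log odds ratio and Woolf SE.
oracle_woolf <- function(case_car, case_non, ctrl_car, ctrl_non) {
  list(beta = log(case_car * ctrl_non / (case_non * ctrl_car)),
       se = sqrt(1 / case_car + 1 / case_non + 1 / ctrl_car + 1 / ctrl_non))
}

# Random interval table on a handful of chromosomes.
random_intervals <- function(n, max_pos = 1000, max_len = 60,
                             chroms = c("chr1", "chr2", "chr3")) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             name = sprintf("iv%04d", seq_len(n)),
             class = NA_character_)
}

# Random genotype vector with given call-state probabilities.
random_geno_row <- function(n, p_hom = 0.62, p_het = 0.35) {
  states <- sample(c(0L, 2L, 1L, NA_integer_), n, replace = TRUE,
                   prob = c(p_hom / 2, p_hom / 2, p_het, 1 - p_hom - p_het))
  states
}

# Tiny genotype_matrix built from an explicit genotype matrix.
toy_gm <- function(geno, chrom = NULL, bp = NULL, phenotype = NULL,
                   sex = NULL) {
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(bp)) bp <- unlist(lapply(split(seq_len(m), chrom)[unique(chrom)],
                                       seq_along)) * 100L
  if (is.null(phenotype)) phenotype <- rep_len(c(1L, 0L), n)
  if (is.null(sex)) sex <- rep_len(c(0L, 1L), n)
  genotype_matrix(geno,
                  data.frame(chrom = chrom,
                             snp_id = sprintf("snp%04d", seq_len(m)),
                             bp = as.integer(bp)),
                  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                             phenotype = phenotype, sex = sex))
}

# Vectorised all-pairs intersection oracle (same brute-force predicate as
# oracle_intersect, expanded per chromosome instead of looped).
oracle_intersect_fast <- function(query, subject) {
  out <- list()
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    grid <- expand.grid(q = qi, s = si)
    keep <- query$start[grid$q] < subject$end[grid$s] &
      subject$start[grid$s] < query$end[grid$q]
    out[[ch]] <- grid[keep, ]
  }
  if (!length(out)) return(data.frame(query = integer(), subject = integer()))
  all <- do.call(rbind, out)
  data.frame(query = all$q, subject = all$s)
}

# Union-find clustering over the explicitly enumerated linked pairs.
oracle_cluster_fast <- function(indels, merge_window) {
  n <- nrow(indels)
  s <- indels$pos - 1
  e <- s + indels$length
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ch in unique(indels$chrom)) {
    ci <- which(indels$chrom == ch)
    grid <- expand.grid(i = ci, j = ci)
    grid <- grid[grid$i < grid$j, ]
    linked <- s[grid$i] < e[grid$j] + merge_window &
      s[grid$j] < e[grid$i] + merge_window
    for (k in which(linked)) {
      ri <- find(grid$i[k]); rj <- find(grid$j[k])
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, 0L)
}

# Partition equality: two cluster labelings describe the same partition.
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(tapply(b, a, function(x) length(unique(x)) == 1L))
}
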