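# Genotype quality control: sample call rate, per-SNP missingness,
# exact Hardy-Weinberg test and minor allele frequency filters.

#' Quality-control thresholds
#'
#' Defaults follow standard array QC practice: samples need a 95% call
#' rate; SNPs are dropped for > 5% missingness, Hardy-Weinberg exact
#' p-value below 1e-7, or minor allele frequency below 3%.
#'
#' @param min_sample_call_rate Minimum fraction of non-missing calls per
#'   sample.
#' @param max_snp_missingness Maximum fraction of missing calls per SNP.
#' @param hwe_alpha SNPs with exact Hardy-Weinberg p-value strictly below
#'   this are removed.
#' @param min_maf Minimum minor allele frequency.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_sample_call_rate = 0.95,
                          max_snp_missingness = 0.05,
                          hwe_alpha = 1e-7,
                          min_maf = 0.03) {
  vals <- c(min_sample_call_rate, max_snp_missingness, hwe_alpha, min_maf)
  if (any(vals < 0 | vals > 1)) stop("all thresholds must be in [0, 1]")
  structure(list(min_sample_call_rate = min_sample_call_rate,
                 max_snp_missingness = max_snp_missingness,
                 hwe_alpha = hwe_alpha, min_maf = min_maf),
            class = "qc_thresholds")
}

#' Per-sample genotype call rate
#'
#' Fraction of non-missing calls, per genotype row.
#'
#' @param geno A genotype vector (one individual) or an
#'   individuals-by-SNPs matrix; `NA` marks missing calls.
#' @return A numeric vector of call rates (one per row for a matrix).
#' @export
sample_call_rate <- function(geno) {
  if (is.matrix(geno)) {
    if (ncol(geno) == 0L) stop("zero-length genotype rows")
    return(rowMeans(!is.na(geno)))
  }
  if (length(geno) == 0L) stop("zero-length genotype row")
  mean(!is.na(geno))
}

# Normalised log-probabilities of every heterozygote count compatible
# with `n_minor` copies of the minor allele among `n_total` diploids,
# under the exact conditional Hardy-Weinberg null.  Computed with the
# ratio recurrence P(h+2)/P(h) = 4 nAA nBB / ((h+1)(h+2)) in log space.
hwe_het_log_probs <- function(n_minor, n_total) {
  h <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  n_major <- 2L * n_total - n_minor
  lp <- numeric(length(h))
  if (length(h) > 1L) {
    hh <- h[-length(h)]
    naa <- (n_minor - hh) / 2
    nbb <- (n_major - hh) / 2
    steps <- log(4 * naa * nbb) - log((hh + 2) * (hh + 1))
    lp <- c(0, cumsum(steps))
  }
  mx <- max(lp)
  list(het = h, log_prob = lp - (mx + log(sum(exp(lp - mx)))))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, every
#' compatible heterozygote count is enumerated, its probability under the
#' Hardy-Weinberg null computed, and the p-value is the sum of the
#' probabilities of all configurations no more likely than the observed
#' one.  Vectorised over SNPs; work is shared across SNPs with the same
#' (total, minor-allele-count) pair.
#'
#' @param n_hom_a,n_het,n_hom_b Genotype counts (recycled to a common
#'   length); each total must be positive.
#' @return Exact p-values in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_a, n_het, n_hom_b) {
  k <- max(length(n_hom_a), length(n_het), length(n_hom_b))
  a <- rep_len(as.numeric(n_hom_a), k)
  h <- rep_len(as.numeric(n_het), k)
  b <- rep_len(as.numeric(n_hom_b), k)
  if (any(is.na(a) | is.na(b) | is.na(h)) || any(a < 0 | h < 0 | b < 0))
    stop("genotype counts must be non-negative")
  n <- a + h + b
  if (any(n == 0)) stop("total genotype count must be positive")
  n_a <- 2 * a + h
  n_minor <- pmin(n_a, 2 * n - n_a)
  out <- numeric(k)
  grp <- split(seq_len(k), paste(n, n_minor))
  for (idx in grp) {
    d <- hwe_het_log_probs(n_minor[idx[1]], n[idx[1]])
    pr <- exp(d$log_prob)
    # p-value for each possible het count, with a relative tolerance on
    # the "no more likely" comparison so exact ties are kept together
    ord <- order(pr)
    cum <- cumsum(pr[ord])
    pos <- findInterval(pr[ord] * (1 + 1e-9), pr[ord])
    pv_by_het <- numeric(length(pr))
    pv_by_het[ord] <- pmin(cum[pos], 1)
    out[idx] <- pv_by_het[match(h[idx], d$het)]
  }
  if (anyNA(out)) stop("heterozygote count incompatible with allele counts")
  out
}

#' Minor allele frequency from genotype counts
#'
#' @param n_hom_a,n_het,n_hom_b Genotype counts (recycled); each total
#'   must be positive.
#' @return `min(f_A, f_B)` where `f_A = (2 n_hom_a + n_het) / (2 total)`.
#' @export
minor_allele_frequency <- function(n_hom_a, n_het, n_hom_b) {
  k <- max(length(n_hom_a), length(n_het), length(n_hom_b))
  a <- rep_len(as.numeric(n_hom_a), k)
  h <- rep_len(as.numeric(n_het), k)
  b <- rep_len(as.numeric(n_hom_b), k)
  n <- a + h + b
  if (any(n == 0)) stop("total genotype count must be positive")
  fa <- (2 * a + h) / (2 * n)
  pmin(fa, 1 - fa)
}

#' Apply genotype quality control
#'
#' Samples below the minimum call rate are removed first; SNP statistics
#' are then computed on the retained samples, and SNPs failing the
#' missingness, Hardy-Weinberg or minor-allele-frequency thresholds (in
#' that order of recorded reason) are removed.
#'
#' @param gm A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()] object.
#' @param hwe_on Compute the Hardy-Weinberg test on all retained samples
#'   (`"all"`, default) or on controls only (`"controls"`).
#' @return A list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report` (class `qc_report`: removed samples and SNPs with reasons,
#'   per-SNP statistics, thresholds, and reconciling counts).
#' @export
apply_qc <- function(gm, thresholds = qc_thresholds(),
                     hwe_on = c("all", "controls")) {
  if (!inherits(gm, "genotype_matrix")) stop("`gm` must be a genotype_matrix")
  if (!inherits(thresholds, "qc_thresholds"))
    stop("`thresholds` must come from qc_thresholds()")
  hwe_on <- match.arg(hwe_on)
  g <- gm$geno
  if (nrow(g) == 0L || ncol(g) == 0L) stop("empty genotype matrix")

  cr <- sample_call_rate(g)
  drop_samp <- cr < thresholds$min_sample_call_rate
  if (all(drop_samp))
    stop("all ", nrow(g), " samples fall below the minimum call rate ",
         thresholds$min_sample_call_rate)
  samples_removed <- data.frame(
    sample_id = gm$samples$sample_id[drop_samp],
    reason = rep("call_rate", sum(drop_samp)),
    call_rate = cr[drop_samp])

  g2 <- g[!drop_samp, , drop = FALSE]
  samples2 <- gm$samples[!drop_samp, , drop = FALSE]

  miss <- colMeans(is.na(g2))
  gh <- if (hwe_on == "controls") {
    g2[samples2$phenotype %in% 0L, , drop = FALSE]
  } else g2
  a <- colSums(gh == 0L, na.rm = TRUE)
  h <- colSums(gh == 1L, na.rm = TRUE)
  b <- colSums(gh == 2L, na.rm = TRUE)
  tot <- a + h + b
  hwe_p <- rep(NA_real_, ncol(g2))
  hwe_p[tot > 0] <- hwe_exact_test(a[tot > 0], h[tot > 0], b[tot > 0])

  ac <- colSums(g2 == 0L, na.rm = TRUE)
  hc <- colSums(g2 == 1L, na.rm = TRUE)
  bc <- colSums(g2 == 2L, na.rm = TRUE)
  totc <- ac + hc + bc
  maf <- rep(NA_real_, ncol(g2))
  maf[totc > 0] <- minor_allele_frequency(ac[totc > 0], hc[totc > 0],
                                          bc[totc > 0])

  fail_miss <- miss > thresholds$max_snp_missingness | totc == 0
  fail_hwe <- !is.na(hwe_p) & hwe_p < thresholds$hwe_alpha
  fail_maf <- !is.na(maf) & maf < thresholds$min_maf
  drop_snp <- fail_miss | fail_hwe | fail_maf
  reason <- rep(NA_character_, ncol(g2))
  reason[fail_maf] <- "maf"
  reason[fail_hwe] <- "hwe"
  reason[fail_miss] <- "missingness"

  snp_stats <- data.frame(snp_id = gm$map$snp_id, missingness = miss,
                          maf = maf, hwe_p = hwe_p)
  snps_removed <- data.frame(snp_id = gm$map$snp_id[drop_snp],
                             reason = reason[drop_snp])

  out <- genotype_matrix(g2[, !drop_snp, drop = FALSE],
                         gm$map[!drop_snp, , drop = FALSE],
                         samples2)
  report <- structure(list(
    samples_removed = samples_removed,
    snps_removed = snps_removed,
    snp_stats = snp_stats,
    thresholds = thresholds,
    hwe_on = hwe_on,
    n_samples_in = nrow(g), n_samples_out = nrow(g2),
    n_snps_in = ncol(g), n_snps_out = sum(!drop_snp)),
    class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report: samples", x$n_samples_in, "->", x$n_samples_out,
      "| SNPs", x$n_snps_in, "->", x$n_snps_out, "\n")
  if (nrow(x$snps_removed))
    print(table(x$snps_removed$reason))
  invisible(x)
}
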