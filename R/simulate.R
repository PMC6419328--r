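# Synthetic cohorts and exome annotation sets with recorded ground truth.
#
# The simulator emulates a dense biallelic SNP array: markers with
# exponential bp spacing, genotypes drawn from Hardy-Weinberg proportions
# at frequencies sampled in a MAF band, optional two-subpopulation
# Balding-Nichols structure, independent per-call dropout, and homozygous
# tracts planted at chosen case/control carrier probabilities.

#' Specify a planted homozygous tract
#'
#' A planted tract forces carriers to be homozygous at `n_snps`
#' consecutive markers, creating a shared tract of homozygosity whose
#' case/control carrier frequencies (`p_case`, `p_control`) define the
#' true association signal.
#'
#' @param chromosome Chromosome label (`"chr3"` or just `3`).
#' @param start_snp 1-based index of the first tract SNP on that
#'   chromosome.
#' @param n_snps Number of consecutive SNPs in the tract (>= 1).
#' @param p_case,p_control Carrier probabilities in cases and controls,
#'   each in `[0, 1]`.
#' @return An object of class `planted_tract`.
#' @seealso [implied_odds_ratio()] for the odds ratio the two carrier
#'   probabilities imply.
#' @export
planted_tract <- function(chromosome, start_snp, n_snps, p_case, p_control) {
  chromosome <- as.character(chromosome)
  if (!grepl("^chr", chromosome)) chromosome <- paste0("chr", chromosome)
  start_snp <- as.integer(start_snp)
  n_snps <- as.integer(n_snps)
  if (is.na(n_snps) || n_snps < 1L) stop("`n_snps` must be >= 1")
  if (is.na(start_snp) || start_snp < 1L) stop("`start_snp` must be >= 1")
  for (p in c(p_case, p_control))
    if (is.na(p) || p < 0 || p > 1) stop("carrier probabilities must be in [0, 1]")
  structure(list(chromosome = chromosome, start_snp = start_snp,
                 n_snps = n_snps, p_case = p_case, p_control = p_control),
            class = "planted_tract")
}

#' Configure a synthetic SNP cohort
#'
#' Defaults give a desk-scale cohort: 100 cases + 100 controls typed on
#' 4 chromosomes x 2,000 SNPs, mean marker spacing 5 kb, allele
#' frequencies in (0.05, 0.5), no population structure, 1% per-call
#' dropout.
#'
#' @param n_cases,n_controls Cohort arm sizes.
#' @param n_chromosomes,snps_per_chr Panel geometry; chromosomes are
#'   labelled `chr1..chrN`.
#' @param bp_spacing_mean Mean bp gap between adjacent markers
#'   (exponential spacing, cumulative 1-based positions).
#' @param maf_range Lower/upper bound of the minor-allele-frequency band
#'   markers are sampled from; within `(0, 0.5]`.
#' @param fst Balding-Nichols drift parameter in `[0, 1)`; `0` means a
#'   panmictic cohort, `> 0` splits individuals into two subpopulations
#'   whose allele frequencies are drawn
#'   `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral `p`.
#' @param planted_tracts List of [planted_tract()] objects.
#' @param sex_ratio Proportion of males (sex indicator 0) in the cohort.
#' @param missing_rate Independent per-call dropout probability.
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 100L, n_controls = 100L,
                       n_chromosomes = 4L, snps_per_chr = 2000L,
                       bp_spacing_mean = 5000, maf_range = c(0.05, 0.5),
                       fst = 0, planted_tracts = list(),
                       sex_ratio = 0.5, missing_rate = 0.01, seed = 1L) {
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  n_chromosomes <- as.integer(n_chromosomes)
  snps_per_chr <- as.integer(snps_per_chr)
  if (n_cases < 0L || n_controls < 0L || n_cases + n_controls < 1L)
    stop("need at least one individual")
  if (n_chromosomes < 1L) stop("`n_chromosomes` must be >= 1")
  if (snps_per_chr < 0L) stop("`snps_per_chr` must be >= 0")
  if (bp_spacing_mean <= 0) stop("`bp_spacing_mean` must be positive")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("`maf_range` must be within (0, 0.5]")
  if (fst < 0 || fst >= 1) stop("`fst` must be in [0, 1)")
  if (sex_ratio < 0 || sex_ratio > 1) stop("`sex_ratio` must be in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1) stop("`missing_rate` must be in [0, 1)")
  if (!is.list(planted_tracts) ||
      !all(vapply(planted_tracts, inherits, TRUE, "planted_tract")))
    stop("`planted_tracts` must be a list of planted_tract objects")
  chroms <- paste0("chr", seq_len(n_chromosomes))
  for (tr in planted_tracts) {
    if (!tr$chromosome %in% chroms)
      stop("planted tract on unknown chromosome ", tr$chromosome)
    if (tr$start_snp + tr$n_snps - 1L > snps_per_chr)
      stop("planted tract does not fit on ", tr$chromosome,
           " (", snps_per_chr, " SNPs)")
  }
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_chromosomes = n_chromosomes, snps_per_chr = snps_per_chr,
                 bp_spacing_mean = bp_spacing_mean, maf_range = maf_range,
                 fst = fst, planted_tracts = planted_tracts,
                 sex_ratio = sex_ratio, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a case-control SNP cohort with planted homozygous tracts
#'
#' Genotypes are drawn per SNP from Hardy-Weinberg proportions at an
#' allele frequency sampled inside `maf_range` (with Balding-Nichols
#' subpopulation drift when `fst > 0`).  Each planted tract then
#' overwrites its carriers' genotypes with per-SNP homozygous calls for
#' the locally more frequent allele, after which independent per-call
#' dropout is applied.  All randomness derives from `config$seed` through
#' fixed stage-level sub-seeds, so identical configurations reproduce
#' bit-identical cohorts.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `toh_cohort`: list with `genotypes` (a
#'   [genotype_matrix()]), `truth_tracts` (per planted tract, the tract
#'   spec, its global SNP index span and the per-individual carrier
#'   flags), `subpop` (integer subpopulation labels) and `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  set.seed(config$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 6L)
  n <- config$n_cases + config$n_controls
  m_chr <- config$snps_per_chr
  n_chr <- config$n_chromosomes
  m <- m_chr * n_chr
  chroms <- paste0("chr", seq_len(n_chr))

  set.seed(stage_seed[1])                               # marker map
  if (m > 0L) {
    map <- do.call(rbind, lapply(seq_len(n_chr), function(ci) {
      gaps <- pmax(1, round(stats::rexp(m_chr, 1 / config$bp_spacing_mean)))
      data.frame(chrom = chroms[ci],
                 snp_id = sprintf("%s_snp%05d", chroms[ci], seq_len(m_chr)),
                 bp = as.integer(cumsum(gaps)))
    }))
  } else {
    map <- data.frame(chrom = character(), snp_id = character(),
                      bp = integer())
  }

  set.seed(stage_seed[2])                               # individuals
  sample_id <- sprintf("ind%04d", seq_len(n))
  phenotype <- rep(c(1L, 0L), c(config$n_cases, config$n_controls))
  sex <- stats::rbinom(n, 1L, 1 - config$sex_ratio)     # 0 = male, 1 = female
  subpop <- if (config$fst > 0) sample(rep(1:2, length.out = n)) else rep(1L, n)

  set.seed(stage_seed[3])                               # allele frequencies
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  p_anc <- ifelse(stats::runif(m) < 0.5, 1 - maf, maf)  # freq of allele B
  if (config$fst > 0) {
    f <- config$fst
    a <- p_anc * (1 - f) / f
    b <- (1 - p_anc) * (1 - f) / f
    p_sub <- rbind(stats::rbeta(m, a, b), stats::rbeta(m, a, b))
    p_sub <- pmin(pmax(p_sub, 1e-6), 1 - 1e-6)
  } else {
    p_sub <- rbind(p_anc, p_anc)
  }

  set.seed(stage_seed[4])                               # genotypes
  geno <- matrix(NA_integer_, n, m)
  if (m > 0L) {
    for (k in sort(unique(subpop))) {
      rows <- which(subpop == k)
      geno[rows, ] <- matrix(
        stats::rbinom(length(rows) * m, 2L, rep(p_sub[k, ], each = length(rows))),
        nrow = length(rows))
    }
  }

  set.seed(stage_seed[5])                               # planted tracts
  truth <- vector("list", length(config$planted_tracts))
  for (i in seq_along(config$planted_tracts)) {
    tr <- config$planted_tracts[[i]]
    ci <- match(tr$chromosome, chroms)
    cols <- (ci - 1L) * m_chr + tr$start_snp + seq_len(tr$n_snps) - 1L
    pr <- ifelse(phenotype == 1L, tr$p_case, tr$p_control)
    carrier <- stats::rbinom(n, 1L, pr) == 1L
    hom <- ifelse(p_anc[cols] >= 0.5, 2L, 0L)           # locally major allele
    if (any(carrier))
      geno[carrier, cols] <- rep(hom, each = sum(carrier))
    truth[[i]] <- list(tract = tr, snp_index = range(cols), carrier = carrier)
  }

  set.seed(stage_seed[6])                               # dropout
  if (config$missing_rate > 0 && n * m > 0L)
    geno[stats::runif(n * m) < config$missing_rate] <- NA_integer_

  samples <- data.frame(sample_id = sample_id, phenotype = phenotype,
                        sex = sex)
  gm <- genotype_matrix(geno, map, samples)
  structure(list(genotypes = gm, truth_tracts = truth, subpop = subpop,
                 config = config),
            class = "toh_cohort")
}

#' @export
print.toh_cohort <- function(x, ...) {
  cat("toh_cohort:", x$config$n_cases, "cases +", x$config$n_controls,
      "controls,", ncol(x$genotypes$geno), "SNPs,",
      length(x$truth_tracts), "planted tract(s)\n")
  invisible(x)
}

#' Odds ratio implied by two carrier probabilities
#'
#' The true odds ratio of the carrier/disease association generated when
#' a tract is planted with carrier probability `p_case` in cases and
#' `p_control` in controls:
#' `p_case (1 - p_control) / (p_control (1 - p_case))`.
#'
#' @param p_case,p_control Probabilities strictly inside `(0, 1)`
#'   (boundary values give an undefined odds ratio).
#' @return The implied odds ratio (vectorised).
#' @export
implied_odds_ratio <- function(p_case, p_control) {
  if (any(p_case <= 0 | p_case >= 1 | p_control <= 0 | p_control >= 1))
    stop("odds ratio undefined at boundary probabilities; need (0, 1)")
  p_case * (1 - p_control) / (p_control * (1 - p_case))
}
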