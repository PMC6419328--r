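# Per-individual tract-of-homozygosity (TOH) calling.
#
# A tract is a maximal window of consecutive SNPs on one chromosome that
# contains at least `min_snps` homozygous calls, at most `max_het`
# heterozygous calls and at most `max_missing` missing calls, and that
# starts and ends on a homozygous call.  "Maximal" means no valid window
# strictly contains it.

#' Tract-calling parameters
#'
#' Defaults require 100 homozygous calls with strict homozygosity
#' (`max_het = 0`) while tolerating two missing calls of array dropout.
#'
#' @param min_snps Minimum number of homozygous calls in a tract.
#' @param max_het Maximum heterozygous calls allowed inside a tract.
#' @param max_missing Maximum missing calls allowed inside a tract.
#' @param min_bp Optional minimum bp span (first-to-last SNP, inclusive);
#'   `0` disables the filter.
#' @return An object of class `toh_params`.
#' @export
toh_params <- function(min_snps = 100L, max_het = 0L, max_missing = 2L,
                       min_bp = 0) {
  min_snps <- as.integer(min_snps)
  max_het <- as.integer(max_het)
  max_missing <- as.integer(max_missing)
  if (min_snps < 1L) stop("`min_snps` must be >= 1")
  if (max_het < 0L || max_missing < 0L) stop("allowances must be >= 0")
  if (min_bp < 0) stop("`min_bp` must be >= 0")
  structure(list(min_snps = min_snps, max_het = max_het,
                 max_missing = max_missing, min_bp = min_bp),
            class = "toh_params")
}

# Maximal homozygous windows in one genotype vector (one chromosome).
# Returns a matrix with columns start, end (local indices), n_hom, n_het,
# n_missing, or NULL when the vector holds no tract.
#
# For each homozygous start l the furthest admissible end R(l) sits just
# before the (max_het+1)-th het and the (max_missing+1)-th missing call
# at or after l; R(l) is non-decreasing in l, so after trimming the end
# back to the last homozygous call, the first start attaining each
# distinct end is exactly the set of maximal windows.
toh_windows <- function(g, params) {
  n <- length(g)
  hom_ind <- !is.na(g) & g != 1L
  hom <- which(hom_ind)
  if (length(hom) < params$min_snps) return(NULL)
  het <- which(!is.na(g) & g == 1L)
  mis <- which(is.na(g))

  lim_after <- function(pos, allow) {
    if (!length(pos)) return(rep.int(n, length(hom)))
    j <- findInterval(hom - 1L, pos) + allow + 1L
    ifelse(j <= length(pos), pos[j] - 1L, n)
  }
  r_max <- pmin(lim_after(het, params$max_het),
                lim_after(mis, params$max_missing))
  last_hom <- cummax(seq_len(n) * hom_ind)
  r <- last_hom[r_max]
  keep <- !duplicated(r)
  l <- hom[keep]
  r <- r[keep]

  ch <- cumsum(hom_ind)
  cht <- cumsum(!is.na(g) & g == 1L)
  cmis <- cumsum(is.na(g))
  n_hom <- ch[r] - ch[l] + 1L
  ok <- n_hom >= params$min_snps
  if (!any(ok)) return(NULL)
  l <- l[ok]; r <- r[ok]; n_hom <- n_hom[ok]
  cbind(start = l, end = r, n_hom = n_hom,
        n_het = cht[r] - ifelse(l > 1L, cht[l - 1L], 0L),
        n_missing = cmis[r] - ifelse(l > 1L, cmis[l - 1L], 0L))
}

#' Call tracts of homozygosity
#'
#' Scans every individual's genotypes chromosome by chromosome and
#' returns all maximal tract windows under the given parameters.  Tracts
#' never cross chromosome boundaries and never start or end on a
#' heterozygous or missing call.
#'
#' @param gm A [genotype_matrix()] (typically QC-passed).
#' @param params A [toh_params()] object.
#' @return A data frame of class `toh_calls`, one row per tract:
#'   `sample_id`, `chrom`, `start_idx`/`end_idx` (1-based global map row
#'   indices, inclusive), `start_bp`/`end_bp`, `n_snps` (index span
#'   size), `n_hom`, `n_het`, `n_missing`.
#' @export
call_tohs <- function(gm, params = toh_params()) {
  if (!inherits(gm, "genotype_matrix")) stop("`gm` must be a genotype_matrix")
  if (!inherits(params, "toh_params")) stop("`params` must come from toh_params()")
  validate_map(gm$map)
  blocks <- chrom_blocks(gm$map)
  res <- list()
  for (chrom in names(blocks)) {
    idx <- blocks[[chrom]]
    off <- idx[1] - 1L
    bp <- gm$map$bp[idx]
    for (i in seq_len(nrow(gm$geno))) {
      w <- toh_windows(gm$geno[i, idx], params)
      if (is.null(w)) next
      if (params$min_bp > 0) {
        span <- bp[w[, "end"]] - bp[w[, "start"]] + 1L
        w <- w[span >= params$min_bp, , drop = FALSE]
        if (!nrow(w)) next
      }
      res[[length(res) + 1L]] <- data.frame(
        sample_id = gm$samples$sample_id[i], chrom = chrom,
        start_idx = w[, "start"] + off, end_idx = w[, "end"] + off,
        start_bp = bp[w[, "start"]], end_bp = bp[w[, "end"]],
        n_snps = w[, "end"] - w[, "start"] + 1L,
        n_hom = w[, "n_hom"], n_het = w[, "n_het"],
        n_missing = w[, "n_missing"])
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(sample_id = character(), chrom = character(),
               start_idx = integer(), end_idx = integer(),
               start_bp = integer(), end_bp = integer(),
               n_snps = integer(), n_hom = integer(), n_het = integer(),
               n_missing = integer())
  rownames(out) <- NULL
  class(out) <- c("toh_calls", "data.frame")
  out
}

#' Summary statistics of tract lengths
#'
#' @param calls A [call_tohs()] result.
#' @return A data frame with one row per scale (`snp` span and `bp`
#'   span): count, min, max, mean, sd, median, first and third quartile.
#'   With no tracts, count is 0 and the statistics are `NA`.
#' @export
toh_length_summary <- function(calls) {
  stat_row <- function(x, scale) {
    if (length(x) == 0L)
      return(data.frame(scale = scale, count = 0L, min = NA_real_,
                        max = NA_real_, mean = NA_real_, sd = NA_real_,
                        median = NA_real_, q1 = NA_real_, q3 = NA_real_))
    q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75)))
    data.frame(scale = scale, count = length(x), min = min(x), max = max(x),
               mean = mean(x), sd = stats::sd(x), median = q[2],
               q1 = q[1], q3 = q[3])
  }
  bp_len <- if (nrow(calls)) calls$end_bp - calls$start_bp + 1 else numeric(0)
  rbind(stat_row(calls$n_snps, "snp"), stat_row(bp_len, "bp"))
}
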