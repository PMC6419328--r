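# Common-TOH (cTOH) regions: per-SNP coverage by individual tracts,
# maximal qualifying runs, and per-individual carrier status.

# Merge possibly-overlapping inclusive index spans (start, end) into
# disjoint spans.  Used so one individual never counts twice at a SNP.
merge_spans <- function(start, end) {
  if (length(start) == 0L) return(cbind(start = integer(), end = integer()))
  ord <- order(start, end)
  s <- start[ord]; e <- end[ord]
  cm <- cummax(e)
  new_grp <- c(TRUE, s[-1L] > cm[-length(cm)])
  grp <- cumsum(new_grp)
  cbind(start = as.integer(tapply(s, grp, min)),
        end = as.integer(tapply(e, grp, max)))
}

#' Per-SNP tract coverage
#'
#' Counts, at every SNP of the map, how many distinct individuals have a
#' tract of homozygosity covering that position.
#'
#' @param tohs A [call_tohs()] result.
#' @param map The marker map the tracts were called on.
#' @return An integer vector with one count per map row.
#' @export
toh_coverage <- function(tohs, map) {
  validate_map(map)
  n <- nrow(map)
  cov <- integer(n)
  if (nrow(tohs) == 0L) return(cov)
  if (any(tohs$start_idx < 1L | tohs$end_idx > n | tohs$end_idx < tohs$start_idx))
    stop("tract indices outside the map")
  if (any(map$chrom[tohs$start_idx] != tohs$chrom |
          map$chrom[tohs$end_idx] != tohs$chrom))
    stop("tract chromosome not found at its map indices")
  delta <- integer(n + 1L)
  for (spans in split(tohs[c("start_idx", "end_idx")], tohs$sample_id)) {
    m <- merge_spans(spans$start_idx, spans$end_idx)
    delta[m[, "start"]] <- delta[m[, "start"]] + 1L
    delta[m[, "end"] + 1L] <- delta[m[, "end"] + 1L] - 1L
  }
  cumsum(delta[-(n + 1L)])
}

#' Define common-TOH regions from a coverage track
#'
#' A cTOH region is a maximal run of consecutive SNPs, within one
#' chromosome, at which at least `min_subjects` individuals carry a
#' tract; runs shorter than `min_snps` SNPs are discarded.  Defaults (10
#' subjects, 100 SNPs) follow the shared-coverage consensus rule.
#'
#' @param coverage Integer coverage track from [toh_coverage()].
#' @param map The marker map (same length as `coverage`).
#' @param min_subjects Minimum number of covering individuals at every
#'   SNP of the region.
#' @param min_snps Minimum run length in SNPs.
#' @return A data frame of class `ctoh_regions`: `region_id`, `chrom`,
#'   `start_idx`, `end_idx` (global map rows, inclusive), `start_bp`,
#'   `end_bp`, `n_snps`, `bp_length`, `min_cov`, `max_cov`.
#' @export
define_ctohs <- function(coverage, map, min_subjects = 10L, min_snps = 100L) {
  validate_map(map)
  if (length(coverage) != nrow(map))
    stop("coverage length does not match the map")
  min_subjects <- as.integer(min_subjects)
  min_snps <- as.integer(min_snps)
  if (min_subjects < 1L || min_snps < 1L)
    stop("`min_subjects` and `min_snps` must be >= 1")
  res <- list()
  for (idx in chrom_blocks(map)) {
    ok <- coverage[idx] >= min_subjects
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values & r$lengths >= min_snps)
    for (j in sel) {
      gi <- idx[starts[j]:ends[j]]
      res[[length(res) + 1L]] <- data.frame(
        chrom = map$chrom[gi[1]],
        start_idx = gi[1], end_idx = gi[length(gi)],
        start_bp = map$bp[gi[1]], end_bp = map$bp[gi[length(gi)]],
        n_snps = length(gi),
        bp_length = map$bp[gi[length(gi)]] - map$bp[gi[1]] + 1L,
        min_cov = min(coverage[gi]), max_cov = max(coverage[gi]))
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), start_idx = integer(),
               end_idx = integer(), start_bp = integer(), end_bp = integer(),
               n_snps = integer(), bp_length = integer(),
               min_cov = integer(), max_cov = integer())
  out <- cbind(region_id = if (nrow(out)) sprintf("ctoh_%03d", seq_len(nrow(out)))
               else character(), out)
  rownames(out) <- NULL
  class(out) <- c("ctoh_regions", "data.frame")
  out
}

#' Assign per-individual cTOH carrier status
#'
#' An individual carries a region when their own tracts cover at least
#' `min_cover_frac` of the region's SNPs; the covered-SNP threshold is
#' `ceiling(min_cover_frac * n_snps)` with a 1e-9 guard so that coverage
#' exactly at the fraction counts as carriage.
#'
#' @param regions A [define_ctohs()] result.
#' @param tohs The [call_tohs()] result the regions were built from.
#' @param sample_ids Character vector of all individuals (rows of the
#'   returned matrix); individuals without tracts are non-carriers
#'   everywhere.
#' @param min_cover_frac Required covered fraction, in `(0, 1]`.
#' @return A binary integer matrix, individuals x regions, with
#'   `sample_ids` rownames and `region_id` colnames.
#' @export
assign_carriers <- function(regions, tohs, sample_ids, min_cover_frac = 0.9) {
  if (min_cover_frac <= 0 || min_cover_frac > 1)
    stop("`min_cover_frac` must be in (0, 1]")
  carriers <- matrix(0L, length(sample_ids), nrow(regions),
                     dimnames = list(sample_ids, regions$region_id))
  if (nrow(regions) == 0L || nrow(tohs) == 0L) return(carriers)
  merged <- do.call(rbind, lapply(
    split(tohs[c("sample_id", "chrom", "start_idx", "end_idx")],
          tohs$sample_id), function(d) {
      m <- merge_spans(d$start_idx, d$end_idx)
      data.frame(sample_id = d$sample_id[1], start = m[, "start"],
                 end = m[, "end"])
    }))
  for (j in seq_len(nrow(regions))) {
    rs <- regions$start_idx[j]; re <- regions$end_idx[j]
    sel <- merged$end >= rs & merged$start <= re
    if (!any(sel)) next
    ov <- pmin(merged$end[sel], re) - pmax(merged$start[sel], rs) + 1L
    covered <- tapply(ov, merged$sample_id[sel], sum)
    need <- ceiling(min_cover_frac * regions$n_snps[j] - 1e-9)
    hit <- intersect(names(covered)[covered >= need], sample_ids)
    carriers[match(hit, sample_ids), j] <- 1L
  }
  carriers
}
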