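# Feature integration: genomic-interval overlap, cross-sample indel
# clustering, the recurrence + repeat-overlap filter, gene shortlisting
# within significant cTOH regions, and per-chromosome repeat summaries.
#
# Intervals are 0-based half-open throughout this module (BED
# convention); strand is ignored.

#' Build a genomic-interval table
#'
#' @param chrom Chromosome labels (non-empty).
#' @param start 0-based inclusive starts (`>= 0`).
#' @param end Exclusive ends (`end > start`).
#' @param name Optional payload label (gene symbol, repeat id, ...).
#' @param class Optional class tag (`"inverted"`, `"simple"`, `"gene"`,
#'   `"indel"`, `"ctoh"`).
#' @return A data frame with columns `chrom`, `start`, `end`, `name`,
#'   `class`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              class = NA_character_) {
  out <- data.frame(chrom = as.character(chrom),
                    start = as.numeric(start), end = as.numeric(end),
                    name = as.character(name), class = as.character(class))
  validate_intervals(out)
  out
}

validate_intervals <- function(x) {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop("malformed interval table: need chrom, start, end columns")
  if (nrow(x) == 0L) return(invisible(TRUE))
  if (any(is.na(x$chrom) | !nzchar(x$chrom)))
    stop("malformed interval: empty chromosome label")
  if (any(is.na(x$start) | is.na(x$end) | x$start < 0 | x$end <= x$start))
    stop("malformed interval: need 0 <= start < end")
  invisible(TRUE)
}

intervals_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Intersect two interval sets
#'
#' Reports every pair (query, subject) on the same chromosome with
#' `q.start < s.end` and `s.start < q.end` (at least one shared base),
#' in a deterministic order sorted by query chromosome, start and
#' payload.
#'
#' @param query,subject Interval tables as produced by
#'   [genomic_intervals()] (any table with `chrom`, `start`, `end`
#'   works; a `name` column refines the ordering).
#' @return A data frame with columns `query` and `subject`: row indices
#'   into the two inputs.
#' @export
intersect_intervals <- function(query, subject) {
  validate_intervals(query)
  validate_intervals(subject)
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.frame(query = integer(), subject = integer()))
  hits <- GenomicRanges::findOverlaps(intervals_granges(query),
                                      intervals_granges(subject))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  qn <- if ("name" %in% names(query)) as.character(query$name[q])
        else character(length(q))
  sn <- if ("name" %in% names(subject)) as.character(subject$name[s])
        else character(length(s))
  qn[is.na(qn)] <- ""; sn[is.na(sn)] <- ""
  ord <- order(query$chrom[q], query$start[q], qn, q,
               subject$start[s], sn, s)
  data.frame(query = q[ord], subject = s[ord])
}

#' Cluster indel calls across samples
#'
#' Single-linkage clustering of indel reference spans
#' (`[pos - 1, pos - 1 + length)`, 0-based) on each chromosome: two
#' calls link when their spans overlap or are separated by a gap of
#' fewer than `merge_window` bases, and clusters are the transitive
#' closure.  With `merge_window = 0` exactly the overlapping calls
#' cluster together.
#'
#' @param indels Data frame of indel calls with columns `sample`,
#'   `chrom`, `pos` (1-based), `length` (bp, `>= 1`), `type`
#'   (`"insertion"`/`"deletion"`).
#' @param merge_window Non-negative linkage gap in bp (default 10).
#' @return A list of class `indel_clusters` with `calls` (the input plus
#'   a `cluster_id` column) and `clusters` (one row per cluster:
#'   `cluster_id`, `chrom`, `start`, `end` of the merged span,
#'   `n_calls`, `n_samples`, `samples` as a comma-separated sorted
#'   string).
#' @export
cluster_indels <- function(indels, merge_window = 10) {
  if (merge_window < 0) stop("`merge_window` must be >= 0")
  req <- c("sample", "chrom", "pos", "length")
  if (!all(req %in% names(indels)))
    stop("`indels` needs columns sample, chrom, pos, length")
  n <- nrow(indels)
  cluster_id <- character(n)
  clusters <- list()
  if (n > 0L) {
    if (any(indels$length < 1)) stop("indel lengths must be >= 1")
    start <- indels$pos - 1
    end <- start + indels$length
    for (ch in unique(indels$chrom)) {
      ci <- which(indels$chrom == ch)
      ord <- ci[order(start[ci], end[ci])]
      cm <- cummax(end[ord])
      new_grp <- c(TRUE, start[ord][-1L] >= cm[-length(cm)] + merge_window)
      grp <- cumsum(new_grp)
      for (gidx in split(ord, grp)) {
        id <- sprintf("cluster_%04d", length(clusters) + 1L)
        cluster_id[gidx] <- id
        smp <- sort(unique(as.character(indels$sample[gidx])))
        clusters[[length(clusters) + 1L]] <- data.frame(
          cluster_id = id, chrom = ch,
          start = min(start[gidx]), end = max(end[gidx]),
          n_calls = length(gidx), n_samples = length(smp),
          samples = paste(smp, collapse = ","))
      }
    }
  }
  calls <- cbind(indels, cluster_id = cluster_id)
  cl <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(cluster_id = character(), chrom = character(),
               start = numeric(), end = numeric(), n_calls = integer(),
               n_samples = integer(), samples = character())
  rownames(cl) <- NULL
  structure(list(calls = calls, clusters = cl), class = "indel_clusters")
}

#' Retain recurrent, repeat-overlapping indel clusters
#'
#' Keeps clusters supported by at least `min_samples` distinct samples
#' whose merged span overlaps at least one repeat interval (inverted or
#' simple); both conditions must hold.
#'
#' @param clusters An [cluster_indels()] result.
#' @param repeats Repeat intervals ([genomic_intervals()] with class
#'   `"inverted"`/`"simple"`).
#' @param min_samples Minimum number of distinct supporting samples
#'   (default 3).
#' @return The retained rows of `clusters$clusters`, with an added
#'   `repeat_names` column (comma-separated overlapping repeat labels).
#' @export
recurrent_indels <- function(clusters, repeats, min_samples = 3L) {
  if (!inherits(clusters, "indel_clusters"))
    stop("`clusters` must come from cluster_indels()")
  cl <- clusters$clusters
  cl$repeat_names <- ""
  if (nrow(cl) == 0L) return(cl[cl$n_samples >= min_samples, , drop = FALSE])
  hits <- intersect_intervals(cl[c("chrom", "start", "end")], repeats)
  rep_names <- if ("name" %in% names(repeats) && !all(is.na(repeats$name)))
    as.character(repeats$name) else
    paste0(repeats$chrom, ":", repeats$start, "-", repeats$end)
  if (nrow(hits)) {
    agg <- tapply(rep_names[hits$subject], hits$query,
                  function(x) paste(sort(unique(x)), collapse = ","))
    cl$repeat_names[as.integer(names(agg))] <- unname(agg)
  }
  keep <- cl$n_samples >= min_samples & nzchar(cl$repeat_names)
  out <- cl[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# cTOH regions (1-based closed bp spans) as 0-based half-open intervals.
#' Convert cTOH regions to genomic intervals
#'
#' @param regions A [define_ctohs()] result (optionally already filtered
#'   to significant regions).
#' @return A [genomic_intervals()] table with `name = region_id` and
#'   class `"ctoh"`.
#' @export
regions_to_intervals <- function(regions) {
  if (nrow(regions) == 0L)
    return(genomic_intervals(character(), numeric(), numeric()))
  genomic_intervals(regions$chrom, regions$start_bp - 1, regions$end_bp,
                    name = regions$region_id, class = "ctoh")
}

#' Shortlist genes supported by recurrent indels inside significant regions
#'
#' A gene enters the shortlist when it overlaps a significant cTOH
#' region and overlaps the span of at least one retained indel cluster
#' (see [recurrent_indels()]).  Output is sorted by chromosome, start
#' and symbol, so it is invariant to the order of the input records.
#'
#' @param genes Gene intervals (`name` = gene symbol).
#' @param significant_regions Significant cTOH regions, either a
#'   [define_ctohs()] data frame or an interval table from
#'   [regions_to_intervals()].
#' @param retained_clusters Result of [recurrent_indels()].
#' @return A data frame, one row per shortlisted gene: `gene`, `chrom`,
#'   `start`, `end`, `region_ids`, `cluster_ids`, `samples` (union of
#'   supporting samples, comma-separated), `n_samples`, `repeat_names`.
#' @export
shortlist_genes <- function(genes, significant_regions, retained_clusters) {
  regions <- if (inherits(significant_regions, "ctoh_regions") ||
                 "start_bp" %in% names(significant_regions))
    regions_to_intervals(significant_regions) else significant_regions
  validate_intervals(genes)
  empty <- data.frame(gene = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      region_ids = character(), cluster_ids = character(),
                      samples = character(), n_samples = integer(),
                      repeat_names = character())
  if (nrow(genes) == 0L || nrow(regions) == 0L ||
      nrow(retained_clusters) == 0L) return(empty)
  in_region <- intersect_intervals(genes, regions)
  in_cluster <- intersect_intervals(genes, retained_clusters)
  sel <- sort(intersect(unique(in_region$query), unique(in_cluster$query)))
  if (!length(sel)) return(empty)
  rows <- lapply(sel, function(gi) {
    rids <- regions$name[in_region$subject[in_region$query == gi]]
    cls <- retained_clusters[in_cluster$subject[in_cluster$query == gi], ,
                             drop = FALSE]
    smp <- sort(unique(unlist(strsplit(cls$samples, ","))))
    reps <- sort(unique(unlist(strsplit(cls$repeat_names, ","))))
    data.frame(gene = as.character(genes$name[gi]), chrom = genes$chrom[gi],
               start = genes$start[gi], end = genes$end[gi],
               region_ids = paste(sort(unique(rids)), collapse = ","),
               cluster_ids = paste(sort(unique(cls$cluster_id)), collapse = ","),
               samples = paste(smp, collapse = ","),
               n_samples = length(smp),
               repeat_names = paste(reps, collapse = ","))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-chromosome summary of repeats inside cTOH regions
#'
#' Restricts the repeat set to repeats overlapping a cTOH region, then
#' reports per chromosome the repeat count, min/max/mean length, and the
#' number of genes overlapped by at least one such repeat.  Chromosomes
#' without in-region repeats are omitted.
#'
#' @param repeats Repeat intervals.
#' @param ctohs cTOH regions (data frame from [define_ctohs()] or an
#'   interval table).
#' @param genes Gene intervals (`name` = symbol).
#' @return A data frame with columns `chrom`, `n_irs`, `min_bp`,
#'   `max_bp`, `mean_bp`, `n_genes_with_irs`.
#' @export
ir_summary <- function(repeats, ctohs, genes) {
  regions <- if ("start_bp" %in% names(ctohs))
    regions_to_intervals(ctohs) else ctohs
  empty <- data.frame(chrom = character(), n_irs = integer(),
                      min_bp = numeric(), max_bp = numeric(),
                      mean_bp = numeric(), n_genes_with_irs = integer())
  if (nrow(repeats) == 0L || nrow(regions) == 0L) return(empty)
  hits <- intersect_intervals(repeats, regions)
  sel <- sort(unique(hits$query))
  if (!length(sel)) return(empty)
  rsel <- repeats[sel, , drop = FALSE]
  len <- rsel$end - rsel$start
  gene_hits <- if (nrow(genes)) intersect_intervals(genes, rsel) else
    data.frame(query = integer(), subject = integer())
  rows <- lapply(sort(unique(rsel$chrom)), function(ch) {
    ci <- rsel$chrom == ch
    gsel <- unique(gene_hits$query[genes$chrom[gene_hits$query] == ch])
    data.frame(chrom = ch, n_irs = sum(ci), min_bp = min(len[ci]),
               max_bp = max(len[ci]), mean_bp = mean(len[ci]),
               n_genes_with_irs = length(gsel))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
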