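# Synthetic exome annotation sets: repeat elements, per-sample indel
# calls and gene models placed around cTOH regions, with a planted gene
# guaranteed to satisfy the full integration filter and recorded as
# ground truth.

#' Configure a synthetic exome annotation set
#'
#' Defaults emulate a small exome validation series: 8 sequenced
#' samples, indel lengths uniform on 1-191 bp, repeat lengths
#' log-uniform on 39-21,947 bp (geometric mean a few kb, matching the
#' scale of annotated inverted/simple repeats), and a >= 3-of-8
#' recurrence rule.
#'
#' @param n_samples Number of sequenced samples (`>= 0`).
#' @param n_repeats Number of background repeat elements.
#' @param repeat_length_range Repeat length bounds in bp (log-uniform).
#' @param indels_per_sample Background indel calls per sample.
#' @param indel_length_range Indel length bounds in bp (uniform integer).
#' @param n_genes Number of background gene models.
#' @param gene_length_range Gene length bounds in bp.
#' @param n_planted Genes planted to satisfy the full integration filter
#'   (recurrent indel cluster in `>= min_samples` samples overlapping a
#'   repeat inside a cTOH region).
#' @param n_decoys Decoy genes planted to fail exactly one conjunct: an
#'   under-recurrent cluster (`min_samples - 1` samples, repeat overlap
#'   present) and a repeat-free recurrent cluster, alternating.
#' @param min_samples Recurrence threshold the planted genes must meet.
#' @param merge_window Clustering window the planted indel positions are
#'   jittered within.
#' @param background_in_genes Allow background indels to fall inside
#'   gene bodies; the default `FALSE` keeps the simulation "tight" so
#'   the shortlist equals the planted truth exactly.
#' @param seed Integer seed.
#' @return An object of class `exome_config`.
#' @export
exome_config <- function(n_samples = 8L, n_repeats = 300L,
                         repeat_length_range = c(39, 21947),
                         indels_per_sample = 25L,
                         indel_length_range = c(1L, 191L),
                         n_genes = 40L, gene_length_range = c(2e4, 2e5),
                         n_planted = 1L, n_decoys = 2L, min_samples = 3L,
                         merge_window = 10, background_in_genes = FALSE,
                         seed = 1L) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 0L) stop("`n_samples` must be >= 0")
  if (length(repeat_length_range) != 2L || repeat_length_range[1] < 1 ||
      diff(repeat_length_range) < 0)
    stop("invalid `repeat_length_range`")
  if (length(indel_length_range) != 2L || indel_length_range[1] < 1 ||
      diff(indel_length_range) < 0)
    stop("invalid `indel_length_range`")
  if (n_planted < 0L || n_decoys < 0L) stop("planted counts must be >= 0")
  if (min_samples < 1L) stop("`min_samples` must be >= 1")
  structure(list(n_samples = n_samples, n_repeats = as.integer(n_repeats),
                 repeat_length_range = repeat_length_range,
                 indels_per_sample = as.integer(indels_per_sample),
                 indel_length_range = as.integer(indel_length_range),
                 n_genes = as.integer(n_genes),
                 gene_length_range = gene_length_range,
                 n_planted = as.integer(n_planted),
                 n_decoys = as.integer(n_decoys),
                 min_samples = as.integer(min_samples),
                 merge_window = merge_window,
                 background_in_genes = isTRUE(background_in_genes),
                 seed = as.integer(seed)),
            class = "exome_config")
}

#' Simulate exome-derived annotations around cTOH regions
#'
#' Generates repeat elements (inverted/simple, log-uniform lengths),
#' gene models and per-sample indel calls (uniform lengths) on the
#' chromosomes carrying the supplied cTOH regions.  When planting is
#' requested, one gene per plant is placed inside a region together with
#' an overlapping repeat and co-located indels in `min_samples` distinct
#' samples, so it must survive the downstream integration filter; decoy
#' genes are placed that fail exactly one filter conjunct.
#'
#' @param config An [exome_config()] object.
#' @param ctoh_regions cTOH regions (a [define_ctohs()] data frame,
#'   usually the significant ones) used as planting territory.
#' @param chrom_sizes Optional named vector of chromosome sizes in bp;
#'   defaults to 2 Mb beyond the last region on each chromosome.
#' @return An object of class `exome_features`: list with `repeats`,
#'   `genes` (interval tables), `indels` (sample/chrom/pos/length/type
#'   data frame), `truth_shortlist` (planted gene symbols),
#'   `decoy_genes`, and `config`.
#' @export
simulate_exome_features <- function(config, ctoh_regions,
                                    chrom_sizes = NULL) {
  if (!inherits(config, "exome_config")) stop("`config` must be an exome_config")
  want_plant <- config$n_planted > 0L && config$n_samples >= config$min_samples
  if (config$n_planted > 0L && nrow(ctoh_regions) == 0L)
    stop("planting requested but no cTOH regions supplied")
  set.seed(config$seed)

  region_iv <- regions_to_intervals(ctoh_regions)
  chroms <- unique(region_iv$chrom)
  if (!length(chroms)) chroms <- "chr1"
  if (is.null(chrom_sizes)) {
    chrom_sizes <- vapply(chroms, function(ch) {
      mx <- if (any(region_iv$chrom == ch))
        max(region_iv$end[region_iv$chrom == ch]) else 0
      mx + 2e6
    }, 0)
  }

  # planting slots: planted and decoy genes each get a private segment of
  # a region so their signals cannot bleed into one another
  n_slots <- if (want_plant) config$n_planted + config$n_decoys else 0L
  slots <- list()
  if (n_slots > 0L) {
    ord <- order(-(region_iv$end - region_iv$start))
    take <- region_iv[rep(ord, length.out = n_slots), , drop = FALSE]
    per_region <- table(take$name)
    for (rn in names(per_region)) {
      rv <- region_iv[region_iv$name == rn, ][1, ]
      kk <- per_region[[rn]]
      width <- (rv$end - rv$start) / kk
      for (q in seq_len(kk))
        slots[[length(slots) + 1L]] <-
          list(chrom = rv$chrom, start = rv$start + (q - 1) * width,
               end = rv$start + q * width, region = rn)
    }
  }

  sample_ids <- if (config$n_samples > 0L)
    sprintf("ex%02d", seq_len(config$n_samples)) else character(0)

  genes <- repeats <- list()
  indels <- list()
  truth <- character(0)
  decoys <- character(0)
  avoid <- list()   # spans background features must keep clear of

  rand_len_log <- function(k, range)
    exp(stats::runif(k, log(range[1]), log(range[2])))

  plant_one <- function(slot, symbol, kind) {
    seg_len <- slot$end - slot$start
    glen <- min(max(seg_len * 0.5, 1000), diff(range(config$gene_length_range)) +
                config$gene_length_range[1])
    gstart <- slot$start + seg_len * 0.2
    gene <- data.frame(chrom = slot$chrom, start = round(gstart),
                       end = round(gstart + glen), name = symbol,
                       class = "gene")
    anchor <- round(gstart + glen / 2)
    k <- if (kind == "under") config$min_samples - 1L else config$min_samples
    smp <- sample(sample_ids, k)
    jitter <- if (config$merge_window > 1)
      sample.int(max(1, floor(config$merge_window / 2)), k, replace = TRUE) - 1L
    else rep(0L, k)
    lens <- sample(seq(config$indel_length_range[1],
                       config$indel_length_range[2]), k, replace = TRUE)
    calls <- data.frame(sample = smp, chrom = slot$chrom,
                        pos = anchor + jitter, length = lens,
                        type = sample(c("insertion", "deletion"), k,
                                      replace = TRUE))
    rep_iv <- NULL
    if (kind != "norepeat") {
      rlen <- max(1000, min(5000, seg_len * 0.3))
      rep_iv <- data.frame(chrom = slot$chrom, start = anchor - rlen / 2,
                           end = anchor + rlen / 2,
                           name = paste0("IR_", symbol),
                           class = sample(c("inverted", "simple"), 1L))
    }
    list(gene = gene, calls = calls, rep_iv = rep_iv,
         avoid = c(gene$start - 2 * rlen_guard, gene$end + 2 * rlen_guard,
                   slot$chrom))
  }
  rlen_guard <- 25000

  if (want_plant) {
    kinds <- c(rep("planted", config$n_planted),
               rep(c("under", "norepeat"), length.out = config$n_decoys))
    for (i in seq_along(kinds)) {
      symbol <- if (kinds[i] == "planted")
        sprintf("GENE_TRUE%02d", i) else sprintf("GENE_DECOY%02d", i)
      pl <- plant_one(slots[[i]], symbol,
                      if (kinds[i] == "planted") "planted" else kinds[i])
      genes[[length(genes) + 1L]] <- pl$gene
      indels[[length(indels) + 1L]] <- pl$calls
      if (!is.null(pl$rep_iv)) repeats[[length(repeats) + 1L]] <- pl$rep_iv
      avoid[[length(avoid) + 1L]] <-
        list(chrom = slots[[i]]$chrom,
             start = pl$gene$start - rlen_guard,
             end = pl$gene$end + rlen_guard)
      if (kinds[i] == "planted") truth <- c(truth, symbol)
      else decoys <- c(decoys, symbol)
    }
  }

  overlaps_avoid <- function(chrom, start, end) {
    for (a in avoid)
      if (a$chrom == chrom && start < a$end && a$start < end) return(TRUE)
    FALSE
  }
  draw_clear <- function(len_fun, n_draw) {
    out <- list()
    guard <- 0L
    while (length(out) < n_draw && guard < n_draw * 20L) {
      guard <- guard + 1L
      ch <- sample(chroms, 1L)
      len <- len_fun()
      st <- floor(stats::runif(1, 0, max(1, chrom_sizes[[ch]] - len)))
      if (!overlaps_avoid(ch, st, st + len))
        out[[length(out) + 1L]] <- c(ch, st, st + len)
    }
    out
  }

  # background genes
  bg_genes <- draw_clear(function()
    stats::runif(1, config$gene_length_range[1], config$gene_length_range[2]),
    config$n_genes)
  for (i in seq_along(bg_genes)) {
    b <- bg_genes[[i]]
    genes[[length(genes) + 1L]] <- data.frame(
      chrom = b[1], start = as.numeric(b[2]), end = as.numeric(b[3]),
      name = sprintf("GENE_BG%03d", i), class = "gene")
  }

  # background repeats (half coaxed into region spans so in-region repeat
  # summaries are non-trivial); all kept clear of planted segments
  n_rep <- config$n_repeats
  n_in <- if (nrow(region_iv)) floor(n_rep / 2) else 0L
  made <- 0L
  guard <- 0L
  while (made < n_in && guard < n_in * 20L) {
    guard <- guard + 1L
    rv <- region_iv[sample.int(nrow(region_iv), 1L), ]
    len <- rand_len_log(1L, config$repeat_length_range)
    st <- floor(stats::runif(1, max(0, rv$start - len / 2), rv$end))
    if (overlaps_avoid(rv$chrom, st, st + len)) next
    made <- made + 1L
    repeats[[length(repeats) + 1L]] <- data.frame(
      chrom = rv$chrom, start = st, end = floor(st + len),
      name = sprintf("IR_BG%04d", made),
      class = sample(c("inverted", "simple"), 1L))
  }
  bg_rep <- draw_clear(function() rand_len_log(1L, config$repeat_length_range),
                       n_rep - made)
  for (i in seq_along(bg_rep)) {
    b <- bg_rep[[i]]
    repeats[[length(repeats) + 1L]] <- data.frame(
      chrom = b[1], start = as.numeric(b[2]), end = floor(as.numeric(b[3])),
      name = sprintf("IR_BG%04d", made + i),
      class = sample(c("inverted", "simple"), 1L))
  }

  # background indels: independent per sample, kept out of gene bodies
  # unless background_in_genes is set
  if (config$n_samples > 0L && config$indels_per_sample > 0L) {
    gene_df <- if (length(genes)) do.call(rbind, genes) else NULL
    clear_of_genes <- function(ch, st, en) {
      if (config$background_in_genes || is.null(gene_df)) return(TRUE)
      sel <- gene_df$chrom == ch &
        st < gene_df$end + 1000 & gene_df$start - 1000 < en
      !any(sel)
    }
    for (s in sample_ids) {
      made_i <- 0L
      guard <- 0L
      while (made_i < config$indels_per_sample &&
             guard < config$indels_per_sample * 30L) {
        guard <- guard + 1L
        ch <- sample(chroms, 1L)
        len <- sample(seq(config$indel_length_range[1],
                          config$indel_length_range[2]), 1L)
        pos <- floor(stats::runif(1, 1, chrom_sizes[[ch]] - len))
        if (!clear_of_genes(ch, pos - 1, pos - 1 + len)) next
        if (overlaps_avoid(ch, pos - 1, pos - 1 + len)) next
        made_i <- made_i + 1L
        indels[[length(indels) + 1L]] <- data.frame(
          sample = s, chrom = ch, pos = pos, length = len,
          type = sample(c("insertion", "deletion"), 1L))
      }
    }
  }

  bind_or_empty <- function(lst, proto) {
    if (length(lst)) {
      out <- do.call(rbind, lst); rownames(out) <- NULL; out
    } else proto
  }
  structure(list(
    repeats = bind_or_empty(repeats, genomic_intervals(character(), numeric(),
                                                       numeric())),
    genes = bind_or_empty(genes, genomic_intervals(character(), numeric(),
                                                   numeric())),
    indels = bind_or_empty(indels, data.frame(sample = character(),
                                              chrom = character(),
                                              pos = numeric(),
                                              length = integer(),
                                              type = character())),
    truth_shortlist = truth, decoy_genes = decoys, config = config),
    class = "exome_features")
}

#' @export
print.exome_features <- function(x, ...) {
  cat("exome_features:", nrow(x$repeats), "repeats,", nrow(x$genes),
      "genes,", nrow(x$indels), "indel calls across",
      length(unique(x$indels$sample)), "samples;",
      length(x$truth_shortlist), "planted truth gene(s)\n")
  invisible(x)
}
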