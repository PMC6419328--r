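# Readers and writers for the interchange formats used by the pipeline:
# PLINK text .ped/.map, BED intervals, minimal VCF indel calls, and TSV
# tables.  TSV is the canonical tabular interchange; every writer's
# output parses back with the matching reader.

#' Write a canonical TSV table
#'
#' Tab-separated, no quoting, no row names; the format every pipeline
#' stage uses for its tabular outputs.
#'
#' @param x A data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a canonical TSV table
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Write genotypes as PLINK text .ped/.map
#'
#' Alleles are written as `A`/`B` (missing `0 0`); sex as 1 = male,
#' 2 = female; phenotype as 2 = case, 1 = control, -9 = missing.
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map`
#'   are written.
#' @return The two file paths, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  if (!inherits(gm, "genotype_matrix")) stop("`gm` must be a genotype_matrix")
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  utils::write.table(
    data.frame(gm$map$chrom, gm$map$snp_id, 0, gm$map$bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  code <- c(`0` = "A\tA", `1` = "A\tB", `2` = "B\tB")
  g <- gm$geno
  lines <- vapply(seq_len(nrow(g)), function(i) {
    alleles <- code[as.character(g[i, ])]
    alleles[is.na(alleles)] <- "0\t0"
    sex <- gm$samples$sex[i]
    phe <- gm$samples$phenotype[i]
    paste(c(gm$samples$sample_id[i], gm$samples$sample_id[i], "0", "0",
            if (is.na(sex)) "0" else sex + 1L,
            if (is.na(phe)) "-9" else phe + 1L,
            alleles), collapse = "\t")
  }, "")
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK text .ped/.map genotypes
#'
#' Genotypes are recoded to 0/1/2 copies of allele B, where B is the
#' lexicographically larger of the two alleles observed at each SNP;
#' allele code `0` marks missing.  The map gives chromosome, SNP id and
#' 1-based bp.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  if (!file.exists(map_path)) stop("no such file: ", map_path)
  map_raw <- utils::read.table(map_path, stringsAsFactors = FALSE)
  if (ncol(map_raw) == 3L) {
    map <- data.frame(chrom = as.character(map_raw[[1]]),
                      snp_id = as.character(map_raw[[2]]),
                      bp = as.integer(map_raw[[3]]))
  } else if (ncol(map_raw) >= 4L) {
    map <- data.frame(chrom = as.character(map_raw[[1]]),
                      snp_id = as.character(map_raw[[2]]),
                      bp = as.integer(map_raw[[4]]))
  } else stop("malformed .map file: need 3 or 4 columns")
  if (anyDuplicated(map$snp_id))
    stop("duplicate SNP ids in ", map_path)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  geno <- matrix(NA_integer_, n, m)
  sample_id <- character(n)
  sex <- integer(n)
  phenotype <- integer(n)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m)
      stop(".ped line ", i, " has ", length(f), " fields; expected ",
           6L + 2L * m)
    sample_id[i] <- f[2]
    sx <- f[5]
    sex[i] <- if (sx == "1") 0L else if (sx == "2") 1L else NA_integer_
    ph <- f[6]
    phenotype[i] <- if (ph == "2") 1L else if (ph == "1") 0L else NA_integer_
    a1[i, ] <- f[seq(7L, by = 2L, length.out = m)]
    a2[i, ] <- f[seq(8L, by = 2L, length.out = m)]
  }
  for (j in seq_len(m)) {
    al <- sort(setdiff(unique(c(a1[, j], a2[, j])), "0"))
    if (length(al) > 2L)
      stop("SNP ", map$snp_id[j], " has more than two alleles")
    b <- if (length(al) == 2L) al[2] else "\x01none"
    miss <- a1[, j] == "0" | a2[, j] == "0"
    geno[, j] <- (a1[, j] == b) + (a2[, j] == b)
    geno[miss, j] <- NA_integer_
  }
  samples <- data.frame(sample_id = sample_id, phenotype = phenotype,
                        sex = sex)
  genotype_matrix(geno, map, samples)
}

#' Write intervals as BED
#'
#' 0-based half-open, four columns (chrom, start, end, name); the name
#' field carries the payload (gene symbol or repeat class/id).
#'
#' @param x An interval table ([genomic_intervals()]).
#' @param path Output path.
#' @param name_col Column written into the BED name field (default
#'   `"name"`).
#' @export
write_bed <- function(x, path, name_col = "name") {
  validate_intervals(x)
  nm <- if (name_col %in% names(x)) as.character(x[[name_col]]) else "."
  nm[is.na(nm)] <- "."
  utils::write.table(
    data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE), nm),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as genomic intervals
#'
#' @param path Path to a 3+ column BED file.
#' @param class Optional class tag stored on every interval.
#' @return A [genomic_intervals()] table (0-based half-open, name from
#'   column 4 when present).
#' @export
read_bed <- function(path, class = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(raw) < 3L) stop("malformed BED: need at least 3 columns")
  nm <- if (ncol(raw) >= 4L) as.character(raw[[4]]) else NA_character_
  genomic_intervals(raw[[1]], raw[[2]], raw[[3]], name = nm, class = class)
}

#' Write indel calls as TSV
#'
#' @param indels Data frame with columns `sample`, `chrom`, `pos`,
#'   `length`, `type`.
#' @param path Output path.
#' @export
write_indels_tsv <- function(indels, path) {
  write_tsv(indels[c("sample", "chrom", "pos", "length", "type")], path)
}

#' Read indel calls from TSV
#' @param path Path written by [write_indels_tsv()].
#' @return The indel call data frame.
#' @export
read_indels_tsv <- function(path) {
  x <- read_tsv(path)
  req <- c("sample", "chrom", "pos", "length", "type")
  if (!all(req %in% names(x)))
    stop("indel TSV needs columns ", paste(req, collapse = ", "))
  x[req]
}

#' Write one sample's indels as a minimal VCF
#'
#' Only CHROM/POS/ID/REF/ALT carry information; alleles are written as
#' runs of `N` whose length difference encodes the indel length
#' (REF longer = deletion, ALT longer = insertion).
#'
#' @param indels Indel calls of a single sample.
#' @param path Output path.
#' @export
write_indel_vcf <- function(indels, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(indels)) {
    ref <- ifelse(indels$type == "deletion",
                  strrep("N", indels$length + 1L), "N")
    alt <- ifelse(indels$type == "insertion",
                  strrep("N", indels$length + 1L), "N")
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                       indels$chrom, as.integer(indels$pos),
                       sprintf("indel%04d", seq_len(nrow(indels))),
                       ref, alt), con)
  }
  invisible(path)
}

#' Read indel calls from a minimal VCF
#'
#' Consumes CHROM/POS/REF/ALT only; multi-allelic records are split, and
#' each allele with `|len(REF) - len(ALT)| >= 1` becomes one call of
#' that length (SNVs are dropped).  Positions are 1-based as in VCF.
#'
#' @param path Path to the VCF.
#' @param sample_id Sample label attached to every call.
#' @return An indel call data frame (`sample`, `chrom`, `pos`, `length`,
#'   `type`).
#' @export
read_indel_vcf <- function(path, sample_id) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- data.frame(sample = character(), chrom = character(),
                      pos = numeric(), length = integer(),
                      type = character())
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    for (alt in strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]) {
      len <- abs(nchar(fix$REF[i]) - nchar(alt))
      if (len < 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_id, chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]), length = len,
        type = if (nchar(alt) > nchar(fix$REF[i])) "insertion" else "deletion")
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
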