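# Genotype container shared by every stage of the pipeline.
#
# Genotypes are coded as the number of copies of allele B: 0 (hom A),
# 1 (het), 2 (hom B), NA (missing).  The marker map is 1-based bp,
# grouped by chromosome and sorted by position within each chromosome.

#' Construct a genotype matrix object
#'
#' Bundles an individuals-by-SNPs genotype matrix with its marker map and
#' sample sheet.  This is the container consumed by [apply_qc()],
#' [make_covariates()], [call_tohs()] and the pipeline driver.
#'
#' @param geno Integer matrix, individuals in rows, SNPs in columns, coded
#'   0/1/2 copies of allele B with `NA` for missing calls.
#' @param map Data frame with columns `chrom` (character), `snp_id`
#'   (unique character) and `bp` (1-based integer position), grouped by
#'   chromosome and sorted by `bp` within chromosome; one row per column
#'   of `geno`.
#' @param samples Data frame with columns `sample_id` (unique character),
#'   `phenotype` (1 = case, 0 = control, NA allowed) and `sex`
#'   (0 = male, 1 = female, NA allowed); one row per row of `geno`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno`, `map` and `samples`.
#' @export
genotype_matrix <- function(geno, map, samples) {
  if (!is.matrix(geno)) stop("`geno` must be a matrix")
  storage.mode(geno) <- "integer"
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad)) stop("genotypes must be coded 0/1/2 or NA")
  if (!is.data.frame(map) || !all(c("chrom", "snp_id", "bp") %in% names(map)))
    stop("`map` must have columns chrom, snp_id, bp")
  if (!is.data.frame(samples) ||
      !all(c("sample_id", "phenotype", "sex") %in% names(samples)))
    stop("`samples` must have columns sample_id, phenotype, sex")
  if (nrow(map) != ncol(geno))
    stop("map has ", nrow(map), " SNPs but geno has ", ncol(geno), " columns")
  if (nrow(samples) != nrow(geno))
    stop("samples has ", nrow(samples), " rows but geno has ", nrow(geno))
  if (anyDuplicated(map$snp_id)) stop("duplicate SNP ids in map")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  validate_map(map)
  rownames(geno) <- samples$sample_id
  colnames(geno) <- map$snp_id
  structure(list(geno = geno, map = map, samples = samples),
            class = "genotype_matrix")
}

# A map is valid when chromosomes form contiguous blocks and bp strictly
# increases within each block.
validate_map <- function(map) {
  if (nrow(map) == 0L) return(invisible(TRUE))
  r <- rle(as.character(map$chrom))
  if (anyDuplicated(r$values))
    stop("marker map is not grouped by chromosome")
  within_ok <- unlist(tapply(map$bp, factor(map$chrom, levels = r$values),
                             function(x) length(x) < 2L || all(diff(x) > 0)))
  if (!all(within_ok))
    stop("marker map positions are not strictly increasing within chromosome")
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "individuals x", ncol(x$geno),
      "SNPs on", length(unique(x$map$chrom)), "chromosome(s)\n")
  cat("  cases:", sum(x$samples$phenotype == 1, na.rm = TRUE),
      " controls:", sum(x$samples$phenotype == 0, na.rm = TRUE), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

# Row indices of the map belonging to each chromosome, in map order.
chrom_blocks <- function(map) {
  if (nrow(map) == 0L) return(list())
  r <- rle(as.character(map$chrom))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  stats::setNames(mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE),
                  r$values)
}
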