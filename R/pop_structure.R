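# Population-structure covariates: EigenStrat-style genotype
# standardization and principal components of the genotype matrix.

#' Standardize a genotype matrix for PCA
#'
#' Per SNP j with estimated allele-B frequency `p_j`, a genotype `x` is
#' transformed to `(x - 2 p_j) / sqrt(2 p_j (1 - p_j))`; missing entries
#' are set to 0 after centering and monomorphic (or all-missing) SNPs are
#' dropped.
#'
#' @param gm A [genotype_matrix()], or a plain 0/1/2/NA genotype matrix.
#' @return A numeric matrix with the retained SNP columns, with attribute
#'   `"kept"` giving the retained column indices of the input.
#' @export
standardize_genotypes <- function(gm) {
  x <- if (inherits(gm, "genotype_matrix")) gm$geno else gm
  if (!is.matrix(x)) stop("`gm` must be a genotype_matrix or a matrix")
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty genotype matrix")
  p <- colMeans(x, na.rm = TRUE) / 2
  keep <- which(!is.na(p) & p > 0 & p < 1)
  x <- x[, keep, drop = FALSE]
  p <- p[keep]
  z <- sweep(x, 2L, 2 * p, "-")
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  attr(z, "kept") <- keep
  z
}

#' Principal-component scores of a standardized genotype matrix
#'
#' Returns the top-`k` left singular vectors (per-individual scores) of
#' the standardized matrix.  The component sign is fixed by making each
#' component's largest-magnitude SNP loading positive, so results are
#' fully deterministic.
#'
#' @param z Standardized matrix from [standardize_genotypes()]
#'   (individuals in rows).
#' @param k Number of components, `0 <= k < nrow(z)`.
#' @return An `nrow(z) x k` matrix of PC scores (columns `PC1..PCk`).
#' @export
compute_pcs <- function(z, k = 2L) {
  if (!is.matrix(z)) stop("`z` must be a matrix")
  k <- as.integer(k)
  if (k < 0L) stop("`k` must be >= 0")
  n <- nrow(z)
  if (k >= n) stop("`k` must be smaller than the number of individuals")
  if (k == 0L) {
    out <- matrix(numeric(0), n, 0L)
    rownames(out) <- rownames(z)
    return(out)
  }
  if (ncol(z) == 0L) stop("no polymorphic SNPs to decompose")
  # scores via the small n x n cross-product; loadings recovered to fix sign
  e <- eigen(tcrossprod(z), symmetric = TRUE)
  d2 <- pmax(e$values[seq_len(k)], 0)
  u <- e$vectors[, seq_len(k), drop = FALSE]
  d <- sqrt(d2)
  for (j in seq_len(k)) {
    if (d[j] <= sqrt(.Machine$double.eps) * max(d, 1)) next
    v <- crossprod(z, u[, j]) / d[j]
    if (v[which.max(abs(v))] < 0) u[, j] <- -u[, j]
  }
  colnames(u) <- paste0("PC", seq_len(k))
  rownames(u) <- rownames(z)
  u
}

#' Sex and principal-component covariates for association testing
#'
#' Convenience wrapper producing the covariate block used by
#' [associate_all()]: the sample sheet's sex indicator plus the top-`k`
#' genotype principal components.
#'
#' Carrier status at a cTOH region is itself built from a block of
#' consecutive markers, so including those markers in the covariate PCA
#' lets a leading component collude with the predictor under test
#' (the same reason EigenStrat workflows exclude long-range LD regions).
#' Pass the region SNPs through `exclude_snps` to keep the ancestry
#' axes clean; [run_toh_pipeline()] does this automatically.
#'
#' @param gm A QC-passed [genotype_matrix()].
#' @param k Number of principal components (default 2).
#' @param exclude_snps SNP ids (or column indices) dropped before the
#'   PCA, e.g. markers inside detected cTOH regions.
#' @return A data frame with columns `sample_id`, `sex`, `PC1..PCk`.
#' @export
make_covariates <- function(gm, k = 2L, exclude_snps = NULL) {
  if (!inherits(gm, "genotype_matrix")) stop("`gm` must be a genotype_matrix")
  g <- gm$geno
  if (!is.null(exclude_snps) && length(exclude_snps)) {
    drop <- if (is.numeric(exclude_snps)) as.integer(exclude_snps)
            else match(exclude_snps, gm$map$snp_id)
    drop <- drop[!is.na(drop)]
    if (length(drop)) g <- g[, -drop, drop = FALSE]
  }
  z <- standardize_genotypes(g)
  pcs <- compute_pcs(z, k)
  out <- data.frame(sample_id = gm$samples$sample_id, sex = gm$samples$sex)
  if (ncol(pcs)) out <- cbind(out, as.data.frame(pcs))
  rownames(out) <- NULL
  out
}
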