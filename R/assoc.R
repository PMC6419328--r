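# Per-region case-control association: logistic carrier model with
# covariate adjustment, Wald inference, odds ratios with confidence
# intervals, and Benjamini-Hochberg FDR across regions.

#' Maximum-likelihood logistic regression fit
#'
#' Fits a binomial GLM by iteratively reweighted least squares
#' (`stats::glm.fit`, tolerance 1e-10, at most 50 iterations) and
#' returns coefficient estimates with standard errors from the inverse
#' observed information.  Non-convergence and complete or quasi-complete
#' separation are flagged rather than silently reported.
#'
#' @param y Binary outcome vector (0/1), not constant.
#' @param x Design matrix including an intercept column; must have full
#'   column rank.
#' @return A list with `beta`, `se` (named as the columns of `x`) and
#'   `converged` (FALSE when IRLS failed to converge or fitted
#'   probabilities collapsed to 0/1, the signature of separation).
#' @export
fit_logistic <- function(y, x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (length(y) != nrow(x)) stop("`y` and `x` have different lengths")
  if (!all(y %in% c(0, 1))) stop("`y` must be binary 0/1")
  if (length(unique(y)) < 2L) stop("constant outcome: model not estimable")
  if (qr(x)$rank < ncol(x)) stop("rank-deficient design matrix")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(x, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 50L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  p <- fit$rank
  if (p < ncol(x) || anyNA(fit$coefficients))
    stop("rank-deficient design matrix")
  # observed information evaluated at the returned MLE (the QR inside
  # glm.fit carries the weights of the penultimate IRLS step)
  mu <- fit$fitted.values
  info <- crossprod(x, x * (mu * (1 - mu)))
  se <- sqrt(diag(solve(info)))
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  list(beta = stats::setNames(fit$coefficients, nm),
       se = stats::setNames(se, nm),
       converged = fit$converged && !separated)
}

#' Two-sided Wald test
#'
#' `p = 2 (1 - Phi(|beta / se|))`.
#'
#' @param beta Coefficient estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return Two-sided p-values in `(0, 1]`.
#' @export
wald_test <- function(beta, se) {
  if (any(se <= 0)) stop("`se` must be positive")
  2 * stats::pnorm(-abs(beta / se))
}

#' Odds ratio and Wald confidence interval
#'
#' `OR = exp(beta)` with bounds `exp(beta -/+ z * se)` where `z` is the
#' exact normal quantile for the requested level.
#'
#' @param beta Log-odds coefficient(s).
#' @param se Standard error(s), strictly positive.
#' @param level Confidence level in `(0, 1)` (default 0.95).
#' @return A data frame with columns `odds_ratio`, `ci_low`, `ci_high`.
#' @export
odds_ratio_ci <- function(beta, se, level = 0.95) {
  if (any(se <= 0)) stop("`se` must be positive")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(odds_ratio = exp(beta),
             ci_low = exp(beta - z * se),
             ci_high = exp(beta + z * se))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} m p_(j) / j`, capped at
#' 1 and mapped back to the input order.
#'
#' @param p_values P-values in `(0, 1]`.
#' @return Q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Test every cTOH region for case-control association
#'
#' For each region, fits disease status on
#' `[intercept, carrier, sex, PC1..PCk]` and reports the carrier
#' coefficient: log-odds, SE, Wald z and p, odds ratio with 95% CI, and
#' a Benjamini-Hochberg q-value computed across all converged region
#' fits.  Regions whose carrier indicator is constant are flagged
#' non-estimable; non-converged (separated) fits are flagged and
#' excluded from the FDR adjustment.
#'
#' @param regions A [define_ctohs()] result.
#' @param carriers Carrier matrix from [assign_carriers()] (individuals
#'   x regions).
#' @param phenotype Binary 0/1 disease status, aligned with the carrier
#'   matrix rows.
#' @param covariates Data frame of covariates aligned with the carrier
#'   matrix rows, e.g. from [make_covariates()]; a `sample_id` column is
#'   ignored, the rest enter the design.  `NULL` fits the unadjusted
#'   model.
#' @return A data frame of class `ctoh_assoc`, one row per region:
#'   `region_id`, `n_carriers`, `beta`, `se`, `wald_z`, `p_value`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `fdr_q`, `estimable`,
#'   `converged`.
#' @export
associate_all <- function(regions, carriers, phenotype, covariates = NULL) {
  if (nrow(regions) == 0L) {
    warning("no regions to test")
    out <- data.frame(region_id = character(), n_carriers = integer(),
                      beta = numeric(), se = numeric(), wald_z = numeric(),
                      p_value = numeric(), odds_ratio = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      fdr_q = numeric(), estimable = logical(),
                      converged = logical())
    class(out) <- c("ctoh_assoc", "data.frame")
    return(out)
  }
  if (nrow(carriers) != length(phenotype))
    stop("carrier matrix and phenotype are not aligned")
  if (ncol(carriers) != nrow(regions))
    stop("carrier matrix and regions are not aligned")
  covar_block <- NULL
  if (!is.null(covariates)) {
    if (nrow(covariates) != length(phenotype))
      stop("covariates and phenotype are not aligned")
    covar_block <- as.matrix(covariates[setdiff(names(covariates), "sample_id")])
    storage.mode(covar_block) <- "double"
  }
  n <- length(phenotype)
  rows <- vector("list", nrow(regions))
  for (j in seq_len(nrow(regions))) {
    cr <- carriers[, j]
    row <- data.frame(region_id = regions$region_id[j],
                      n_carriers = sum(cr), beta = NA_real_, se = NA_real_,
                      wald_z = NA_real_, p_value = NA_real_,
                      odds_ratio = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, fdr_q = NA_real_,
                      estimable = FALSE, converged = FALSE)
    if (length(unique(cr)) > 1L) {
      x <- cbind(`(Intercept)` = 1, carrier = cr, covar_block)
      fit <- tryCatch(fit_logistic(phenotype, x), error = function(e) NULL)
      if (!is.null(fit)) {
        b <- fit$beta["carrier"]; s <- fit$se["carrier"]
        ci <- odds_ratio_ci(b, s)
        row$estimable <- TRUE
        row$converged <- fit$converged
        row$beta <- b; row$se <- s; row$wald_z <- b / s
        row$p_value <- wald_test(b, s)
        row$odds_ratio <- ci$odds_ratio
        row$ci_low <- ci$ci_low; row$ci_high <- ci$ci_high
      }
    }
    rows[[j]] <- row
  }
  out <- do.call(rbind, rows)
  usable <- out$estimable & out$converged
  if (any(usable)) out$fdr_q[usable] <- bh_fdr(out$p_value[usable])
  rownames(out) <- NULL
  class(out) <- c("ctoh_assoc", "data.frame")
  out
}
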