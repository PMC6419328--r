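# End-to-end driver: simulate (optional) -> QC -> PCA covariates -> TOH
# calling -> cTOH regions -> association -> exome feature integration,
# with every intermediate written as TSV/BED/PLINK and a run log whose
# counts reconcile across stages.  Outputs are byte-identical across
# reruns of the same configuration.

#' Configure a full pipeline run
#'
#' @param sim A [sim_config()] describing the cohort to simulate, or
#'   `NULL` when `genotypes` is supplied directly to
#'   [run_toh_pipeline()].
#' @param qc [qc_thresholds()].
#' @param toh [toh_params()].
#' @param k_pcs Number of genotype principal components used as
#'   covariates.
#' @param min_subjects,min_snps cTOH consensus rule: minimum subjects
#'   sharing a tract over a minimum number of consecutive SNPs.
#' @param min_cover_frac Carrier rule (fraction of region SNPs an
#'   individual's tracts must cover).
#' @param fdr_threshold Regions with `fdr_q` below this feed the
#'   integration stage.
#' @param exome An [exome_config()] for the annotation simulation, or
#'   `NULL` to skip integration.
#' @param merge_window,min_samples Indel clustering window (bp) and
#'   recurrence threshold for the integration filter.
#' @param seed Pipeline seed (propagated to `sim`/`exome` configs when
#'   they do not set their own).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), qc = qc_thresholds(),
                            toh = toh_params(), k_pcs = 2L,
                            min_subjects = 10L, min_snps = 100L,
                            min_cover_frac = 0.9, fdr_threshold = 0.05,
                            exome = exome_config(), merge_window = 10,
                            min_samples = 3L, seed = 1L) {
  if (!is.null(sim) && !inherits(sim, "sim_config"))
    stop("`sim` must be a sim_config or NULL")
  if (!inherits(qc, "qc_thresholds")) stop("`qc` must come from qc_thresholds()")
  if (!inherits(toh, "toh_params")) stop("`toh` must come from toh_params()")
  if (!is.null(exome) && !inherits(exome, "exome_config"))
    stop("`exome` must be an exome_config or NULL")
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    stop("`fdr_threshold` must be in (0, 1]")
  if (min_cover_frac <= 0 || min_cover_frac > 1)
    stop("`min_cover_frac` must be in (0, 1]")
  structure(list(sim = sim, qc = qc, toh = toh, k_pcs = as.integer(k_pcs),
                 min_subjects = as.integer(min_subjects),
                 min_snps = as.integer(min_snps),
                 min_cover_frac = min_cover_frac,
                 fdr_threshold = fdr_threshold, exome = exome,
                 merge_window = merge_window,
                 min_samples = as.integer(min_samples),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Demonstration pipeline configuration
#'
#' Desk-scale run: 100 cases + 100 controls on 4 chromosomes x 2,000
#' SNPs with one strongly associated planted tract (carrier
#' probabilities 0.6 vs 0.05) and one null tract (0.25 vs 0.25), plus a
#' planted exome annotation set with one truth gene and two decoys.
#'
#' @param seed Integer seed.
#' @return A [pipeline_config()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  pipeline_config(
    sim = sim_config(
      planted_tracts = list(
        planted_tract("chr1", 500L, 150L, p_case = 0.6, p_control = 0.05),
        planted_tract("chr2", 1000L, 150L, p_case = 0.25, p_control = 0.25)),
      seed = seed),
    exome = exome_config(seed = seed + 1L),
    seed = seed)
}

#' Run the full TOH/cTOH analysis pipeline
#'
#' Executes simulate (when configured) -> QC -> PCA -> TOH calling ->
#' cTOH regions -> carrier association -> exome feature integration,
#' writing every intermediate into `out_dir` (PLINK genotypes, TSV
#' tables, BED tracks) together with a `run_log.tsv` whose in/out
#' counts reconcile at every stage.  Two runs with the same
#' configuration produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param genotypes Optional [genotype_matrix()] to analyse instead of
#'   simulating (`config$sim` is then ignored).
#' @return A list of class `toh_pipeline_result` with elements `cohort`,
#'   `qc`, `covariates`, `tohs`, `coverage`, `regions`, `carriers`,
#'   `assoc`, `significant`, `exome`, `clusters`, `recurrent`,
#'   `shortlist`, `ir_summary`, `log`.
#' @export
run_toh_pipeline <- function(config, out_dir = NULL, genotypes = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must come from pipeline_config()")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(x, name) {
    if (!is.null(out_dir)) write_tsv(x, file.path(out_dir, name))
  }
  log_rows <- list()
  log_stage <- function(stage, key, value)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(stage = stage,
                                                     key = key,
                                                     value = as.character(value))

  stage <- "simulate"
  res <- tryCatch({
    cohort <- NULL
    if (is.null(genotypes)) {
      if (is.null(config$sim)) stop("no genotypes and no simulation config")
      cohort <- simulate_cohort(config$sim)
      genotypes <- cohort$genotypes
      if (!is.null(out_dir)) {
        write_plink(genotypes, file.path(out_dir, "cohort"))
        emit(genotypes$samples, "phenotypes.tsv")
        truth <- do.call(rbind, lapply(cohort$truth_tracts, function(tt)
          data.frame(chromosome = tt$tract$chromosome,
                     start_snp = tt$tract$start_snp,
                     n_snps = tt$tract$n_snps, p_case = tt$tract$p_case,
                     p_control = tt$tract$p_control,
                     n_carriers = sum(tt$carrier))))
        if (!is.null(truth)) emit(truth, "truth_tracts.tsv")
      }
    }
    log_stage("simulate", "n_individuals", nrow(genotypes$geno))
    log_stage("simulate", "n_snps", ncol(genotypes$geno))

    stage <- "qc"
    qcres <- apply_qc(genotypes, config$qc)
    gm <- qcres$genotypes
    emit(qcres$report$snp_stats, "qc_snp_stats.tsv")
    emit(qcres$report$snps_removed, "qc_snps_removed.tsv")
    emit(qcres$report$samples_removed, "qc_samples_removed.tsv")
    log_stage("qc", "samples_in", qcres$report$n_samples_in)
    log_stage("qc", "samples_removed", nrow(qcres$report$samples_removed))
    log_stage("qc", "samples_out", qcres$report$n_samples_out)
    log_stage("qc", "snps_in", qcres$report$n_snps_in)
    log_stage("qc", "snps_removed", nrow(qcres$report$snps_removed))
    log_stage("qc", "snps_out", qcres$report$n_snps_out)

    stage <- "toh"
    tohs <- call_tohs(gm, config$toh)
    emit(tohs, "toh_calls.tsv")
    log_stage("toh", "n_calls", nrow(tohs))

    stage <- "ctoh"
    coverage <- toh_coverage(tohs, gm$map)
    regions <- define_ctohs(coverage, gm$map, config$min_subjects,
                            config$min_snps)
    emit(regions, "ctoh_regions.tsv")
    if (!is.null(out_dir) && nrow(regions))
      write_bed(regions_to_intervals(regions),
                file.path(out_dir, "ctoh_regions.bed"))
    carriers <- assign_carriers(regions, tohs, gm$samples$sample_id,
                                config$min_cover_frac)
    if (!is.null(out_dir))
      write_tsv(data.frame(sample_id = rownames(carriers), carriers,
                           check.names = FALSE),
                file.path(out_dir, "carriers.tsv"))
    log_stage("ctoh", "n_regions", nrow(regions))

    stage <- "pca"
    # covariate PCA runs on markers outside the detected regions so the
    # ancestry axes cannot collude with the carrier predictor
    region_snps <- unlist(mapply(seq, regions$start_idx, regions$end_idx,
                                 SIMPLIFY = FALSE))
    covariates <- make_covariates(gm, config$k_pcs,
                                  exclude_snps = region_snps)
    emit(covariates, "covariates.tsv")
    log_stage("pca", "k", config$k_pcs)
    log_stage("pca", "snps_excluded", length(region_snps))

    stage <- "assoc"
    assoc <- if (nrow(regions))
      associate_all(regions, carriers, gm$samples$phenotype, covariates)
    else suppressWarnings(associate_all(regions, carriers,
                                        gm$samples$phenotype, covariates))
    results <- merge(regions, assoc, by = "region_id", sort = FALSE)
    emit(results, "association.tsv")
    significant <- results[!is.na(results$fdr_q) &
                             results$fdr_q < config$fdr_threshold, ,
                           drop = FALSE]
    class(significant) <- class(regions)
    log_stage("assoc", "n_tested", sum(assoc$estimable & assoc$converged))
    log_stage("assoc", "n_flagged",
              sum(!(assoc$estimable & assoc$converged)))
    log_stage("assoc", "n_significant", nrow(significant))

    stage <- "integrate"
    exome <- clusters <- recurrent <- shortlist <- irs <- NULL
    if (!is.null(config$exome) && nrow(significant)) {
      exome <- simulate_exome_features(config$exome, significant)
      if (!is.null(out_dir)) {
        write_bed(exome$repeats, file.path(out_dir, "repeats.bed"))
        write_bed(exome$genes, file.path(out_dir, "genes.bed"))
        write_indels_tsv(exome$indels, file.path(out_dir, "indels.tsv"))
      }
      clusters <- cluster_indels(exome$indels, config$merge_window)
      recurrent <- recurrent_indels(clusters, exome$repeats,
                                    config$min_samples)
      shortlist <- shortlist_genes(exome$genes, significant, recurrent)
      irs <- ir_summary(exome$repeats, significant, exome$genes)
      emit(clusters$clusters, "indel_clusters.tsv")
      emit(recurrent, "recurrent_clusters.tsv")
      emit(shortlist, "gene_shortlist.tsv")
      emit(irs, "ir_summary.tsv")
      log_stage("integrate", "n_clusters", nrow(clusters$clusters))
      log_stage("integrate", "n_recurrent", nrow(recurrent))
      log_stage("integrate", "n_shortlisted", nrow(shortlist))
    } else {
      log_stage("integrate", "skipped",
                if (is.null(config$exome)) "no_exome_config"
                else "no_significant_regions")
    }

    log <- do.call(rbind, log_rows)
    emit(log, "run_log.tsv")
    structure(list(cohort = cohort, qc = qcres$report,
                   covariates = covariates, tohs = tohs,
                   coverage = coverage, regions = regions,
                   carriers = carriers, assoc = results,
                   significant = significant, exome = exome,
                   clusters = clusters, recurrent = recurrent,
                   shortlist = shortlist, ir_summary = irs, log = log),
              class = "toh_pipeline_result")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' @export
print.toh_pipeline_result <- function(x, ...) {
  cat("toh_pipeline_result:\n")
  cat("  regions:", nrow(x$regions), " significant:", nrow(x$significant),
      "\n")
  if (!is.null(x$shortlist))
    cat("  shortlisted genes:", nrow(x$shortlist), "\n")
  invisible(x)
}
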