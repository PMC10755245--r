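#' Configure the end-to-end pipeline
#'
#' Bundles the per-stage settings: simulation, genotype QC, clumping and
#' threshold-scan parameters, brain-age model settings, mediation bootstrap
#' size, and the three covariate lists (score selection; volume
#' residualization; association model 1 / model 2).
#'
#' @param sim A [sim_config] for the synthetic cohort.
#' @param qc A [qc_thresholds].
#' @param clump_r2,clump_window_kb Clumping parameters (defaults 0.1, 250).
#' @param grid P-value threshold grid (default [default_threshold_grid()]).
#' @param top_k Thresholds retained by the scan (default 10).
#' @param n_outer_folds,n_inner_folds Nested-CV fold counts.
#' @param param_grid Brain-age hyperparameter grid (`NULL` = default).
#' @param n_boot Mediation bootstrap resamples (default 1000).
#' @param selection_covariates Covariates for threshold selection (partial
#'   correlation with ever-smoker status).
#' @param residual_covariates Covariates residualized out of the regional
#'   volumes before brain-age modelling.
#' @param model1_covariates,model2_covariates Covariate sets for the two
#'   association models.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            qc = qc_thresholds(),
                            clump_r2 = 0.1,
                            clump_window_kb = 250,
                            grid = default_threshold_grid(),
                            top_k = 10,
                            n_outer_folds = 5,
                            n_inner_folds = 5,
                            param_grid = NULL,
                            n_boot = 1000,
                            selection_covariates = c(
                              "age", "sex", "handedness", "bmi", "alcohol",
                              "tiv", paste0("pc", 1:5)
                            ),
                            residual_covariates = c(
                              "sex", "ethnicity", "handedness", "bmi",
                              "alcohol", "tiv", "site", "education"
                            ),
                            model1_covariates = c("sex", "age"),
                            model2_covariates = c(
                              "sex", "age", "tiv", "handedness", "bmi",
                              "alcohol", "site", "education"
                            ),
                            seed = 1L) {
  structure(
    list(
      sim = sim, qc = qc, clump_r2 = clump_r2,
      clump_window_kb = clump_window_kb, grid = grid, top_k = top_k,
      n_outer_folds = n_outer_folds, n_inner_folds = n_inner_folds,
      param_grid = param_grid, n_boot = n_boot,
      selection_covariates = selection_covariates,
      residual_covariates = residual_covariates,
      model1_covariates = model1_covariates,
      model2_covariates = model2_covariates,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

stage_error <- function(stage, e) {
  stop_bagprs(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
              "bagprs_stage_error")
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes, in dependency order: cohort simulation; genotype QC; LD
#' clumping and the p-value threshold scan (selection against ever-smoker
#' status with the configured covariates); volume residualization and
#' brain-age modelling trained on never-smokers only, with the never-smoker
#' bias model applied to everyone; covariate-adjusted associations of the
#' z-scored optimal score with corrected BAG, total gray-matter volume,
#' pack-years (smokers) and quit duration (former smokers) under the two
#' covariate models; smoker-vs-non-smoker comparisons of corrected BAG and
#' score; the region-wise association scan; two-mediator (corrected BAG +
#' tGMV) and single-mediator mediation of the score -> pack-years path among
#' smokers; and gene-set over-representation of the SNPs entering the
#' optimal score against a synthetic gene annotation.
#'
#' @param config A [pipeline_config].
#' @param out_dir Optional directory; when given, stage tables are written as
#'   TSV and the manifest as JSON.
#' @return A `bagprs_pipeline` list with per-stage results and a `manifest`
#'   recording every parameter, seed and stage size.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  sim <- tryCatch(simulate_cohort(config$sim), error = function(e) stage_error("simulate", e))
  qc <- tryCatch(qc_filter(sim$genotypes, config$qc), error = function(e) stage_error("qc", e))

  keep <- rownames(qc$genotypes$dosage)
  cohort <- dplyr::filter(sim$cohort, .data$subject %in% keep)
  cohort <- cohort[match(keep, cohort$subject), , drop = FALSE]
  stats <- dplyr::filter(sim$summary_stats, .data$snp %in% qc$genotypes$snps$snp)

  prs <- tryCatch({
    clumped <- clump(stats, qc$genotypes, config$clump_r2, config$clump_window_kb)
    scan <- threshold_scan(
      qc$genotypes, stats, clumped$snp,
      phenotype = as.numeric(cohort$smoker),
      covariates = cohort[, config$selection_covariates],
      grid = config$grid, top_k = config$top_k
    )
    list(clumped = clumped, scan = scan)
  }, error = function(e) stage_error("prs", e))
  cohort$prs_z <- prs$scan$optimal$prs_z

  ba <- tryCatch({
    region_cols <- grep("^rgmv_", names(cohort), value = TRUE)
    resid <- residualize(cohort[, region_cols],
                         cohort[, config$residual_covariates])
    is_never <- cohort$smoking_status == "never"
    fit <- fit_brainage(
      resid[is_never, , drop = FALSE], cohort$age[is_never],
      n_outer_folds = config$n_outer_folds,
      n_inner_folds = config$n_inner_folds,
      param_grid = config$param_grid, seed = config$seed + 10L
    )
    bias <- fit_bias(fit$oof$predicted, fit$oof$age)
    predicted <- numeric(nrow(cohort))
    predicted[is_never] <- fit$oof$predicted
    predicted[!is_never] <- predict(fit, resid[!is_never, , drop = FALSE])
    table <- dplyr::bind_cols(
      tibble::tibble(subject = cohort$subject, group = cohort$smoking_status),
      apply_bias(bias, predicted, cohort$age)
    )
    list(fit = fit, bias = bias, table = table,
         metrics_smoker = fit_metrics(predicted[!is_never], cohort$age[!is_never]))
  }, error = function(e) stage_error("brainage", e))
  cohort$corrected_bag <- ba$table$corrected_bag

  assoc <- tryCatch({
    smokers <- cohort[cohort$smoker, , drop = FALSE]
    former <- cohort[cohort$smoking_status == "former", , drop = FALSE]
    spec <- list(
      list(data = cohort, outcome = "corrected_bag"),
      list(data = cohort, outcome = "tgmv"),
      list(data = smokers, outcome = "pack_years"),
      list(data = former, outcome = "quit_years")
    )
    rows <- purrr::map(spec, function(s) {
      dplyr::bind_rows(
        glm_association(s$data[[s$outcome]], s$data$prs_z,
                        s$data[, config$model1_covariates],
                        outcome_name = s$outcome, model_tag = "model1"),
        glm_association(s$data[[s$outcome]], s$data$prs_z,
                        s$data[, config$model2_covariates],
                        outcome_name = s$outcome, model_tag = "model2")
      )
    })
    dplyr::bind_rows(rows)
  }, error = function(e) stage_error("association", e))

  comparisons <- tryCatch(dplyr::bind_rows(
    dplyr::mutate(
      two_sample_comparison(cohort$corrected_bag[cohort$smoker],
                            cohort$corrected_bag[!cohort$smoker]),
      measure = "corrected_bag", .before = 1
    ),
    dplyr::mutate(
      two_sample_comparison(cohort$prs_z[cohort$smoker],
                            cohort$prs_z[!cohort$smoker]),
      measure = "prs_z", .before = 1
    )
  ), error = function(e) stage_error("comparison", e))

  regions <- tryCatch(
    regionwise_scan(cohort$prs_z,
                    cohort[, grep("^rgmv_", names(cohort), value = TRUE)],
                    cohort[, config$model2_covariates]),
    error = function(e) stage_error("regions", e)
  )

  med <- tryCatch({
    smokers <- cohort[cohort$smoker, , drop = FALSE]
    cc <- smokers[, config$model2_covariates]
    list(
      bag_tgmv = mediate_two(
        smokers$prs_z, smokers$corrected_bag, smokers$tgmv, smokers$pack_years,
        covariates = cc, n_boot = config$n_boot, seed = config$seed + 20L
      ),
      bag = mediate(
        smokers$prs_z, smokers$corrected_bag, smokers$pack_years,
        covariates = cc, n_boot = config$n_boot, seed = config$seed + 21L
      )
    )
  }, error = function(e) stage_error("mediation", e))

  enr <- tryCatch({
    anno <- simulate_gene_annotation(qc$genotypes$snps, seed = config$seed + 30L)
    used <- stats$snp[stats$snp %in% prs$clumped$snp &
                        stats$p < prs$scan$optimal_threshold]
    genes <- map_snps_to_genes(
      qc$genotypes$snps[qc$genotypes$snps$snp %in% used, ], anno$intervals
    )
    list(genes = genes,
         table = ora(genes, anno$sets, universe = anno$intervals$gene))
  }, error = function(e) stage_error("enrichment", e))

  manifest <- list(
    seed = config$seed,
    sim = unclass(config$sim),
    qc_thresholds = unclass(config$qc),
    clump = list(r2 = config$clump_r2, window_kb = config$clump_window_kb),
    grid = list(min = min(config$grid), max = max(config$grid),
                n = length(config$grid)),
    top_k = config$top_k,
    folds = list(outer = config$n_outer_folds, inner = config$n_inner_folds),
    n_boot = config$n_boot,
    covariates = list(
      selection = config$selection_covariates,
      residualization = config$residual_covariates,
      model1 = config$model1_covariates, model2 = config$model2_covariates
    ),
    stage_sizes = list(
      n_subjects = nrow(cohort),
      n_snps_post_qc = ncol(qc$genotypes$dosage),
      n_index_snps = nrow(prs$clumped),
      optimal_threshold = prs$scan$optimal_threshold,
      n_smokers = sum(cohort$smoker)
    )
  )

  out <- structure(
    list(
      sim = sim, qc = qc, cohort = cohort, prs = prs, brainage = ba,
      associations = assoc, comparisons = comparisons, regions = regions,
      mediation = med, enrichment = enr, manifest = manifest,
      config = config
    ),
    class = "bagprs_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.bagprs_pipeline <- function(x, ...) {
  s <- x$manifest$stage_sizes
  cat(sprintf(
    paste0("<bagprs_pipeline> n = %d (%d smokers), %d SNPs post-QC, ",
           "%d index SNPs, optimal P_T = %.3g\n"),
    s$n_subjects, s$n_smokers, s$n_snps_post_qc, s$n_index_snps,
    s$optimal_threshold
  ))
  invisible(x)
}

write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x$cohort, file.path(out_dir, "cohort.tsv"))
  readr::write_tsv(x$prs$clumped, file.path(out_dir, "clumped.tsv"))
  readr::write_tsv(x$prs$scan$thresholds, file.path(out_dir, "threshold_scan.tsv"))
  readr::write_tsv(x$brainage$table, file.path(out_dir, "brainage.tsv"))
  readr::write_tsv(x$associations, file.path(out_dir, "associations.tsv"))
  readr::write_tsv(x$comparisons, file.path(out_dir, "comparisons.tsv"))
  readr::write_tsv(x$regions, file.path(out_dir, "regions.tsv"))
  readr::write_tsv(x$enrichment$table, file.path(out_dir, "enrichment.tsv"))
  readr::write_tsv(x$mediation$bag_tgmv$estimates,
                   file.path(out_dir, "mediation_two.tsv"))
  readr::write_tsv(x$mediation$bag$estimates,
                   file.path(out_dir, "mediation_bag.tsv"))
  jsonlite::write_json(x$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(x)
}
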