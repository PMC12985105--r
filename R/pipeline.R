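#' Pipeline configuration
#'
#' Collects all stage options for [run_pipeline()]. Provide either a
#' `simulate` config (the bundled generator supplies cohort + counts) or
#' paths to a cohort table and a dataset directory written in the package's
#' MTX + TSV layout.
#'
#' @param output_dir Directory for stage outputs (TSV tables, JSON
#'   manifest).
#' @param simulate Optional [sim_config()]; when given, inputs are
#'   simulated.
#' @param cohort_path,dataset_path Input paths (used when `simulate` is
#'   `NULL`).
#' @param gmt_path Optional GMT geneset file for the enrichment stage.
#' @param contrasts Outcomes to analyse; each is tested with the other
#'   outcome and batch as covariates (default both).
#' @param modalities Modalities to analyse (default RNA and protein).
#' @param qc Named list of QC thresholds (see [qc_filter()]).
#' @param alpha Mixed-track FDR level for consensus calls.
#' @param min_cells_mixed,min_expressing,nodes Mixed-track options (see
#'   [de_mixed()]).
#' @param pb_min_cells Minimum cells per pseudobulk unit.
#' @param eps Composition smoothing pseudo-count.
#' @param robustness_candidates Clinical factor columns screened by
#'   [eligible_confounders()]; factors passing enter the robustness scan.
#' @param min_minority Eligibility threshold (see [eligible_confounders()]).
#' @param run_robustness Set `FALSE` to skip the (refit-heavy) robustness
#'   stage.
#' @param seed Seed recorded in the manifest and used for simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, simulate = NULL, cohort_path = NULL,
                            dataset_path = NULL, gmt_path = NULL,
                            contrasts = c("cgvhd", "relapse"),
                            modalities = c("rna", "protein"),
                            qc = list(min_umi = 50, min_genes = 35,
                                      min_novelty = 0.55),
                            alpha = 0.05, min_cells_mixed = 20,
                            min_expressing = 3, nodes = 10, pb_min_cells = 3,
                            eps = 0.5,
                            robustness_candidates = c("donor_source", "hla_match",
                                                      "ptcy", "all_risk", "agvhd"),
                            min_minority = 4, run_robustness = TRUE, seed = 1L) {
  structure(list(output_dir = output_dir, simulate = simulate,
                 cohort_path = cohort_path, dataset_path = dataset_path,
                 gmt_path = gmt_path, contrasts = contrasts,
                 modalities = modalities, qc = qc, alpha = alpha,
                 min_cells_mixed = min_cells_mixed,
                 min_expressing = min_expressing, nodes = nodes,
                 pb_min_cells = pb_min_cells, eps = eps,
                 robustness_candidates = robustness_candidates,
                 min_minority = min_minority,
                 run_robustness = run_robustness, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest, QC, both differential-expression tracks,
#' consensus calling, composition testing, confounder robustness, and
#' geneset enrichment, writing one TSV per result table plus a JSON
#' manifest (package version, config hash, seed, per-stage row counts and
#' timings, and each contrast's covariate set) under
#' `config$output_dir`. Deterministic given the config (the seed governs
#' the only stochastic stage, simulation): the same config yields identical
#' tables.
#'
#' @param config A [pipeline_config()], or the path to a YAML file whose
#'   keys mirror it (a `simulate:` mapping is passed to [sim_config()]).
#' @return Invisibly, a list with all in-memory results plus the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    if (!is.null(raw$simulate)) raw$simulate <- do.call(sim_config, raw$simulate)
    config <- do.call(pipeline_config, raw)
  }
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "abseqde",
                   version = as.character(utils::packageVersion("abseqde")),
                   seed = config$seed,
                   config_hash = rlang::hash(
                     unclass(config)[setdiff(names(config), "output_dir")]),
                   stages = list())
  results <- list()

  stage <- function(name, expr) {
    t0 <- Sys.time()
    value <- tryCatch(expr, error = function(e) {
      rlang::abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                   class = "abseqde_stage_error")
    })
    manifest$stages[[name]] <<- list(
      elapsed_s = round(as.numeric(Sys.time() - t0), 3),
      n_records = if (is.data.frame(value)) nrow(value) else NA)
    value
  }

  # --- input ------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", simulate_cohort(config$simulate))
    cohort <- sim$cohort; dataset <- sim$dataset
    results$truth <- sim$truth
    manifest$stages$simulate$n_cells <- nrow(dataset$counts)
  } else {
    cohort <- stage("load_cohort", load_cohort(config$cohort_path))
    dataset <- stage("read_dataset", read_dataset(config$dataset_path))
  }
  readr::write_tsv(cohort, file.path(out_dir, "cohort.tsv"), progress = FALSE)
  results$cohort <- cohort
  manifest$contrasts <- lapply(config$contrasts, function(v) {
    ctr <- build_contrast(cohort, v)
    list(variable = ctr$variable, covariates = ctr$covariates,
         n_positive = length(ctr$positive_group),
         n_negative = length(ctr$negative_group))
  })
  if (length(config$contrasts) < 2) {
    manifest$note <- paste0("restricted to contrast(s): ",
                            paste(config$contrasts, collapse = ", "))
  }

  # --- qc ---------------------------------------------------------------
  qc <- stage("qc", do.call(qc_filter, c(list(dataset), config$qc)))
  write_qc_report(qc$report, out_dir)
  dataset <- qc$dataset
  results$qc_report <- qc$report
  manifest$stages$qc$n_cells_kept <- length(qc$report$survivors)

  # --- composition ------------------------------------------------------
  props <- stage("proportions", subject_proportions(dataset$cells))
  readr::write_tsv(props, file.path(out_dir, "proportions.tsv"), progress = FALSE)
  comp <- stage("composition",
                test_composition(props, cohort, variables = config$contrasts,
                                 eps = config$eps))
  readr::write_tsv(comp, file.path(out_dir, "composition.tsv"), progress = FALSE)
  results$proportions <- props; results$composition <- comp

  # --- differential expression, both tracks, per modality ---------------
  pb <- stage("pseudobulk_aggregate",
              aggregate_pseudobulk(dataset, min_cells = config$pb_min_cells))
  results$mixed <- list(); results$pseudobulk <- list(); results$consensus <- list()
  for (mod in config$modalities) {
    mixed <- stage(paste0("de_mixed_", mod),
                   de_mixed(dataset, cohort, variables = config$contrasts,
                            modality = mod, min_cells = config$min_cells_mixed,
                            min_expressing = config$min_expressing,
                            nodes = config$nodes))
    pbres <- stage(paste0("de_pseudobulk_", mod),
                   test_pseudobulk(pb, cohort, variables = config$contrasts,
                                   modality = mod))
    cons <- stage(paste0("consensus_", mod),
                  call_consensus(mixed, pbres, alpha = config$alpha))
    readr::write_tsv(dplyr::bind_rows(mixed, pbres),
                     file.path(out_dir, paste0("de_", mod, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(cons, file.path(out_dir, paste0("consensus_", mod, ".tsv")),
                     progress = FALSE)
    manifest$stages[[paste0("consensus_", mod)]]$n_called <- sum(cons$called)
    results$mixed[[mod]] <- mixed
    results$pseudobulk[[mod]] <- pbres
    results$consensus[[mod]] <- cons
  }

  # --- robustness -------------------------------------------------------
  if (isTRUE(config$run_robustness)) {
    candidates <- intersect(config$robustness_candidates, names(cohort))
    factors <- eligible_confounders(cohort, candidates,
                                    min_minority = config$min_minority)
    manifest$robustness_factors <- factors
    rob_all <- list()
    for (mod in config$modalities) {
      rob <- stage(paste0("robustness_", mod),
                   robustness_scan(dataset, cohort, factors = factors,
                                   variables = config$contrasts,
                                   modality = mod,
                                   baseline = results$mixed[[mod]],
                                   min_cells = config$min_cells_mixed,
                                   min_expressing = config$min_expressing,
                                   nodes = config$nodes))
      rob_all[[mod]] <- rob
    }
    correlations <- dplyr::bind_rows(lapply(rob_all, `[[`, "correlations"))
    scatter <- dplyr::bind_rows(lapply(rob_all, `[[`, "scatter"))
    readr::write_tsv(correlations, file.path(out_dir, "robustness.tsv"),
                     progress = FALSE)
    readr::write_tsv(scatter, file.path(out_dir, "robustness_scatter.tsv"),
                     progress = FALSE)
    results$robustness <- list(correlations = correlations, scatter = scatter)
  }

  # --- enrichment -------------------------------------------------------
  if (!is.null(config$gmt_path) && "rna" %in% config$modalities) {
    panel <- unique(results$consensus$rna$feature_id)
    genesets <- stage("read_gmt", read_gmt(config$gmt_path, panel))
    enr <- stage("enrichment",
                 test_enrichment(results$consensus$rna, genesets,
                                 modality = "rna"))
    readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"), progress = FALSE)
    results$enrichment <- enr
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  results$manifest <- manifest
  invisible(results)
}
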