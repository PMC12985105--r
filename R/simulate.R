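#' Configuration for the multimodal cohort simulator
#'
#' Defaults emulate the study design this package was built around: 14
#' subjects processed in 3 cartridges (batches), two partially overlapping
#' binary outcomes with joint counts 1/5/4/4 (cGvHD+/relapse+, cGvHD+/
#' relapse-, cGvHD-/relapse+, cGvHD-/relapse-), ~15 annotated cell types
#' with subject-varying proportions, a targeted panel of 397 RNA features
#' and 41 surface-protein (ADT-like) features, and roughly 50,000 cells in
#' total (cells per subject drawn uniformly from `cells_per_subject`).
#'
#' Counts follow a negative binomial model on the log scale:
#' `log mu = baseline + cell-type offset + batch effect + outcome effect +
#' subject intercept + log(cell size factor)`, with `var = mu + phi * mu^2`.
#' Subject intercepts are shared across a subject's cells for each feature,
#' inducing the within-subject correlation the mixed-model track targets.
#' True differential effects are sparse: per cell type and contrast, a
#' `de_fraction` of features receives a natural-log fold change of random
#' sign with magnitude drawn from `N(lfc_mean, lfc_sd)`.
#'
#' @param n_subjects,n_batches,n_cell_types,n_rna,n_protein Design sizes.
#' @param cells_per_subject Integer range (length 2) for per-subject cell
#'   counts before QC.
#' @param outcome_crosstab Integer vector of length 4, joint outcome counts
#'   in the order (cgvhd+/relapse+, cgvhd+/relapse-, cgvhd-/relapse+,
#'   cgvhd-/relapse-); must sum to `n_subjects`.
#' @param de_fraction Fraction of features that are truly differential per
#'   (contrast, cell type).
#' @param lfc_mean,lfc_sd Mean and SD of the magnitude of true natural-log
#'   fold changes; signs are random.
#' @param sigma_subject SD of the subject random intercept (log scale).
#' @param phi Negative binomial dispersion (`var = mu + phi mu^2`); `0`
#'   gives Poisson counts.
#' @param batch_effect_sd SD of per-(batch, feature) log-scale offsets.
#' @param celltype_baseline_sd SD of per-(cell type, feature) log-scale
#'   baseline offsets (marker-like structure).
#' @param proportion_effect Logit-scale shift applied to the cell-type
#'   proportions of cGvHD-positive subjects for the cell types in
#'   `proportion_affected`; 0 (the default) gives the study's null
#'   composition structure.
#' @param proportion_affected Integer indices of affected cell types.
#' @param proportion_concentration Dirichlet concentration controlling how
#'   much per-subject proportions vary around the baseline.
#' @param qc_fail_fraction Fraction of cells emitted as QC failures (droplet
#'   debris: total RNA UMI below 50 or detected genes below 35).
#' @param multiplet_fraction Fraction of cells flagged as multiplets.
#' @param size_factor_sd SD of log-normal per-cell size factors.
#' @param rna_baseline_meanlog,protein_baseline_meanlog Log-scale mean of
#'   per-feature baseline expression; proteins default much higher,
#'   ADT-like.
#' @param baseline_sdlog SD of per-feature log baselines.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 14, n_batches = 3, n_cell_types = 15,
                       n_rna = 397, n_protein = 41,
                       cells_per_subject = c(2500L, 4700L),
                       outcome_crosstab = c(1L, 5L, 4L, 4L),
                       de_fraction = 0.1, lfc_mean = 1.5, lfc_sd = 0.25,
                       sigma_subject = 0.5, phi = 0.4, batch_effect_sd = 0.2,
                       celltype_baseline_sd = 0.5,
                       proportion_effect = 0, proportion_affected = integer(0),
                       proportion_concentration = 150,
                       qc_fail_fraction = 0.05, multiplet_fraction = 0.03,
                       size_factor_sd = 0.3,
                       rna_baseline_meanlog = log(0.5),
                       protein_baseline_meanlog = log(15),
                       baseline_sdlog = 1,
                       seed = 1L) {
  config <- list(n_subjects = as.integer(n_subjects), n_batches = as.integer(n_batches),
                 n_cell_types = as.integer(n_cell_types), n_rna = as.integer(n_rna),
                 n_protein = as.integer(n_protein),
                 cells_per_subject = as.integer(cells_per_subject),
                 outcome_crosstab = as.integer(outcome_crosstab),
                 de_fraction = de_fraction, lfc_mean = lfc_mean, lfc_sd = lfc_sd,
                 sigma_subject = sigma_subject, phi = phi,
                 batch_effect_sd = batch_effect_sd,
                 celltype_baseline_sd = celltype_baseline_sd,
                 proportion_effect = proportion_effect,
                 proportion_affected = as.integer(proportion_affected),
                 proportion_concentration = proportion_concentration,
                 qc_fail_fraction = qc_fail_fraction,
                 multiplet_fraction = multiplet_fraction,
                 size_factor_sd = size_factor_sd,
                 rna_baseline_meanlog = rna_baseline_meanlog,
                 protein_baseline_meanlog = protein_baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 seed = as.integer(seed))
  validate_sim_config(config)
  structure(config, class = "sim_config")
}

validate_sim_config <- function(config) {
  for (f in c("n_subjects", "n_batches", "n_cell_types")) {
    if (is.na(config[[f]]) || config[[f]] < 1) {
      rlang::abort(paste0("config field '", f, "' must be a positive count"),
                   class = "abseqde_config_error")
    }
  }
  if (config$n_rna < 0 || config$n_protein < 0 ||
      config$n_rna + config$n_protein < 1) {
    rlang::abort("panel sizes must be nonnegative with at least one feature",
                 class = "abseqde_config_error")
  }
  if (length(config$cells_per_subject) != 2 ||
      any(config$cells_per_subject < 1) || diff(config$cells_per_subject) < 0) {
    rlang::abort("cells_per_subject must be an increasing positive range",
                 class = "abseqde_config_error")
  }
  if (length(config$outcome_crosstab) != 4 || any(config$outcome_crosstab < 0) ||
      sum(config$outcome_crosstab) != config$n_subjects) {
    rlang::abort("outcome_crosstab must be 4 nonnegative counts summing to n_subjects",
                 class = "abseqde_config_error")
  }
  for (f in c("de_fraction", "qc_fail_fraction", "multiplet_fraction")) {
    if (config[[f]] < 0 || config[[f]] > 1) {
      rlang::abort(paste0("config field '", f, "' must be in [0, 1]"),
                   class = "abseqde_config_error")
    }
  }
  if (config$sigma_subject < 0 || config$phi < 0 || config$batch_effect_sd < 0) {
    rlang::abort("variance components must be nonnegative",
                 class = "abseqde_config_error")
  }
  if (any(config$proportion_affected > config$n_cell_types)) {
    rlang::abort("proportion_affected indexes a cell type beyond n_cell_types",
                 class = "abseqde_config_error")
  }
  invisible(config)
}

#' Simulate a multimodal single-cell cohort with known ground truth
#'
#' Generates a clinical cohort table, a sparse cell x feature count matrix
#' with cell/feature annotations, and a ground-truth record (true LFCs and
#' DE sets per contrast/cell type/modality, variance components, QC-fail
#' and multiplet labels) for validating every downstream stage. See
#' [sim_config()] for the generative model. Fully reproducible: the same
#' config (including its seed) yields identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `cohort` (tibble), `dataset`
#'   ([abseq_dataset]), and `truth` (list: `de` tibble with columns
#'   contrast/cell_type/modality/feature_id/lfc, `sigma_subject`, `phi`,
#'   `proportion_effects` tibble, `cell_flags` tibble with per-cell
#'   `qc_fail`/`multiplet` labels, and the `config`).
#' @examples
#' sim <- simulate_cohort(sim_config(n_rna = 40, n_protein = 8,
#'   n_cell_types = 3, cells_per_subject = c(60, 100), seed = 7))
#' sim$dataset
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  ns <- config$n_subjects
  K <- config$n_cell_types
  G <- config$n_rna + config$n_protein

  subject_id <- sprintf("S%02d", seq_len(ns))
  ct_tab <- config$outcome_crosstab
  cgvhd <- rep(c(1L, 1L, 0L, 0L), ct_tab)
  relapse <- rep(c(1L, 0L, 1L, 0L), ct_tab)
  batch <- paste0("B", rep_len(seq_len(config$n_batches), ns))
  # clinical factors with marginals typical of a small pediatric HSCT cohort
  cohort <- tibble::tibble(
    subject_id = subject_id, cgvhd = cgvhd, relapse = relapse, batch = batch,
    donor_source = sample(c("related", "unrelated"), ns, TRUE, c(0.75, 0.25)),
    hla_match = sample(c("10/10", "5/10"), ns, TRUE, c(0.45, 0.55)),
    ptcy = stats::rbinom(ns, 1, 0.45),
    all_risk = sample(c("high", "standard"), ns, TRUE, c(0.65, 0.35)),
    agvhd = stats::rbinom(ns, 1, 0.75),
    conditioning = "TBI/Cy", prophylaxis = "Tacro/MMF",
    sampling_day = sample(c(60L, 100L), ns, TRUE, c(0.15, 0.85)))
  cohort <- validate_cohort(cohort)

  feature_id <- c(sprintf("RNA%03d", seq_len(config$n_rna)),
                  sprintf("ADT%03d", seq_len(config$n_protein)))
  modality <- rep(c("rna", "protein"), c(config$n_rna, config$n_protein))
  features <- tibble::tibble(feature_id = feature_id, modality = modality)
  baseline <- stats::rnorm(G,
    mean = ifelse(modality == "rna", config$rna_baseline_meanlog,
                  config$protein_baseline_meanlog),
    sd = config$baseline_sdlog)

  cell_types <- sprintf("CT%02d", seq_len(K))
  ct_offset <- matrix(stats::rnorm(K * G, 0, config$celltype_baseline_sd), K, G)
  batch_levels <- sort(unique(batch))
  batch_eff <- matrix(stats::rnorm(length(batch_levels) * G, 0, config$batch_effect_sd),
                      length(batch_levels), G, dimnames = list(batch_levels, NULL))
  u <- matrix(stats::rnorm(ns * G, 0, config$sigma_subject), ns, G,
              dimnames = list(subject_id, NULL))

  lfc <- draw_true_lfcs(config, cell_types, features)
  lfc_arrays <- lapply(c("cgvhd", "relapse"), function(ctr) {
    L <- matrix(0, K, G, dimnames = list(cell_types, feature_id))
    rows <- lfc[lfc$contrast == ctr, ]
    if (nrow(rows) > 0) L[cbind(rows$cell_type, rows$feature_id)] <- rows$lfc
    L
  })
  names(lfc_arrays) <- c("cgvhd", "relapse")

  # baseline cell-type composition: geometrically decreasing, Dirichlet-
  # perturbed per subject, with an optional logit-scale outcome shift
  p0 <- exp(-0.25 * (seq_len(K) - 1)); p0 <- p0 / sum(p0)
  alpha <- p0 * config$proportion_concentration
  subj_props <- do.call(rbind, lapply(seq_len(ns), function(j) {
    g <- stats::rgamma(K, shape = alpha)
    p <- g / sum(g)
    if (config$proportion_effect != 0 && cohort$cgvhd[j] == 1 &&
        length(config$proportion_affected) > 0) {
      odds_scale <- rep(1, K)
      odds_scale[config$proportion_affected] <- exp(config$proportion_effect)
      p <- p * odds_scale
      p <- p / sum(p)
    }
    p
  }))

  n_cells_subj <- sample(seq(config$cells_per_subject[1], config$cells_per_subject[2]),
                         ns, replace = TRUE)

  blocks <- vector("list", ns)
  cells_meta <- vector("list", ns)
  size_theta <- if (config$phi > 0) 1 / config$phi else Inf
  for (j in seq_len(ns)) {
    nc <- n_cells_subj[j]
    ct_idx <- sample.int(K, nc, replace = TRUE, prob = subj_props[j, ])
    sf <- exp(stats::rnorm(nc, 0, config$size_factor_sd))
    qc_fail <- stats::runif(nc) < config$qc_fail_fraction
    multiplet <- !qc_fail & stats::runif(nc) < config$multiplet_fraction
    sf[qc_fail] <- sf[qc_fail] * 0.01   # debris-like: drives RNA totals below QC floor
    sf[multiplet] <- sf[multiplet] * 2  # two cell loads worth of material
    logmu <- matrix(baseline + batch_eff[batch[j], ] + u[j, ], nc, G, byrow = TRUE) +
      ct_offset[ct_idx, , drop = FALSE] +
      cohort$cgvhd[j] * lfc_arrays$cgvhd[ct_idx, , drop = FALSE] +
      cohort$relapse[j] * lfc_arrays$relapse[ct_idx, , drop = FALSE]
    mu <- sf * exp(logmu)
    y <- if (is.finite(size_theta)) {
      stats::rnbinom(nc * G, size = size_theta, mu = as.vector(mu))
    } else {
      stats::rpois(nc * G, lambda = as.vector(mu))
    }
    blocks[[j]] <- Matrix::Matrix(matrix(y, nc, G), sparse = TRUE)
    cells_meta[[j]] <- tibble::tibble(
      cell_id = sprintf("%s_C%05d", subject_id[j], seq_len(nc)),
      subject_id = subject_id[j],
      cell_type = cell_types[ct_idx],
      multiplet_flag = multiplet, qc_fail = qc_fail)
  }
  counts <- do.call(rbind, blocks)
  cells <- dplyr::bind_rows(cells_meta)

  dataset <- abseq_dataset(counts,
                           cells[, c("cell_id", "subject_id", "cell_type", "multiplet_flag")],
                           features)
  attr(dataset, "seed") <- config$seed
  truth <- list(
    de = lfc,
    sigma_subject = config$sigma_subject,
    phi = config$phi,
    proportion_effects = tibble::tibble(
      cell_type = cell_types[config$proportion_affected],
      logit_shift = rep(config$proportion_effect,
                        length(config$proportion_affected))),
    baseline_proportions = tibble::tibble(cell_type = cell_types, proportion = p0),
    cell_flags = cells[, c("cell_id", "qc_fail", "multiplet_flag")],
    config = config)
  list(cohort = cohort, dataset = dataset, truth = truth)
}

draw_true_lfcs <- function(config, cell_types, features) {
  G <- nrow(features)
  per_ct <- round(config$de_fraction * G)
  out <- list()
  for (ctr in c("cgvhd", "relapse")) {
    for (ct in cell_types) {
      if (per_ct == 0) next
      idx <- sample.int(G, per_ct)
      out[[paste(ctr, ct)]] <- tibble::tibble(
        contrast = ctr, cell_type = ct,
        modality = features$modality[idx],
        feature_id = features$feature_id[idx],
        lfc = sample(c(-1, 1), per_ct, TRUE) *
          abs(stats::rnorm(per_ct, config$lfc_mean, config$lfc_sd)))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(contrast = character(), cell_type = character(),
                          modality = character(), feature_id = character(),
                          lfc = numeric()))
  }
  dplyr::bind_rows(out)
}
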