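#' Confounder-robustness scan of the mixed-model prioritization
#'
#' Quantifies how sensitive the feature prioritization is to clinical
#' confounders: each eligible clinical factor is appended (binarized,
#' majority level vs rest) to the mixed-model fixed effects one at a time
#' — the small cohort rules out multi-factor adjustment — and the signed
#' -log10 p-values with and without the factor are correlated across
#' features, per cell type (and pooled over cell types), per contrast and
#' modality. High correlations indicate that the factor only mildly
#' perturbs the ranking.
#'
#' @param dataset A QC-filtered [abseq_dataset].
#' @param cohort A validated cohort tibble.
#' @param factors Clinical factor columns to scan (pass the output of
#'   [eligible_confounders()]).
#' @param variables Outcomes to contrast; default both.
#' @param modality `"rna"` or `"protein"`.
#' @param baseline Optional precomputed [de_mixed()] result for this
#'   modality/variables (avoids refitting the base model).
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @param ... Passed on to [de_mixed()] (e.g. `min_cells`, `nodes`).
#' @return A list with `correlations` (tibble: `clinical_factor`,
#'   `cell_type` — including a `"pooled"` row per factor —, `modality`,
#'   `contrast`, `r`, `n_features`) and `scatter` (tibble of the paired
#'   signed -log10 p values behind each correlation, for plotting without
#'   refitting). Features untestable in either fit are excluded from both
#'   vectors; cell types whose augmented design is singular are skipped
#'   with a warning.
#' @export
robustness_scan <- function(dataset, cohort, factors,
                            variables = c("cgvhd", "relapse"),
                            modality = c("rna", "protein"),
                            baseline = NULL, method = c("pearson", "spearman"),
                            ...) {
  modality <- match.arg(modality)
  method <- match.arg(method)
  if (is.null(baseline)) {
    baseline <- de_mixed(dataset, cohort, variables = variables,
                         modality = modality, ...)
  }
  base <- dplyr::mutate(baseline, slp_base = signed_logp(baseline))
  keys <- c("feature_id", "cell_type", "contrast")

  cors <- list(); scatters <- list()
  for (f in factors) {
    aug <- de_mixed(dataset, cohort, variables = variables,
                    modality = modality, extra_factor = f, ...)
    singular <- unique(aug$cell_type[!is.na(aug$note) &
                                       aug$note == "singular_design"])
    if (length(singular) > 0) {
      rlang::warn(paste0("factor '", f, "': augmented design singular for ",
                         "cell type(s) ", paste(singular, collapse = ", "),
                         "; skipped"))
    }
    aug <- dplyr::mutate(aug, slp_aug = signed_logp(aug))
    paired <- dplyr::inner_join(
      dplyr::select(base, dplyr::all_of(keys), "slp_base"),
      dplyr::select(aug, dplyr::all_of(keys), "slp_aug"),
      by = keys)
    paired <- paired[stats::complete.cases(paired$slp_base, paired$slp_aug), ]
    if (nrow(paired) == 0) next
    per_ct <- paired |>
      dplyr::group_by(.data$cell_type, .data$contrast) |>
      dplyr::summarise(r = cor_safe(.data$slp_base, .data$slp_aug, method),
                       n_features = dplyr::n(), .groups = "drop")
    pooled <- paired |>
      dplyr::group_by(.data$contrast) |>
      dplyr::summarise(r = cor_safe(.data$slp_base, .data$slp_aug, method),
                       n_features = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(cell_type = "pooled")
    cors[[f]] <- dplyr::bind_rows(per_ct, pooled) |>
      dplyr::mutate(clinical_factor = f, modality = modality)
    scatters[[f]] <- dplyr::mutate(paired, clinical_factor = f,
                                   modality = modality)
  }
  correlations <- if (length(cors)) dplyr::bind_rows(cors) else
    tibble::tibble(cell_type = character(), contrast = character(),
                   r = numeric(), n_features = integer(),
                   clinical_factor = character(), modality = character())
  scatter <- if (length(scatters)) dplyr::bind_rows(scatters) else
    tibble::tibble()
  list(correlations = dplyr::select(correlations, "clinical_factor",
                                    "cell_type", "modality", "contrast",
                                    "r", "n_features"),
       scatter = scatter)
}

# Pearson/Spearman correlation that tolerates degenerate vectors (constant
# input gives NA rather than an error/warning).
cor_safe <- function(x, y, method) {
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}
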