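#' Heatmap of signed -log10 p with consensus calls starred
#'
#' The differential-expression heatmap layout: features x cell types,
#' filled by the mixed-track signed -log10 p, with consensus-called
#' entries starred. Features with no called entry in any cell type can be
#' dropped to keep panels readable.
#'
#' @param consensus Output of [call_consensus()].
#' @param contrast,modality Slice to draw.
#' @param called_only Keep only features consensus-called in at least one
#'   cell type (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_consensus_heatmap <- function(consensus, contrast, modality = "rna",
                                   called_only = TRUE) {
  slice <- consensus[consensus$contrast == contrast &
                       consensus$modality == modality, ]
  if (called_only) {
    keep <- unique(slice$feature_id[slice$called])
    slice <- slice[slice$feature_id %in% keep, ]
  }
  ggplot2::ggplot(slice, ggplot2::aes(x = .data$feature_id,
                                      y = .data$cell_type,
                                      fill = .data$signed_logp)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$called, "*", "")),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", na.value = "grey90",
                                  name = "signed -log10 p") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0(contrast, " differential ", modality,
                                 " (consensus calls starred)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Stacked bars of per-subject cell-type proportions
#'
#' @param props Output of [subject_proportions()].
#' @return A ggplot object.
#' @export
plot_composition <- function(props) {
  ggplot2::ggplot(props, ggplot2::aes(x = .data$subject_id,
                                      y = .data$proportion,
                                      fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of cells", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Tile plot of robustness correlations
#'
#' Clinical factors x cell types, filled by the correlation between signed
#' -log10 p with and without each factor in the model; one facet per
#' contrast.
#'
#' @param correlations The `correlations` tibble from [robustness_scan()].
#' @return A ggplot object.
#' @export
plot_robustness <- function(correlations) {
  ggplot2::ggplot(correlations,
                  ggplot2::aes(x = .data$cell_type, y = .data$clinical_factor,
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 2.5) +
    ggplot2::facet_grid(.data$modality ~ .data$contrast) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Scatter of signed -log10 p with vs without a clinical factor
#'
#' @param scatter The `scatter` tibble from [robustness_scan()].
#' @param clinical_factor Which factor to draw.
#' @return A ggplot object, one facet per cell type.
#' @export
plot_robustness_scatter <- function(scatter, clinical_factor) {
  slice <- scatter[scatter$clinical_factor == clinical_factor, ]
  ggplot2::ggplot(slice, ggplot2::aes(x = .data$slp_base, y = .data$slp_aug)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~ .data$cell_type) +
    ggplot2::labs(x = "signed -log10 p (baseline)",
                  y = paste0("signed -log10 p (+ ", clinical_factor, ")")) +
    ggplot2::theme_minimal()
}

#' QC scatter of per-cell metrics
#'
#' Total RNA UMI vs detected genes, coloured by the filter that removed
#' each cell (kept cells in grey).
#'
#' @param object A `qc_report` from [qc_filter()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qc_report <- function(object, ...) {
  m <- object$cell_metrics
  m$status <- ifelse(is.na(m$removed_by), "kept", m$removed_by)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$total_umi, y = .data$n_genes,
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "total RNA UMI", y = "detected genes", colour = NULL) +
    ggplot2::theme_minimal()
}
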