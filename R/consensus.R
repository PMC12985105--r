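#' Signed -log10 p-values
#'
#' The prioritization score used for heatmaps and robustness correlations:
#' `sign(effect) * (-log10(p))`, with p floored at 1e-300 and a zero effect
#' mapped to 0 by convention. Missing p-values give `NA`.
#'
#' @param results A data frame with columns `p` and `effect` (e.g. the
#'   output of [de_mixed()]).
#' @return Numeric vector, one value per row.
#' @export
signed_logp <- function(results) {
  p <- pmax(results$p, 1e-300)
  s <- sign(results$effect)
  out <- s * (-log10(p))
  out[!is.na(s) & s == 0] <- 0
  out
}

#' Direction-concordant consensus differential calls
#'
#' Combines the mixed-model and pseudobulk tracks into the final call: a
#' feature is declared differential in a cell type and contrast when
#' (1) its mixed-model q-value passes FDR at `alpha`, (2) its pseudobulk
#' p-value is below 0.05, and (3) the two tracks' effect estimates agree in
#' sign (strict sign equality; a zero effect fails). Entries untestable in
#' either track are never called and carry the reason in `note`.
#'
#' @param mixed Result tibble from [de_mixed()].
#' @param pb Result tibble from [test_pseudobulk()] over the same features,
#'   cell types, contrasts and modality; a key mismatch raises an
#'   alignment error.
#' @param alpha FDR level for the mixed track (default 0.05).
#' @return A tibble keyed by (feature_id, cell_type, contrast, modality)
#'   with both tracks' effects and p-values, the three condition flags
#'   (`cond1_fdr_pass`, `cond2_pb_pass`, `cond3_direction_pass`), the final
#'   `called` flag, and `signed_logp` (sign of the mixed effect times
#'   -log10 of the mixed p).
#' @export
call_consensus <- function(mixed, pb, alpha = 0.05) {
  keys <- c("feature_id", "cell_type", "contrast", "modality")
  m <- dplyr::select(mixed, dplyr::all_of(keys), effect_mixed = "effect",
                     p_mixed = "p", q_mixed = "q", note_mixed = "note")
  b <- dplyr::select(pb, dplyr::all_of(keys), effect_pb = "effect",
                     p_pb = "p", note_pb = "note")
  if (nrow(m) != nrow(b) ||
      !identical(dplyr::arrange(m[keys], dplyr::across(dplyr::everything())),
                 dplyr::arrange(b[keys], dplyr::across(dplyr::everything())))) {
    rlang::abort("mixed and pseudobulk results are not keyed identically",
                 class = "abseqde_alignment_error")
  }
  res <- dplyr::inner_join(m, b, by = keys)
  res <- dplyr::mutate(
    res,
    cond1_fdr_pass = !is.na(.data$q_mixed) & .data$q_mixed < alpha,
    cond2_pb_pass = !is.na(.data$p_pb) & .data$p_pb < 0.05,
    cond3_direction_pass = !is.na(.data$effect_mixed) & !is.na(.data$effect_pb) &
      sign(.data$effect_mixed) != 0 &
      sign(.data$effect_mixed) == sign(.data$effect_pb),
    called = .data$cond1_fdr_pass & .data$cond2_pb_pass & .data$cond3_direction_pass,
    note = dplyr::case_when(
      !is.na(.data$note_mixed) ~ paste0("mixed:", .data$note_mixed),
      !is.na(.data$note_pb) ~ paste0("pseudobulk:", .data$note_pb),
      TRUE ~ NA_character_))
  res$signed_logp <- signed_logp(tibble::tibble(p = res$p_mixed,
                                                effect = res$effect_mixed))
  dplyr::select(res, -"note_mixed", -"note_pb")
}

#' Heatmap-ready matrix of signed -log10 p
#'
#' Pivots consensus calls for one contrast and modality into a cell type x
#' feature matrix of signed -log10 mixed-track p-values, the layout used
#' for the differential heatmaps (called entries can be starred via the
#' matching `called` matrix in the attribute of the same name).
#'
#' @param consensus Output of [call_consensus()].
#' @param contrast,modality Which slice to pivot.
#' @return A numeric matrix (cell types x features) with a logical
#'   attribute `called` of the same shape.
#' @export
consensus_matrix <- function(consensus, contrast, modality = "rna") {
  slice <- consensus[consensus$contrast == contrast &
                       consensus$modality == modality, ]
  cts <- sort(unique(slice$cell_type))
  fts <- sort(unique(slice$feature_id))
  m <- matrix(NA_real_, length(cts), length(fts), dimnames = list(cts, fts))
  cl <- matrix(FALSE, length(cts), length(fts), dimnames = list(cts, fts))
  m[cbind(slice$cell_type, slice$feature_id)] <- slice$signed_logp
  cl[cbind(slice$cell_type, slice$feature_id)] <- slice$called
  attr(m, "called") <- cl
  m
}
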