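#' Per-subject cell-type counts and proportions
#'
#' Tabulates each subject's annotated cells into per-cell-type counts and
#' proportions. The grid is completed so that cell types absent from a
#' subject appear with count 0; per-subject proportions sum to 1.
#'
#' @param cells Cell metadata with columns `subject_id` and `cell_type`
#'   (e.g. the `cells` element of an [abseq_dataset]).
#' @return A tibble with columns `subject_id`, `cell_type`, `n_cells`
#'   (type count), `n_total` (subject total), `proportion`.
#' @export
subject_proportions <- function(cells) {
  if (!all(c("subject_id", "cell_type") %in% names(cells))) {
    rlang::abort("cells must have subject_id and cell_type columns",
                 class = "abseqde_schema_error")
  }
  props <- cells |>
    dplyr::count(.data$subject_id, .data$cell_type, name = "n_cells") |>
    tidyr::complete(.data$subject_id, .data$cell_type,
                    fill = list(n_cells = 0L)) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(n_total = sum(.data$n_cells),
                  proportion = .data$n_cells / .data$n_total) |>
    dplyr::ungroup()
  empty <- unique(props$subject_id[props$n_total == 0])
  if (length(empty) > 0) {
    rlang::warn(paste0("excluding subject(s) with 0 cells: ",
                       paste(empty, collapse = ", ")))
    props <- props[!props$subject_id %in% empty, ]
  }
  props
}

#' Cell-type composition tests on logit proportions
#'
#' For each cell type and contrast, regresses the logit-transformed
#' per-subject proportion on the outcome of interest with batch and the
#' other outcome as covariates. Zero (and unit) proportions are handled by
#' count-based smoothing before the transform:
#' `p* = (k + eps) / (n + 2 eps)` with `k` the subject's type count and
#' `n` the subject total, keeping the logit argument strictly inside
#' (0, 1). P-values are BH-adjusted across all cell types x requested
#' contrasts (one family).
#'
#' @param props Output of [subject_proportions()].
#' @param cohort A validated cohort tibble.
#' @param variables Outcomes to contrast; default both.
#' @param eps Smoothing pseudo-count (default 0.5).
#' @return A tibble: `cell_type`, `contrast`, `estimate` (logit-scale
#'   coefficient), `se`, `p`, `q`, `n_subjects`.
#' @export
test_composition <- function(props, cohort, variables = c("cgvhd", "relapse"),
                             eps = 0.5) {
  variables <- match.arg(variables, c("cgvhd", "relapse"), several.ok = TRUE)
  out <- list()
  for (variable in variables) {
    contrast <- build_contrast(cohort, variable)
    other <- setdiff(c("cgvhd", "relapse"), variable)
    for (ct in sort(unique(props$cell_type))) {
      slice <- props[props$cell_type == ct, ]
      srow <- match(slice$subject_id, cohort$subject_id)
      if (anyNA(srow)) {
        rlang::abort("proportions contain subjects absent from the cohort",
                     class = "abseqde_validation_error")
      }
      x <- cohort[[variable]][srow]
      if (sum(x == 1) < 2 || sum(x == 0) < 2) {
        rlang::abort("each outcome group needs >= 2 subjects",
                     class = "abseqde_contrast_error")
      }
      p_star <- (slice$n_cells + eps) / (slice$n_total + 2 * eps)
      df <- data.frame(y = stats::qlogis(p_star), x = x,
                       batch = factor(cohort$batch[srow]),
                       other = cohort[[other]][srow])
      fit <- stats::lm(y ~ x + batch + other, data = df)
      sm <- summary(fit)$coefficients
      if (!"x" %in% rownames(sm)) {
        rlang::abort("degenerate composition design (outcome aliased)",
                     class = "abseqde_design_error")
      }
      out[[paste(variable, ct)]] <- tibble::tibble(
        cell_type = ct, contrast = variable,
        estimate = sm["x", "Estimate"], se = sm["x", "Std. Error"],
        p = sm["x", "Pr(>|t|)"], n_subjects = nrow(slice))
    }
  }
  res <- dplyr::bind_rows(out)
  res$q <- bh_adjust(res$p)
  dplyr::select(res, "cell_type", "contrast", "estimate", "se", "p", "q",
                "n_subjects")
}
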