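#' Benjamini-Hochberg adjustment over a declared family
#'
#' Standard BH step-up with enforced monotonicity. Missing p-values are
#' excluded from the family and returned as `NA`. `family_size` can be set
#' larger than the number of observed p-values to adjust within a declared
#' family of which only part was testable.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (or `NA`).
#' @param family_size Family size `m` for the step-up rule; defaults to the
#'   number of non-missing p-values.
#' @return Vector of q-values, same length and order as `p_values`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p_values, family_size = sum(!is.na(p_values))) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) {
    rlang::abort("p-values must lie in [0, 1]", class = "abseqde_validation_error")
  }
  q <- rep(NA_real_, length(p_values))
  n <- length(p)
  if (n == 0) return(q)
  m <- max(family_size, n)
  ord <- order(p)
  ranked <- m * p[ord] / seq_len(n)
  ranked <- rev(cummin(rev(ranked)))   # step-up monotonicity
  qq <- numeric(n)
  qq[ord] <- pmin(ranked, 1)
  q[ok] <- qq
  q
}

#' Per-cell negative binomial mixed-model differential expression
#'
#' The per-cell track of the dual-track analysis: for every feature of one
#' modality and every annotated cell type, fits the subject-random-intercept
#' NB mixed model of [fit_nbmm()] with the outcome of interest, processing
#' batch, and the other outcome as fixed effects, and the log per-cell
#' total count over the modality's panel as offset. Wald p-values for the
#' outcome coefficient are BH-adjusted across the full declared family:
#' all features x cell types x all requested contrasts (RNA and protein
#' run, and are adjusted, separately).
#'
#' A (feature, cell type) combination is recorded as untestable (with the
#' reason in `note` and missing p) when the cell type has fewer than
#' `min_cells` cells, lacks 2 subjects in either outcome group, the feature
#' has fewer than `min_expressing` expressing cells, or the fixed-effect
#' design is singular.
#'
#' @param dataset A QC-filtered [abseq_dataset] with cell-type labels.
#' @param cohort A validated cohort tibble covering the dataset's subjects.
#' @param variables Outcomes to contrast (each is tested with the other as
#'   covariate); default both.
#' @param modality `"rna"` or `"protein"`.
#' @param min_cells Minimum cells per cell type (default 20).
#' @param min_expressing Minimum expressing cells per feature (default 3).
#' @param nodes Quadrature nodes passed to [fit_nbmm()].
#' @param extra_factor Optional cohort column appended (binarized, majority
#'   level vs rest) to the fixed effects — used by [robustness_scan()].
#' @return A tibble with one row per feature x cell type x contrast:
#'   `feature_id`, `cell_type`, `contrast`, `modality`, `track` (`"mixed"`),
#'   `effect` (natural-log fold change for the outcome), `se`, `z`, `p`,
#'   `q`, `converged`, `boundary`, `n_cells`, `n_subjects`, `note`.
#' @export
de_mixed <- function(dataset, cohort, variables = c("cgvhd", "relapse"),
                     modality = c("rna", "protein"), min_cells = 20,
                     min_expressing = 3, nodes = 10, extra_factor = NULL) {
  modality <- match.arg(modality)
  variables <- match.arg(variables, c("cgvhd", "relapse"), several.ok = TRUE)
  cols <- modality_cols(dataset, modality)
  if (length(cols) == 0) {
    rlang::abort(paste0("dataset has no ", modality, " features"),
                 class = "abseqde_precondition_error")
  }
  counts <- dataset$counts[, cols, drop = FALSE]
  feature_ids <- dataset$features$feature_id[cols]
  panel_total <- Matrix::rowSums(counts)

  cells <- dataset$cells
  subj_row <- match(cells$subject_id, cohort$subject_id)
  if (anyNA(subj_row)) {
    rlang::abort("dataset contains subjects absent from the cohort",
                 class = "abseqde_validation_error")
  }

  extra <- NULL
  if (!is.null(extra_factor)) {
    if (!extra_factor %in% names(cohort)) {
      rlang::abort(paste0("extra_factor '", extra_factor, "' not in cohort"),
                   class = "abseqde_schema_error")
    }
    extra <- binarize_factor(cohort[[extra_factor]])
  }

  out <- vector("list", 2 * length(unique(cells$cell_type)))
  k <- 0
  for (variable in variables) {
    contrast <- build_contrast(cohort, variable)
    x_subj <- cohort[[variable]]
    other_subj <- cohort[[setdiff(c("cgvhd", "relapse"), variable)]]
    for (ct in sort(unique(cells$cell_type))) {
      k <- k + 1
      idx <- which(cells$cell_type == ct & panel_total > 0)
      res <- de_mixed_celltype(
        counts = counts, idx = idx, feature_ids = feature_ids,
        x = x_subj[subj_row[idx]], other = other_subj[subj_row[idx]],
        batch = cohort$batch[subj_row[idx]],
        extra = if (is.null(extra)) NULL else extra[subj_row[idx]],
        offset = log(panel_total[idx]), subject = cells$subject_id[idx],
        min_cells = min_cells, min_expressing = min_expressing, nodes = nodes)
      res$cell_type <- ct
      res$contrast <- variable
      out[[k]] <- res
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_de_result())
  res <- dplyr::mutate(res, modality = modality, track = "mixed",
                       q = bh_adjust(.data$p))
  dplyr::select(res, "feature_id", "cell_type", "contrast", "modality",
                "track", "effect", "se", "z", "p", "q", "converged",
                "boundary", "n_cells", "n_subjects", "note")
}

empty_de_result <- function() {
  tibble::tibble(feature_id = character(), cell_type = character(),
                 contrast = character(), modality = character(),
                 track = character(), effect = numeric(), se = numeric(),
                 z = numeric(), p = numeric(), q = numeric(),
                 converged = logical(), boundary = logical(),
                 n_cells = integer(), n_subjects = integer(),
                 note = character())
}

de_mixed_celltype <- function(counts, idx, feature_ids, x, other, batch, extra,
                              offset, subject, min_cells, min_expressing, nodes) {
  G <- length(feature_ids)
  skeleton <- tibble::tibble(
    feature_id = feature_ids, effect = NA_real_, se = NA_real_, z = NA_real_,
    p = NA_real_, converged = NA, boundary = NA,
    n_cells = length(idx), n_subjects = length(unique(subject)),
    note = NA_character_)
  if (length(idx) < min_cells) {
    skeleton$note <- "too_few_cells"
    return(skeleton)
  }
  if (length(unique(subject[x == 1])) < 2 || length(unique(subject[x == 0])) < 2) {
    skeleton$note <- "group_missing"
    return(skeleton)
  }
  X <- stats::model.matrix(~ x_ + batch_ + other_,
                           data = data.frame(x_ = x, batch_ = factor(batch),
                                             other_ = other))
  colnames(X)[1:2] <- c("intercept", "x")
  if (!is.null(extra)) X <- cbind(X, extra_factor = extra)
  # drop constant non-intercept columns, then require full rank
  const <- apply(X, 2, function(col) length(unique(col)) == 1)
  const[1] <- FALSE
  X <- X[, !const, drop = FALSE]
  if (qr(X)$rank < ncol(X)) {
    skeleton$note <- "singular_design"
    return(skeleton)
  }

  Y <- as.matrix(counts[idx, , drop = FALSE])
  expressing <- Matrix::colSums(Y > 0)
  for (g in seq_len(G)) {
    if (expressing[g] < min_expressing) {
      skeleton$note[g] <- if (expressing[g] == 0) "all_zero" else "low_expression"
      next
    }
    fit <- tryCatch(
      fit_nbmm(Y[, g], X, offset = offset, subject = subject, nodes = nodes),
      error = function(e) NULL)
    if (is.null(fit)) {
      skeleton$note[g] <- "fit_error"
      next
    }
    row <- which(fit$coefficients$term == "x")
    skeleton$effect[g] <- fit$coefficients$estimate[row]
    skeleton$se[g] <- fit$coefficients$se[row]
    skeleton$z[g] <- fit$coefficients$z[row]
    skeleton$converged[g] <- fit$converged
    skeleton$boundary[g] <- fit$boundary
    if (fit$converged) {
      skeleton$p[g] <- fit$coefficients$p[row]
    } else {
      skeleton$note[g] <- "not_converged"
    }
  }
  skeleton
}
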