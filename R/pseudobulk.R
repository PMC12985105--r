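#' Aggregate single-cell counts to subject x cell-type pseudobulk
#'
#' Sums raw counts over all cells of each (subject, cell type) unit. Units
#' with fewer than `min_cells` cells are excluded from the matrix and
#' listed in `excluded`. Normalized expression is log2(CPM + 1), with
#' counts-per-million computed within each modality's panel (RNA and
#' protein library sizes are kept separate so the much deeper ADT counts do
#' not distort RNA normalization).
#'
#' @param dataset An [abseq_dataset] (typically QC-filtered).
#' @param min_cells Minimum cells per unit (default 3).
#' @return A `pseudobulk_matrix`: `raw` (integer unit x feature matrix),
#'   `normalized` (log2 CPM + 1), `units` tibble (`subject_id`,
#'   `cell_type`, `n_cells`), `features`, `excluded` tibble, and
#'   `cell_types` (every cell type seen in the input, including ones whose
#'   units were all excluded).
#' @export
aggregate_pseudobulk <- function(dataset, min_cells = 3) {
  cells <- dataset$cells
  unit_key <- paste(cells$subject_id, cells$cell_type, sep = "\r")
  unit_levels <- unique(unit_key)
  ind <- Matrix::sparseMatrix(
    i = match(unit_key, unit_levels), j = seq_len(nrow(cells)), x = 1,
    dims = c(length(unit_levels), nrow(cells)))
  raw <- as.matrix(ind %*% dataset$counts)
  parts <- do.call(rbind, strsplit(unit_levels, "\r", fixed = TRUE))
  units <- tibble::tibble(subject_id = parts[, 1], cell_type = parts[, 2],
                          n_cells = as.integer(Matrix::rowSums(ind)))
  keep <- units$n_cells >= min_cells
  excluded <- units[!keep, , drop = FALSE]
  units <- units[keep, , drop = FALSE]
  raw <- raw[keep, , drop = FALSE]

  normalized <- raw
  for (mod in unique(dataset$features$modality)) {
    cols <- which(dataset$features$modality == mod)
    lib <- rowSums(raw[, cols, drop = FALSE])
    cpm <- raw[, cols, drop = FALSE] / pmax(lib, 1) * 1e6
    normalized[, cols] <- log2(cpm + 1)
  }
  dimnames(raw) <- dimnames(normalized) <-
    list(paste(units$subject_id, units$cell_type, sep = ":"),
         dataset$features$feature_id)
  structure(list(raw = raw, normalized = normalized, units = units,
                 features = dataset$features, excluded = excluded,
                 cell_types = sort(unique(cells$cell_type)),
                 min_cells = min_cells),
            class = "pseudobulk_matrix")
}

#' @export
print.pseudobulk_matrix <- function(x, ...) {
  cat("<pseudobulk_matrix> ", nrow(x$raw), " units x ", ncol(x$raw),
      " features (", nrow(x$excluded), " unit(s) below ", x$min_cells,
      " cells excluded)\n", sep = "")
  invisible(x)
}

#' Subject-level pseudobulk differential expression
#'
#' The subject-level track of the dual-track analysis: for every feature of
#' one modality and every cell type, ordinary least squares of normalized
#' pseudobulk expression (log2 CPM + 1) on the outcome of interest with
#' batch and the other outcome as covariates, one observation per subject
#' unit. Reports the two-sided t-test p-value for the outcome coefficient;
#' no multiplicity adjustment is applied on this track (the consensus rule
#' consumes the raw p < 0.05). The reported `effect` is converted from the
#' fitted log2 scale to natural log so both tracks share units.
#'
#' @param pb A `pseudobulk_matrix` from [aggregate_pseudobulk()].
#' @param cohort A validated cohort tibble.
#' @param variables Outcomes to contrast; default both.
#' @param modality `"rna"` or `"protein"`.
#' @return A tibble with the same schema as [de_mixed()] (`track =
#'   "pseudobulk"`, `q = NA`). Cell types with fewer than 2 units per
#'   outcome group, or designs with no residual degrees of freedom, are
#'   flagged untestable.
#' @export
test_pseudobulk <- function(pb, cohort, variables = c("cgvhd", "relapse"),
                            modality = c("rna", "protein")) {
  modality <- match.arg(modality)
  variables <- match.arg(variables, c("cgvhd", "relapse"), several.ok = TRUE)
  cols <- which(pb$features$modality == modality)
  if (length(cols) == 0) {
    rlang::abort(paste0("pseudobulk has no ", modality, " features"),
                 class = "abseqde_precondition_error")
  }
  feature_ids <- pb$features$feature_id[cols]
  out <- list()
  for (variable in variables) {
    contrast <- build_contrast(cohort, variable)
    for (ct in pb$cell_types) {
      rows <- which(pb$units$cell_type == ct)
      res <- test_pseudobulk_celltype(
        Y = pb$normalized[rows, cols, drop = FALSE],
        units = pb$units[rows, , drop = FALSE],
        cohort = cohort, variable = variable, feature_ids = feature_ids)
      res$cell_type <- ct
      res$contrast <- variable
      out[[paste(variable, ct)]] <- res
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_de_result())
  res <- dplyr::mutate(res, modality = modality, track = "pseudobulk",
                       q = NA_real_)
  dplyr::select(res, "feature_id", "cell_type", "contrast", "modality",
                "track", "effect", "se", "z", "p", "q", "converged",
                "boundary", "n_cells", "n_subjects", "note")
}

test_pseudobulk_celltype <- function(Y, units, cohort, variable, feature_ids) {
  skeleton <- tibble::tibble(
    feature_id = feature_ids, effect = NA_real_, se = NA_real_, z = NA_real_,
    p = NA_real_, converged = NA, boundary = NA,
    n_cells = sum(units$n_cells), n_subjects = nrow(units),
    note = NA_character_)
  srow <- match(units$subject_id, cohort$subject_id)
  x <- cohort[[variable]][srow]
  if (sum(x == 1) < 2 || sum(x == 0) < 2) {
    skeleton$note <- "group_missing"
    return(skeleton)
  }
  other <- cohort[[setdiff(c("cgvhd", "relapse"), variable)]][srow]
  X <- stats::model.matrix(~ x_ + batch_ + other_,
                           data = data.frame(x_ = x,
                                             batch_ = factor(cohort$batch[srow]),
                                             other_ = other))
  colnames(X)[1:2] <- c("intercept", "x")
  const <- apply(X, 2, function(col) length(unique(col)) == 1)
  const[1] <- FALSE
  X <- X[, !const, drop = FALSE]
  qrX <- qr(X)
  df <- nrow(X) - qrX$rank
  if (qrX$rank < ncol(X) || df < 1) {
    skeleton$note <- if (qrX$rank < ncol(X)) "singular_design" else "insufficient_df"
    return(skeleton)
  }
  # vectorized OLS across features: one QR, all responses at once
  coefs <- qr.coef(qrX, Y)
  resid <- Y - X %*% coefs
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  cx <- xtx_inv[which(colnames(X) == "x"), which(colnames(X) == "x")]
  beta_x <- coefs[which(colnames(X) == "x"), ]
  se <- sqrt(sigma2 * cx)
  tval <- beta_x / se
  # exact-arithmetic degeneracies: a residual-free fit has either a truly
  # null effect (p = 1) or perfect separation (p = 0); guard against
  # floating-point dust standing in for zero
  exact <- sigma2 < 1e-20
  tval[exact & abs(beta_x) < 1e-10] <- 0
  tval[exact & abs(beta_x) >= 1e-10] <- sign(beta_x[exact & abs(beta_x) >= 1e-10]) * Inf
  tval[is.nan(tval)] <- 0
  pval <- 2 * stats::pt(-abs(tval), df)
  skeleton$effect <- as.numeric(beta_x) * log(2)   # log2 -> natural log
  skeleton$se <- as.numeric(se) * log(2)
  skeleton$z <- as.numeric(tval)
  skeleton$p <- as.numeric(pval)
  skeleton$converged <- TRUE
  skeleton
}
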