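#' Cell-level quality-control filtering
#'
#' Removes flagged multiplets and low-quality cells from a multimodal
#' dataset. Metrics are computed on the RNA panel only (surface-protein
#' tags would inflate UMI totals, and the default thresholds are calibrated
#' to a ~400-gene targeted panel): per-cell total RNA UMI, number of
#' detected genes, and the novelty score. Cells are removed when flagged as
#' multiplets or when `total UMI < min_umi`, `detected genes < min_genes`,
#' or `novelty < min_novelty`; each removed cell is attributed to the first
#' matching filter in that order.
#'
#' The printed QC rule "log10(number of genes per UMI) < 0.55" is
#' implemented by default as the standard novelty score
#' `log10(n_genes) / log10(n_UMI)`: the literal `log10(genes/UMI)` is
#' non-positive for every real cell (genes <= UMI), so a 0.55 threshold on
#' it would remove all cells. The literal reading is available with
#' `novelty_method = "ratio"`.
#'
#' @param dataset An [abseq_dataset] with at least one RNA feature.
#' @param min_umi Minimum total RNA UMI per cell (default 50).
#' @param min_genes Minimum detected RNA genes per cell (default 35).
#' @param min_novelty Minimum novelty score (default 0.55).
#' @param novelty_method `"log_ratio"` (default, `log10(genes)/log10(UMI)`)
#'   or `"ratio"` (`log10(genes/UMI)`).
#' @return A list with `dataset` (the filtered [abseq_dataset]) and
#'   `report` (a `qc_report`: per-cell metrics with the attributed removal
#'   filter, per-filter removal counts, and surviving cell ids).
#' @examples
#' sim <- simulate_cohort(sim_config(n_rna = 50, n_protein = 5,
#'   n_cell_types = 3, cells_per_subject = c(80, 120), seed = 2))
#' qc <- qc_filter(sim$dataset)
#' qc$report
#' @export
qc_filter <- function(dataset, min_umi = 50, min_genes = 35, min_novelty = 0.55,
                      novelty_method = c("log_ratio", "ratio")) {
  novelty_method <- match.arg(novelty_method)
  rna_cols <- modality_cols(dataset, "rna")
  if (length(rna_cols) == 0) {
    rlang::abort("QC metrics require at least one RNA feature",
                 class = "abseqde_precondition_error")
  }
  rna <- dataset$counts[, rna_cols, drop = FALSE]
  total_umi <- Matrix::rowSums(rna)
  n_genes <- Matrix::rowSums(rna > 0)
  novelty <- if (novelty_method == "log_ratio") {
    suppressWarnings(log10(n_genes) / log10(total_umi))
  } else {
    suppressWarnings(log10(n_genes / total_umi))
  }

  removed_by <- rep(NA_character_, nrow(dataset$counts))
  mark <- function(cond, label) {
    hit <- is.na(removed_by) & cond
    removed_by[hit] <<- label
  }
  mark(dataset$cells$multiplet_flag, "multiplet")
  mark(total_umi < min_umi, "low_umi")
  mark(n_genes < min_genes, "low_genes")
  mark(is.na(novelty) | novelty < min_novelty, "low_novelty")

  metrics <- tibble::tibble(cell_id = dataset$cells$cell_id,
                            total_umi = as.numeric(total_umi),
                            n_genes = as.integer(n_genes),
                            novelty = as.numeric(novelty),
                            removed_by = removed_by)
  keep <- is.na(removed_by)
  removal_counts <- metrics |>
    dplyr::filter(!is.na(.data$removed_by)) |>
    dplyr::count(.data$removed_by, name = "n_removed")
  report <- structure(
    list(cell_metrics = metrics, removal_counts = removal_counts,
         survivors = metrics$cell_id[keep],
         n_input = nrow(metrics), n_removed = sum(!keep),
         thresholds = list(min_umi = min_umi, min_genes = min_genes,
                           min_novelty = min_novelty,
                           novelty_method = novelty_method)),
    class = "qc_report")
  list(dataset = subset_cells(dataset, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$n_input, " cells in, ", x$n_removed, " removed, ",
      length(x$survivors), " kept\n", sep = "")
  if (nrow(x$removal_counts) > 0) {
    for (i in seq_len(nrow(x$removal_counts))) {
      cat("  ", x$removal_counts$removed_by[i], ": ",
          x$removal_counts$n_removed[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a QC report to disk
#'
#' Emits the per-cell metrics as TSV and the removal summary as JSON.
#'
#' @param report A `qc_report` from [qc_filter()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$cell_metrics, file.path(path, "qc_cell_metrics.tsv"),
                   progress = FALSE)
  summary <- list(n_input = report$n_input, n_removed = report$n_removed,
                  n_kept = length(report$survivors),
                  removal_counts = stats::setNames(
                    as.list(report$removal_counts$n_removed),
                    report$removal_counts$removed_by),
                  thresholds = report$thresholds)
  jsonlite::write_json(summary, file.path(path, "qc_summary.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
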