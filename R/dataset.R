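#' Construct a multimodal single-cell expression dataset
#'
#' Bundles a sparse cell x feature count matrix with its cell and feature
#' annotations. Features carry a modality tag (`rna` or `protein`, i.e.
#' targeted mRNA panel vs antibody-derived surface tags); cells carry their
#' subject of origin, cell-type annotation, and a multiplet flag from
#' sample-multiplexing calls.
#'
#' @param counts Nonnegative integer matrix, cells in rows and features in
#'   columns (coerced to a sparse `dgCMatrix`). Row names are cell ids and
#'   column names feature ids; if absent they are taken from the metadata.
#' @param cells Data frame with columns `cell_id`, `subject_id`, `cell_type`
#'   and optionally `multiplet_flag` (logical, default `FALSE`), one row per
#'   matrix row, in matrix order.
#' @param features Data frame with columns `feature_id` and `modality`
#'   (`"rna"` or `"protein"`), one row per matrix column, in matrix order.
#' @return An `abseq_dataset` object (list with elements `counts`, `cells`,
#'   `features`).
#' @export
abseq_dataset <- function(counts, cells, features) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "dMatrix")
  cells <- tibble::as_tibble(cells)
  features <- tibble::as_tibble(features)
  if (!"multiplet_flag" %in% names(cells)) cells$multiplet_flag <- FALSE
  for (col in c("cell_id", "subject_id", "cell_type")) {
    if (!col %in% names(cells)) {
      rlang::abort(paste0("cell metadata lacks column '", col, "'"),
                   class = "abseqde_schema_error")
    }
  }
  for (col in c("feature_id", "modality")) {
    if (!col %in% names(features)) {
      rlang::abort(paste0("feature metadata lacks column '", col, "'"),
                   class = "abseqde_schema_error")
    }
  }
  if (nrow(counts) != nrow(cells) || ncol(counts) != nrow(features)) {
    rlang::abort("count matrix dimensions do not match cell/feature metadata",
                 class = "abseqde_validation_error")
  }
  if (length(counts@x) && min(counts@x) < 0) {
    rlang::abort("counts must be nonnegative", class = "abseqde_validation_error")
  }
  if (!all(features$modality %in% c("rna", "protein"))) {
    rlang::abort("feature modality must be 'rna' or 'protein'",
                 class = "abseqde_validation_error")
  }
  rownames(counts) <- cells$cell_id
  colnames(counts) <- features$feature_id
  structure(list(counts = counts, cells = cells, features = features),
            class = "abseq_dataset")
}

#' @export
print.abseq_dataset <- function(x, ...) {
  cat("<abseq_dataset> ", nrow(x$counts), " cells x ", ncol(x$counts), " features (",
      sum(x$features$modality == "rna"), " rna, ",
      sum(x$features$modality == "protein"), " protein), ",
      length(unique(x$cells$subject_id)), " subjects, ",
      length(unique(x$cells$cell_type)), " cell types\n", sep = "")
  invisible(x)
}

#' @export
dim.abseq_dataset <- function(x) dim(x$counts)

# Column indices of one modality's features.
modality_cols <- function(dataset, modality) {
  which(dataset$features$modality == modality)
}

# Subset a dataset to a set of cells (logical or integer index).
subset_cells <- function(dataset, idx) {
  abseq_dataset(dataset$counts[idx, , drop = FALSE],
                dataset$cells[idx, , drop = FALSE],
                dataset$features)
}

#' Write a dataset to Matrix Market + TSV sidecar files
#'
#' Writes `matrix.mtx` (1-based coordinate Matrix Market, cells x features),
#' `cells.tsv`, `features.tsv`, and a small `manifest.json` recording the
#' dimensions (and the generating seed, when the dataset carries one) into
#' `path`.
#'
#' @param dataset An `abseq_dataset`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(dataset$counts, file.path(path, "matrix.mtx"))
  readr::write_tsv(dataset$cells, file.path(path, "cells.tsv"), progress = FALSE)
  readr::write_tsv(dataset$features, file.path(path, "features.tsv"), progress = FALSE)
  manifest <- list(n_cells = nrow(dataset$counts), n_features = ncol(dataset$counts),
                   seed = attr(dataset, "seed"))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path Directory containing `matrix.mtx`, `cells.tsv`, `features.tsv`.
#' @return An `abseq_dataset`. Malformed Matrix Market input (bad header or
#'   coordinates outside the declared shape) raises a format error.
#' @export
read_dataset <- function(path) {
  mtx_path <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx_path)) {
    rlang::abort(paste0("no matrix.mtx under ", path), class = "abseqde_format_error")
  }
  counts <- tryCatch(
    Matrix::readMM(mtx_path),
    error = function(e) rlang::abort(paste0("malformed Matrix Market file: ",
                                            conditionMessage(e)),
                                     class = "abseqde_format_error"))
  check_mtx_coordinates(mtx_path, dim(counts))
  cells <- readr::read_tsv(file.path(path, "cells.tsv"),
                           col_types = readr::cols(.default = "c",
                                                   multiplet_flag = "l"),
                           progress = FALSE)
  features <- readr::read_tsv(file.path(path, "features.tsv"),
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)
  abseq_dataset(counts, cells, features)
}

# readMM relies on the sparse-matrix validity check to reject coordinates
# beyond the declared shape; verify explicitly for small files so the error
# is a format error regardless of Matrix version. Large files (our own
# writes) are covered by the tryCatch around readMM.
check_mtx_coordinates <- function(mtx_path, declared_dim) {
  if (file.size(mtx_path) > 5e6) return(invisible(TRUE))
  lines <- readLines(mtx_path)
  body <- lines[!startsWith(lines, "%")]
  if (length(body) < 1) {
    rlang::abort("malformed Matrix Market file: no size line",
                 class = "abseqde_format_error")
  }
  entries <- body[-1]
  entries <- entries[nzchar(trimws(entries))]
  if (length(entries) == 0) return(invisible(TRUE))
  coords <- utils::read.table(text = entries, colClasses = "numeric")
  if (any(coords[[1]] < 1 | coords[[1]] > declared_dim[1]) ||
      any(coords[[2]] < 1 | coords[[2]] > declared_dim[2])) {
    rlang::abort("Matrix Market coordinate outside declared shape",
                 class = "abseqde_format_error")
  }
  invisible(TRUE)
}
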