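#' Load and validate a clinical cohort table
#'
#' Reads a per-subject clinical table (TSV or CSV, with a header row) and
#' validates it against the cohort schema used throughout the package:
#' two binary outcomes (`cgvhd`, `relapse`), a processing-batch label, and
#' a set of clinical factors used for confounder-robustness analysis.
#'
#' Required columns: `subject_id`, `cgvhd`, `relapse`, `batch`. Recognised
#' optional columns: `donor_source`, `hla_match`, `ptcy`, `all_risk`,
#' `agvhd`, `conditioning`, `prophylaxis`, `sampling_day`. Outcome columns
#' must be strictly binary (accepted encodings: 0/1, yes/no, true/false,
#' pos/neg — case-insensitive); missing values are disallowed for outcomes
#' and batch, and recoded to the category `"missing"` for other factors.
#' Categorical levels are case-folded to lower case (HLA labels such as
#' `"10/10"` are kept verbatim).
#'
#' @param path Path to a TSV/CSV file. The delimiter is inferred from the
#'   file extension (`.csv` -> comma, otherwise tab).
#' @return A validated cohort tibble, one row per subject.
#' @seealso [cohort_fixture()] for the packaged 14-subject study table.
#' @examples
#' cohort <- load_cohort(cohort_fixture())
#' nrow(cohort) # 14
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("cohort file not found: ", path), class = "abseqde_schema_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  validate_cohort(raw)
}

#' Path to the packaged 14-subject cohort fixture
#'
#' Returns the path to `cohort_tables12.tsv`, a transcription of the study's
#' printed patient-characteristics and outcome tables for the 14 pediatric
#' ALL HSCT subjects: cGvHD and marrow-relapse status (attributed between
#' days 114 and 365 post-transplant), donor source, HLA matching, PTCy use,
#' ALL risk, acute GvHD, conditioning, GvHD prophylaxis, and marrow sampling
#' day (60 or 100).
#'
#' Two caveats are inherited from the printed tables. The per-subject
#' cartridge assignment is not printed (only that 14 samples ran on three
#' cartridges), so the `batch` column is a deterministic synthetic
#' assignment (subjects 1-5 -> C1, 6-10 -> C2, 11-14 -> C3). Subject UPN03's
#' ALL risk is printed only as a second-transplant CR3 entry and is coded
#' `high`.
#'
#' @return File path of the packaged fixture.
#' @export
cohort_fixture <- function() {
  system.file("extdata", "cohort_tables12.tsv", package = "abseqde", mustWork = TRUE)
}

required_cohort_cols <- c("subject_id", "cgvhd", "relapse", "batch")
binary_cohort_cols <- c("cgvhd", "relapse", "ptcy", "agvhd")

parse_binary <- function(x, col) {
  key <- tolower(trimws(as.character(x)))
  pos <- key %in% c("1", "yes", "true", "y", "pos", "positive")
  neg <- key %in% c("0", "no", "false", "n", "neg", "negative")
  bad <- !(pos | neg)
  if (any(bad)) {
    rlang::abort(
      paste0("column '", col, "' must be binary; offending value(s): ",
             paste(unique(key[bad]), collapse = ", ")),
      class = "abseqde_validation_error")
  }
  as.integer(pos)
}

#' Validate a cohort data frame
#'
#' Checks the cohort schema and invariants (unique subject ids, strictly
#' binary outcomes, batch label present for every subject) and normalizes
#' encodings. Called by [load_cohort()]; exported so that cohorts built in
#' code (e.g. by [simulate_cohort()]) can be re-validated.
#'
#' @param cohort A data frame with at least the required cohort columns.
#' @return A validated cohort tibble.
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(required_cohort_cols, names(cohort))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("missing required cohort column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "abseqde_schema_error")
  }
  cohort$subject_id <- as.character(cohort$subject_id)
  if (anyNA(cohort$subject_id) || any(cohort$subject_id == "")) {
    rlang::abort("subject_id must be non-missing", class = "abseqde_validation_error")
  }
  if (anyDuplicated(cohort$subject_id)) {
    rlang::abort("subject_id must be unique", class = "abseqde_validation_error")
  }
  for (col in c("cgvhd", "relapse")) {
    if (anyNA(cohort[[col]])) {
      rlang::abort(paste0("outcome '", col, "' has missing values"),
                   class = "abseqde_validation_error")
    }
    cohort[[col]] <- parse_binary(cohort[[col]], col)
  }
  if (anyNA(cohort$batch) || any(trimws(as.character(cohort$batch)) == "")) {
    rlang::abort("every subject must have a batch label",
                 class = "abseqde_validation_error")
  }
  cohort$batch <- as.character(cohort$batch)
  for (col in intersect(c("ptcy", "agvhd"), names(cohort))) {
    x <- cohort[[col]]
    x[is.na(x)] <- "missing"
    if (all(x != "missing")) cohort[[col]] <- parse_binary(x, col) else cohort[[col]] <- x
  }
  for (col in intersect(c("donor_source", "all_risk"), names(cohort))) {
    x <- tolower(trimws(as.character(cohort[[col]])))
    x[is.na(x) | x == ""] <- "missing"
    cohort[[col]] <- x
  }
  if ("hla_match" %in% names(cohort)) {
    x <- trimws(as.character(cohort$hla_match))
    x[is.na(x) | x == ""] <- "missing"
    cohort$hla_match <- x
  }
  if ("sampling_day" %in% names(cohort)) {
    cohort$sampling_day <- as.integer(cohort$sampling_day)
  }
  cohort
}

#' Define an outcome contrast with role-swapped covariates
#'
#' Builds the group contrast for one binary outcome, following the study's
#' convention that each outcome is tested with the processing batch and the
#' *other* outcome as covariates (cGvHD adjusted for relapse, and vice
#' versa when the roles are swapped).
#'
#' @param cohort A validated cohort tibble.
#' @param variable Outcome of interest: `"cgvhd"` or `"relapse"`.
#' @return A `contrast_spec` object: the variable of interest, covariate
#'   names (`batch` plus the other outcome), and the positive/negative
#'   subject-id groups.
#' @examples
#' cohort <- load_cohort(cohort_fixture())
#' build_contrast(cohort, "cgvhd") # 6 vs 8 subjects
#' @export
build_contrast <- function(cohort, variable) {
  variable <- match.arg(variable, c("cgvhd", "relapse"))
  other <- setdiff(c("cgvhd", "relapse"), variable)
  pos <- cohort$subject_id[cohort[[variable]] == 1L]
  neg <- cohort$subject_id[cohort[[variable]] == 0L]
  if (length(pos) < 2 || length(neg) < 2) {
    rlang::abort(
      paste0("degenerate contrast for '", variable, "': groups of size ",
             length(pos), " and ", length(neg), " (each must have >= 2 subjects)"),
      class = "abseqde_contrast_error")
  }
  structure(
    list(variable = variable, covariates = c("batch", other),
         positive_group = pos, negative_group = neg),
    class = "contrast_spec")
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat("<contrast_spec> ", x$variable, ": ", length(x$positive_group), " positive vs ",
      length(x$negative_group), " negative subjects\n", sep = "")
  cat("  covariates: ", paste(x$covariates, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Cross-tabulate the two outcomes
#'
#' @param cohort A validated cohort tibble (may be empty).
#' @return A 2x2 integer matrix of subject counts, rows `cgvhd` (pos, neg)
#'   by columns `relapse` (pos, neg).
#' @examples
#' crosstab_outcomes(load_cohort(cohort_fixture()))
#' @export
crosstab_outcomes <- function(cohort) {
  m <- matrix(0L, 2, 2, dimnames = list(cgvhd = c("pos", "neg"),
                                        relapse = c("pos", "neg")))
  if (nrow(cohort) > 0) {
    tab <- table(factor(cohort$cgvhd, levels = c(1, 0)),
                 factor(cohort$relapse, levels = c(1, 0)))
    m[] <- as.integer(tab)
  }
  m
}

# Binarize a clinical factor as majority level (0) vs rest (1); ties broken
# by the alphabetically first level. With n = 14 subjects a multi-level
# factor is unestimable, so all factors enter eligibility and robustness
# models in this binarized form.
binarize_factor <- function(x) {
  x <- as.character(x)
  counts <- sort(table(x), decreasing = TRUE)
  majority <- names(counts)[1]
  as.integer(x != majority)
}

#' Select clinical factors eligible for confounder-robustness analysis
#'
#' A factor is eligible when it shows adequate variation across subjects:
#' after binarizing multi-level factors as majority level vs rest, the
#' smaller category must contain at least `min_minority` subjects. The
#' default of 4 encodes the "more than 3 subjects different from the
#' others" rule.
#'
#' @param cohort A validated cohort tibble.
#' @param candidate_fields Character vector of cohort column names to assess.
#' @param min_minority Minimum size of the minority category (default 4).
#' @return Character vector of eligible field names (subset of
#'   `candidate_fields`, in the given order).
#' @examples
#' cohort <- load_cohort(cohort_fixture())
#' eligible_confounders(cohort,
#'   c("donor_source", "hla_match", "ptcy", "all_risk", "agvhd"))
#' @export
eligible_confounders <- function(cohort, candidate_fields, min_minority = 4) {
  missing_fields <- setdiff(candidate_fields, names(cohort))
  if (length(missing_fields) > 0) {
    rlang::abort(paste0("candidate field(s) not in cohort: ",
                        paste(missing_fields, collapse = ", ")),
                 class = "abseqde_schema_error")
  }
  keep <- vapply(candidate_fields, function(f) {
    b <- binarize_factor(cohort[[f]])
    sum(b == 1L) >= min_minority
  }, logical(1))
  candidate_fields[keep]
}
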