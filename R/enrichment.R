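#' Read genesets in GMT format, restricted to a measured panel
#'
#' Parses a tab-delimited GMT file (per line: set name, description, then
#' member genes) and intersects every set with the measured panel, since
#' enrichment against a targeted panel must use the panel — not the genome
#' — as background. Duplicate members are dropped; sets empty after
#' intersection are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @param panel Character vector of measured feature ids.
#' @return A tibble with one row per geneset: `geneset`, `description`,
#'   `members` (list column of panel feature ids), `size`.
#' @export
read_gmt <- function(path, panel) {
  if (!file.exists(path)) {
    rlang::abort(paste0("GMT file not found: ", path),
                 class = "abseqde_format_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(geneset = character(), description = character(),
                          members = list(), size = integer()))
  }
  parsed <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      rlang::abort(paste0("malformed GMT line ", i,
                          ": expected name, description, members"),
                   class = "abseqde_format_error")
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    tibble::tibble(geneset = fields[1], description = fields[2],
                   members = list(intersect(members, panel)))
  })
  sets <- dplyr::bind_rows(parsed)
  sets$size <- lengths(sets$members)
  if (any(sets$size == 0)) {
    rlang::warn(paste0("dropping geneset(s) with no panel members: ",
                       paste(sets$geneset[sets$size == 0], collapse = ", ")))
    sets <- sets[sets$size > 0, ]
  }
  sets
}

#' One-sided Fisher enrichment of a DEG set in one geneset
#'
#' Tests over-representation of a differential feature set within a
#' geneset against the measured-panel background, using the one-sided
#' ("greater") Fisher exact test, i.e. the hypergeometric upper tail of
#' the overlap given the margins. No multiplicity adjustment is applied:
#' with a targeted panel of a few hundred genes, enrichment is highlighted
#' at a nominal p below 0.05.
#'
#' @param deg_set Character vector of differential feature ids (must lie
#'   within `panel`).
#' @param geneset Character vector of geneset member ids (within `panel`).
#' @param panel Character vector of all measured feature ids (background).
#' @return A one-row tibble: the 2x2 table cells (`n_overlap`,
#'   `n_set_only`, `n_deg_only`, `n_neither`, summing to the panel size),
#'   `odds_ratio`, one-sided `p`, and `highlighted` (`p < 0.05`).
#' @examples
#' fisher_enrichment(paste0("g", 1:5), paste0("g", 1:5), paste0("g", 1:20))
#' @export
fisher_enrichment <- function(deg_set, geneset, panel) {
  deg_set <- unique(deg_set); geneset <- unique(geneset); panel <- unique(panel)
  if (length(setdiff(deg_set, panel)) > 0 || length(setdiff(geneset, panel)) > 0) {
    rlang::abort("deg_set and geneset must be subsets of the panel",
                 class = "abseqde_validation_error")
  }
  a <- length(intersect(deg_set, geneset))
  b <- length(setdiff(geneset, deg_set))
  cc <- length(setdiff(deg_set, geneset))
  d <- length(panel) - a - b - cc
  ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, 2),
                           alternative = "greater")
  tibble::tibble(n_overlap = a, n_set_only = b, n_deg_only = cc,
                 n_neither = d, odds_ratio = unname(ft$estimate),
                 p = ft$p.value, highlighted = ft$p.value < 0.05)
}

#' Geneset enrichment of consensus calls, per cell type and contrast
#'
#' Applies [fisher_enrichment()] to every (cell type, contrast) consensus
#' DEG set of one modality against every geneset, with the measured panel
#' as background.
#'
#' @param consensus Output of [call_consensus()].
#' @param genesets Output of [read_gmt()].
#' @param modality Modality whose calls to test (default `"rna"`; geneset
#'   enrichment is typically meaningless for a 41-protein panel).
#' @return A tibble: `geneset`, `cell_type`, `contrast`, `n_deg`, the 2x2
#'   cells, `odds_ratio`, `p`, `highlighted`.
#' @export
test_enrichment <- function(consensus, genesets, modality = "rna") {
  slice <- consensus[consensus$modality == modality, ]
  panel <- unique(slice$feature_id)
  out <- list()
  for (ctr in unique(slice$contrast)) {
    for (ct in unique(slice$cell_type)) {
      sub <- slice[slice$contrast == ctr & slice$cell_type == ct, ]
      deg <- sub$feature_id[sub$called]
      for (i in seq_len(nrow(genesets))) {
        res <- fisher_enrichment(deg, genesets$members[[i]], panel)
        res$geneset <- genesets$geneset[i]
        res$cell_type <- ct
        res$contrast <- ctr
        res$n_deg <- length(deg)
        out[[paste(ctr, ct, genesets$geneset[i])]] <- res
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(geneset = character(), cell_type = character(),
                          contrast = character(), n_deg = integer(),
                          n_overlap = integer(), n_set_only = integer(),
                          n_deg_only = integer(), n_neither = integer(),
                          odds_ratio = numeric(), p = numeric(),
                          highlighted = logical()))
  }
  dplyr::bind_rows(out) |>
    dplyr::select("geneset", "cell_type", "contrast", "n_deg", "n_overlap",
                  "n_set_only", "n_deg_only", "n_neither", "odds_ratio",
                  "p", "highlighted")
}
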