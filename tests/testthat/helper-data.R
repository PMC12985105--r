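# Shared fixtures, built in code and cached for the duration of the run.

`%||%` <- rlang::`%||%`

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# A small multimodal simulation with sparse strong effects, QC-filtered with
# thresholds scaled to its 60-gene panel, plus both DE tracks and consensus.
smoke_analysis <- function() {
  cached("smoke", {
    cfg <- sim_config(n_rna = 40, n_protein = 8, n_cell_types = 2,
                      cells_per_subject = c(140, 180), de_fraction = 0.1,
                      lfc_mean = 1.5, lfc_sd = 0.25, seed = 11)
    sim <- simulate_cohort(cfg)
    qc <- qc_filter(sim$dataset, min_umi = 15, min_genes = 8)
    mixed <- de_mixed(qc$dataset, sim$cohort, modality = "rna")
    pb <- aggregate_pseudobulk(qc$dataset)
    pbres <- test_pseudobulk(pb, sim$cohort, modality = "rna")
    list(sim = sim, dataset = qc$dataset, mixed = mixed, pb = pb,
         pbres = pbres, consensus = call_consensus(mixed, pbres))
  })
}

# Recovery-scale simulation (study-like effects, LFC 1.5) with both tracks
# and truth labels joined onto the consensus calls.
recovery_analysis <- function(seed) {
  cached(paste0("recovery", seed), {
    cfg <- sim_config(n_rna = 120, n_protein = 6, n_cell_types = 2,
                      cells_per_subject = c(160, 220), de_fraction = 0.1,
                      lfc_mean = 1.5, lfc_sd = 0.25, seed = seed)
    sim <- simulate_cohort(cfg)
    qc <- qc_filter(sim$dataset, min_umi = 30, min_genes = 15)
    mixed <- de_mixed(qc$dataset, sim$cohort, modality = "rna")
    pbres <- test_pseudobulk(aggregate_pseudobulk(qc$dataset), sim$cohort,
                             modality = "rna")
    cons <- call_consensus(mixed, pbres)
    truth <- dplyr::mutate(dplyr::filter(sim$truth$de, modality == "rna"),
                           true_de = TRUE)
    joined <- dplyr::left_join(cons, truth,
                               by = c("cell_type", "feature_id", "contrast"))
    joined$true_de[is.na(joined$true_de)] <- FALSE
    list(sim = sim, mixed = mixed, pbres = pbres, consensus = cons,
         joined = joined)
  })
}

# Hand-built dataset from an explicit dense count matrix (cells x features).
toy_dataset <- function(counts, cell_types = NULL, subjects = NULL,
                        multiplet = NULL, n_protein = 0) {
  n <- nrow(counts); G <- ncol(counts)
  cells <- tibble::tibble(
    cell_id = sprintf("c%03d", seq_len(n)),
    subject_id = subjects %||% rep("S01", n),
    cell_type = cell_types %||% rep("CT01", n),
    multiplet_flag = multiplet %||% rep(FALSE, n))
  features <- tibble::tibble(
    feature_id = sprintf("F%03d", seq_len(G)),
    modality = rep(c("rna", "protein"), c(G - n_protein, n_protein)))
  abseq_dataset(counts, cells, features)
}

# A cell row with `genes` expressed features (count 1) padded on the first
# feature so the total UMI equals `umi`.
qc_cell <- function(umi, genes, n_features = 60) {
  stopifnot(umi >= genes, genes <= n_features)
  row <- rep(0, n_features)
  if (genes > 0) row[seq_len(genes)] <- 1
  row[1] <- row[1] + (umi - genes)
  row
}
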