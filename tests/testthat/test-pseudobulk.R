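test_that("aggregation sums counts exactly and conserves totals", {
  counts <- rbind(c(3, 0, 1), c(4, 2, 0),   # S01/CT01
                  c(1, 1, 1),               # S01/CT02
                  c(0, 5, 2), c(2, 2, 2), c(1, 0, 0))  # S02/CT01
  ds <- toy_dataset(counts,
                    subjects = c("S01", "S01", "S01", "S02", "S02", "S02"),
                    cell_types = c("CT01", "CT01", "CT02", "CT01", "CT01", "CT01"))
  pb <- aggregate_pseudobulk(ds, min_cells = 1)
  expect_equal(pb$raw["S01:CT01", ], c(F001 = 7, F002 = 2, F003 = 1))
  expect_equal(pb$raw["S02:CT01", ], c(F001 = 3, F002 = 7, F003 = 4))
  expect_equal(sum(pb$raw), sum(counts))
})

test_that("units below min_cells are excluded and reported", {
  counts <- matrix(1, 5, 2)
  ds <- toy_dataset(counts, subjects = c("S01", "S01", "S01", "S02", "S02"),
                    cell_types = "CT01")
  pb <- aggregate_pseudobulk(ds, min_cells = 3)
  expect_equal(nrow(pb$raw), 1)
  expect_equal(pb$excluded$subject_id, "S02")
  expect_equal(pb$excluded$n_cells, 2L)
  expect_true("CT01" %in% pb$cell_types)
})

test_that("aggregation equals a brute-force loop over cells", {
  sim <- simulate_cohort(sim_config(n_rna = 15, n_protein = 3, n_cell_types = 3,
                                    cells_per_subject = c(30, 50), seed = 51))
  pb <- aggregate_pseudobulk(sim$dataset, min_cells = 1)
  dense <- as.matrix(sim$dataset$counts)
  cells <- sim$dataset$cells
  for (i in sample(nrow(pb$raw), 10)) {
    rows <- cells$subject_id == pb$units$subject_id[i] &
      cells$cell_type == pb$units$cell_type[i]
    expect_equal(unname(pb$raw[i, ]), unname(colSums(dense[rows, , drop = FALSE])))
  }
})

test_that("degenerate responses give exact p-values", {
  # 8 subjects, one cell type, two features: one constant, one equal to x
  cohort <- validate_cohort(tibble::tibble(
    subject_id = sprintf("S%02d", 1:8), cgvhd = rep(c(1, 0), each = 4),
    relapse = rep(c(1, 0), 4), batch = rep(c("B1", "B1", "B2", "B2"), 2)))
  units <- tibble::tibble(subject_id = cohort$subject_id, cell_type = "CT01",
                          n_cells = 5L)
  x <- cohort$cgvhd
  pb <- structure(list(
    raw = NULL,
    normalized = cbind(F001 = rep(1, 8), F002 = as.numeric(x)),
    units = units,
    features = tibble::tibble(feature_id = c("F001", "F002"), modality = "rna"),
    excluded = units[0, ], cell_types = "CT01", min_cells = 1),
    class = "pseudobulk_matrix")
  res <- test_pseudobulk(pb, cohort, variables = "cgvhd")
  const_row <- res[res$feature_id == "F001", ]
  expect_equal(const_row$effect, 0)
  expect_equal(const_row$p, 1)
  sep_row <- res[res$feature_id == "F002", ]
  expect_gt(sep_row$effect, 0)
  expect_equal(sep_row$p, 0)
})

test_that("pseudobulk OLS agrees with stats::lm per feature", {
  sh <- smoke_analysis()
  pbres <- sh$pbres
  pb <- sh$pb
  cohort <- sh$sim$cohort
  ct <- pb$units$cell_type[1]
  rows <- pb$units$cell_type == ct
  srow <- match(pb$units$subject_id[rows], cohort$subject_id)
  df <- data.frame(x = cohort$cgvhd[srow], batch = factor(cohort$batch[srow]),
                   other = cohort$relapse[srow])
  for (g in c("RNA001", "RNA010", "RNA025")) {
    df$y <- pb$normalized[rows, g]
    sm <- summary(lm(y ~ x + batch + other, data = df))$coefficients
    ours <- pbres[pbres$feature_id == g & pbres$cell_type == ct &
                    pbres$contrast == "cgvhd", ]
    expect_equal(ours$effect, sm["x", "Estimate"] * log(2), tolerance = 1e-10)
    expect_equal(ours$p, sm["x", "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("simulated log-fold changes of 1 are recovered by the pseudobulk track", {
  effs <- c()
  for (s in 1:50) {
    cfg <- sim_config(n_rna = 100, n_protein = 5, n_cell_types = 1,
                      cells_per_subject = c(200, 200), de_fraction = 0.02,
                      lfc_mean = 1, lfc_sd = 0, sigma_subject = 0.3,
                      qc_fail_fraction = 0, multiplet_fraction = 0,
                      seed = 100 + s)
    sim <- simulate_cohort(cfg)
    pbres <- test_pseudobulk(aggregate_pseudobulk(sim$dataset), sim$cohort,
                             modality = "rna")
    tr <- dplyr::inner_join(pbres,
                            dplyr::filter(sim$truth$de, modality == "rna"),
                            by = c("cell_type", "feature_id", "contrast"))
    effs <- c(effs, tr$effect * sign(tr$lfc))
  }
  expect_equal(mean(effs), 1, tolerance = 0.2)
})

test_that("both tracks agree in direction on strong effects", {
  sh <- smoke_analysis()
  truth <- dplyr::filter(sh$sim$truth$de, modality == "rna", abs(lfc) >= 1.2)
  j <- dplyr::inner_join(
    dplyr::inner_join(truth,
                      dplyr::select(sh$mixed, "cell_type", "feature_id",
                                    "contrast", em = "effect"),
                      by = c("cell_type", "feature_id", "contrast")),
    dplyr::select(sh$pbres, "cell_type", "feature_id", "contrast",
                  ep = "effect"),
    by = c("cell_type", "feature_id", "contrast"))
  j <- j[stats::complete.cases(j$em, j$ep), ]
  expect_gt(nrow(j), 10)
  expect_gt(mean(sign(j$em) == sign(j$ep)), 0.95)
})
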