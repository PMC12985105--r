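small_cfg <- function(...) {
  args <- list(n_rna = 20, n_protein = 4, n_cell_types = 3,
               cells_per_subject = c(50, 70), seed = 21)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("simulation is deterministic given the config seed", {
  a <- simulate_cohort(small_cfg())
  b <- simulate_cohort(small_cfg())
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$dataset$counts, b$dataset$counts)
  expect_identical(a$dataset$cells, b$dataset$cells)
  expect_identical(a$truth$de, b$truth$de)
  # and a different seed changes the data
  c <- simulate_cohort(small_cfg(seed = 22))
  expect_false(identical(a$dataset$counts, c$dataset$counts))
})

test_that("simulated cohort matches the configured outcome crosstab", {
  sim <- simulate_cohort(small_cfg())
  tab <- crosstab_outcomes(sim$cohort)
  expect_equal(as.integer(t(tab)), c(1L, 5L, 4L, 4L))
  expect_equal(length(unique(sim$cohort$batch)), 3)
})

test_that("counts are nonnegative integers and truth features exist", {
  sim <- simulate_cohort(small_cfg(de_fraction = 0.2))
  x <- sim$dataset$counts@x
  expect_true(all(x >= 0))
  expect_true(all(x == round(x)))
  expect_true(all(sim$truth$de$feature_id %in% sim$dataset$features$feature_id))
  expect_true(all(sim$truth$de$cell_type %in% sim$dataset$cells$cell_type))
})

test_that("null genes follow the var = mu + phi mu^2 dispersion model", {
  # single subject, no size-factor/batch/subject noise: pure NB sampling
  cfg <- sim_config(n_subjects = 2, outcome_crosstab = c(1, 0, 1, 0),
                    n_batches = 1, n_cell_types = 1, n_rna = 50, n_protein = 0,
                    cells_per_subject = c(6000, 6000), de_fraction = 0,
                    sigma_subject = 0, batch_effect_sd = 0,
                    celltype_baseline_sd = 0, size_factor_sd = 0,
                    qc_fail_fraction = 0, multiplet_fraction = 0,
                    phi = 0.4, seed = 31)
  sim <- simulate_cohort(cfg)
  y <- as.matrix(sim$dataset$counts)
  mu <- colMeans(y)
  v <- apply(y, 2, stats::var)
  keep <- mu > 0.5
  phi_hat <- sum(v[keep] - mu[keep]) / sum(mu[keep]^2)
  expect_gt(phi_hat, 0.3)
  expect_lt(phi_hat, 0.5)
})

test_that("per-subject cell-type proportions sum to one", {
  sim <- simulate_cohort(small_cfg())
  props <- subject_proportions(sim$dataset$cells)
  totals <- tapply(props$proportion, props$subject_id, sum)
  expect_equal(as.numeric(totals), rep(1, 14), tolerance = 1e-12)
})

test_that("generator-flagged QC failures fall below the default thresholds", {
  cfg <- sim_config(n_rna = 397, n_protein = 41, n_cell_types = 4,
                    cells_per_subject = c(40, 60), qc_fail_fraction = 0.08,
                    seed = 33)
  sim <- simulate_cohort(cfg)
  qc <- qc_filter(sim$dataset)
  flags <- sim$truth$cell_flags
  expect_false(any(flags$cell_id[flags$qc_fail] %in% qc$report$survivors))
  expect_false(any(flags$cell_id[flags$multiplet_flag] %in% qc$report$survivors))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(outcome_crosstab = c(1, 5, 4, 3)),
               class = "abseqde_config_error")
  expect_error(sim_config(de_fraction = 1.5), class = "abseqde_config_error")
  expect_error(sim_config(sigma_subject = -1), class = "abseqde_config_error")
  expect_error(sim_config(cells_per_subject = c(100, 50)),
               class = "abseqde_config_error")
  expect_error(sim_config(n_cell_types = 2, proportion_affected = 3),
               class = "abseqde_config_error")
})

test_that("datasets round-trip through Matrix Market + TSV files", {
  sim <- simulate_cohort(small_cfg())
  dir <- withr::local_tempdir()
  write_dataset(sim$dataset, dir)
  back <- read_dataset(dir)
  expect_equal(as.matrix(back$counts), as.matrix(sim$dataset$counts))
  expect_equal(back$cells, sim$dataset$cells)
  expect_equal(back$features, sim$dataset$features)
})

test_that("an empty dataset (0 cells) round-trips", {
  empty <- abseq_dataset(
    matrix(0, 0, 2),
    tibble::tibble(cell_id = character(), subject_id = character(),
                   cell_type = character(), multiplet_flag = logical()),
    tibble::tibble(feature_id = c("F1", "F2"), modality = "rna"))
  dir <- withr::local_tempdir()
  write_dataset(empty, dir)
  back <- read_dataset(dir)
  expect_equal(dim(back$counts), c(0L, 2L))
})

test_that("malformed Matrix Market input raises a format error", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(small_cfg())
  write_dataset(sim$dataset, dir)
  # coordinate beyond the declared shape
  mtx <- file.path(dir, "matrix.mtx")
  lines <- readLines(mtx)
  body_at <- which(!startsWith(lines, "%"))[1]
  dims <- scan(text = lines[body_at], quiet = TRUE)
  lines[body_at + 1] <- paste(dims[1] + 5, 1, 3)
  writeLines(lines, mtx)
  expect_error(read_dataset(dir), class = "abseqde_format_error")
  # garbage header
  writeLines(c("%%MatrixMarket banana", "1 1 1", "1 1 1"), mtx)
  expect_error(read_dataset(dir), class = "abseqde_format_error")
  expect_error(read_dataset(withr::local_tempdir()),
               class = "abseqde_format_error")
})
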