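test_that("the packaged cohort fixture reproduces the printed study counts", {
  cohort <- load_cohort(cohort_fixture())
  expect_equal(nrow(cohort), 14)

  cg <- build_contrast(cohort, "cgvhd")
  expect_equal(length(cg$positive_group), 6)
  expect_equal(length(cg$negative_group), 8)
  expect_setequal(cg$covariates, c("batch", "relapse"))

  rl <- build_contrast(cohort, "relapse")
  expect_equal(length(rl$positive_group), 5)
  expect_equal(length(rl$negative_group), 9)
  expect_setequal(rl$covariates, c("batch", "cgvhd"))

  tab <- crosstab_outcomes(cohort)
  expect_equal(unname(tab), matrix(c(1L, 4L, 5L, 4L), 2, 2))
  expect_equal(sum(tab), 14)

  expect_equal(sum(grepl("Tacro/MMF", cohort$prophylaxis)), 11)
  expect_equal(sum(!grepl("TBI", cohort$conditioning)), 1)
  expect_equal(sum(cohort$hla_match == "5/10"), 7)
})

test_that("crosstab margins agree with contrast group sizes", {
  cohort <- load_cohort(cohort_fixture())
  tab <- crosstab_outcomes(cohort)
  cg <- build_contrast(cohort, "cgvhd")
  rl <- build_contrast(cohort, "relapse")
  expect_equal(rowSums(tab), c(pos = length(cg$positive_group),
                               neg = length(cg$negative_group)))
  expect_equal(colSums(tab), c(pos = length(rl$positive_group),
                               neg = length(rl$negative_group)))
})

test_that("cohort validation rejects malformed tables", {
  cohort <- load_cohort(cohort_fixture())

  dup <- cohort
  dup$subject_id[2] <- dup$subject_id[1]
  expect_error(validate_cohort(dup), class = "abseqde_validation_error")

  bad <- cohort
  bad$cgvhd <- as.character(bad$cgvhd)
  bad$cgvhd[3] <- "maybe"
  expect_error(validate_cohort(bad), class = "abseqde_validation_error")

  nobatch <- cohort
  nobatch$batch[1] <- NA
  expect_error(validate_cohort(nobatch), class = "abseqde_validation_error")

  expect_error(validate_cohort(cohort[, setdiff(names(cohort), "relapse")]),
               class = "abseqde_schema_error")
  expect_error(load_cohort(tempfile("nope")), class = "abseqde_schema_error")
})

test_that("binary encodings are normalized case-insensitively", {
  df <- tibble::tibble(subject_id = c("a", "b", "c", "d"),
                       cgvhd = c("Yes", "no", "TRUE", "0"),
                       relapse = c("pos", "NEG", "1", "false"),
                       batch = "B1")
  cohort <- validate_cohort(df)
  expect_equal(cohort$cgvhd, c(1L, 0L, 1L, 0L))
  expect_equal(cohort$relapse, c(1L, 0L, 1L, 0L))
})

test_that("degenerate contrasts are rejected", {
  toy <- tibble::tibble(subject_id = paste0("s", 1:4),
                        cgvhd = c(1, 0, 0, 0), relapse = c(0, 1, 1, 0),
                        batch = "B1")
  expect_error(build_contrast(validate_cohort(toy), "cgvhd"),
               class = "abseqde_contrast_error")
})

test_that("crosstab handles empty and single-cell-population cohorts", {
  empty <- validate_cohort(tibble::tibble(subject_id = character(),
                                          cgvhd = integer(),
                                          relapse = integer(),
                                          batch = character()))
  expect_equal(sum(crosstab_outcomes(empty)), 0)

  allpos <- validate_cohort(tibble::tibble(subject_id = paste0("s", 1:3),
                                           cgvhd = 1, relapse = 1, batch = "B1"))
  tab <- crosstab_outcomes(allpos)
  expect_equal(tab["pos", "pos"], 3L)
  expect_equal(sum(tab), 3)
})

test_that("confounder eligibility applies the minority-size rule", {
  cohort <- load_cohort(cohort_fixture())
  elig <- eligible_confounders(
    cohort, c("donor_source", "hla_match", "ptcy", "all_risk", "agvhd"))
  # HLA binarizes majority (seven 5/10) vs rest (seven) -> minority 7
  expect_true("hla_match" %in% elig)
  expect_true("ptcy" %in% elig)       # 6 vs 8
  expect_true("all_risk" %in% elig)   # 5 standard-risk
  # donor source and aGvHD have printed minorities of 3 -> below threshold
  expect_false("donor_source" %in% elig)
  expect_false("agvhd" %in% elig)

  # constant field is never eligible; threshold boundary is sharp
  cohort$constant <- "x"
  expect_equal(eligible_confounders(cohort, "constant"), character(0))
  toy <- validate_cohort(tibble::tibble(
    subject_id = paste0("s", 1:10), cgvhd = rep(c(1, 0), 5),
    relapse = rep(c(0, 1), 5), batch = "B1",
    f3 = rep(c("a", "b"), c(7, 3)), f4 = rep(c("a", "b"), c(6, 4))))
  expect_equal(eligible_confounders(toy, c("f3", "f4")), "f4")
  expect_equal(eligible_confounders(toy, c("f3", "f4"), min_minority = 3),
               c("f3", "f4"))
  expect_error(eligible_confounders(toy, "missing_field"),
               class = "abseqde_schema_error")
})
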