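write_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("GMT parsing restricts to the panel and deduplicates", {
  panel <- paste0("g", 1:20)
  path <- write_gmt(c(
    paste(c("setA", "descA", paste0("g", 1:4), "g4", paste0("x", 1:6)),
          collapse = "\t"),
    paste(c("setB", "descB", "g5", "g6"), collapse = "\t")))
  sets <- read_gmt(path, panel)
  expect_equal(sets$size, c(4L, 2L))
  expect_equal(sort(sets$members[[1]]), paste0("g", 1:4))
})

test_that("GMT edge cases: empty files, off-panel sets, malformed lines", {
  panel <- paste0("g", 1:5)
  empty <- write_gmt(character(0))
  expect_equal(nrow(read_gmt(empty, panel)), 0)

  offpanel <- write_gmt(paste(c("setX", "d", "z1", "z2"), collapse = "\t"))
  expect_warning(sets <- read_gmt(offpanel, panel), "no panel members")
  expect_equal(nrow(sets), 0)

  malformed <- write_gmt(c(paste(c("ok", "d", "g1"), collapse = "\t"),
                           "broken_line_without_members"))
  expect_error(read_gmt(malformed, panel), class = "abseqde_format_error",
               regexp = "line 2")
})

test_that("Fisher enrichment matches closed forms and the tail-sum oracle", {
  panel <- paste0("g", 1:20)
  # the whole panel differential: no enrichment is possible
  expect_equal(fisher_enrichment(panel, paste0("g", 1:5), panel)$p, 1)
  # perfect overlap of 5 DEGs with a 5-gene set: p = 1 / C(20, 5)
  res <- fisher_enrichment(paste0("g", 1:5), paste0("g", 1:5), panel)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$n_overlap, 5L)
  expect_equal(res$n_overlap + res$n_set_only + res$n_deg_only + res$n_neither,
               20L)

  # random tables against the brute-force hypergeometric upper tail
  set.seed(71)
  for (rep in 1:25) {
    N <- sample(15:60, 1)
    panel <- paste0("f", seq_len(N))
    set <- sample(panel, sample(2:(N - 2), 1))
    deg <- sample(panel, sample(2:(N - 2), 1))
    a <- length(intersect(deg, set))
    tail_sum <- sum(dhyper(a:min(length(set), length(deg)),
                           length(set), N - length(set), length(deg)))
    expect_equal(fisher_enrichment(deg, set, panel)$p, tail_sum,
                 tolerance = 1e-12)
  }
})

test_that("enrichment p is invariant to relabeling and monotone in overlap", {
  panel <- paste0("g", 1:30)
  deg <- paste0("g", 1:6)
  set <- paste0("g", c(1:3, 10:12))
  p1 <- fisher_enrichment(deg, set, panel)$p
  # relabel all features by permutation
  perm <- setNames(sample(panel), panel)
  p2 <- fisher_enrichment(unname(perm[deg]), unname(perm[set]), panel)$p
  expect_equal(p1, p2, tolerance = 1e-12)

  # adding one overlap member (margins held fixed) cannot increase p
  deg_more <- c(paste0("g", 1:4), "g20", "g21")  # overlap 4, same sizes
  expect_lte(fisher_enrichment(deg_more, set, panel)$p, p1)
})

test_that("preconditions on deg/geneset membership are enforced", {
  expect_error(fisher_enrichment("z9", paste0("g", 1:3), paste0("g", 1:5)),
               class = "abseqde_validation_error")
})

test_that("consensus-driven enrichment runs per cell type and contrast", {
  cons <- smoke_analysis()$consensus
  panel <- unique(cons$feature_id)
  path <- write_gmt(c(
    paste(c("panelish", "d", panel[1:10]), collapse = "\t"),
    paste(c("other", "d", panel[11:15]), collapse = "\t")))
  sets <- read_gmt(path, panel)
  enr <- test_enrichment(cons, sets)
  expect_equal(nrow(enr), 2 * 2 * 2)  # 2 sets x 2 cell types x 2 contrasts
  expect_true(all(enr$p >= 0 & enr$p <= 1))
  expect_equal(unique(enr$n_overlap + enr$n_set_only + enr$n_deg_only +
                        enr$n_neither), length(panel))
  expect_equal(enr$highlighted, enr$p < 0.05)
})
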