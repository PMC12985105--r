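test_that("intercept-only fit with sigma^2 fixed at 0 recovers log(mean)", {
  y <- rep(5, 80)
  X <- matrix(1, 80, 1, dimnames = list(NULL, "intercept"))
  fit <- fit_nbmm(y, X, subject = rep(c("a", "b"), 40), fix_sigma2 = 0)
  expect_equal(fit$coefficients$estimate, log(5), tolerance = 1e-5)
})

test_that("on sigma^2 = 0 data the fit matches an independent NB GLM", {
  set.seed(101)
  n <- 1400
  subj <- rep(sprintf("S%02d", 1:14), each = 100)
  xs <- rep(c(rep(1, 6), rep(0, 8)), each = 100)
  b2 <- as.numeric(subj %in% sprintf("S%02d", 5:9))
  off <- log(runif(n, 50, 150))
  y <- rnbinom(n, mu = exp(-2.5 + 0.8 * xs - 0.3 * b2 + off), size = 2)
  X <- cbind(intercept = 1, x = xs, b2 = b2)

  fit <- fit_nbmm(y, X, offset = off, subject = subj)
  oracle <- MASS::glm.nb(y ~ xs + b2 + offset(off))
  expect_equal(fit$coefficients$estimate, unname(coef(oracle)),
               tolerance = 1e-3)
  expect_equal(fit$phi, 1 / oracle$theta, tolerance = 0.01)
  expect_true(fit$boundary)   # variance component collapses to 0
})

test_that("quadrature is stable: doubling the nodes moves beta by < 1e-4", {
  set.seed(102)
  subj <- rep(sprintf("S%02d", 1:14), each = 120)
  xs <- rep(c(rep(1, 6), rep(0, 8)), each = 120)
  u <- rep(rnorm(14, 0, 0.5), each = 120)
  y <- rnbinom(length(subj), mu = exp(0.2 + 0.7 * xs + u), size = 2.5)
  X <- cbind(intercept = 1, x = xs)
  f10 <- fit_nbmm(y, X, subject = subj, nodes = 10)
  f20 <- fit_nbmm(y, X, subject = subj, nodes = 20)
  expect_lt(max(abs(f10$coefficients$estimate - f20$coefficients$estimate)),
            1e-4)
  expect_gt(f10$sigma2, 0.05)   # heterogeneity actually detected
})

test_that("with real heterogeneity the fit agrees with an independent GLMM", {
  set.seed(106)
  subj <- rep(sprintf("S%02d", 1:14), each = 150)
  xs <- rep(c(rep(1, 6), rep(0, 8)), each = 150)
  u <- rep(rnorm(14, 0, 0.5), each = 150)
  off <- log(runif(length(subj), 60, 140))
  y <- rnbinom(length(subj), mu = exp(-2.8 + 0.8 * xs + u + off), size = 2)
  fit <- fit_nbmm(y, cbind(intercept = 1, x = xs), offset = off, subject = subj)
  tmb <- glmmTMB::glmmTMB(y ~ x + (1 | subj) + offset(off),
                          family = glmmTMB::nbinom2,
                          data = data.frame(y = y, x = xs, subj = subj,
                                            off = off))
  # Laplace (glmmTMB) vs 10-node adaptive quadrature: near agreement
  expect_equal(fit$coefficients$estimate,
               unname(glmmTMB::fixef(tmb)$cond), tolerance = 0.02)
  expect_equal(fit$sigma2,
               unname(glmmTMB::VarCorr(tmb)$cond$subj[1, 1]), tolerance = 0.05)
  expect_equal(fit$phi, 1 / glmmTMB::sigma(tmb), tolerance = 0.02)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(stats::vcov(tmb)$cond))), tolerance = 0.05)
})

test_that("Poisson data drives the dispersion estimate to zero", {
  set.seed(103)
  subj <- rep(sprintf("S%02d", 1:10), each = 500)
  y <- rpois(5000, lambda = exp(1))
  fit <- fit_nbmm(y, matrix(1, 5000, 1, dimnames = list(NULL, "intercept")),
                  subject = subj)
  expect_lt(fit$phi, 0.05)
  expect_equal(fit$coefficients$estimate, 1, tolerance = 0.05)
})

test_that("the subject-intercept SD is recovered across replicates", {
  sig <- vapply(1:50, function(s) {
    set.seed(500 + s)
    subj <- rep(sprintf("S%02d", 1:14), each = 200)
    xs <- rep(rep(0:1, 7), each = 200)
    u <- rep(rnorm(14, 0, 0.5), each = 200)
    y <- rnbinom(2800, mu = exp(0.3 + 0.4 * xs + u), size = 2.5)
    sqrt(fit_nbmm(y, cbind(intercept = 1, x = xs), subject = subj)$sigma2)
  }, numeric(1))
  expect_equal(mean(sig), 0.5, tolerance = 0.2)
})

test_that("the free-variance likelihood dominates the sigma^2 = 0 fit", {
  set.seed(104)
  subj <- rep(sprintf("S%02d", 1:14), each = 80)
  u <- rep(rnorm(14, 0, 0.6), each = 80)
  y <- rnbinom(length(subj), mu = exp(0.5 + u), size = 2)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  free <- fit_nbmm(y, X, subject = subj)
  null <- fit_nbmm(y, X, subject = subj, fix_sigma2 = 0)
  expect_gte(free$logLik, null$logLik - 1e-6)
  expect_gt(free$logLik, null$logLik + 2)   # clearly better here
})

test_that("degenerate designs and inputs are rejected", {
  y <- rpois(40, 5)
  subj <- rep(c("a", "b"), 20)
  X <- cbind(intercept = 1, x = rep(0:1, 20), x2 = rep(0:1, 20))
  expect_error(fit_nbmm(y, X, subject = subj), class = "abseqde_design_error")
  expect_error(fit_nbmm(y, cbind(1), subject = subj),
               class = "abseqde_design_error")
  expect_error(fit_nbmm(c(-1, y[-1]), cbind(intercept = rep(1, 40)),
                        subject = subj),
               class = "abseqde_design_error")
  expect_error(fit_nbmm(y, cbind(intercept = rep(1, 40)),
                        subject = rep("a", 40)),
               class = "abseqde_design_error")
})

test_that("tidy() and glance() expose the fit in broom shape", {
  set.seed(105)
  subj <- rep(c("a", "b", "c", "d"), each = 50)
  y <- rnbinom(200, mu = 4, size = 2)
  fit <- fit_nbmm(y, matrix(1, 200, 1, dimnames = list(NULL, "intercept")),
                  subject = subj)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate", "se", "z", "p"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("sigma2", "phi", "logLik", "converged") %in% names(gl)))
})
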