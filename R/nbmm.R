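#' Fit a negative binomial mixed model with a subject random intercept
#'
#' Fits, for one feature's per-cell counts within one cell type, the model
#' \deqn{y_{ij} \sim NB(\mu_{ij}, \phi), \quad
#'       \log \mu_{ij} = x_{ij}^\top \beta + o_{ij} + u_j, \quad
#'       u_j \sim N(0, \sigma^2),}
#' where \eqn{\phi} is the cell-level dispersion (`var = mu + phi mu^2`),
#' \eqn{o_{ij}} a known offset (typically the log per-cell panel total),
#' and \eqn{u_j} a random intercept shared by all cells of subject `j`.
#' The marginal likelihood factorizes over subjects; each subject's
#' one-dimensional integral is evaluated by adaptive Gauss-Hermite
#' quadrature centered at the conditional mode. The joint parameter
#' `(beta, log sigma^2, log phi)` is maximized by bounded quasi-Newton
#' (`nlminb`), initialized deterministically from a Poisson GLM fit.
#' Wald tests use the inverse of the numerically evaluated Hessian.
#'
#' @param counts Nonnegative integer response vector (one feature's counts
#'   across cells).
#' @param design Fixed-effect design matrix (rows = cells). Constant
#'   columns other than the intercept are dropped; a design that is rank
#'   deficient after that raises a design error.
#' @param offset Optional numeric offset vector (log scale); default 0.
#' @param subject Subject identifier per cell (the random-effect grouping).
#' @param nodes Number of Gauss-Hermite quadrature nodes (default 10).
#' @param fix_sigma2 If non-`NULL`, the random-intercept variance is fixed
#'   at this value (e.g. `0` for a plain NB GLM) instead of estimated.
#' @param max_iter,tol Optimizer iteration cap and relative tolerance.
#' @return An `nbmm_fit` object: `coefficients` tibble (term, estimate, se,
#'   z, p), `sigma2`, `phi`, `logLik`, `converged`, `boundary` (`TRUE` when
#'   the variance estimate hit its lower bound, i.e. effectively 0),
#'   `n_cells`, `n_subjects`, `nodes`.
#' @examples
#' set.seed(1)
#' subj <- rep(sprintf("S%02d", 1:6), each = 40)
#' x <- as.numeric(as.integer(factor(subj)) %% 2 == 0)
#' u <- rnorm(6, 0, 0.3)[as.integer(factor(subj))]
#' y <- rnbinom(length(subj), mu = exp(0.5 + x + u), size = 2)
#' fit <- fit_nbmm(y, cbind(intercept = 1, x = x), subject = subj)
#' tidy(fit)
#' @export
fit_nbmm <- function(counts, design, offset = NULL, subject,
                     nodes = 10, fix_sigma2 = NULL, max_iter = 200, tol = 1e-6) {
  y <- as.numeric(counts)
  X <- as.matrix(design)
  n <- length(y)
  if (is.null(offset)) offset <- rep(0, n)
  if (nrow(X) != n || length(offset) != n || length(subject) != n) {
    rlang::abort("counts, design, offset and subject must have matching length",
                 class = "abseqde_design_error")
  }
  if (any(y < 0)) {
    rlang::abort("counts must be nonnegative", class = "abseqde_design_error")
  }
  subject <- as.character(subject)
  if (length(unique(subject)) < 2 && is.null(fix_sigma2)) {
    rlang::abort("at least 2 subjects are required to estimate sigma^2",
                 class = "abseqde_design_error")
  }

  # drop constant columns (except a single intercept column), then require
  # full rank
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  is_const <- apply(X, 2, function(col) length(unique(col)) == 1)
  keep <- !is_const
  if (any(is_const)) keep[which(is_const)[1]] <- TRUE  # retain one intercept
  X <- X[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    rlang::abort("design matrix is singular after dropping constant columns",
                 class = "abseqde_design_error")
  }
  p <- ncol(X)

  # sort cells by subject for the per-subject likelihood factorization
  ord <- order(subject)
  y <- y[ord]; X <- X[ord, , drop = FALSE]; offset <- offset[ord]
  subject <- subject[ord]
  subj_rle <- rle(subject)
  subj_start <- c(0L, cumsum(subj_rle$lengths))

  gh <- pracma::gaussHermite(nodes)

  sigma_free <- is.null(fix_sigma2)
  sigma2_fixed <- if (sigma_free) -1 else fix_sigma2
  n_subj <- length(subj_rle$lengths)

  # warm-start buffer for the per-subject conditional modes: successive
  # likelihood evaluations start their Newton search near the last solution
  state <- new.env(parent = emptyenv())
  state$u <- rep(0, n_subj)
  nll <- function(par) {
    res <- nbmm_nll_cpp(par, X, y, offset, subj_start, gh$x, gh$w,
                        sigma_free, sigma2_fixed, state$u)
    state$u <- res$u
    res$nll
  }

  # deterministic initialization: Poisson GLM for beta, moment estimate for
  # phi, between-subject residual variance for sigma^2; sigma and sqrt(phi)
  # are optimized on their natural scale with a lower bound of 0 so that
  # null variance components terminate at the bound
  init <- nbmm_init(y, X, offset, subject)
  start <- init$beta
  lower <- rep(-Inf, p); upper <- rep(Inf, p)
  if (sigma_free) {
    start <- c(start, sqrt(min(max(init$sigma2, 1e-3), 2)))
    lower <- c(lower, 0); upper <- c(upper, 5)
  }
  start <- c(start, sqrt(min(max(init$phi, 1e-3), 5)))
  lower <- c(lower, 0); upper <- c(upper, 3)

  opt <- tryCatch(
    stats::nlminb(start, nll, lower = lower, upper = upper,
                  control = list(rel.tol = tol, iter.max = max_iter,
                                 eval.max = 8 * max_iter)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) {
    return(nbmm_failed(colnames(X), n, n_subj, nodes))
  }
  converged <- opt$convergence == 0 ||
    grepl("relative convergence|x-convergence", opt$message %||% "")

  sigma2 <- if (sigma_free) unname(opt$par[p + 1])^2 else fix_sigma2
  phi <- unname(opt$par[length(opt$par)])^2
  boundary <- sigma_free && sigma2 < 1e-6

  # Wald covariance from the numerically evaluated Hessian; when a variance
  # component sits on its boundary the full Hessian is singular in that
  # direction, so fall back on the beta-block Hessian at the optimum
  H <- tryCatch(stats::optimHess(opt$par, nll), error = function(e) NULL)
  se <- rep(NA_real_, p)
  cov_from <- function(H, idx) {
    cov_all <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(cov_all)) return(NULL)
    d <- diag(cov_all)[idx]
    if (any(!is.finite(d)) || any(d <= 0)) return(NULL)
    sqrt(d)
  }
  if (!is.null(H)) se_try <- cov_from(H, seq_len(p)) else se_try <- NULL
  if (is.null(se_try)) {
    nll_beta <- function(b) nll(c(b, opt$par[-seq_len(p)]))
    Hb <- tryCatch(stats::optimHess(opt$par[seq_len(p)], nll_beta),
                   error = function(e) NULL)
    if (!is.null(Hb)) se_try <- cov_from(Hb, seq_len(p))
  }
  if (!is.null(se_try)) se <- se_try
  est <- unname(opt$par[seq_len(p)])
  se <- unname(se)
  z <- est / se
  pval <- 2 * stats::pnorm(-abs(z))

  structure(list(
    coefficients = tibble::tibble(term = colnames(X), estimate = est,
                                  se = se, z = z, p = pval),
    sigma2 = sigma2, phi = phi, logLik = -opt$objective,
    converged = converged && !all(is.na(se)), boundary = boundary,
    n_cells = n, n_subjects = length(subj_rle$lengths), nodes = nodes),
    class = "nbmm_fit")
}

nbmm_init <- function(y, X, offset, subject) {
  pois <- suppressWarnings(
    tryCatch(stats::glm.fit(X, y, family = stats::poisson(), offset = offset),
             error = function(e) NULL))
  if (is.null(pois) || !all(is.finite(pois$coefficients))) {
    beta <- c(log(mean(y) + 0.01), rep(0, ncol(X) - 1))
    mu <- exp(drop(X %*% beta) + offset)
  } else {
    beta <- pois$coefficients
    mu <- pois$fitted.values
  }
  phi <- sum((y - mu)^2 - mu) / sum(mu^2)
  resid_rate <- tapply(y, subject, sum) / pmax(tapply(mu, subject, sum), 1e-8)
  sigma2 <- stats::var(log(pmax(resid_rate, 1e-3)))
  if (!is.finite(sigma2)) sigma2 <- 0.05
  list(beta = beta, phi = phi, sigma2 = sigma2)
}

nbmm_failed <- function(terms, n, n_subj, nodes) {
  structure(list(
    coefficients = tibble::tibble(term = terms, estimate = NA_real_,
                                  se = NA_real_, z = NA_real_, p = NA_real_),
    sigma2 = NA_real_, phi = NA_real_, logLik = NA_real_,
    converged = FALSE, boundary = FALSE,
    n_cells = n, n_subjects = n_subj, nodes = nodes),
    class = "nbmm_fit")
}

#' @export
print.nbmm_fit <- function(x, ...) {
  cat("<nbmm_fit> ", x$n_cells, " cells, ", x$n_subjects, " subjects; sigma^2 = ",
      signif(x$sigma2, 3), if (isTRUE(x$boundary)) " (boundary)" else "",
      ", phi = ", signif(x$phi, 3),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_nbmm
#' @param x An `nbmm_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nbmm_fit <- function(x, ...) x$coefficients

#' @rdname fit_nbmm
#' @exportS3Method generics::glance
glance.nbmm_fit <- function(x, ...) {
  tibble::tibble(sigma2 = x$sigma2, phi = x$phi, logLik = x$logLik,
                 converged = x$converged, boundary = x$boundary,
                 n_cells = x$n_cells, n_subjects = x$n_subjects,
                 nodes = x$nodes)
}
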