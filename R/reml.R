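# Mixed linear model y = mu + Wg + Zu + e with u ~ N(0, G sigma2_a),
# e ~ N(0, I sigma2_e), fitted by REML on the eigendecomposition of G.
# One record per individual, so Z is the identity.

# Profiled restricted log-likelihood at heritability h2, on rotated data.
# V = sigma2 * diag(w), w_i = h2 * d_i + (1 - h2); sigma2 profiled out with
# REML denominator (n - p).
reml_profile <- function(h2, d, yt, Xt) {
  n <- length(yt)
  p <- ncol(Xt)
  w <- h2 * d + (1 - h2)
  if (any(w <= 0)) return(list(loglik = -Inf))
  Xw <- Xt / w
  XtWX <- crossprod(Xt, Xw)
  XtWy <- crossprod(Xw, yt)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  resid <- yt - Xt %*% beta
  rss <- sum(resid^2 / w)
  sigma2 <- rss / (n - p)
  if (!is.finite(sigma2) || sigma2 <= 0) return(list(loglik = -Inf))
  loglik <- -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) +
                      sum(log(w)) + 2 * sum(log(diag(ch))))
  list(loglik = loglik, sigma2 = sigma2, beta = beta, rss = rss, w = w)
}

# Maximize the profiled REML log-likelihood over h2 by coarse grid + Brent.
reml_optimize <- function(d, yt, Xt, bounds = c(1e-6, 1 - 1e-6),
                          tol = 1e-8, n_grid = 64) {
  f <- function(h2) reml_profile(h2, d, yt, Xt)$loglik
  grid <- seq(bounds[1], bounds[2], length.out = n_grid)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE, tol = tol)
  cand_h2 <- c(opt$maximum, grid[i], bounds)
  cand_ll <- c(opt$objective, vals[i], f(bounds[1]), f(bounds[2]))
  best <- which.max(cand_ll)
  list(h2 = cand_h2[best], loglik = cand_ll[best])
}

#' Fit the null mixed model by REML
#'
#' Fits `y = X beta + u + e` (no CNVR term) with `u ~ N(0, G sigma2_a)` and
#' `e ~ N(0, I sigma2_e)`. The GRM is eigendecomposed once (`G = U D U'`),
#' phenotypes and fixed effects are rotated by `U'`, and the restricted
#' log-likelihood, profiled over the total variance, is maximized over
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)` by a coarse grid followed by Brent
#' search. Samples with missing phenotype (or covariate) values are dropped
#' listwise before decomposition.
#'
#' @param phenotypes Phenotype tibble from [read_phenotypes()].
#' @param trait Name of the trait column to model.
#' @param grm A `cnv_grm` covering the phenotyped samples.
#' @param covariates Optional character vector of additional phenotype-table
#'   columns to include as fixed effects (intercept is always included).
#' @param ridge Small value added to the diagonal of G before decomposition
#'   to guard against rank deficiency. Default `1e-6`.
#' @param h2_bounds Search interval for h2.
#' @param tol Convergence tolerance on h2.
#' @param n_grid Coarse-grid size preceding the Brent search.
#' @param min_n Minimum number of retained samples (default 30).
#' @return A `cnvr_reml` object with elements `h2`, `sigma2_a`, `sigma2_e`,
#'   `reml_loglik`, `n`, retained `sample_ids`, and the decomposition
#'   (`U`, `d`, rotated `ytilde`, `Xtilde`) reused by [test_cnvr()].
#' @export
fit_null_reml <- function(phenotypes, trait, grm, covariates = NULL,
                          ridge = 1e-6, h2_bounds = c(1e-6, 1 - 1e-6),
                          tol = 1e-8, n_grid = 64, min_n = 30) {
  if (!trait %in% names(phenotypes)) {
    stop_user(paste0("Trait '", trait, "' not found in the phenotype table."))
  }
  cols <- c(trait, covariates)
  keep <- phenotypes$sample_id %in% grm$sample_ids &
    stats::complete.cases(phenotypes[, cols, drop = FALSE])
  ids <- phenotypes$sample_id[keep]
  n <- length(ids)
  if (n < min_n) {
    stop_user(paste0("Only ", n, " samples retained; need at least ", min_n, "."))
  }
  y <- phenotypes[[trait]][keep]
  if (stats::var(y) == 0) stop_user("Phenotype has zero variance.")
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    X <- cbind(X, as.matrix(phenotypes[keep, covariates, drop = FALSE]))
  }

  G <- grm_subset_samples(grm, ids)$values
  diag(G) <- diag(G) + ridge
  eig <- eigen(G, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  opt <- reml_optimize(d, yt, Xt, bounds = h2_bounds, tol = tol,
                       n_grid = n_grid)
  prof <- reml_profile(opt$h2, d, yt, Xt)
  if (!is.finite(prof$loglik)) {
    stop_user("REML log-likelihood is not finite at the optimum.")
  }
  structure(
    list(
      trait = trait, n = n, p = ncol(Xt),
      h2 = opt$h2,
      sigma2 = prof$sigma2,
      sigma2_a = opt$h2 * prof$sigma2,
      sigma2_e = (1 - opt$h2) * prof$sigma2,
      reml_loglik = prof$loglik,
      sample_ids = ids,
      d = d, U = U, ytilde = yt, Xtilde = Xt,
      ridge = ridge, h2_bounds = h2_bounds
    ),
    class = "cnvr_reml"
  )
}

#' @export
print.cnvr_reml <- function(x, ...) {
  cat("<cnvr_reml> trait '", x$trait, "', n = ", x$n,
      "; h2 = ", signif(x$h2, 4),
      ", sigma2_a = ", signif(x$sigma2_a, 4),
      ", sigma2_e = ", signif(x$sigma2_e, 4),
      ", REML logLik = ", signif(x$reml_loglik, 6), "\n", sep = "")
  invisible(x)
}

#' Tidy variance components of a fitted null model
#'
#' @param x A `cnvr_reml` object.
#' @param ... Unused.
#' @return Tibble with one row per component (`sigma2_a`, `sigma2_e`, `h2`).
#' @method tidy cnvr_reml
#' @export
tidy.cnvr_reml <- function(x, ...) {
  tibble(
    component = c("sigma2_a", "sigma2_e", "h2"),
    estimate = c(x$sigma2_a, x$sigma2_e, x$h2)
  )
}

#' One-row model summary of a fitted null model
#'
#' @param x A `cnvr_reml` object.
#' @param ... Unused.
#' @return One-row tibble: `trait`, `n`, `h2`, `sigma2_a`, `sigma2_e`,
#'   `reml_loglik`.
#' @method glance cnvr_reml
#' @export
glance.cnvr_reml <- function(x, ...) {
  tibble(trait = x$trait, n = x$n, h2 = x$h2, sigma2_a = x$sigma2_a,
         sigma2_e = x$sigma2_e, reml_loglik = x$reml_loglik)
}
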