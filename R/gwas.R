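# Per-CNVR association tests under the fitted mixed model.

# Weighted least squares of rotated y on a rotated design; residual scale
# re-estimated with denominator n - p (REML flavour), variance RATIO fixed.
gls_rotated <- function(yt, Xt, w) {
  n <- length(yt)
  p <- ncol(Xt)
  Xw <- Xt / w
  XtWX <- crossprod(Xt, Xw)
  XtWy <- crossprod(Xw, yt)
  ch <- chol(XtWX)
  beta <- drop(backsolve(ch, forwardsolve(t(ch), XtWy)))
  rss <- sum((yt - Xt %*% beta)^2 / w)
  sigma2 <- rss / (n - p)
  cov_unscaled <- chol2inv(ch)
  list(beta = beta, se = sqrt(sigma2 * diag(cov_unscaled)),
       sigma2 = sigma2, rss = rss)
}

degenerate_result <- function(cnvr_id, n) {
  tibble(cnvr_id = cnvr_id, beta = NA_real_, se = NA_real_,
         wald_chi2 = 0, p_value = 1, n_used = n, degenerate = TRUE)
}

#' Test one CNVR for association under the fitted mixed model
#'
#' Generalized least squares of the phenotype on (fixed effects, CNVR code
#' vector) with the variance ratio fixed at the null REML estimate — the
#' one-decomposition (EMMAX-style) test. The total scale is re-profiled per
#' marker so the test collapses exactly to ordinary least squares when
#' `sigma2_a = 0`. Reports the Wald chi-square on 1 df. With `exact = TRUE`
#' the variance components are re-estimated with the marker in the model (slow;
#' used for cross-checking the fast test).
#'
#' @param fit A `cnvr_reml` null fit.
#' @param w Code vector for one CNVR, named by sample id or ordered as
#'   `fit$sample_ids`.
#' @param cnvr_id Identifier copied into the result row.
#' @param exact Re-estimate h2 per marker instead of reusing the null estimate.
#' @return One-row tibble: `cnvr_id`, `beta`, `se`, `wald_chi2`, `p_value`,
#'   `n_used`, `degenerate`. A constant code vector is flagged degenerate and
#'   returns `p_value = 1` instead of failing.
#' @export
test_cnvr <- function(fit, w, cnvr_id = NA_character_, exact = FALSE) {
  stopifnot(inherits(fit, "cnvr_reml"))
  if (!is.null(names(w))) {
    idx <- match(fit$sample_ids, names(w))
    if (anyNA(idx)) stop_user("Code vector is missing a fitted sample.")
    w <- w[idx]
  }
  if (length(w) != fit$n) stop_user("Code vector length does not match fit.")
  if (stats::var(w) == 0) return(degenerate_result(cnvr_id, fit$n))

  xt <- drop(crossprod(fit$U, w))
  Xt <- cbind(fit$Xtilde, cnvr = xt)
  h2 <- if (isTRUE(exact)) {
    reml_optimize(fit$d, fit$ytilde, Xt, bounds = fit$h2_bounds)$h2
  } else {
    fit$h2
  }
  wt <- h2 * fit$d + (1 - h2)
  g <- gls_rotated(fit$ytilde, Xt, wt)
  k <- ncol(Xt)
  beta <- g$beta[k]
  se <- g$se[k]
  chi2 <- (beta / se)^2
  tibble(
    cnvr_id = cnvr_id, beta = beta, se = se, wald_chi2 = chi2,
    p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    n_used = fit$n, degenerate = FALSE
  )
}

#' Genome-wide significance threshold
#'
#' Bonferroni correction: `alpha / n_cnvr`.
#'
#' @param n_cnvr Number of CNVRs tested (>= 1).
#' @param alpha Family-wise error rate. Default 0.05.
#' @return The per-test p-value threshold.
#' @export
significance_threshold <- function(n_cnvr, alpha = 0.05) {
  if (length(n_cnvr) != 1 || is.na(n_cnvr) || n_cnvr < 1) {
    stop_user("n_cnvr must be a positive count.")
  }
  alpha / n_cnvr
}

#' Run a CNVR genome-wide association scan for one trait
#'
#' Reconciles samples across the genotype matrix, phenotype table and GRM
#' (listwise deletion of missing phenotypes), fits the null mixed model once,
#' and tests every CNVR column with the one-decomposition GLS test. The whole
#' scan shares a single eigendecomposition; the per-marker algebra is
#' vectorized across columns.
#'
#' @param gm A `cnv_geno` (typically after [frequency_filter()]).
#' @param phenotypes Phenotype tibble.
#' @param trait Trait column name.
#' @param grm A `cnv_grm`.
#' @param covariates Optional fixed-effect column names (see
#'   [fit_null_reml()]).
#' @param alpha Family-wise error rate / FDR level for the significance flag.
#' @param correction `"bonferroni"` (default) flags `p < alpha / N`;
#'   `"bh"` adds Benjamini-Hochberg `q_value` and flags `q <= alpha`.
#' @param method `"emmax"` (default, fast) or `"exact"` (re-estimates variance
#'   components per marker).
#' @param ridge,min_n Passed to [fit_null_reml()].
#' @return A tibble of class `cnvr_gwas`, one row per CNVR column: `cnvr_id`,
#'   `beta`, `se`, `wald_chi2`, `p_value`, (`q_value`,) `n_used`,
#'   `significant`, `degenerate`. The null fit is attached as attribute
#'   `"null_fit"`, the threshold as `"threshold"`.
#' @export
run_gwas <- function(gm, phenotypes, trait, grm, covariates = NULL,
                     alpha = 0.05, correction = c("bonferroni", "bh"),
                     method = c("emmax", "exact"), ridge = 1e-6, min_n = 30) {
  stopifnot(inherits(gm, "cnv_geno"), inherits(grm, "cnv_grm"))
  correction <- match.arg(correction)
  method <- match.arg(method)
  if (!trait %in% names(phenotypes)) {
    stop_user(paste0("Trait '", trait, "' not found in the phenotype table."))
  }
  if (all(is.na(phenotypes[[trait]]))) {
    stop_user(paste0("Trait '", trait, "' is entirely missing."))
  }
  phen <- phenotypes[phenotypes$sample_id %in% gm$sample_ids, , drop = FALSE]
  fit <- fit_null_reml(phen, trait, grm, covariates = covariates,
                       ridge = ridge, min_n = min_n)
  gm2 <- geno_subset_samples(gm, fit$sample_ids)
  codes <- gm2$codes
  m <- ncol(codes)
  if (m == 0) stop_user("Genotype matrix has no CNVR columns.")

  if (method == "exact") {
    res <- purrr::list_rbind(purrr::map(seq_len(m), function(j) {
      test_cnvr(fit, codes[, j], cnvr_id = gm2$cnvr_ids[j], exact = TRUE)
    }))
  } else {
    res <- gwas_emmax_scan(fit, codes, gm2$cnvr_ids)
  }

  threshold <- NA_real_
  if (correction == "bonferroni") {
    threshold <- significance_threshold(m, alpha)
    res$significant <- res$p_value < threshold
  } else {
    res$q_value <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$q_value <= alpha
    res <- dplyr::relocate(res, "q_value", .after = "p_value")
  }
  res <- dplyr::relocate(res, "significant", .after = "n_used")
  attr(res, "trait") <- trait
  attr(res, "alpha") <- alpha
  attr(res, "correction") <- correction
  attr(res, "threshold") <- threshold
  attr(res, "null_fit") <- fit
  class(res) <- c("cnvr_gwas", class(res))
  res
}

# Vectorized EMMAX-style scan: one rotation of the code matrix, then
# closed-form rank-one updates of the null normal equations per marker.
gwas_emmax_scan <- function(fit, codes, cnvr_ids) {
  n <- fit$n
  wt <- fit$h2 * fit$d + (1 - fit$h2)
  yt <- fit$ytilde
  Xt <- fit$Xtilde
  p <- ncol(Xt)

  col_var <- colMeans(codes^2) - colMeans(codes)^2
  Wt <- crossprod(fit$U, codes)          # n x m rotated codes

  Xw <- Xt / wt
  A <- crossprod(Xt, Xw)                 # p x p
  Ainv <- chol2inv(chol(A))
  b <- drop(crossprod(Xw, yt))           # p
  ab <- drop(Ainv %*% b)
  Syy <- sum(yt^2 / wt)
  rss0 <- Syy - sum(b * ab)

  U1 <- crossprod(Xw, Wt)                # p x m
  AiU <- Ainv %*% U1                     # p x m
  Q <- colSums(Wt^2 / wt)
  Rv <- colSums(Wt * (yt / wt))
  term <- colSums(U1 * ab)               # t(u_j) Ainv b
  denom <- Q - colSums(U1 * AiU)         # t(u_j) Ainv u_j subtracted

  ok <- col_var > 0 & denom > 1e-12 * max(Q, 1)
  beta <- se <- rep(NA_real_, length(cnvr_ids))
  chi2 <- rep(0, length(cnvr_ids))
  pval <- rep(1, length(cnvr_ids))
  if (any(ok)) {
    bj <- (Rv[ok] - term[ok]) / denom[ok]
    rss <- pmax(rss0 - bj^2 * denom[ok], 0)
    sigma2 <- rss / (n - p - 1)
    sej <- sqrt(sigma2 / denom[ok])
    beta[ok] <- bj
    se[ok] <- sej
    chi2[ok] <- (bj / sej)^2
    pval[ok] <- stats::pchisq(chi2[ok], df = 1, lower.tail = FALSE)
  }
  tibble(
    cnvr_id = cnvr_ids, beta = beta, se = se, wald_chi2 = chi2,
    p_value = pval, n_used = n, degenerate = !ok
  )
}

#' Manhattan and QQ plot data with genomic inflation
#'
#' @param results A `cnvr_gwas` result tibble.
#' @param cnvrs CNVR tibble supplying coordinates for every result id.
#' @param chroms Optional chromosome table fixing track order and offsets;
#'   when absent, per-chromosome extents come from the CNVRs themselves.
#' @return List with `manhattan` (per CNVR: `chrom`, `pos_bp` midpoint,
#'   `pos_cum` cumulative bp, `p_value`, `neg_log10_p`, `significant`),
#'   `qq` (`expected`, `observed` on the -log10 scale) and `lambda_gc`
#'   (median Wald chi-square / 0.4549).
#' @export
manhattan_qq_data <- function(results, cnvrs, chroms = NULL) {
  missing_ids <- setdiff(results$cnvr_id, cnvrs$cnvr_id)
  if (length(missing_ids) > 0) {
    stop_user(paste0("Result id '", missing_ids[1], "' has no CNVR."))
  }
  coords <- cnvrs[match(results$cnvr_id, cnvrs$cnvr_id),
                  c("chrom", "start", "end")]
  man <- dplyr::bind_cols(results[, c("cnvr_id", "p_value")], coords)
  man$significant <- results$significant %||% FALSE
  if (is.null(chroms)) {
    chroms <- man |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(length = max(.data$end), .groups = "drop")
    chroms <- chroms[order(chrom_rank(chroms$chrom)), ]
  }
  offsets <- setNames(cumsum(c(0, head(chroms$length, -1))), chroms$chrom)
  man$pos_bp <- (man$start + man$end) / 2
  man$pos_cum <- offsets[man$chrom] + man$pos_bp
  man$neg_log10_p <- -log10(man$p_value)
  man <- man[order(man$pos_cum), ]

  m <- nrow(results)
  p_sorted <- sort(results$p_value)
  qq <- tibble(
    expected = -log10((seq_len(m) - 0.5) / m),
    observed = -log10(p_sorted)
  )
  lambda <- stats::median(results$wald_chi2) / stats::qchisq(0.5, df = 1)
  list(manhattan = as_tibble(man), qq = qq, lambda_gc = lambda)
}
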