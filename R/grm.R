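# CNV-derived genomic relationship matrix.

#' Compute the CNV genomic relationship matrix
#'
#' VanRaden-type construction on the three-state codes: each CNVR column is
#' mean-centered, then `G = C %*% t(C) / s` where `s` is the sum of column
#' variances (denominator `n`). With this scaling `mean(diag(G)) = 1` exactly.
#' Zero-variance columns carry no relationship information and are dropped
#' with a message.
#'
#' @param gm A `cnv_geno` object with at least 2 samples and one column of
#'   nonzero variance.
#' @return A `cnv_grm` object: `values` (n x n symmetric matrix with sample-id
#'   dimnames), `sample_ids`, `n_markers` used, `n_dropped` zero-variance
#'   columns.
#' @export
compute_grm <- function(gm) {
  stopifnot(inherits(gm, "cnv_geno"))
  codes <- gm$codes
  if (nrow(codes) < 2) stop_user("GRM needs at least 2 samples.")
  v <- colMeans(codes^2) - colMeans(codes)^2
  keep <- v > 0
  n_dropped <- sum(!keep)
  if (!any(keep)) stop_user("No informative CNVRs: all columns are constant.")
  if (n_dropped > 0) {
    rlang::inform(paste0("Dropped ", n_dropped,
                         " zero-variance CNVR column(s) from the GRM."))
  }
  C <- scale(codes[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  G <- tcrossprod(C) / sum(v[keep])
  dimnames(G) <- list(gm$sample_ids, gm$sample_ids)
  structure(
    list(values = G, sample_ids = gm$sample_ids,
         n_markers = sum(keep), n_dropped = n_dropped),
    class = "cnv_grm"
  )
}

#' GRM diagnostics
#'
#' @param g A `cnv_grm` object.
#' @return One-row tibble: `mean_diag`, `mean_offdiag`, `min_eigenvalue`.
#' @export
grm_diagnostics <- function(g) {
  stopifnot(inherits(g, "cnv_grm"))
  G <- g$values
  n <- nrow(G)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  tibble(
    mean_diag = mean(diag(G)),
    mean_offdiag = if (n > 1) (sum(G) - sum(diag(G))) / (n * (n - 1)) else NA_real_,
    min_eigenvalue = min(ev)
  )
}

#' @export
as.matrix.cnv_grm <- function(x, ...) x$values

#' @export
dim.cnv_grm <- function(x) dim(x$values)

#' @export
print.cnv_grm <- function(x, ...) {
  d <- grm_diagnostics(x)
  cat("<cnv_grm> ", nrow(x$values), " samples from ", x$n_markers,
      " CNVRs; mean diag ", signif(d$mean_diag, 4),
      ", min eigenvalue ", signif(d$min_eigenvalue, 4), "\n", sep = "")
  invisible(x)
}

#' Write a GRM as TSV with sample-id header and row names
#'
#' @param g A `cnv_grm`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_grm_tsv <- function(g, path) {
  df <- as.data.frame(g$values)
  df <- cbind(sample_id = g$sample_ids, df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a GRM written by [write_grm_tsv()]
#'
#' @param path TSV path.
#' @return A `cnv_grm` object.
#' @export
read_grm_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- as.character(df$sample_id)
  G <- as.matrix(df[, -1, drop = FALSE])
  dimnames(G) <- list(ids, ids)
  structure(
    list(values = G, sample_ids = ids, n_markers = NA_integer_,
         n_dropped = NA_integer_),
    class = "cnv_grm"
  )
}

# Subset/reorder a GRM by sample ids.
grm_subset_samples <- function(g, sample_ids) {
  idx <- match(sample_ids, g$sample_ids)
  if (anyNA(idx)) stop_user("Sample id absent from GRM.")
  structure(
    list(values = g$values[idx, idx, drop = FALSE], sample_ids = sample_ids,
         n_markers = g$n_markers, n_dropped = g$n_dropped),
    class = "cnv_grm"
  )
}
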