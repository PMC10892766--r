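# Three-state CNVR genotype matrix: gain = +1, normal = 0, loss = -1.

new_cnv_geno <- function(codes, sample_ids, cnvr_ids) {
  stopifnot(nrow(codes) == length(sample_ids), ncol(codes) == length(cnvr_ids))
  dimnames(codes) <- list(sample_ids, cnvr_ids)
  structure(
    list(
      codes = codes,
      sample_ids = sample_ids,
      cnvr_ids = cnvr_ids,
      frequencies = colMeans(codes != 0)
    ),
    class = "cnv_geno"
  )
}

#' Build the coded CNVR genotype matrix
#'
#' Codes every (sample, CNVR) cell as +1 (gain), -1 (loss) or 0 (normal copy
#' number). A sample carrying only DUP calls in a region is +1, only DEL calls
#' -1. When a sample has both call types inside one region the type covering
#' more total bases wins; an exact tie codes -1, since losses dominate CNV
#' landscapes. Each tie-break is reported via a message.
#'
#' @param cnvrs CNVR tibble from [merge_to_cnvrs()] (needs the nested `calls`
#'   column).
#' @param samples Ordered character vector of all sample ids (defines rows;
#'   samples without calls get all-zero rows).
#' @return A `cnv_geno` object: integer matrix `codes` (samples x CNVRs) plus
#'   `sample_ids`, `cnvr_ids` and per-CNVR carrier `frequencies`.
#' @export
build_genotype_matrix <- function(cnvrs, samples) {
  if (anyDuplicated(samples)) stop_user("Duplicate sample ids.")
  codes <- matrix(0L, nrow = length(samples), ncol = nrow(cnvrs))
  n_ties <- 0L
  for (j in seq_len(nrow(cnvrs))) {
    cc <- cnvrs$calls[[j]]
    unknown <- setdiff(cc$sample_id, samples)
    if (length(unknown) > 0) {
      stop_user(paste0("Call sample '", unknown[1],
                       "' absent from the sample list."))
    }
    len <- cc$end - cc$start + 1
    del <- tapply(len * (cc$svtype == "DEL"), cc$sample_id, sum)
    dup <- tapply(len * (cc$svtype == "DUP"), cc$sample_id, sum)
    ids <- names(del)
    code <- ifelse(dup > del, 1L, -1L)
    n_ties <- n_ties + sum(del > 0 & dup > 0 & del == dup)
    codes[match(ids, samples), j] <- code
  }
  if (n_ties > 0) {
    rlang::inform(paste0(n_ties, " sample/CNVR cell(s) had equal DEL and DUP ",
                         "overlap; coded as loss."))
  }
  new_cnv_geno(codes, samples, cnvrs$cnvr_id)
}

#' Drop rare CNVRs from a genotype matrix
#'
#' Retains columns whose carrier frequency (proportion of nonzero codes among
#' all samples) is strictly greater than `min_freq`; column order is preserved.
#'
#' @param gm A `cnv_geno` object.
#' @param min_freq Minimum carrier frequency, in `[0, 1)`. Default 0.005
#'   (0.5%).
#' @return A `cnv_geno` with the retained columns.
#' @export
frequency_filter <- function(gm, min_freq = 0.005) {
  stopifnot(inherits(gm, "cnv_geno"))
  if (min_freq < 0 || min_freq >= 1) stop_user("min_freq must be in [0, 1).")
  keep <- gm$frequencies > min_freq
  new_cnv_geno(gm$codes[, keep, drop = FALSE], gm$sample_ids,
               gm$cnvr_ids[keep])
}

#' @export
as.matrix.cnv_geno <- function(x, ...) x$codes

#' @export
dim.cnv_geno <- function(x) dim(x$codes)

#' @export
print.cnv_geno <- function(x, ...) {
  cat("<cnv_geno> ", nrow(x$codes), " samples x ", ncol(x$codes),
      " CNVRs; carrier frequency ",
      if (ncol(x$codes) > 0) {
        paste0(signif(min(x$frequencies), 3), "-",
               signif(max(x$frequencies), 3))
      } else "NA", "\n", sep = "")
  invisible(x)
}

#' Tidy a CNVR genotype matrix into long form
#'
#' @param x A `cnv_geno` object.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `cnvr_id`, `code`.
#' @method tidy cnv_geno
#' @export
tidy.cnv_geno <- function(x, ...) {
  tibble(
    sample_id = rep(x$sample_ids, times = ncol(x$codes)),
    cnvr_id = rep(x$cnvr_ids, each = nrow(x$codes)),
    code = as.integer(x$codes)
  )
}

# Subset a genotype matrix to (and reorder by) the given sample ids.
geno_subset_samples <- function(gm, sample_ids) {
  idx <- match(sample_ids, gm$sample_ids)
  if (anyNA(idx)) stop_user("Sample id absent from genotype matrix.")
  new_cnv_geno(gm$codes[idx, , drop = FALSE], sample_ids, gm$cnvr_ids)
}
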