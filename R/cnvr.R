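#' Filter CNV calls by length
#'
#' Retains calls whose length (`end - start + 1`) lies within
#' `[min_bp, max_bp]`, both bounds inclusive. The defaults (50 bp to 5 Mb)
#' are the usual size window for short-read CNV calls.
#'
#' @param calls Call tibble from [read_cnv_vcf()].
#' @param min_bp,max_bp Inclusive length bounds in bp.
#' @return The retained calls, order preserved.
#' @export
filter_calls_by_size <- function(calls, min_bp = 50, max_bp = 5e6) {
  if (min_bp > max_bp) stop_user("min_bp must not exceed max_bp.")
  len <- calls$end - calls$start + 1
  calls[len >= min_bp & len <= max_bp, , drop = FALSE]
}

#' Classify a CNVR from the types of its supporting calls
#'
#' @param svtypes Character vector of supporting-call types (`DEL`/`DUP`).
#' @return `"loss"` (all DEL), `"gain"` (all DUP) or `"mixed"` (both).
#' @export
classify_cnvr <- function(svtypes) {
  if (length(svtypes) == 0) stop_user("Cannot classify a CNVR with no calls.")
  has_del <- any(svtypes == "DEL")
  has_dup <- any(svtypes == "DUP")
  if (has_del && has_dup) "mixed" else if (has_del) "loss" else "gain"
}

#' Merge overlapping CNV calls across samples into CNVRs
#'
#' Per chromosome, CNVRs are the connected components of the interval-overlap
#' graph: calls sharing at least one base pair belong to the same region.
#' Book-ended calls (one ends where the next starts minus one) share no base
#' and are NOT merged. Each CNVR spans `min(start)..max(end)` of its component
#' and is typed loss/gain/mixed by [classify_cnvr()]. Output is sorted by
#' (chromosome, start) and ids are assigned in sort order as
#' `DEL`/`DUP`/`MIX` + zero-padded 8-digit index, so the result is independent
#' of input call order.
#'
#' @param calls Size-filtered call tibble.
#' @return Tibble with columns `cnvr_id`, `chrom`, `start`, `end`, `length`,
#'   `type`, `n_calls`, `n_carriers`, `carriers` (list of sample ids) and
#'   `calls` (nested tibble of supporting calls).
#' @export
merge_to_cnvrs <- function(calls) {
  empty <- tibble(
    cnvr_id = character(), chrom = character(), start = integer(),
    end = integer(), length = integer(), type = character(),
    n_calls = integer(), n_carriers = integer(),
    carriers = list(), calls = list()
  )
  if (is.null(calls) || nrow(calls) == 0) return(empty)
  calls <- sort_genomic(calls)

  per_chrom <- split(calls, calls$chrom)
  regions <- purrr::map(per_chrom, function(cc) {
    ir <- IRanges::IRanges(start = cc$start, end = cc$end)
    # min.gapwidth = 0 merges only truly overlapping ranges (>= 1 shared bp)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    tibble(
      chrom = cc$chrom[1],
      start = IRanges::start(red),
      end = IRanges::end(red),
      calls = unname(split(cc, factor(grp, levels = sort(unique(grp)))))
    )
  })
  out <- dplyr::bind_rows(regions)
  out <- sort_genomic(out)
  out$type <- purrr::map_chr(out$calls, ~ classify_cnvr(.x$svtype))
  out$carriers <- purrr::map(out$calls, ~ sort(unique(.x$sample_id)))
  out$n_calls <- purrr::map_int(out$calls, nrow)
  out$n_carriers <- lengths(out$carriers)
  out$length <- out$end - out$start + 1L
  prefix <- c(loss = "DEL", gain = "DUP", mixed = "MIX")[out$type]
  out$cnvr_id <- sprintf("%s%08d", prefix, seq_len(nrow(out)))
  out[, c("cnvr_id", "chrom", "start", "end", "length", "type",
          "n_calls", "n_carriers", "carriers", "calls")]
}

#' Filter CNVRs by length
#'
#' Same inclusive window as [filter_calls_by_size()], applied after merging
#' (a merged region can exceed the per-call maximum).
#'
#' @param cnvrs CNVR tibble.
#' @param min_bp,max_bp Inclusive length bounds in bp.
#' @return The retained CNVRs.
#' @export
filter_cnvrs_by_size <- function(cnvrs, min_bp = 50, max_bp = 5e6) {
  if (min_bp > max_bp) stop_user("min_bp must not exceed max_bp.")
  cnvrs[cnvrs$length >= min_bp & cnvrs$length <= max_bp, , drop = FALSE]
}
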