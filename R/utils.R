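# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Fixed-point rounding in which exact .5 ties go up (e.g. 1.45 -> 1.5),
#' matching how the package formats percentages and mean sizes in summary
#' tables. Base `round()` rounds half to even and would print 1.4.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(c(1.45, 0.75, 2.0743), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Natural chromosome ordering: numeric-looking names sort numerically and come
# first; everything else follows alphabetically.
chrom_rank <- function(chrom) {
  u <- unique(chrom)
  num <- suppressWarnings(as.numeric(sub("^chr", "", u, ignore.case = TRUE)))
  match(chrom, u[order(is.na(num), num, u)])
}

# Sort a region/call table by (chromosome, start, end).
sort_genomic <- function(df) {
  dplyr::arrange(df, chrom_rank(.data$chrom), .data$start, .data$end)
}

stop_user <- function(msg, class = "cnvrgwas_error") {
  rlang::abort(msg, class = class)
}
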