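# Proximal-gene annotation of CNVRs within a symmetric flanking window.

#' Genes proximal to CNVRs
#'
#' For each CNVR, reports every gene whose span intersects the window
#' `[max(1, start - flank), end + flank]` by at least one base (closed
#' intervals, boundary inclusive; strand is ignored). Each hit is classified
#' `inside` (gene entirely within the CNVR), `overlaps_cnvr` (intersects the
#' CNVR but extends beyond it) or `flank_only` (intersects only the flank).
#' Overlap search uses an interval index ([GenomicRanges::findOverlaps()]).
#'
#' @param cnvrs CNVR tibble (any subset, e.g. the significant hits).
#' @param genes Gene-model tibble from [read_gff()].
#' @param flank Flank size in bp on each side. Default 50,000 (a 100 kb
#'   window).
#' @return Tibble with one row per (CNVR, gene) pair: `cnvr_id`, `chrom`,
#'   `window_start`, `window_end`, `gene_id`, `gene_start`, `gene_end`,
#'   `strand`, `overlap_class`; sorted by CNVR then gene start. CNVRs with no
#'   proximal gene are absent.
#' @export
proximal_genes <- function(cnvrs, genes, flank = 50000) {
  if (flank < 0) stop_user("flank must be non-negative.")
  empty <- tibble(
    cnvr_id = character(), chrom = character(),
    window_start = integer(), window_end = integer(),
    gene_id = character(), gene_start = integer(), gene_end = integer(),
    strand = character(), overlap_class = character()
  )
  if (nrow(cnvrs) == 0 || nrow(genes) == 0) return(empty)

  win_start <- pmax(1, cnvrs$start - flank)
  win_end <- cnvrs$end + flank
  win <- GenomicRanges::GRanges(cnvrs$chrom,
                                IRanges::IRanges(win_start, win_end))
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(win, gr, ignore.strand = TRUE))
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)

  gs <- genes$start[si]
  ge <- genes$end[si]
  cs <- cnvrs$start[qi]
  ce <- cnvrs$end[qi]
  cls <- ifelse(gs >= cs & ge <= ce, "inside",
                ifelse(gs <= ce & ge >= cs, "overlaps_cnvr", "flank_only"))
  out <- tibble(
    cnvr_id = cnvrs$cnvr_id[qi],
    chrom = cnvrs$chrom[qi],
    window_start = win_start[qi],
    window_end = win_end[qi],
    gene_id = genes$gene_id[si],
    gene_start = gs,
    gene_end = ge,
    strand = genes$strand[si],
    overlap_class = cls
  )
  dplyr::arrange(out, chrom_rank(.data$chrom), .data$window_start,
                 .data$cnvr_id, .data$gene_start)
}
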