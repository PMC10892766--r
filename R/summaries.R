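# Landscape summaries: per-chromosome table, type and size distributions,
# genome track.

#' Per-chromosome CNVR summary
#'
#' One row per chromosome of `chroms` (zero-filled where no CNVRs fall), plus
#' an `overall` row whose count and total length are column sums, whose mean
#' size is total length / total count and whose coverage uses the summed
#' chromosome lengths. Coverage percentages and mean sizes are half-up rounded
#' to 1 decimal, the convention used for published CNVR landscape tables.
#'
#' @param cnvrs CNVR tibble.
#' @param chroms Chromosome table (`chrom`, `length`).
#' @return Tibble with columns `chrom`, `chrom_length`, `cnvr_count`,
#'   `cnvr_total_length`, `coverage_pct`, `max_size`, `mean_size`, `min_size`.
#' @export
per_chromosome_summary <- function(cnvrs, chroms) {
  unknown <- setdiff(cnvrs$chrom, chroms$chrom)
  if (length(unknown) > 0) {
    stop_user(paste0("CNVR on unknown chromosome '", unknown[1], "'."))
  }
  by_chr <- cnvrs |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      cnvr_count = dplyr::n(),
      cnvr_total_length = sum(.data$length),
      max_size = max(.data$length),
      min_size = min(.data$length),
      .groups = "drop"
    )
  rows <- chroms |>
    dplyr::rename(chrom_length = "length") |>
    dplyr::left_join(by_chr, by = "chrom") |>
    dplyr::mutate(
      cnvr_count = dplyr::coalesce(.data$cnvr_count, 0L),
      cnvr_total_length = dplyr::coalesce(as.numeric(.data$cnvr_total_length), 0),
      max_size = dplyr::coalesce(as.numeric(.data$max_size), 0),
      min_size = dplyr::coalesce(as.numeric(.data$min_size), 0),
      coverage_pct = ifelse(
        .data$cnvr_count > 0,
        round_half_up(100 * .data$cnvr_total_length / .data$chrom_length, 1), 0),
      mean_size = ifelse(
        .data$cnvr_count > 0,
        round_half_up(.data$cnvr_total_length / .data$cnvr_count, 1), 0)
    )
  overall <- tibble(
    chrom = "overall",
    chrom_length = sum(rows$chrom_length),
    cnvr_count = sum(rows$cnvr_count),
    cnvr_total_length = sum(rows$cnvr_total_length),
    max_size = max(c(rows$max_size, 0)),
    min_size = if (any(rows$cnvr_count > 0)) {
      min(rows$min_size[rows$cnvr_count > 0])
    } else 0,
    coverage_pct = if (sum(rows$cnvr_count) > 0) {
      round_half_up(100 * sum(rows$cnvr_total_length) / sum(rows$chrom_length), 1)
    } else 0,
    mean_size = if (sum(rows$cnvr_count) > 0) {
      round_half_up(sum(rows$cnvr_total_length) / sum(rows$cnvr_count), 1)
    } else 0
  )
  cols <- c("chrom", "chrom_length", "cnvr_count", "cnvr_total_length",
            "coverage_pct", "max_size", "mean_size", "min_size")
  dplyr::bind_rows(rows[cols], overall[cols])
}

#' CNVR type distribution
#'
#' @param cnvrs CNVR tibble.
#' @return Tibble with one row per type (`loss`, `gain`, `mixed`), columns
#'   `type`, `n`, `percentage` (half-up, 1 decimal).
#' @export
type_distribution <- function(cnvrs) {
  lv <- c("loss", "gain", "mixed")
  n <- vapply(lv, function(t) sum(cnvrs$type == t), integer(1))
  total <- sum(n)
  tibble(
    type = lv,
    n = unname(n),
    percentage = if (total > 0) round_half_up(100 * unname(n) / total, 1) else 0
  )
}

#' CNVR size distribution over fixed bins
#'
#' Bins are `[edge_k, edge_{k+1})`, the last unbounded above. CNVRs shorter
#' than the first edge are counted in an `underflow` bin and reported via a
#' message. The default edges split at 1, 5, 10 and 50 kb.
#'
#' @param cnvrs CNVR tibble.
#' @param edges Strictly increasing bp boundaries; a final `Inf` is implied.
#' @return Tibble with columns `bin`, `lower`, `upper`, `n`, `percentage`
#'   (half-up, 1 decimal; percentages are of all CNVRs including underflow).
#' @export
size_distribution <- function(cnvrs,
                              edges = c(50, 1000, 5000, 10000, 50000)) {
  edges <- edges[is.finite(edges)]
  if (any(diff(edges) <= 0)) stop_user("Bin edges must be strictly increasing.")
  lower <- edges
  upper <- c(edges[-1], Inf)
  len <- cnvrs$length
  n_under <- sum(len < edges[1])
  if (n_under > 0) {
    rlang::inform(paste0(n_under, " CNVR(s) below the first size edge; ",
                         "counted as underflow."))
  }
  n <- vapply(seq_along(lower), function(k) {
    sum(len >= lower[k] & len < upper[k])
  }, integer(1))
  total <- length(len)
  out <- tibble(
    bin = paste0("[", format(lower, scientific = FALSE, trim = TRUE), ",",
                 ifelse(is.finite(upper),
                        format(upper, scientific = FALSE, trim = TRUE), "Inf"),
                 ")"),
    lower = lower,
    upper = upper,
    n = n,
    percentage = if (total > 0) round_half_up(100 * n / total, 1) else 0
  )
  if (n_under > 0) {
    out <- dplyr::bind_rows(
      tibble(bin = "underflow", lower = 0, upper = edges[1], n = n_under,
             percentage = round_half_up(100 * n_under / total, 1)),
      out
    )
  }
  out
}

#' Plot-ready genome track of CNVRs
#'
#' Converts CNVR spans to Mb for a per-chromosome map colored by type.
#'
#' @param cnvrs CNVR tibble, sorted by (chrom, start).
#' @param chroms Chromosome table; defines track order and extents.
#' @return Tibble with columns `chrom`, `chrom_length_mb`, `start_mb`,
#'   `end_mb`, `type`.
#' @export
genome_track <- function(cnvrs, chroms) {
  segs <- cnvrs |>
    dplyr::left_join(
      chroms |> dplyr::rename(chrom_length = "length"), by = "chrom") |>
    dplyr::transmute(
      chrom = factor(.data$chrom, levels = chroms$chrom),
      chrom_length_mb = .data$chrom_length / 1e6,
      start_mb = .data$start / 1e6,
      end_mb = .data$end / 1e6,
      type = .data$type
    )
  segs
}
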