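#' Read per-sample CNV calls from a structural-variant VCF
#'
#' Parses a multi-sample VCF of DELLY-style structural-variant records and
#' returns one row per (record, carrier sample) pair. A sample is a carrier
#' when its GT field contains at least one "1" allele; `./.` and `0/0` are
#' non-carriers. Records whose `SVTYPE` is not `DEL` or `DUP` (inversions,
#' breakends, ...) are skipped with a message. Copy-number FORMAT fields are
#' ignored: downstream genotype coding needs only carrier status and call type.
#'
#' @param path Path to a VCF (plain or bgzipped) with `SVTYPE` and `END` INFO
#'   keys and a per-sample `GT` FORMAT field.
#' @param require_pass If `TRUE` (default), keep only records whose FILTER
#'   value contains "pass" (case-insensitive), mirroring the upstream caller's
#'   quality filter.
#' @return A tibble of CNV calls with columns `sample_id`, `chrom`,
#'   `start` (= POS, 1-based inclusive), `end` (= INFO/END, 1-based inclusive),
#'   `svtype` ("DEL"/"DUP") and `filter_status`.
#' @export
read_cnv_vcf <- function(path, require_pass = TRUE) {
  if (!file.exists(path)) stop_user(paste0("VCF not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) {
    return(tibble(
      sample_id = character(), chrom = character(), start = integer(),
      end = integer(), svtype = character(), filter_status = character()
    ))
  }
  svtype <- vcfR::extract.info(vcf, element = "SVTYPE")
  filt <- fix[, "FILTER"]

  keep <- rep(TRUE, nrow(fix))
  if (isTRUE(require_pass)) {
    keep <- keep & !is.na(filt) & grepl("pass", filt, ignore.case = TRUE)
  }
  bad_type <- keep & (is.na(svtype) | !svtype %in% c("DEL", "DUP"))
  # records with a recognisable non-CNV SVTYPE are skipped, not an error
  n_skipped <- sum(keep & !is.na(svtype) & !svtype %in% c("DEL", "DUP"))
  if (n_skipped > 0) {
    rlang::inform(paste0("Skipped ", n_skipped,
                         " record(s) with SVTYPE outside DEL/DUP."))
  }
  missing_svtype <- keep & is.na(svtype)
  if (any(missing_svtype)) {
    i <- which(missing_svtype)[1]
    stop_user(paste0("Record at ", fix[i, "CHROM"], ":", fix[i, "POS"],
                     " lacks INFO/SVTYPE."))
  }
  keep <- keep & !bad_type

  end <- suppressWarnings(as.integer(vcfR::extract.info(vcf, element = "END")))
  if (any(keep & is.na(end))) {
    i <- which(keep & is.na(end))[1]
    stop_user(paste0("Record at ", fix[i, "CHROM"], ":", fix[i, "POS"],
                     " lacks a parseable INFO/END."))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop_user("VCF has no per-sample GT field.")
  gt <- gt[, , drop = FALSE]

  out <- vector("list", sum(keep))
  rows <- which(keep)
  samples <- colnames(gt)
  for (k in seq_along(rows)) {
    r <- rows[k]
    carriers <- vapply(gt[r, ], gt_is_carrier, logical(1),
                       ctx = paste0(fix[r, "CHROM"], ":", fix[r, "POS"]))
    if (!any(carriers)) next
    out[[k]] <- tibble(
      sample_id = unname(samples[carriers]),
      chrom = unname(fix[r, "CHROM"]),
      start = as.integer(unname(fix[r, "POS"])),
      end = unname(end[r]),
      svtype = unname(svtype[r]),
      filter_status = unname(filt[r])
    )
  }
  calls <- dplyr::bind_rows(out)
  if (nrow(calls) == 0) {
    calls <- tibble(
      sample_id = character(), chrom = character(), start = integer(),
      end = integer(), svtype = character(), filter_status = character()
    )
  }
  if (any(calls$end < calls$start)) {
    stop_user("VCF contains a record with END < POS.")
  }
  calls
}

# TRUE if a GT string carries >= 1 alternate allele; NA/"."/"0" alleles do not.
gt_is_carrier <- function(gt, ctx = "") {
  if (is.na(gt) || gt == ".") return(FALSE)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (!all(alleles %in% c(".", "0", "1"))) {
    stop_user(paste0("Unparseable GT '", gt, "' at ", ctx))
  }
  any(alleles == "1")
}

#' Read a chromosome-length table
#'
#' @param path TSV with header columns `chrom` and `length` (bp).
#' @return Tibble with columns `chrom` (character) and `length` (integer bp).
#' @export
read_chromosome_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(chrom = "c", length = "d"))
  if (!all(c("chrom", "length") %in% names(tab))) {
    stop_user("Chromosome table needs columns 'chrom' and 'length'.")
  }
  if (anyDuplicated(tab$chrom)) stop_user("Duplicate chromosome names.")
  if (any(tab$length <= 0 | is.na(tab$length))) {
    stop_user("Chromosome lengths must be positive.")
  }
  tibble(chrom = tab$chrom, length = as.numeric(tab$length))
}

#' Read a phenotype table
#'
#' @param path TSV with header; first column is the sample identifier, the
#'   remaining columns are numeric traits. Empty cells and "NA" become missing
#'   values (never zero).
#' @return Tibble with column `sample_id` followed by one numeric column per
#'   trait.
#' @export
read_phenotypes <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"))
  if (ncol(tab) < 1) stop_user("Phenotype table is empty.")
  names(tab)[1] <- "sample_id"
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) {
    stop_user("Duplicate sample_id in phenotype table.")
  }
  for (tr in names(tab)[-1]) {
    tab[[tr]] <- suppressWarnings(as.numeric(tab[[tr]]))
    if (all(is.na(tab[[tr]]))) {
      rlang::warn(paste0("Trait '", tr, "' has no non-missing values."))
    }
  }
  as_tibble(tab)
}

#' Read gene models from a GFF3 file
#'
#' Keeps only rows whose feature type is `gene`; coordinates stay 1-based
#' inclusive as in GFF3. The gene identifier is taken from the `ID` attribute,
#' falling back to `gene_id`.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (one of `+`, `-`, `.`).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop_user(paste0("GFF not found: ", path))
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    bad <- which(body)[which(nf != 9)[1]]
    stop_user(paste0("Malformed GFF line ", bad, ": expected 9 columns, got ",
                     nf[which(nf != 9)[1]], "."))
  }
  if (!any(body)) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  gff <- ape::read.gff(path)
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  ids <- vapply(as.character(genes$attributes), function(a) {
    v <- sub(".*(?:^|;)\\s*ID=([^;]+).*", "\\1", a)
    if (identical(v, a)) v <- sub(".*(?:^|;)\\s*gene_id=([^;]+).*", "\\1", a)
    if (identical(v, a)) NA_character_ else v
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(ids)) stop_user("A gene feature lacks an ID/gene_id attribute.")
  strand <- as.character(genes$strand)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  tibble(
    gene_id = ids,
    chrom = as.character(genes$seqid),
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = strand
  )
}

#' Write CNVRs to a BED6+2 file
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention (`chromStart = start - 1`, `chromEnd = end`). Columns:
#' chrom, chromStart, chromEnd, name (CNVR id), score (0), strand (`.`),
#' type, carrier count.
#'
#' @param cnvrs CNVR tibble sorted by (chrom, start), as from
#'   [merge_to_cnvrs()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_cnvr_bed <- function(cnvrs, path) {
  if (nrow(cnvrs) > 0) {
    srt <- sort_genomic(cnvrs)
    if (!identical(srt$cnvr_id, cnvrs$cnvr_id)) {
      stop_user("CNVRs must be sorted by (chrom, start) before BED export.")
    }
  }
  bed <- tibble(
    chrom = cnvrs$chrom,
    chromStart = cnvrs$start - 1L,
    chromEnd = cnvrs$end,
    name = cnvrs$cnvr_id,
    score = 0L,
    strand = ".",
    type = cnvrs$type,
    n_carriers = cnvrs$n_carriers
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read CNVRs back from a BED6+2 file written by [write_cnvr_bed()]
#'
#' @param path BED file path.
#' @return CNVR tibble with 1-based inclusive `start`/`end`.
#' @export
read_cnvr_bed <- function(path) {
  bed <- readr::read_tsv(
    path, col_names = c("chrom", "chromStart", "chromEnd", "name", "score",
                        "strand", "type", "n_carriers"),
    col_types = "ciicicci", show_col_types = FALSE
  )
  tibble(
    cnvr_id = bed$name,
    chrom = bed$chrom,
    start = bed$chromStart + 1L,
    end = bed$chromEnd,
    length = bed$chromEnd - bed$chromStart,
    type = bed$type,
    n_carriers = bed$n_carriers
  )
}

#' Write a CNVR table as TSV
#'
#' @param cnvrs CNVR tibble.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_cnvr_tsv <- function(cnvrs, path) {
  cols <- intersect(
    c("cnvr_id", "chrom", "start", "end", "length", "type", "n_carriers",
      "frequency"),
    names(cnvrs)
  )
  readr::write_tsv(cnvrs[cols], path)
  invisible(path)
}
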