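# End-to-end orchestration: read -> size filter -> merge -> classify ->
# genotype -> frequency filter -> GRM -> per-trait REML + GWAS -> threshold ->
# annotate -> summarize.

#' Build a pipeline configuration
#'
#' All stage constants default to the package's standard analysis settings:
#' 50 bp-5 Mb size window, 0.5% carrier-frequency filter, Bonferroni 0.05,
#' 50 kb annotation flank, ridge 1e-6.
#'
#' @param vcf,phenotypes,chromosomes,gff Input file paths (`gff` optional:
#'   `NULL` disables annotation).
#' @param out_dir Output directory (created if absent).
#' @param traits Character vector of trait columns to scan; default all
#'   phenotype columns.
#' @param covariates Optional fixed-effect columns.
#' @param min_bp,max_bp Size window applied to calls and to merged CNVRs.
#' @param min_freq Carrier-frequency filter.
#' @param correction `"bonferroni"` or `"bh"`.
#' @param alpha Significance level.
#' @param ridge GRM diagonal ridge.
#' @param flank Annotation flank (bp).
#' @param require_pass Keep only FILTER "pass" records.
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, phenotypes, chromosomes, gff = NULL,
                            out_dir = "cnvrgwas_out", traits = NULL,
                            covariates = NULL, min_bp = 50, max_bp = 5e6,
                            min_freq = 0.005,
                            correction = c("bonferroni", "bh"), alpha = 0.05,
                            ridge = 1e-6, flank = 50000, require_pass = TRUE,
                            seed = 1) {
  structure(
    list(vcf = vcf, phenotypes = phenotypes, chromosomes = chromosomes,
         gff = gff, out_dir = out_dir, traits = traits,
         covariates = covariates, min_bp = min_bp, max_bp = max_bp,
         min_freq = min_freq, correction = match.arg(correction),
         alpha = alpha, ridge = ridge, flank = flank,
         require_pass = require_pass, seed = seed),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `overrides`
#' (a named list) wins over file values.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) {
    stop_user(paste0("Config file not found: ", path))
  }
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop_user(paste0("Unknown config key: ", unknown[1]))
  }
  do.call(pipeline_config, vals)
}

#' Run the CNVR-GWAS pipeline end to end
#'
#' Executes every stage in order, writes all artifacts under
#' `cfg$out_dir` (CNVR TSV and BED, per-chromosome summary, type and size
#' distributions, per-trait association TSVs, annotated significant hits,
#' Manhattan/QQ data, a log with per-stage row counts, and a machine-readable
#' `manifest.json`), and returns the in-memory results. Re-running with
#' identical inputs and configuration reproduces the outputs bit for bit.
#'
#' @param cfg A `pipeline_config` (or path to a YAML accepted by
#'   [load_pipeline_config()]).
#' @return Invisibly, a list with `cnvrs`, `genotypes`, `grm`, `summary`,
#'   `associations` (named by trait), `annotated_hits`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- load_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  for (f in c("vcf", "phenotypes", "chromosomes")) {
    if (!file.exists(cfg[[f]])) {
      stop_user(paste0("Input '", f, "' not found: ", cfg[[f]]))
    }
  }
  if (!is.null(cfg$gff) && !file.exists(cfg$gff)) {
    stop_user(paste0("Input 'gff' not found: ", cfg$gff))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  logf <- function(...) cat(paste0(..., "\n"), file = log_path, append = TRUE)
  cat("", file = log_path)
  counts <- list()

  chroms <- read_chromosome_table(cfg$chromosomes)
  phen <- read_phenotypes(cfg$phenotypes)
  traits <- cfg$traits %||% setdiff(names(phen), "sample_id")

  calls <- read_cnv_vcf(cfg$vcf, require_pass = cfg$require_pass)
  counts$calls_read <- nrow(calls)
  logf("calls read: ", nrow(calls))

  calls <- filter_calls_by_size(calls, cfg$min_bp, cfg$max_bp)
  counts$calls_after_size_filter <- nrow(calls)
  logf("calls after size filter: ", nrow(calls))

  cnvrs <- merge_to_cnvrs(calls)
  cnvrs <- filter_cnvrs_by_size(cnvrs, cfg$min_bp, cfg$max_bp)
  counts$cnvrs <- nrow(cnvrs)
  logf("CNVRs after merge + size filter: ", nrow(cnvrs))

  samples <- phen$sample_id
  gm <- build_genotype_matrix(cnvrs, samples)
  gm_f <- frequency_filter(gm, cfg$min_freq)
  counts$cnvrs_after_frequency_filter <- ncol(gm_f$codes)
  logf("CNVR columns after frequency filter: ", ncol(gm_f$codes))

  grm <- compute_grm(gm_f)

  write_cnvr_tsv(cnvrs, file.path(cfg$out_dir, "cnvr.tsv"))
  write_cnvr_bed(cnvrs, file.path(cfg$out_dir, "cnvr.bed"))
  summ <- per_chromosome_summary(cnvrs, chroms)
  readr::write_tsv(summ, file.path(cfg$out_dir, "summary_by_chromosome.tsv"))
  readr::write_tsv(type_distribution(cnvrs),
                   file.path(cfg$out_dir, "type_distribution.tsv"))
  readr::write_tsv(size_distribution(cnvrs),
                   file.path(cfg$out_dir, "size_distribution.tsv"))
  write_grm_tsv(grm, file.path(cfg$out_dir, "grm.tsv"))

  genes <- if (!is.null(cfg$gff)) read_gff(cfg$gff) else NULL

  assoc <- list()
  hits <- list()
  for (tr in traits) {
    res <- run_gwas(gm_f, phen, tr, grm, covariates = cfg$covariates,
                    alpha = cfg$alpha, correction = cfg$correction,
                    ridge = cfg$ridge)
    counts[[paste0("samples_", tr)]] <- res$n_used[1]
    logf("trait ", tr, ": n = ", res$n_used[1], ", significant = ",
         sum(res$significant))
    out <- dplyr::left_join(
      res, cnvrs[, c("cnvr_id", "chrom", "start", "end", "type")],
      by = "cnvr_id")
    out <- dplyr::relocate(out, "chrom", "start", "end", "type",
                           .after = "cnvr_id")
    readr::write_tsv(out, file.path(cfg$out_dir, paste0("gwas_", tr, ".tsv")))
    mq <- manhattan_qq_data(res, cnvrs, chroms)
    readr::write_tsv(mq$manhattan,
                     file.path(cfg$out_dir, paste0("manhattan_", tr, ".tsv")))
    readr::write_tsv(mq$qq, file.path(cfg$out_dir, paste0("qq_", tr, ".tsv")))
    assoc[[tr]] <- out

    sig <- out[out$significant & !out$degenerate, , drop = FALSE]
    if (!is.null(genes) && nrow(sig) > 0) {
      ann <- proximal_genes(cnvrs[cnvrs$cnvr_id %in% sig$cnvr_id, ],
                            genes, flank = cfg$flank)
      if (nrow(ann) > 0) ann <- dplyr::mutate(ann, trait = tr, .before = 1)
      hits[[tr]] <- ann
    }
  }
  annotated <- dplyr::bind_rows(hits)
  if (!is.null(genes)) {
    readr::write_tsv(annotated, file.path(cfg$out_dir, "annotated_hits.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cnvrgwas")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cnvrs = cnvrs, genotypes = gm_f, grm = grm, summary = summ,
                 associations = assoc, annotated_hits = annotated,
                 manifest = manifest))
}
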