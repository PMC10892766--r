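# Seeded simulator of CNV landscapes, call-level VCFs and phenotypes with
# known architecture, used so every pipeline stage is testable without
# external data.

#' Default chicken autosome table
#'
#' The 38 autosome lengths shipped with the package (from a published chicken
#' assembly), used as the default simulation coordinate system.
#'
#' @return Chromosome tibble (`chrom`, `length`).
#' @export
chicken_autosomes <- function() {
  read_chromosome_table(system.file("extdata", "chicken_autosomes.tsv",
                                    package = "cnvrgwas"))
}

#' Simulation configuration
#'
#' Defaults emulate the CNVR landscape of a large laying-hen resequencing
#' population: 834 samples; type mix 94.7% loss / 4.4% gain / 0.9% mixed;
#' sizes drawn log-uniformly within bins 50 bp-1 kb / 1-5 kb / 5-10 kb /
#' 10-50 kb / >50 kb with masses 87.4 / 9.6 / 1.3 / 1.5 / 0.2%; carrier
#' frequencies Beta(1, 19)-distributed rescaled to (0.001, 0.5) (median about
#' 1.8%, so most regions are rare); polygenic heritability 0.3, a mid-range
#' value for poultry growth and egg traits. `n_cnvr` defaults to 2,000 — a
#' desk-scale landscape with the same composition.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_samples Number of individuals.
#' @param chromosomes Chromosome tibble (default [chicken_autosomes()]).
#' @param n_cnvr Number of non-overlapping regions to place.
#' @param type_proportions Named or ordered numeric (loss, gain, mixed),
#'   summing to 1.
#' @param size_bin_edges,size_bin_masses Size-mixture bins (bp) and masses
#'   (must sum to 1). The last bin is bounded above by `size_max_bp`.
#' @param size_max_bp Upper bound of the largest size bin.
#' @param carrier_freq_shape Beta shape parameters for carrier frequency,
#'   rescaled to `carrier_freq_range`.
#' @param carrier_freq_range Interval of attainable carrier frequencies.
#' @param n_causal Number of causal CNVRs for phenotype simulation.
#' @param causal_variance_fractions Phenotypic variance fraction explained by
#'   each causal CNVR (length `n_causal`).
#' @param h2_polygenic Polygenic heritability (variance of u on a unit-variance
#'   trait).
#' @param mu Trait mean.
#' @param trait_name Name of the simulated trait column.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_samples = 834,
                              chromosomes = chicken_autosomes(),
                              n_cnvr = 2000,
                              type_proportions = c(loss = 0.947, gain = 0.044,
                                                   mixed = 0.009),
                              size_bin_edges = c(50, 1000, 5000, 10000, 50000),
                              size_bin_masses = c(0.874, 0.096, 0.013, 0.015,
                                                  0.002),
                              size_max_bp = 642753,
                              carrier_freq_shape = c(1, 19),
                              carrier_freq_range = c(0.001, 0.5),
                              n_causal = 0,
                              causal_variance_fractions = numeric(0),
                              h2_polygenic = 0.3,
                              mu = 0,
                              trait_name = "trait") {
  if (abs(sum(type_proportions) - 1) > 1e-9) {
    stop_user("type_proportions must sum to 1.")
  }
  if (abs(sum(size_bin_masses) - 1) > 1e-9) {
    stop_user("size_bin_masses must sum to 1.")
  }
  if (length(causal_variance_fractions) != n_causal) {
    stop_user("causal_variance_fractions must have length n_causal.")
  }
  if (h2_polygenic < 0 || h2_polygenic >= 1) {
    stop_user("h2_polygenic must be in [0, 1).")
  }
  if (sum(causal_variance_fractions) + h2_polygenic >= 1) {
    stop_user("Causal fractions plus polygenic h2 must leave residual variance.")
  }
  structure(
    list(seed = seed, n_samples = n_samples, chromosomes = chromosomes,
         n_cnvr = n_cnvr, type_proportions = type_proportions,
         size_bin_edges = size_bin_edges, size_bin_masses = size_bin_masses,
         size_max_bp = size_max_bp, carrier_freq_shape = carrier_freq_shape,
         carrier_freq_range = carrier_freq_range, n_causal = n_causal,
         causal_variance_fractions = causal_variance_fractions,
         h2_polygenic = h2_polygenic, mu = mu, trait_name = trait_name),
    class = "sim_config"
  )
}

sim_sample_ids <- function(cfg) sprintf("S%04d", seq_len(cfg$n_samples))

#' Simulate a CNVR landscape
#'
#' Places `n_cnvr` non-overlapping regions by rejection sampling (chromosome
#' chosen proportional to length, start uniform), draws type and size from the
#' configured mixtures and a carrier set per region from the carrier-frequency
#' distribution (at least one carrier; mixed regions get at least two, split
#' between a deletion and a duplication subset so the classifier is genuinely
#' exercised). Deterministic given `cfg$seed`.
#'
#' @param cfg A `sim_config`.
#' @return List with `cnvrs` (CNVR-shaped tibble: `cnvr_id`, `chrom`, `start`,
#'   `end`, `length`, `type`, `n_carriers`, `frequency`, plus carrier list
#'   columns) and `truth` (the same tibble plus the configuration — ground
#'   truth for recovery tests).
#' @export
simulate_cnv_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- cfg$chromosomes
  n <- cfg$n_cnvr
  empty <- tibble(
    cnvr_id = character(), chrom = character(), start = integer(),
    end = integer(), length = integer(), type = character(),
    n_carriers = integer(), frequency = numeric(),
    carriers = list(), del_carriers = list(), dup_carriers = list()
  )
  if (n == 0) {
    return(list(cnvrs = empty, truth = list(regions = empty, config = cfg)))
  }

  edges_lo <- cfg$size_bin_edges
  edges_hi <- c(cfg$size_bin_edges[-1], cfg$size_max_bp)
  placed <- vector("list", n)
  occupied <- lapply(setNames(vector("list", nrow(chroms)), chroms$chrom),
                     function(x) NULL)
  attempts <- 0L
  max_attempts <- 200L * n
  k <- 0L
  while (k < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop_user(paste0("Could not place ", n, " non-overlapping regions; ",
                       "use fewer or smaller regions."))
    }
    bin <- sample.int(length(edges_lo), 1, prob = cfg$size_bin_masses)
    size <- round(exp(stats::runif(1, log(edges_lo[bin]),
                                   log(edges_hi[bin]))))
    size <- max(edges_lo[1], min(size, cfg$size_max_bp))
    ci <- sample.int(nrow(chroms), 1, prob = chroms$length)
    L <- chroms$length[ci]
    if (size > L) next
    start <- sample.int(L - size + 1L, 1)
    end <- start + size - 1L
    occ <- occupied[[chroms$chrom[ci]]]
    if (!is.null(occ) && any(start <= occ[, 2] & end >= occ[, 1])) next
    occupied[[chroms$chrom[ci]]] <- rbind(occ, c(start, end))
    k <- k + 1L
    placed[[k]] <- tibble(chrom = chroms$chrom[ci], start = start, end = end)
  }
  regions <- dplyr::bind_rows(placed)
  regions$length <- regions$end - regions$start + 1L
  regions$type <- sample(names(cfg$type_proportions), n, replace = TRUE,
                         prob = cfg$type_proportions)
  shp <- cfg$carrier_freq_shape
  rng <- cfg$carrier_freq_range
  freq <- rng[1] + (rng[2] - rng[1]) * stats::rbeta(n, shp[1], shp[2])

  ids <- sim_sample_ids(cfg)
  regions$carriers <- purrr::map2(freq, regions$type, function(f, ty) {
    k_min <- if (ty == "mixed") 2L else 1L
    nc <- max(k_min, stats::rbinom(1, cfg$n_samples, f))
    sort(sample(ids, nc))
  })
  regions$del_carriers <- purrr::map2(regions$carriers, regions$type,
    function(cr, ty) {
      if (ty == "gain") character(0)
      else if (ty == "loss") cr
      else {
        n_del <- sample.int(length(cr) - 1L, 1)
        sort(sample(cr, n_del))
      }
    })
  regions$dup_carriers <- purrr::map2(regions$carriers, regions$del_carriers,
                                      ~ sort(setdiff(.x, .y)))
  regions$n_carriers <- lengths(regions$carriers)
  regions$frequency <- regions$n_carriers / cfg$n_samples

  regions <- sort_genomic(regions)
  prefix <- c(loss = "DEL", gain = "DUP", mixed = "MIX")[regions$type]
  regions$cnvr_id <- sprintf("%s%08d", prefix, seq_len(nrow(regions)))
  regions <- regions[, c("cnvr_id", "chrom", "start", "end", "length", "type",
                         "n_carriers", "frequency", "carriers",
                         "del_carriers", "dup_carriers")]
  list(cnvrs = regions, truth = list(regions = regions, config = cfg))
}

#' Genotype matrix implied by a simulated landscape
#'
#' Codes loss carriers -1, gain carriers +1; mixed regions code their deletion
#' subset -1 and duplication subset +1.
#'
#' @param sim Output of [simulate_cnv_landscape()].
#' @return A `cnv_geno`.
#' @export
genotypes_from_landscape <- function(sim) {
  regions <- sim$truth$regions
  cfg <- sim$truth$config
  ids <- sim_sample_ids(cfg)
  codes <- matrix(0L, nrow = length(ids), ncol = nrow(regions))
  for (j in seq_len(nrow(regions))) {
    codes[match(regions$del_carriers[[j]], ids), j] <- -1L
    codes[match(regions$dup_carriers[[j]], ids), j] <- 1L
  }
  new_cnv_geno(codes, ids, regions$cnvr_id)
}

#' Write a simulated landscape as a multi-sample structural-variant VCF
#'
#' Emits one DEL or DUP record per region-carrier cluster (mixed regions
#' become one DEL plus one DUP record over the same span, so merging recovers
#' a mixed region) with per-sample GT fields (`0/1` carriers, `0/0`
#' otherwise), FILTER `PASS`, and `SVTYPE`/`END` INFO keys. With
#' `jitter > 0`, each record's span is independently perturbed by up to
#' `jitter` of its length on each side.
#'
#' @param sim Output of [simulate_cnv_landscape()].
#' @param path Output VCF path.
#' @param jitter Relative boundary noise in `[0, 0.5)`. Default 0.
#' @return Invisibly, the path.
#' @export
simulate_cnv_vcf <- function(sim, path, jitter = 0) {
  regions <- sim$truth$regions
  cfg <- sim$truth$config
  set.seed(cfg$seed + 1L)
  ids <- sim_sample_ids(cfg)
  chroms <- cfg$chromosomes

  rec <- purrr::pmap(
    list(regions$chrom, regions$start, regions$end,
         regions$del_carriers, regions$dup_carriers, regions$cnvr_id),
    function(chrom, start, end, del, dup, id) {
      out <- list()
      if (length(del) > 0) {
        out <- c(out, list(tibble(chrom = chrom, start = start, end = end,
                                  svtype = "DEL", id = paste0(id, "_del"),
                                  carriers = list(del))))
      }
      if (length(dup) > 0) {
        out <- c(out, list(tibble(chrom = chrom, start = start, end = end,
                                  svtype = "DUP", id = paste0(id, "_dup"),
                                  carriers = list(dup))))
      }
      dplyr::bind_rows(out)
    }
  )
  rec <- dplyr::bind_rows(rec)
  if (jitter > 0) {
    L <- setNames(chroms$length, chroms$chrom)
    span <- rec$end - rec$start + 1L
    rec$start <- pmax(1L, rec$start +
                        as.integer(round(stats::runif(nrow(rec), -jitter, jitter) * span)))
    rec$end <- pmin(as.integer(L[rec$chrom]),
                    rec$end +
                      as.integer(round(stats::runif(nrow(rec), -jitter, jitter) * span)))
    rec$end <- pmax(rec$end, rec$start)
  }
  rec <- sort_genomic(rec)

  gt_mat <- vapply(rec$carriers, function(cr) {
    ifelse(ids %in% cr, "0/1", "0/0")
  }, character(length(ids)))
  gt_mat <- matrix(gt_mat, nrow = length(ids))

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cnvrgwas_simulator",
    paste0("##contig=<ID=", chroms$chrom, ",length=",
           format(chroms$length, scientific = FALSE, trim = TRUE), ">"),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(rec)), function(i) {
    paste(c(rec$chrom[i], rec$start[i], rec$id[i], "N",
            paste0("<", rec$svtype[i], ">"), ".", "PASS",
            paste0("SVTYPE=", rec$svtype[i], ";END=", rec$end[i]),
            "GT", gt_mat[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate phenotypes under the mixed model
#'
#' Draws `y = mu + W beta + u + e` with `u ~ N(0, G sigma2_a)` (via the
#' eigendecomposition of the supplied GRM) and `e ~ N(0, I sigma2_e)`. Causal
#' effect sizes are back-computed from the empirical code variance so each
#' causal CNVR explains exactly its configured variance fraction;
#' `sigma2_a = h2_polygenic` and `sigma2_e = 1 - h2_polygenic - sum(fractions)`
#' so the trait has unit variance in expectation.
#'
#' @param gm A `cnv_geno` over the simulated samples.
#' @param grm A `cnv_grm` over the same samples.
#' @param cfg The `sim_config` (fields `n_causal`,
#'   `causal_variance_fractions`, `h2_polygenic`, `mu`, `trait_name`, `seed`).
#' @param causal_ids Optional CNVR ids to make causal; by default drawn among
#'   columns with carrier frequency of at least 0.02 (falling back to any
#'   non-constant column).
#' @return List with `phenotypes` (tibble `sample_id` + trait column) and
#'   `truth` (causal ids, effects, variance fractions, polygenic values,
#'   variance components).
#' @export
simulate_phenotypes <- function(gm, grm, cfg, causal_ids = NULL) {
  stopifnot(inherits(gm, "cnv_geno"), inherits(grm, "cnv_grm"),
            inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n <- length(gm$sample_ids)
  codes <- gm$codes
  col_var <- colMeans(codes^2) - colMeans(codes)^2

  if (cfg$n_causal > 0) {
    if (is.null(causal_ids)) {
      pool <- gm$cnvr_ids[gm$frequencies >= 0.02 & col_var > 0]
      if (length(pool) < cfg$n_causal) pool <- gm$cnvr_ids[col_var > 0]
      if (length(pool) < cfg$n_causal) {
        stop_user("Not enough non-constant CNVRs to draw causal loci.")
      }
      causal_ids <- sample(pool, cfg$n_causal)
    }
    jc <- match(causal_ids, gm$cnvr_ids)
    if (anyNA(jc)) stop_user("Causal CNVR id absent from genotype matrix.")
    if (any(col_var[jc] == 0)) {
      stop_user("A causal CNVR has zero code variance.")
    }
    effects <- sqrt(cfg$causal_variance_fractions / col_var[jc])
    causal_term <- codes[, jc, drop = FALSE] %*% effects
  } else {
    causal_ids <- character(0)
    effects <- numeric(0)
    causal_term <- rep(0, n)
  }

  sigma2_a <- cfg$h2_polygenic
  sigma2_e <- 1 - cfg$h2_polygenic - sum(cfg$causal_variance_fractions)
  if (sigma2_a > 0) {
    eig <- eigen(grm$values, symmetric = TRUE)
    u <- drop(eig$vectors %*% (sqrt(pmax(eig$values, 0)) * stats::rnorm(n))) *
      sqrt(sigma2_a)
  } else {
    u <- rep(0, n)
  }
  e <- stats::rnorm(n, sd = sqrt(sigma2_e))
  y <- cfg$mu + drop(causal_term) + u + e

  phen <- tibble(sample_id = gm$sample_ids)
  phen[[cfg$trait_name]] <- y
  list(
    phenotypes = phen,
    truth = list(causal_ids = causal_ids, effects = effects,
                 causal_variance_fractions = cfg$causal_variance_fractions,
                 h2_polygenic = cfg$h2_polygenic,
                 sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 polygenic = u, mu = cfg$mu)
  )
}

#' Write a phenotype table and chromosome table for a simulation
#'
#' @param phenotypes Phenotype tibble.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_phenotypes_tsv <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path)
  invisible(path)
}
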