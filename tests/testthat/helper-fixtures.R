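# Shared fixture builders and independent oracles. Everything is generated in
# code; no binary files.

# Write a small structural-variant VCF from a record table.
# records: tibble/data.frame with chrom, pos, id, svtype, end, filter and a
# list column gts of per-sample GT strings (one per sample, in `samples`
# order).
write_test_vcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(records)), function(i) {
    info <- paste0("SVTYPE=", records$svtype[i])
    if (!is.na(records$end[i])) info <- paste0(info, ";END=", records$end[i])
    paste(c(records$chrom[i], records$pos[i], records$id[i], "N",
            paste0("<", records$svtype[i], ">"), ".", records$filter[i],
            info, "GT", records$gts[[i]]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Independent text-level oracle for read_cnv_vcf: re-derive (record, carrier)
# pairs straight from the file lines.
brute_force_vcf_calls <- function(path, require_pass = TRUE) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  out <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    if (require_pass && !grepl("pass", f[7], ignore.case = TRUE)) next
    sv <- sub(".*SVTYPE=([^;]+).*", "\\1", f[8])
    if (!sv %in% c("DEL", "DUP")) next
    end <- as.integer(sub(".*END=([0-9]+).*", "\\1", f[8]))
    gts <- f[-(1:9)]
    carrier <- vapply(gts, function(g) {
      any(strsplit(g, "[/|]")[[1]] == "1")
    }, logical(1))
    if (any(carrier)) {
      out[[length(out) + 1]] <- data.frame(
        sample_id = samples[carrier], chrom = f[1], start = as.integer(f[2]),
        end = end, svtype = sv, stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    df <- data.frame(sample_id = character(), chrom = character(),
                     start = integer(), end = integer(), svtype = character())
  }
  df[order(df$chrom, df$start, df$sample_id, df$svtype), , drop = FALSE]
}

# Random call table on short chromosomes (for merge/filter properties).
random_calls <- function(n, seed, chrom_len = 10000, n_chrom = 2,
                         n_samples = 6, max_len = 400) {
  set.seed(seed)
  start <- sample.int(chrom_len - max_len, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(
    sample_id = sample(sprintf("S%02d", seq_len(n_samples)), n, replace = TRUE),
    chrom = sample(as.character(seq_len(n_chrom)), n, replace = TRUE),
    start = start,
    end = start + len - 1L,
    svtype = sample(c("DEL", "DUP"), n, replace = TRUE, prob = c(0.8, 0.2)),
    filter_status = "PASS"
  )
}

# Per-base boolean-track oracle for the covered-base UNION (note a boolean
# track cannot distinguish book-ended from overlapping intervals, so it is
# only used for union equality, never for region boundaries).
brute_force_union_bp <- function(calls, chrom_len = 20000) {
  total <- 0L
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, ]
    track <- logical(chrom_len)
    for (i in seq_len(nrow(cc))) track[cc$start[i]:cc$end[i]] <- TRUE
    total <- total + sum(track)
  }
  total
}

# Sweep-line oracle for the merged regions themselves: strict >= 1 bp overlap
# (book-ended intervals are NOT joined), independent of the IRanges path.
brute_force_merge <- function(calls) {
  out <- list()
  for (ch in sort(unique(calls$chrom))) {
    cc <- calls[calls$chrom == ch, ]
    cc <- cc[order(cc$start, cc$end), ]
    cur_s <- cc$start[1]; cur_e <- cc$end[1]
    regions <- NULL
    for (i in seq_len(nrow(cc))[-1]) {
      if (cc$start[i] <= cur_e) {
        cur_e <- max(cur_e, cc$end[i])
      } else {
        regions <- rbind(regions, c(cur_s, cur_e))
        cur_s <- cc$start[i]; cur_e <- cc$end[i]
      }
    }
    regions <- rbind(regions, c(cur_s, cur_e))
    out[[ch]] <- data.frame(chrom = ch, start = regions[, 1],
                            end = regions[, 2])
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# Dense GLS oracle: explicit V inverse, no rotation tricks.
dense_gls <- function(y, X, V) {
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  sigma2 <- drop(t(r) %*% Vi %*% r) / (length(y) - ncol(X))
  se <- sqrt(sigma2 * diag(solve(XtVX)))
  list(beta = drop(beta), se = se, sigma2 = sigma2)
}

# Minimal hand-built cnv_geno / cnv_grm / cnvr_reml constructors for oracle
# tests that need full control over the inputs.
make_geno <- function(codes, samples = sprintf("S%02d", seq_len(nrow(codes))),
                      ids = sprintf("CNVR%03d", seq_len(ncol(codes)))) {
  cnvrgwas:::new_cnv_geno(codes, samples, ids)
}

make_grm <- function(G, samples = sprintf("S%02d", seq_len(nrow(G)))) {
  dimnames(G) <- list(samples, samples)
  structure(list(values = G, sample_ids = samples,
                 n_markers = NA_integer_, n_dropped = 0L),
            class = "cnv_grm")
}

# Build a cnvr_reml object at a FIXED h2 (no estimation), for tests of the
# per-marker GLS against dense oracles.
make_reml_fit <- function(y, G, h2, X = cbind(`(Intercept)` = rep(1, length(y))),
                          samples = sprintf("S%02d", seq_along(y))) {
  eig <- eigen(G, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  prof <- cnvrgwas:::reml_profile(max(h2, 1e-12), d, yt, Xt)
  structure(
    list(trait = "y", n = length(y), p = ncol(Xt), h2 = h2,
         sigma2 = prof$sigma2, sigma2_a = h2 * prof$sigma2,
         sigma2_e = (1 - h2) * prof$sigma2, reml_loglik = prof$loglik,
         sample_ids = samples, d = d, U = U, ytilde = yt, Xtilde = Xt,
         ridge = 0, h2_bounds = c(1e-6, 1 - 1e-6)),
    class = "cnvr_reml"
  )
}

# Simulated regime used across statistical tests: landscape + genotypes + GRM.
sim_geno_grm <- function(seed, n_samples, n_cnvr, min_freq = 0, ...) {
  cfg <- simulation_config(seed = seed, n_samples = n_samples,
                           n_cnvr = n_cnvr, ...)
  sim <- simulate_cnv_landscape(cfg)
  gm <- genotypes_from_landscape(sim)
  if (min_freq > 0) gm <- frequency_filter(gm, min_freq)
  grm <- compute_grm(gm)
  list(cfg = cfg, sim = sim, gm = gm, grm = grm)
}

# Small GFF3 writer for annotation/pipeline tests.
write_test_gff <- function(genes, path = tempfile(fileext = ".gff3"),
                           extra_lines = character(0)) {
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(genes)), function(i) {
               paste(genes$chrom[i], "test", genes$type[i],
                     genes$start[i], genes$end[i], ".",
                     genes$strand[i], ".",
                     paste0("ID=", genes$gene_id[i]),
                     sep = "\t")
             }, character(1)),
             extra_lines)
  writeLines(lines, path)
  path
}
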