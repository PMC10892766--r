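test_that("Bonferroni threshold is alpha over the number of CNVRs", {
  expect_equal(significance_threshold(11035), 0.05 / 11035)
  expect_equal(significance_threshold(11035), 4.5310e-6, tolerance = 1e-4)
  expect_equal(significance_threshold(1), 0.05)
  expect_error(significance_threshold(0), "positive")
})

test_that("fast EMMAX-style scan agrees with the exact per-marker refit", {
  # polygenic-only regime: with no single strong marker the per-marker
  # variance-component refit stays near the null estimate
  reg <- sim_geno_grm(seed = 51, n_samples = 200, n_cnvr = 60,
                      h2_polygenic = 0.4)
  ph <- simulate_phenotypes(reg$gm, reg$grm, reg$cfg)
  gm <- frequency_filter(reg$gm, 0.01)
  fast <- run_gwas(gm, ph$phenotypes, "trait", reg$grm)
  exact <- run_gwas(gm, ph$phenotypes, "trait", reg$grm, method = "exact")
  ok <- !fast$degenerate
  dlp <- abs(log10(fast$p_value[ok]) - log10(exact$p_value[ok]))
  expect_lte(max(dlp), 0.3)
})

test_that("a causal CNVR is the top association and permutation destroys it", {
  reg <- sim_geno_grm(seed = 52, n_samples = 400, n_cnvr = 200,
                      h2_polygenic = 0.3, n_causal = 1,
                      causal_variance_fractions = 0.1)
  ph <- simulate_phenotypes(reg$gm, reg$grm, reg$cfg)
  res <- run_gwas(reg$gm, ph$phenotypes, "trait", reg$grm)
  expect_equal(res$cnvr_id[which.min(res$p_value)], ph$truth$causal_ids)

  # permuting the phenotype breaks the association
  set.seed(1)
  perm <- ph$phenotypes
  perm$trait <- sample(perm$trait)
  res_p <- run_gwas(reg$gm, perm, "trait", reg$grm)
  expect_gt(res_p$p_value[match(ph$truth$causal_ids, res_p$cnvr_id)], 0.001)
  expect_lte(abs(median(res_p$p_value[!res_p$degenerate]) - 0.5), 0.1)
})

test_that("p-values are invariant to shifting and scaling the phenotype", {
  reg <- sim_geno_grm(seed = 53, n_samples = 150, n_cnvr = 80,
                      h2_polygenic = 0.3)
  ph <- simulate_phenotypes(reg$gm, reg$grm, reg$cfg)
  res <- run_gwas(reg$gm, ph$phenotypes, "trait", reg$grm)

  shifted <- ph$phenotypes
  shifted$trait <- shifted$trait + 100
  res_s <- run_gwas(reg$gm, shifted, "trait", reg$grm)
  expect_equal(res_s$p_value, res$p_value, tolerance = 1e-6)

  scaled <- ph$phenotypes
  scaled$trait <- scaled$trait * 3
  res_c <- run_gwas(reg$gm, scaled, "trait", reg$grm)
  expect_equal(res_c$p_value, res$p_value, tolerance = 1e-6)
  ok <- !res$degenerate
  expect_equal(res_c$beta[ok], 3 * res$beta[ok], tolerance = 1e-6)
})

test_that("identical inputs give bit-identical result tables", {
  reg <- sim_geno_grm(seed = 54, n_samples = 100, n_cnvr = 60,
                      h2_polygenic = 0.2)
  ph <- simulate_phenotypes(reg$gm, reg$grm, reg$cfg)
  r1 <- run_gwas(reg$gm, ph$phenotypes, "trait", reg$grm)
  r2 <- run_gwas(reg$gm, ph$phenotypes, "trait", reg$grm)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$beta, r2$beta)
})

test_that("BH mode reports q-values that match a hand-rolled step-up", {
  reg <- sim_geno_grm(seed = 55, n_samples = 150, n_cnvr = 100,
                      h2_polygenic = 0.2, n_causal = 1,
                      causal_variance_fractions = 0.1)
  ph <- simulate_phenotypes(reg$gm, reg$grm, reg$cfg)
  res <- run_gwas(reg$gm, ph$phenotypes, "trait", reg$grm, correction = "bh")
  expect_true("q_value" %in% names(res))
  # hand BH: sort ascending, q_i = min over j >= i of m p_(j) / j
  p <- res$p_value
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q_hand <- numeric(m)
  q_hand[o] <- pmin(q_sorted, 1)
  expect_equal(res$q_value, q_hand, tolerance = 1e-12)
  expect_equal(res$significant, res$q_value <= 0.05)
})

test_that("trait errors: absent or entirely missing traits are rejected", {
  reg <- sim_geno_grm(seed = 56, n_samples = 50, n_cnvr = 40)
  phen <- tibble::tibble(sample_id = reg$gm$sample_ids,
                         trait = NA_real_)
  expect_error(run_gwas(reg$gm, phen, "other", reg$grm), "not found")
  expect_error(run_gwas(reg$gm, phen, "trait", reg$grm), "entirely missing")
})

test_that("manhattan and qq data are coherent with the scan", {
  reg <- sim_geno_grm(seed = 57, n_samples = 120, n_cnvr = 150,
                      h2_polygenic = 0.2)
  ph <- simulate_phenotypes(reg$gm, reg$grm, reg$cfg)
  res <- run_gwas(reg$gm, ph$phenotypes, "trait", reg$grm)
  mq <- manhattan_qq_data(res, reg$sim$cnvrs, reg$cfg$chromosomes)
  expect_equal(nrow(mq$manhattan), nrow(res))
  # cumulative offsets strictly increase across chromosome boundaries
  man <- mq$manhattan
  expect_true(all(diff(man$pos_cum) > 0))
  # -log10 p of a p-value of 0.01 is exactly 2
  fake <- res[1, ]
  fake$p_value <- 0.01
  mq1 <- manhattan_qq_data(fake, reg$sim$cnvrs)
  expect_equal(mq1$manhattan$neg_log10_p, 2.0)
  # unknown result id errors
  bad <- res
  bad$cnvr_id[1] <- "NOPE"
  expect_error(manhattan_qq_data(bad, reg$sim$cnvrs), "no CNVR")
})

test_that("genomic inflation is near 1 for uniform p-values", {
  set.seed(58)
  m <- 2000
  p <- runif(m)
  res <- tibble::tibble(
    cnvr_id = sprintf("DEL%08d", 1:m), beta = 0, se = 1,
    wald_chi2 = qchisq(p, 1, lower.tail = FALSE), p_value = p,
    n_used = 100L, significant = FALSE, degenerate = FALSE)
  cnvrs <- tibble::tibble(
    cnvr_id = res$cnvr_id, chrom = "1",
    start = seq(1, by = 1000, length.out = m))
  cnvrs$end <- cnvrs$start + 100
  mq <- manhattan_qq_data(res, cnvrs)
  expect_lte(abs(mq$lambda_gc - 1), 0.1)
  expect_equal(nrow(mq$qq), m)
})

test_that("plot builders return ggplot objects", {
  reg <- sim_geno_grm(seed = 59, n_samples = 80, n_cnvr = 60,
                      h2_polygenic = 0.2)
  ph <- simulate_phenotypes(reg$gm, reg$grm, reg$cfg)
  res <- run_gwas(reg$gm, ph$phenotypes, "trait", reg$grm)
  expect_s3_class(plot_manhattan(res, reg$sim$cnvrs), "ggplot")
  expect_s3_class(plot_qq(res, reg$sim$cnvrs), "ggplot")
  expect_s3_class(autoplot(res, reg$sim$cnvrs), "ggplot")
  expect_s3_class(plot_cnvr_landscape(reg$sim$cnvrs, reg$cfg$chromosomes),
                  "ggplot")
  expect_s3_class(plot_size_distribution(size_distribution(reg$sim$cnvrs)),
                  "ggplot")
  expect_s3_class(plot_type_distribution(type_distribution(reg$sim$cnvrs)),
                  "ggplot")
})
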