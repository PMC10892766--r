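make_call <- function(sample, chrom, start, end, svtype) {
  tibble::tibble(sample_id = sample, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), svtype = svtype,
                 filter_status = "PASS")
}

test_that("size filter keeps calls within the inclusive 50 bp - 5 Mb window", {
  calls <- dplyr::bind_rows(
    make_call("A", "1", 100, 148, "DEL"),   # 49 bp: out
    make_call("A", "1", 100, 149, "DEL"),   # 50 bp: in (inclusive)
    make_call("A", "1", 100, 150, "DEL"),   # 51 bp: in
    make_call("A", "1", 1, 5e6, "DUP"),     # 5,000,000 bp: in (inclusive)
    make_call("A", "1", 1, 5e6 + 1, "DUP")  # 5,000,001 bp: out
  )
  kept <- filter_calls_by_size(calls)
  expect_equal(kept$end - kept$start + 1, c(50, 51, 5e6))
  expect_error(filter_calls_by_size(calls, min_bp = 100, max_bp = 50), "min_bp")
})

test_that("size filter agrees with a brute-force length comprehension", {
  calls <- random_calls(1000, seed = 11, max_len = 300)
  kept <- filter_calls_by_size(calls, min_bp = 80, max_bp = 200)
  lens <- calls$end - calls$start + 1
  expect_equal(nrow(kept), sum(lens >= 80 & lens <= 200))
  expect_true(all(kept$end - kept$start + 1 >= 80))
  expect_true(all(kept$end - kept$start + 1 <= 200))
})

test_that("merging forms connected components, typed and sorted", {
  # singleton
  one <- merge_to_cnvrs(make_call("A", "1", 100, 200, "DEL"))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(100, 200))
  expect_equal(one$type, "loss")

  # two overlapping + one separate
  calls <- dplyr::bind_rows(
    make_call("A", "1", 100, 200, "DEL"),
    make_call("B", "1", 150, 250, "DEL"),
    make_call("A", "1", 400, 500, "DEL")
  )
  got <- merge_to_cnvrs(calls)
  expect_equal(got$start, c(100, 400))
  expect_equal(got$end, c(250, 500))
  expect_equal(got$n_carriers, c(2L, 1L))

  # DEL + DUP overlapping -> one mixed region
  mixed <- merge_to_cnvrs(dplyr::bind_rows(
    make_call("A", "1", 100, 200, "DEL"),
    make_call("B", "1", 180, 220, "DUP")
  ))
  expect_equal(nrow(mixed), 1)
  expect_equal(c(mixed$start, mixed$end), c(100, 220))
  expect_equal(mixed$type, "mixed")
  expect_true(startsWith(mixed$cnvr_id, "MIX"))

  # book-ended intervals share no base and stay separate
  touching <- merge_to_cnvrs(dplyr::bind_rows(
    make_call("A", "1", 100, 200, "DEL"),
    make_call("B", "1", 201, 300, "DEL")
  ))
  expect_equal(nrow(touching), 2)

  expect_equal(nrow(merge_to_cnvrs(make_call("A", "1", 1, 2, "DEL")[0, ])), 0)
})

test_that("merge equals the per-base boolean-track oracle and conserves calls", {
  for (seed in c(1, 2, 3)) {
    calls <- random_calls(150, seed = seed)
    got <- merge_to_cnvrs(calls)
    want <- brute_force_merge(calls)
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # conservation: every call in exactly one region
    expect_equal(sum(got$n_calls), nrow(calls))
    # covered bases identical to a per-base boolean-track union
    expect_equal(sum(got$length), brute_force_union_bp(calls))
    # type partition
    td <- type_distribution(got)
    expect_equal(sum(td$n), nrow(got))
  }
})

test_that("merging is idempotent and independent of input order", {
  calls <- random_calls(200, seed = 5)
  got <- merge_to_cnvrs(calls)
  # idempotence: merging the regions themselves returns the same spans
  as_calls <- tibble::tibble(
    sample_id = "X", chrom = got$chrom, start = got$start, end = got$end,
    svtype = "DEL", filter_status = "PASS")
  again <- merge_to_cnvrs(as_calls)
  expect_equal(again$start, got$start)
  expect_equal(again$end, got$end)

  # permuting the calls changes nothing
  set.seed(99)
  shuffled <- merge_to_cnvrs(calls[sample.int(nrow(calls)), ])
  expect_equal(shuffled$start, got$start)
  expect_equal(shuffled$cnvr_id, got$cnvr_id)
  expect_equal(purrr::map_int(shuffled$calls, nrow),
               purrr::map_int(got$calls, nrow))
})

test_that("CNVR classification follows the call-type composition", {
  expect_equal(classify_cnvr(c("DEL", "DEL")), "loss")
  expect_equal(classify_cnvr("DUP"), "gain")
  expect_equal(classify_cnvr(c("DEL", "DUP", "DEL")), "mixed")
  expect_error(classify_cnvr(character(0)), "no calls")
})

test_that("genotype coding matches a hand-enumerated 5x4 call set", {
  # 5 samples, 4 regions; hand-constructed supporting calls
  calls <- dplyr::bind_rows(
    make_call("s1", "1", 100, 199, "DEL"),   # region 1 (100-199)
    make_call("s2", "1", 120, 180, "DEL"),
    make_call("s3", "1", 1000, 1999, "DUP"), # region 2 (1000-1999)
    make_call("s1", "2", 100, 299, "DEL"),   # region 3 mixed (100-350)
    make_call("s4", "2", 250, 350, "DUP"),
    make_call("s5", "2", 5000, 5100, "DUP")  # region 4 (5000-5100)
  )
  cnvrs <- merge_to_cnvrs(calls)
  gm <- build_genotype_matrix(cnvrs, paste0("s", 1:5))
  expected <- rbind(
    c(-1, 0, -1, 0),
    c(-1, 0, 0, 0),
    c(0, 1, 0, 0),
    c(0, 0, 1, 0),
    c(0, 0, 0, 1)
  )
  expect_equal(unname(gm$codes), expected)
  expect_equal(unname(gm$frequencies), c(2, 1, 2, 1) / 5)
  # sample with no calls anywhere -> all-zero row
  gm6 <- build_genotype_matrix(cnvrs, paste0("s", 1:6))
  expect_true(all(gm6$codes[6, ] == 0))
  # unknown sample in calls -> error
  expect_error(build_genotype_matrix(cnvrs, paste0("s", 2:5)), "absent")
})

test_that("a sample with both call types in one region is coded by dominant span", {
  calls <- dplyr::bind_rows(
    make_call("s1", "1", 100, 400, "DEL"),  # 301 bp DEL
    make_call("s1", "1", 350, 450, "DUP"),  # 101 bp DUP, overlaps -> one region
    make_call("s2", "1", 100, 199, "DUP"),
    make_call("s2", "1", 300, 399, "DEL")   # exact tie: 100 vs 100 -> loss
  )
  cnvrs <- merge_to_cnvrs(calls)
  expect_equal(nrow(cnvrs), 1)
  gm <- suppressMessages(build_genotype_matrix(cnvrs, c("s1", "s2", "s3")))
  expect_equal(unname(gm$codes[, 1]), c(-1L, -1L, 0L))
  expect_message(build_genotype_matrix(cnvrs, c("s1", "s2")), "equal DEL and DUP")
})

test_that("frequency filter is strict and matches recounting", {
  # 834 samples: 4 carriers (0.0048) removed, 5 carriers (0.0060) kept
  codes <- matrix(0L, nrow = 834, ncol = 2)
  codes[1:4, 1] <- -1L
  codes[1:5, 2] <- -1L
  gm <- make_geno(codes, samples = sprintf("S%03d", 1:834))
  kept <- frequency_filter(gm, 0.005)
  expect_equal(kept$cnvr_ids, "CNVR002")

  # min_freq = 0: only monomorphic columns removed (strict inequality)
  codes0 <- cbind(c(-1L, 0L, 0L), c(0L, 0L, 0L))
  gm0 <- make_geno(codes0)
  expect_equal(ncol(frequency_filter(gm0, 0)$codes), 1)

  expect_error(frequency_filter(gm0, 1), "min_freq")

  # random matrix: retained set equals brute-force recount
  set.seed(13)
  codes_r <- matrix(sample(c(-1L, 0L, 0L, 0L, 1L), 50 * 40, replace = TRUE),
                    nrow = 50)
  gmr <- make_geno(codes_r)
  kept_r <- frequency_filter(gmr, 0.1)
  manual <- colSums(codes_r != 0) / 50 > 0.1
  expect_equal(kept_r$cnvr_ids, gmr$cnvr_ids[manual])
})
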