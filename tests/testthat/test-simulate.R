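test_that("pure wild-type error-free reads are exact allele substrings", {
  ref <- shared_ref()
  cfg <- simulation_config(n_reads = 200, p_indel = 0, p_hdr = 0,
                           p_hdr_indel = 0, error_rate = 0, seed = 3)
  sim <- simulate_reads(ref, cfg)
  expect_true(all(sim$truth$category == "WT"))
  scid <- ref$sequence
  ok <- vapply(seq_along(sim$reads), function(i) {
    r <- sim$reads[i]
    if (sim$truth$orientation[i] == "revcomp")
      r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    grepl(r, scid, fixed = TRUE)
  }, TRUE)
  expect_true(all(ok))
})

test_that("recurrent-only indel simulation yields 44-bp window deletions", {
  ref <- shared_ref()
  cfg <- simulation_config(n_reads = 150, p_indel = 1, p_hdr = 0,
                           p_hdr_indel = 0, recurrent_del_frac = 1,
                           error_rate = 0, seed = 5)
  sim <- simulate_reads(ref, cfg)
  tr <- sim$truth
  expect_true(all(tr$category == "NHEJ_INDEL"))
  expect_true(all(tr$indel_type == "del"))
  expect_true(all(tr$indel_len == 44L))
  expect_true(all(tr$is_recurrent_deletion))
  cw <- ref$cleavage_window
  expect_true(all(tr$indel_start < cw[2] & tr$indel_start + tr$indel_len > cw[1]))
})

test_that("sampled category fractions follow the configured proportions", {
  ref <- shared_ref()
  n <- 10000
  cfg <- simulation_config(n_reads = n, p_indel = 0.10, p_hdr = 0.18,
                           p_hdr_indel = 0.02, error_rate = 0, seed = 9)
  sim <- simulate_reads(ref, cfg)
  hdr_frac <- mean(sim$truth$category == "HDR_CORRECTED")
  se <- sqrt(0.18 * 0.82 / n)
  expect_lt(abs(hdr_frac - 0.18), 3 * se)
  expect_equal(sum(table(sim$truth$category)), n)   # label conservation
})

test_that("identical configuration reproduces byte-identical outputs", {
  ref <- shared_ref()
  cfg <- simulation_config(n_reads = 300, seed = 77)
  a <- simulate_reads(ref, cfg)
  b <- simulate_reads(ref, cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  fa <- tempfile(fileext = ".fastq"); ta <- tempfile(fileext = ".tsv")
  fb <- tempfile(fileext = ".fastq"); tb <- tempfile(fileext = ".tsv")
  write_simulated_reads(a, fa, ta)
  write_simulated_reads(b, fb, tb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  expect_identical(readBin(ta, "raw", file.size(ta)),
                   readBin(tb, "raw", file.size(tb)))
  unlink(c(fa, ta, fb, tb))
})

test_that("raising the HDR proportion never lowers the HDR truth count", {
  ref <- shared_ref()
  counts <- vapply(c(0.05, 0.10, 0.20), function(p) {
    cfg <- simulation_config(n_reads = 2000, p_indel = 0.1, p_hdr = p,
                             p_hdr_indel = 0, error_rate = 0, seed = 13)
    sum(simulate_reads(ref, cfg)$truth$category == "HDR_CORRECTED")
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("infeasible configurations are rejected", {
  ref <- shared_ref()
  expect_error(simulation_config(p_indel = 0.9, p_hdr = 0.3), "sum to 1")
  # window that excludes the diagnostic positions
  cfg <- simulation_config(n_reads = 10, read_window = c(
    ref$scid_pos + 2L, ref$scid_pos + 2L + 160L))
  expect_error(simulate_reads(ref, cfg), "unclassifiable")
})

test_that("heteroduplex pools match closed-form cleavable fractions", {
  expect_true(all(!make_heteroduplex_pool(c(SCID = 1), 500)$duplexes$cleavable))

  n <- 40000
  pool <- make_heteroduplex_pool(c(SCID = 0.8, mut = 0.2), n, seed = 21)
  se <- sqrt(0.32 * 0.68 / n)
  expect_lt(abs(pool$cleaved_fraction - 0.32), 3 * se)   # 2 * 0.8 * 0.2

  # k equally frequent pairwise-distinct mutants at total p plus WT
  p <- 0.3; k <- 5
  fr <- c(WT = 1 - p, setNames(rep(p / k, k), paste0("m", 1:k)))
  pool <- make_heteroduplex_pool(fr, n, seed = 22)
  expected <- 1 - (1 - p)^2 - p^2 / k
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(pool$cleaved_fraction - expected), 3 * se)

  expect_error(make_heteroduplex_pool(c(a = 0.5, b = 0.4), 10), "sum to 1")
  expect_error(make_heteroduplex_pool(c(a = 1), 0), "empty")
})
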