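test_that("exact substrings align perfectly at their source position", {
  ref <- shared_ref()
  read <- slice0(ref$sequence, 700, 850)
  aln <- align_reads(c(r1 = read), ref)
  expect_true(aln$summary$aligned)
  expect_equal(aln$summary$orientation, "forward")
  expect_equal(aln$summary$ref_start, 700L)
  expect_equal(aln$summary$ref_end, 850L)
  expect_equal(aln$ops$op, "=")
  expect_equal(aln$ops$len, 150L)
})

test_that("the 44-bp deletion is recovered as a single left-aligned operation", {
  ref <- shared_ref()
  rd <- ref$recurrent_del
  molecule <- paste0(slice0(ref$sequence, 0, rd[["start"]]),
                     substr(ref$sequence, rd[["start"]] + rd[["length"]] + 1,
                            nchar(ref$sequence)))
  read <- slice0(molecule, 720, 870)
  aln <- align_reads(c(r1 = read), ref)
  dels <- aln$ops[aln$ops$op == "D", ]
  expect_equal(nrow(dels), 1L)
  expect_equal(dels$len, 44L)
  # leftmost equivalent placement, by exhaustive enumeration on the window
  w0 <- 700L
  slice <- slice0(ref$sequence, w0, w0 + 220L)
  readw <- slice0(molecule, w0, w0 + 220L - 44L)
  expect_equal(dels$ref_start, w0 + brute_leftmost_del(slice, readw, 44L))
})

test_that("indel placement equals the leftmost score-equivalent one", {
  ref <- shared_ref()
  set.seed(11)
  for (i in 1:25) {
    w0 <- sample(200:1200, 1)
    len <- sample(1:6, 1)
    width <- 130L
    slice <- slice0(ref$sequence, w0, w0 + width + len)
    dpos <- sample(30:90, 1)
    read <- paste0(substr(slice, 1, dpos), substr(slice, dpos + len + 1,
                                                  nchar(slice)))
    aln <- align_reads(c(x = read), ref)
    dels <- aln$ops[aln$ops$op == "D", ]
    expect_equal(nrow(dels), 1L, info = paste("del iter", i))
    expect_equal(dels$ref_start, w0 + brute_leftmost_del(slice, read, len),
                 info = paste("del iter", i))

    ins_seq <- random_dna(len)
    slice2 <- slice0(ref$sequence, w0, w0 + width)
    read2 <- paste0(substr(slice2, 1, dpos), ins_seq,
                    substr(slice2, dpos + 1, nchar(slice2)))
    aln2 <- align_reads(c(x = read2), ref)
    ins <- aln2$ops[aln2$ops$op == "I", ]
    expect_equal(nrow(ins), 1L, info = paste("ins iter", i))
    d <- brute_leftmost_ins(slice2, read2, len)
    expect_equal(ins$read_start, d, info = paste("ins iter", i))
    expect_equal(ins$ref_start, w0 + d, info = paste("ins iter", i))
  }
})

test_that("alignment scores agree with an independent dynamic-programming oracle", {
  ref <- shared_ref()
  refd <- Biostrings::DNAString(ref$sequence)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
  set.seed(19)
  for (i in 1:12) {
    s <- sample(100:1400, 1)
    read <- slice0(ref$sequence, s, s + 140L)
    # scatter mismatches and possibly an indel
    for (k in sample(140, 4)) {
      cur <- substr(read, k, k)
      substr(read, k, k) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
    if (i %% 2 == 0) {
      p <- sample(40:100, 1); l <- sample(1:10, 1)
      read <- paste0(substr(read, 1, p), substr(read, p + l + 1, nchar(read)))
    }
    ours <- align_reads(c(x = read), ref)$summary$score
    oracle <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(read), refd, type = "global-local",
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(ours, as.integer(oracle), info = paste("iter", i))
  }
})

test_that("orientation is normalised by alignment score", {
  ref <- shared_ref()
  read <- slice0(ref$sequence, 710, 860)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  aln <- align_reads(c(f = read, r = rc), ref)
  expect_equal(aln$summary$orientation, c("forward", "revcomp"))
  expect_equal(aln$summary$ref_start, c(710L, 710L))
  expect_equal(aln$summary$score, rep(300L, 2))
  expect_identical(aln$oriented[[1]], aln$oriented[[2]])
})

test_that("degenerate reads are handled explicitly", {
  ref <- shared_ref()
  aln <- align_reads(c(n = strrep("N", 100)), ref)
  expect_false(aln$summary$aligned)
  expect_error(align_reads(c(x = random_dna(2000)), ref), "longer")
})
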