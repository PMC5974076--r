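# crafted reads: 150 bp from position 720, covering the diagnostic
# positions, the scid base and the full cleavage window of the shared
# reference

craft <- function(ref, allele = "SCID", del = NULL, subs = NULL,
                  start = 720L, len = 150L) {
  seq <- make_allele(ref, allele)$sequence
  if (!is.null(subs))
    for (p in subs) {
      cur <- substr(seq, p + 1, p + 1)
      substr(seq, p + 1, p + 1) <- c(A = "C", C = "G", G = "T", T = "A")[cur]
    }
  if (!is.null(del))
    seq <- paste0(substr(seq, 1, del[1]), substr(seq, del[1] + del[2] + 1,
                                                 nchar(seq)))
  substr(seq, start + 1, start + len)
}

call_one <- function(ref, read, ...) {
  aln <- align_reads(c(x = read), ref)
  classify_reads(aln, ref, ...)
}

test_that("per-read calling follows the outcome rules", {
  ref <- shared_ref()
  rd <- ref$recurrent_del

  wt <- call_one(ref, craft(ref, "SCID"))
  expect_equal(wt$category, "WT")
  expect_equal(wt$n_diag_subs_matched, 0L)

  nhej <- call_one(ref, craft(ref, "SCID", del = rd))
  expect_equal(nhej$category, "NHEJ_INDEL")
  expect_true(nhej$indel_overlaps_cleavage)
  expect_equal(nhej$indel_len, 44L)

  hdr <- call_one(ref, craft(ref, "CORRECTED"))
  expect_equal(hdr$category, "HDR_CORRECTED")
  expect_equal(hdr$n_diag_subs_matched, 3L)
  expect_false(hdr$indel_overlaps_cleavage)

  both <- call_one(ref, craft(ref, "CORRECTED", del = rd))
  expect_equal(both$category, "HDR_WITH_INDEL")
  expect_equal(both$n_diag_subs_matched, 3L)
  expect_true(both$indel_overlaps_cleavage)

  # partial diagnostic signature without an indel is not "corrected"
  partial <- call_one(ref, craft(ref, "CORRECTED",
                                 subs = ref$diag_subs$pos[1]))
  expect_equal(partial$category, "UNCLASSIFIED")
  expect_lt(partial$n_diag_subs_matched, 3L)

  # diagnostic-complete but too many stray mismatches
  noisy <- call_one(ref, craft(ref, "CORRECTED", subs = c(730L, 745L, 760L)))
  expect_equal(noisy$category, "UNCLASSIFIED")
  expect_equal(noisy$extra_mismatches, 3L)

  # substitutions inside the cleavage window are not indels
  subs_only <- call_one(ref, craft(ref, "SCID", subs = c(833L, 835L)))
  expect_equal(subs_only$category, "WT")
  expect_false(subs_only$indel_overlaps_cleavage)
  expect_equal(subs_only$extra_mismatches, 2L)
})

test_that("the quality filter separates span and identity failures", {
  ref <- shared_ref()
  perfect <- align_reads(c(x = craft(ref, "SCID")), ref)
  f <- passes_quality_filter(perfect, ref)
  expect_true(f$pass)
  expect_equal(f$identity, 1)

  # covers the cleavage window but starts downstream of the diagnostics
  short <- align_reads(c(x = craft(ref, "SCID", start = ref$scid_pos + 3L)),
                       ref)
  f <- passes_quality_filter(short, ref)
  expect_false(f$pass)
  expect_equal(f$reason, "span")

  # heavy mismatching outside the cleavage neighbourhood
  mm_off <- 720L + seq(2L, 78L, by = 4L)           # 20 mismatches
  noisy <- align_reads(c(x = craft(ref, "SCID", subs = mm_off)), ref)
  f <- passes_quality_filter(noisy, ref)
  expect_false(f$pass)
  expect_equal(f$reason, "identity")
  # direct computation: aligned columns outside [cw - 50, cw + 50) are
  # [720, cw[1] - 50), and the mismatches among them are those below it
  nb_lo <- ref$cleavage_window[1] - 50L
  n_out <- nb_lo - 720L
  mm_out <- sum(mm_off < nb_lo)
  expect_equal(f$identity, (n_out - mm_out) / n_out)
})

test_that("insertion boundary rule toggles window involvement", {
  ref <- shared_ref()
  c1 <- ref$cleavage_window[1]
  seq <- ref$sequence
  # insertion anchored exactly at the window start; pick content that
  # cannot left-shift away from the boundary
  left <- substr(seq, c1, c1)
  ins_base <- setdiff(c("A", "C", "G", "T"), left)[1]
  mol <- paste0(substr(seq, 1, c1), strrep(ins_base, 2),
                substr(seq, c1 + 1, nchar(seq)))
  read <- substr(mol, 721, 870)
  closed <- call_one(ref, read,
                     tolerances = classify_tolerances(insertion_window_rule = "closed"))
  open <- call_one(ref, read,
                   tolerances = classify_tolerances(insertion_window_rule = "half-open"))
  expect_equal(closed$category, "NHEJ_INDEL")
  expect_true(closed$indel_overlaps_cleavage)
  expect_equal(open$category, "WT")
  expect_false(open$indel_overlaps_cleavage)
})

test_that("sample summaries use passed-filter denominators and exclude
           indel-associated correction from the headline", {
  mk_calls <- function(categories, passed = TRUE) {
    n <- length(categories)
    data.frame(read_id = sprintf("r%03d", seq_len(n)),
               passed_filter = rep(passed, length.out = n),
               filter_reason = NA_character_, category = categories,
               indel_overlaps_cleavage = categories %in%
                 c("NHEJ_INDEL", "HDR_WITH_INDEL"),
               n_diag_subs_matched = ifelse(grepl("HDR", categories), 3L, 0L),
               extra_mismatches = 0L,
               indel_type = ifelse(categories %in%
                 c("NHEJ_INDEL", "HDR_WITH_INDEL"), "del", NA_character_),
               indel_start = ifelse(categories %in%
                 c("NHEJ_INDEL", "HDR_WITH_INDEL"), 812L, NA_integer_),
               indel_len = ifelse(categories %in%
                 c("NHEJ_INDEL", "HDR_WITH_INDEL"), 44L, NA_integer_),
               stringsAsFactors = FALSE)
  }

  all_wt <- summarize_sample(mk_calls(rep("WT", 100)))
  expect_equal(all_wt$pct_indels, 0)
  expect_equal(all_wt$pct_corrected, 0)

  mix <- summarize_sample(mk_calls(c(rep("WT", 80), rep("NHEJ_INDEL", 18),
                                     rep("UNCLASSIFIED", 2))))
  expect_equal(mix$passed_filter, 100L)
  expect_equal(mix$pct_indels, 18.00)
  expect_equal(sum(mix$counts), mix$passed_filter)
  expect_equal(sum(mix$percentages), 100, tolerance = 0.02)

  corr <- summarize_sample(mk_calls(c(rep("WT", 91), rep("HDR_CORRECTED", 8),
                                      "HDR_WITH_INDEL")))
  expect_equal(corr$pct_corrected, 8.00)
  expect_equal(corr$pct_correction_with_indel_of_total_correction, 11.11)

  empty <- summarize_sample(mk_calls(rep("WT", 5), passed = FALSE))
  expect_true(empty$empty)
  expect_equal(empty$passed_filter, 0L)
  expect_true(is.na(empty$pct_indels))

  expect_equal(nrow(deletion_spectrum(mk_calls(rep("WT", 10)))), 0L)
  spec1 <- deletion_spectrum(mk_calls(rep("NHEJ_INDEL", 10)))
  expect_equal(nrow(spec1), 1L)
  expect_true(spec1$recurrent)
  expect_equal(spec1$del_length, 44L)
})

test_that("classification is invariant to read orientation", {
  ref <- shared_ref()
  cfg <- simulation_config(n_reads = 400, p_indel = 0.3, p_hdr = 0.1,
                           p_hdr_indel = 0.05, error_rate = 0.002, seed = 33)
  sim <- simulate_reads(ref, cfg)
  reads <- setNames(sim$reads, sim$ids)
  fwd <- summarize_sample(classify_reads(align_reads(reads, ref), ref))
  rc <- setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads))), names(reads))
  flip <- summarize_sample(classify_reads(align_reads(rc, ref), ref))
  expect_identical(fwd$counts, flip$counts)
  expect_identical(fwd$deletion_spectrum, flip$deletion_spectrum)
})

test_that("percentages recompute consistently from the per-read call table", {
  ref <- shared_ref()
  cfg <- simulation_config(n_reads = 600, p_indel = 0.25, p_hdr = 0.08,
                           p_hdr_indel = 0.02, error_rate = 0.01, seed = 44)
  sim <- simulate_reads(ref, cfg)
  aln <- align_reads(setNames(sim$reads, sim$ids), ref)
  for (th in list(filter_thresholds(), filter_thresholds(min_identity = 0.99))) {
    calls <- classify_reads(aln, ref, thresholds = th)
    s <- summarize_sample(calls)
    passed <- calls[calls$passed_filter, ]
    expect_equal(s$passed_filter, nrow(passed))
    expect_equal(s$pct_indels,
                 round(100 * mean(passed$category %in%
                   c("NHEJ_INDEL", "HDR_WITH_INDEL")) + 1e-9, 2))
    expect_equal(s$pct_corrected,
                 round(100 * mean(passed$category == "HDR_CORRECTED") + 1e-9, 2))
  }
})
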