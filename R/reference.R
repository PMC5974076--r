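#' Layout of the annotated amplicon reference
#'
#' Coordinate plan for a synthetic amplicon emulating the targeted *Prkdc*
#' locus: a scid point mutation (T>A on the modelled strand), a ZFN cleavage
#' window a fixed distance downstream, and two silent substitutions upstream
#' of the scid base which, together with reversion of the scid base itself,
#' engineer a diagnostic BsaWI recognition site (`WCCGGW`).
#'
#' All positions are 0-based; intervals are half-open. The two diagnostic
#' substitutions sit at `scid_pos - diag_offsets`; the engineered site spans
#' `[scid_pos - 7, scid_pos - 1)` so that it ends two bases upstream of the
#' scid position.
#'
#' @param scid_pos 0-based position of the scid point-mutation base.
#' @param scid_wt_base,scid_mut_base Wild-type and scid bases at `scid_pos`.
#' @param zfn_distance Distance (nt) from `scid_pos` to the start of the ZFN
#'   cleavage window. Default 32.
#' @param cleavage_width Width (bp) of the modelled cleavage window (the
#'   spacer between the two ZFN half-sites). Default 5.
#' @param diag_offsets Upstream offsets (bp) of the two silent diagnostic
#'   substitutions relative to `scid_pos`. Default `c(3, 6)`.
#' @param recurrent_del_length Length of the recurrent deletion modelled at
#'   this locus. Default 44.
#' @return A named list of layout parameters.
#' @export
reference_layout <- function(scid_pos = 800L, scid_wt_base = "T",
                             scid_mut_base = "A", zfn_distance = 32L,
                             cleavage_width = 5L, diag_offsets = c(3L, 6L),
                             recurrent_del_length = 44L) {
  stopifnot(scid_wt_base %in% BASES, scid_mut_base %in% BASES,
            scid_wt_base != scid_mut_base,
            length(diag_offsets) == 2L, zfn_distance > 0,
            cleavage_width >= 1, recurrent_del_length >= 1)
  diag_offsets <- as.integer(diag_offsets)
  if (!all(diag_offsets %in% 3:6) || diag_offsets[1] == diag_offsets[2])
    stop("diagnostic offsets must be two distinct values in 3..6 ",
         "(the C/C/G/G core of the engineered site)")
  list(scid_pos = as.integer(scid_pos),
       scid_wt_base = scid_wt_base, scid_mut_base = scid_mut_base,
       zfn_distance = as.integer(zfn_distance),
       cleavage_width = as.integer(cleavage_width),
       diag_offsets = sort(as.integer(diag_offsets), decreasing = TRUE),
       recurrent_del_length = as.integer(recurrent_del_length))
}

BSAWI_PATTERN <- "WCCGGW"

# IUPAC pattern template for the engineered site, positions relative to the
# span start at scid_pos - 7. The two diagnostic substitutions supply the
# bases at span offsets scid_pos - 6 and scid_pos - 3 ('C' and 'G'); the
# remaining pattern bases are constrained in the background sequence.
bsawi_template <- function() c("W", "C", "C", "G", "G", "W")

#' Build a seeded annotated amplicon reference
#'
#' Generates a random amplicon sequence (the true locus sequence is not
#' reconstructed) carrying the full annotation set used downstream: scid
#' position, ZFN cleavage window, diagnostic substitutions, engineered BsaWI
#' span and the fixed recurrent-deletion interval. The base `sequence` slot
#' holds the *scid* allele, i.e. the unedited sequence actually present in
#' the sequenced samples; wild-type and corrected alleles are derived from
#' it with [make_allele()].
#'
#' The construction guarantees that the corrected allele contains exactly
#' one `WCCGGW` occurrence (inside the engineered span) and that the scid
#' and wild-type alleles contain none anywhere: chance occurrences in the
#' seeded background are locally rewritten, and an error is raised if a
#' conflict-free sequence cannot be produced.
#'
#' @param length Amplicon length in bp (default 1626, >= 200).
#' @param seed Integer seed; the generator is R's default Mersenne-Twister
#'   stream and is recorded in the object metadata.
#' @param layout A [reference_layout()].
#' @param label Sample/site name attached to the reference.
#' @return An object of class `amplicon_reference`.
#' @examples
#' ref <- build_reference(length = 1626, seed = 7)
#' ref$cleavage_window
#' @export
build_reference <- function(length = 1626L, seed = 1L,
                            layout = reference_layout(), label = "amplicon") {
  length <- as.integer(length)
  if (length < 200L) stop("amplicon length must be >= 200 bp")
  s <- layout$scid_pos
  cw <- c(s + layout$zfn_distance, s + layout$zfn_distance + layout$cleavage_width)
  span <- c(s - 7L, s - 1L)
  if (span[1] < 0L || cw[2] > length)
    stop("layout places annotated features outside the sequence")
  if (cw[1] <= s) stop("cleavage window must start downstream of the scid position")

  rd_len <- layout$recurrent_del_length
  rd_start <- cw[1] + layout$cleavage_width %/% 2L - rd_len %/% 2L
  if (rd_start < 0L || rd_start + rd_len > length)
    stop("recurrent deletion interval falls outside the sequence")

  with_seed(seed, {
    seq <- paste(sample(BASES, length, replace = TRUE), collapse = "")

    # engineered span background: A/T flanks and the C/C/G/G core, except
    # that the two diagnostic positions carry a base differing from their
    # corrected-state base (so only the corrected allele forms the site)
    template <- bsawi_template()          # offsets 0..5 from span start s-7
    base_at(seq, s - 7L) <- sample(c("A", "T"), 1L)
    base_at(seq, s - 2L) <- sample(c("A", "T"), 1L)
    diag_pos <- sort(s - layout$diag_offsets)
    for (off in 1:4) {                    # core positions s-6 .. s-3
      p <- s - 7L + off
      b <- template[off + 1L]
      base_at(seq, p) <- if (p %in% diag_pos) sample(setdiff(BASES, b), 1L) else b
    }
    base_at(seq, s) <- layout$scid_mut_base

    diag_subs <- data.frame(
      pos = diag_pos,
      wt_base = vapply(diag_pos, function(p) base_at(seq, p), ""),
      diag_base = template[diag_pos - (s - 7L) + 1L],
      stringsAsFactors = FALSE)

    protected <- c(span[1]:(span[2] - 1L), s)
    ref <- structure(list(
      sequence = seq, length = length, scid_pos = s,
      scid_wt_base = layout$scid_wt_base, scid_mut_base = layout$scid_mut_base,
      cleavage_window = cw, diag_subs = diag_subs, bsawi_span = span,
      recurrent_del = c(start = rd_start, length = rd_len),
      label = label, layout = layout,
      rng = list(algorithm = "Mersenne-Twister", seed = as.integer(seed)),
      coordinate_convention = "0-based half-open"),
      class = "amplicon_reference")

    # Remove chance recognition sites outside the engineered span from
    # every allele — and from the recurrent-deletion molecules, whose
    # junction could otherwise form one — by rewriting one unprotected base
    # per offending occurrence. Each occurrence is reported as the involved
    # reference positions paired with their offset in the pattern, so the
    # rewrite can pick a base class the pattern excludes at that offset.
    drop_rd <- function(s) paste0(substr(s, 1L, rd_start),
                                  substr(s, rd_start + rd_len + 1L, nchar(s)))
    for (iter in 1:100) {
      bad <- list()
      for (allele in c("SCID", "WILD_TYPE", "CORRECTED")) {
        aseq <- make_allele(ref, allele)$sequence
        hits <- find_recognition_sites(aseq, BSAWI_PATTERN)
        if (allele == "CORRECTED") hits <- setdiff(hits, span[1])
        for (q in hits)
          bad[[length(bad) + 1L]] <- cbind(pos = q:(q + 5L), off = 0:5)
        mhits <- find_recognition_sites(drop_rd(aseq), BSAWI_PATTERN)
        if (allele == "CORRECTED") mhits <- setdiff(mhits, span[1])
        for (q in mhits) {
          mp <- q:(q + 5L)
          rp <- ifelse(mp < rd_start, mp, mp + rd_len)
          bad[[length(bad) + 1L]] <- cbind(pos = rp, off = 0:5)
        }
      }
      if (length(bad) == 0L) break
      for (occ in bad) {
        mutable <- which(!(occ[, "pos"] %in% protected))
        if (length(mutable) == 0L)
          stop("cannot host a unique BsaWI site with this layout")
        p <- occ[mutable[[1L]], "pos"]
        breakers <- if (occ[mutable[[1L]], "off"] %in% c(0L, 5L))
          c("C", "G") else c("A", "T")
        base_at(ref$sequence, p) <- sample(breakers, 1L)
      }
      if (iter == 100L)
        stop("cannot host a unique BsaWI site: pattern keeps re-occurring")
    }
    validate_reference(ref)
    ref
  })
}

validate_reference <- function(ref) {
  stopifnot(inherits(ref, "amplicon_reference"))
  s <- ref$scid_pos
  stopifnot(nchar(ref$sequence) == ref$length,
            ref$cleavage_window[1] > s,
            ref$cleavage_window[1] >= 0, ref$cleavage_window[2] <= ref$length,
            nrow(ref$diag_subs) == 2L,
            base_at(ref$sequence, s) == ref$scid_mut_base)
  corr <- make_allele(ref, "CORRECTED")$sequence
  hits <- find_recognition_sites(corr, BSAWI_PATTERN)
  in_span <- hits[hits >= ref$bsawi_span[1] & hits < ref$bsawi_span[2]]
  if (length(in_span) != 1L)
    stop("corrected allele must carry exactly one BsaWI site in the engineered span")
  if (length(find_recognition_sites(ref$sequence, BSAWI_PATTERN)) != 0L)
    stop("scid allele must carry no BsaWI site")
  invisible(ref)
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("amplicon_reference '%s': %d bp (%s coordinates)\n",
              x$label, x$length, x$coordinate_convention))
  cat(sprintf("  scid position %d (%s>%s); ZFN cleavage window [%d, %d)\n",
              x$scid_pos + 1L, x$scid_wt_base, x$scid_mut_base,
              x$cleavage_window[1], x$cleavage_window[2]))
  cat(sprintf("  diagnostic substitutions at %s; BsaWI span [%d, %d); recurrent deletion [%d, +%d)\n",
              paste(x$diag_subs$pos, collapse = ", "),
              x$bsawi_span[1], x$bsawi_span[2],
              x$recurrent_del["start"], x$recurrent_del["length"]))
  invisible(x)
}

#' Derive an allele variant from the annotated reference
#'
#' The scid allele is the reference base sequence; the wild-type allele
#' reverts the scid base; the corrected allele additionally carries the two
#' silent diagnostic substitutions, i.e. it differs from the scid allele at
#' exactly 3 positions (1 to wild-type, 2 creating the BsaWI site).
#'
#' @param ref An `amplicon_reference`.
#' @param name One of `"WILD_TYPE"`, `"SCID"`, `"CORRECTED"`.
#' @return An `allele_variant` list with elements `name` and `sequence`.
#' @export
make_allele <- function(ref, name = c("SCID", "WILD_TYPE", "CORRECTED")) {
  name <- match.arg(name)
  seq <- ref$sequence
  if (name %in% c("WILD_TYPE", "CORRECTED"))
    base_at(seq, ref$scid_pos) <- ref$scid_wt_base
  if (name == "CORRECTED")
    for (k in seq_len(nrow(ref$diag_subs)))
      base_at(seq, ref$diag_subs$pos[k]) <- ref$diag_subs$diag_base[k]
  structure(list(name = name, sequence = seq), class = "allele_variant")
}

# The three substitutions distinguishing the corrected from the scid allele:
# position, scid-allele base, corrected-state base.
diagnostic_positions <- function(ref) {
  data.frame(
    pos = c(ref$diag_subs$pos, ref$scid_pos),
    scid_base = c(ref$diag_subs$wt_base, ref$scid_mut_base),
    corrected_base = c(ref$diag_subs$diag_base, ref$scid_wt_base),
    stringsAsFactors = FALSE)
}

#' Find restriction recognition sites
#'
#' Scans one strand of a sequence for all (possibly overlapping) matches of
#' an IUPAC recognition pattern.
#'
#' @param seq DNA sequence (character or `DNAString`).
#' @param pattern IUPAC pattern; default `"WCCGGW"` (BsaWI).
#' @return Integer vector of 0-based match start positions.
#' @examples
#' find_recognition_sites("ACCGGA", "WCCGGW")  # 0
#' @export
find_recognition_sites <- function(seq, pattern = BSAWI_PATTERN) {
  pattern <- toupper(pattern)
  ok <- strsplit(pattern, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok))
    stop("invalid IUPAC character(s) in pattern: ",
         paste(strsplit(pattern, "")[[1]][!ok], collapse = ", "))
  seq <- if (inherits(seq, "DNAString")) seq else Biostrings::DNAString(as.character(seq))
  hits <- Biostrings::matchPattern(pattern, seq, fixed = FALSE)
  as.integer(Biostrings::start(hits)) - 1L
}
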