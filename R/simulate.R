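#' Configuration for the amplicon read simulator
#'
#' Defaults emulate the deep-sequenced ZFN + repair-template condition of
#' the study this package models: 18% of molecules carry an NHEJ indel at
#' the cleavage site, 1.53% are HDR-corrected without an associated indel,
#' and corrected-with-indel molecules make up 11.25% of total correction.
#' Half of all indel events are the fixed recurrent 44-bp deletion; the
#' remainder draw geometric lengths (deletions mean 4 bp truncated at 60,
#' insertions mean 2 bp). Reads are 150 bp, single-end, orientation
#' randomised 50/50, with independent per-base substitution errors at the
#' Q30-consistent default rate of 0.001.
#'
#' Category proportions must sum to 1; `p_wt` defaults to the remainder.
#'
#' @param n_reads Number of reads.
#' @param p_indel,p_hdr,p_hdr_indel,p_wt Category proportions (NHEJ indel,
#'   HDR-corrected without indel, HDR with associated indel, unedited).
#' @param recurrent_del_frac Fraction of indel events that are the fixed
#'   recurrent 44-bp deletion.
#' @param del_mean_len,ins_mean_len Mean lengths of non-recurrent deletions
#'   and insertions (geometric, support >= 1).
#' @param max_indel_len Truncation for non-recurrent indel lengths.
#' @param ins_del_ratio Probability that a non-recurrent indel is an
#'   insertion.
#' @param error_rate Per-base substitution error probability.
#' @param read_length Read length in bp.
#' @param read_window 0-based half-open reference interval reads are drawn
#'   from; `NULL` derives a default from the reference annotation.
#' @param base_quality Constant Phred quality written to FASTQ.
#' @param seed Integer seed; the full output is determined by it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_reads = 10000L, p_indel = 0.18,
                              p_hdr = 0.0153,
                              p_hdr_indel = p_hdr * 0.1125 / (1 - 0.1125),
                              p_wt = NULL,
                              recurrent_del_frac = 0.5,
                              del_mean_len = 4, ins_mean_len = 2,
                              max_indel_len = 60L, ins_del_ratio = 0.25,
                              error_rate = 0.001, read_length = 150L,
                              read_window = NULL, base_quality = 30L,
                              seed = 1L) {
  if (is.null(p_wt)) p_wt <- 1 - p_indel - p_hdr - p_hdr_indel
  props <- c(p_wt = p_wt, p_indel = p_indel, p_hdr = p_hdr,
             p_hdr_indel = p_hdr_indel)
  if (any(props < -1e-9) || abs(sum(props) - 1) > 1e-9)
    stop("category proportions must be in [0,1] and sum to 1")
  stopifnot_scalar_count(n_reads, "n_reads")
  stopifnot(recurrent_del_frac >= 0, recurrent_del_frac <= 1,
            error_rate >= 0, error_rate < 1,
            del_mean_len >= 1, ins_mean_len >= 1, max_indel_len >= 1,
            ins_del_ratio >= 0, ins_del_ratio <= 1, read_length >= 30)
  structure(list(
    n_reads = as.integer(n_reads), proportions = pmax(props, 0),
    recurrent_del_frac = recurrent_del_frac,
    del_mean_len = del_mean_len, ins_mean_len = ins_mean_len,
    max_indel_len = as.integer(max_indel_len), ins_del_ratio = ins_del_ratio,
    error_rate = error_rate, read_length = as.integer(read_length),
    read_window = read_window, base_quality = as.integer(base_quality),
    seed = as.integer(seed)), class = "simulation_config")
}

# Default sampling window: every read must cover the engineered site span
# and the full cleavage window even in the presence of the longest allowed
# deletion, and must start upstream of any possible deletion breakpoint so
# reads are substrings of the edited molecule at their reference offset.
default_read_window <- function(ref, cfg) {
  c(ref$scid_pos - 89L, ref$cleavage_window[2] + 60L)
}

validate_sim_window <- function(ref, cfg) {
  win <- cfg$read_window
  if (is.null(win)) win <- default_read_window(ref, cfg)
  win <- as.integer(win)
  rl <- cfg$read_length
  c1 <- ref$cleavage_window[1]; c2 <- ref$cleavage_window[2]
  feat_lo <- min(ref$bsawi_span[1], ref$diag_subs$pos)
  if (win[1] < 0 || win[2] > ref$length || win[2] - win[1] < rl)
    stop("read window must lie inside the reference and fit a full read")
  if (win[2] - rl > feat_lo || win[1] + rl < c2)
    stop("read window makes reads unclassifiable: every read must cover ",
         "the diagnostic positions and the full cleavage window")
  if (win[2] - rl > c1 - cfg$max_indel_len)
    stop("read window allows reads starting inside a possible deletion; ",
         "move the window start upstream or shorten max_indel_len")
  if (win[1] + rl - (c2 - 1L) < 20L)
    stop("read window leaves too little sequence beyond the cleavage ",
         "window for indels to be recoverable by alignment")
  win
}

#' Simulate amplicon reads with ground-truth editing outcomes
#'
#' Each read is assigned an outcome category (unedited, NHEJ indel,
#' HDR-corrected, HDR with associated indel), built from the corresponding
#' allele (scid for unedited/NHEJ, corrected for the HDR categories) with
#' its structural edit applied, then sampled as a fixed-length substring,
#' orientation-randomised, and finally subjected to independent per-base
#' substitution errors. Indels always involve at least one base of the
#' cleavage window; in HDR-with-indel molecules deletions never reach the
#' diagnostic bases (a molecule that lost them would be indistinguishable
#' from a pure NHEJ event), and edits whose junction would create a chance
#' BsaWI site are redrawn so the RFLP digest signal maps one-to-one onto
#' HDR truth labels in error-free pools.
#'
#' @param ref An `amplicon_reference`.
#' @param cfg A [simulation_config()].
#' @return A `simulated_reads` object: `ids`, `reads` (oriented sequences),
#'   `truth` (one row per read: category, indel descriptor, recurrence flag,
#'   orientation), `config`, and the resolved `read_window`.
#' @export
simulate_reads <- function(ref, cfg = simulation_config()) {
  stopifnot(inherits(ref, "amplicon_reference"),
            inherits(cfg, "simulation_config"))
  win <- validate_sim_window(ref, cfg)
  n <- cfg$n_reads
  rl <- cfg$read_length
  c1 <- ref$cleavage_window[1]; c2 <- ref$cleavage_window[2]
  scid_seq <- ref$sequence
  corr_seq <- make_allele(ref, "CORRECTED")$sequence
  rd <- ref$recurrent_del
  p <- cfg$proportions

  with_seed(cfg$seed, {
    # category thresholds ordered so that raising an HDR proportion (with
    # p_wt absorbing) can only turn reads into HDR, never the reverse
    u <- runif(n)
    cum <- cumsum(c(p[["p_hdr"]], p[["p_hdr_indel"]], p[["p_indel"]]))
    category <- ifelse(u < cum[1], "HDR_CORRECTED",
                ifelse(u < cum[2], "HDR_WITH_INDEL",
                ifelse(u < cum[3], "NHEJ_INDEL", "WT")))

    ids <- sprintf("read_%06d", seq_len(n))
    reads <- character(n)
    indel_type <- rep(NA_character_, n)
    indel_start <- rep(NA_integer_, n)
    indel_len <- rep(NA_integer_, n)
    is_recurrent <- rep(FALSE, n)
    orientation <- character(n)
    start_max <- win[2] - rl

    draw_len <- function(mean_len) {
      min(1L + rgeom(1L, 1 / mean_len), cfg$max_indel_len)
    }
    count_sites <- function(x) {
      m <- gregexpr("(?=[AT]CCGG[AT])", x, perl = TRUE)[[1]]
      sum(m > 0L)
    }

    for (i in seq_len(n)) {
      cat_i <- category[i]
      hdr <- cat_i %in% c("HDR_CORRECTED", "HDR_WITH_INDEL")
      allele <- if (hdr) corr_seq else scid_seq
      start <- win[1] + floor(runif(1) * (start_max - win[1] + 1L))
      expected_sites <- if (hdr) 1L else 0L

      if (cat_i %in% c("NHEJ_INDEL", "HDR_WITH_INDEL")) {
        # whether this event is the recurrent deletion is decided once, so
        # redraws of invalid non-recurrent indels cannot skew the fraction
        recur <- runif(1) < cfg$recurrent_del_frac
        for (attempt in 1:50) {
          ins_seq <- NULL
          if (recur) {
            typ <- "del"; len <- rd[["length"]]; d <- rd[["start"]]
          } else {
            if (runif(1) < cfg$ins_del_ratio) {
              typ <- "ins"; len <- draw_len(cfg$ins_mean_len)
              d <- c1 + floor(runif(1) * (c2 - c1 + 1L))   # anchor, closed
              ins_seq <- paste(sample(BASES, len, replace = TRUE),
                               collapse = "")
            } else {
              typ <- "del"; len <- draw_len(cfg$del_mean_len)
              lo <- c1 - len + 1L
              if (cat_i == "HDR_WITH_INDEL")
                lo <- max(lo, ref$scid_pos + 1L)
              d <- lo + floor(runif(1) * (c2 - lo))        # start in [lo, c2-1]
            }
          }
          # canonicalise to the leftmost equivalent placement, the same
          # convention the classifier reports, and require THAT placement
          # to involve the cleavage window (an indel whose canonical form
          # lies outside it is molecularly indistinguishable from a
          # non-window event); redraw otherwise
          if (typ == "del") {
            while (d > 0L && base_at(allele, d - 1L) ==
                     base_at(allele, d + len - 1L)) d <- d - 1L
            ok <- d < c2 && d + len > c1 &&
              (cat_i != "HDR_WITH_INDEL" || d > ref$scid_pos)
          } else {
            while (d > 0L && substr(ins_seq, len, len) ==
                     base_at(allele, d - 1L)) {
              ins_seq <- paste0(base_at(allele, d - 1L),
                                substr(ins_seq, 1L, len - 1L))
              d <- d - 1L
            }
            ok <- d >= c1 && d <= c2
          }
          if (ok) {
            molecule <- if (typ == "del") {
              paste0(substr(allele, 1L, d), substr(allele, d + len + 1L,
                                                   nchar(allele)))
            } else {
              paste0(substr(allele, 1L, d), ins_seq,
                     substr(allele, d + 1L, nchar(allele)))
            }
            seq_i <- substr(molecule, start + 1L, start + rl)
            if (count_sites(seq_i) == expected_sites) break
          }
          if (recur)
            stop("the recurrent deletion's canonical placement is invalid ",
                 "for this reference; rebuild it with another seed")
          if (attempt == 50L)
            stop("could not draw a window-involving indel without a chance ",
                 "recognition site")
        }
        indel_type[i] <- typ; indel_start[i] <- d; indel_len[i] <- len
        is_recurrent[i] <- recur
      } else {
        seq_i <- substr(allele, start + 1L, start + rl)
      }

      n_err <- rbinom(1L, nchar(seq_i), cfg$error_rate)
      if (n_err > 0L) {
        pos <- sample.int(nchar(seq_i), n_err)
        for (q in pos) {
          cur <- substr(seq_i, q, q)
          substr(seq_i, q, q) <- sample(setdiff(BASES, cur), 1L)
        }
      }

      orientation[i] <- if (runif(1) < 0.5) "forward" else "revcomp"
      reads[i] <- seq_i
    }
    flip <- orientation == "revcomp"
    if (any(flip)) reads[flip] <- revcomp(reads[flip])

    truth <- data.frame(
      read_id = ids, category = category,
      indel_type = indel_type, indel_start = indel_start,
      indel_len = indel_len, is_recurrent_deletion = is_recurrent,
      orientation = orientation, stringsAsFactors = FALSE)
    structure(list(ids = ids, reads = reads, truth = truth, config = cfg,
                   read_window = win, ref_label = ref$label),
              class = "simulated_reads")
  })
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat(sprintf("simulated_reads: %d reads of %d bp from '%s'\n",
              length(x$reads), x$config$read_length, x$ref_label))
  print(table(x$truth$category))
  invisible(x)
}

#' Simulate a denature/reanneal heteroduplex pool (Cel-I assay front end)
#'
#' Models the Surveyor/Cel-I assay's reannealing step: duplexes are formed
#' by drawing two strands i.i.d. from the allele pool, and a duplex is
#' cleavable by the mismatch-specific endonuclease iff its strands derive
#' from non-identical sequences. For a single mutant at fraction p the
#' expected cleavable fraction is the classical 1 - p^2 - (1-p)^2.
#'
#' @param allele_fractions Named numeric vector of allele fractions
#'   (sums to 1).
#' @param n_duplexes Number of duplexes to draw.
#' @param seed Integer seed.
#' @param sequences Optional named character vector giving each allele's
#'   sequence; when supplied, strand identity is decided on the sequences
#'   (two alleles with identical sequence anneal perfectly).
#' @return A `heteroduplex_pool` list: `duplexes` (strand1, strand2,
#'   cleavable) and `cleaved_fraction`.
#' @export
make_heteroduplex_pool <- function(allele_fractions, n_duplexes,
                                   seed = 1L, sequences = NULL) {
  if (length(allele_fractions) == 0L) stop("empty allele pool")
  if (is.null(names(allele_fractions)) || any(!nzchar(names(allele_fractions))))
    stop("allele_fractions must be named")
  if (abs(sum(allele_fractions) - 1) > 1e-9 || any(allele_fractions < 0))
    stop("allele fractions must be non-negative and sum to 1")
  stopifnot_scalar_count(n_duplexes, "n_duplexes")
  if (n_duplexes == 0L) stop("empty duplex pool")
  alleles <- names(allele_fractions)
  with_seed(seed, {
    s1 <- sample(alleles, n_duplexes, replace = TRUE, prob = allele_fractions)
    s2 <- sample(alleles, n_duplexes, replace = TRUE, prob = allele_fractions)
    cleavable <- if (is.null(sequences)) s1 != s2 else {
      if (!all(alleles %in% names(sequences)))
        stop("sequences must be supplied for every allele")
      sequences[s1] != sequences[s2]
    }
    structure(list(
      duplexes = data.frame(strand1 = s1, strand2 = s2,
                            cleavable = unname(cleavable),
                            stringsAsFactors = FALSE),
      cleaved_fraction = mean(cleavable)),
      class = "heteroduplex_pool")
  })
}
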