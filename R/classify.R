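#' Quality-filter thresholds
#'
#' A read passes when (a) its alignment identity computed over columns
#' outside the cleavage neighbourhood is at least `min_identity`, and (b)
#' its aligned reference span covers all diagnostic positions and the full
#' cleavage window. The neighbourhood is the cleavage window padded by
#' `neighbourhood_pad` bp on each side, wide enough that a genuine editing
#' indel (including the recurrent 44-bp deletion) does not count against
#' identity.
#'
#' @param min_identity Minimum identity outside the neighbourhood
#'   (default 0.90).
#' @param neighbourhood_pad Padding (bp) around the cleavage window
#'   (default 50).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_identity = 0.90, neighbourhood_pad = 50L) {
  stopifnot(min_identity > 0, min_identity <= 1, neighbourhood_pad >= 0)
  structure(list(min_identity = min_identity,
                 neighbourhood_pad = as.integer(neighbourhood_pad)),
            class = "filter_thresholds")
}

#' Classification tolerances
#'
#' @param max_extra_mismatches Mismatches tolerated outside the three
#'   diagnostic positions before a diagnostic-complete read is demoted to
#'   UNCLASSIFIED (default 2, chosen to keep the Q30 false-negative rate of
#'   HDR calls below 1%).
#' @param insertion_window_rule `"closed"` (default) counts an insertion
#'   anchored at either boundary of the half-open cleavage window as
#'   involving it; `"half-open"` requires the anchor strictly inside.
#' @return A `classify_tolerances` list.
#' @export
classify_tolerances <- function(max_extra_mismatches = 2L,
                                insertion_window_rule = c("closed", "half-open")) {
  structure(list(max_extra_mismatches = as.integer(max_extra_mismatches),
                 insertion_window_rule = match.arg(insertion_window_rule)),
            class = "classify_tolerances")
}

# columns of an op interval [s, s+len) falling outside [lo, hi)
cols_outside <- function(s, len, lo, hi) {
  len - pmax(0L, pmin(s + len, hi) - pmax(s, lo))
}

#' Apply the high-quality read filter
#'
#' @param aln An `amplicon_aln` from [align_reads()].
#' @param ref The `amplicon_reference` used for alignment.
#' @param thresholds A [filter_thresholds()].
#' @return Data frame: read_id, pass, reason (`NA`, "unaligned", "span" or
#'   "identity"), identity.
#' @export
passes_quality_filter <- function(aln, ref, thresholds = filter_thresholds()) {
  stopifnot(inherits(aln, "amplicon_aln"))
  n <- nrow(aln$summary)
  cw <- ref$cleavage_window
  nb <- c(cw[1] - thresholds$neighbourhood_pad,
          cw[2] + thresholds$neighbourhood_pad)
  ops <- aln$ops

  # identity over alignment columns outside the neighbourhood: matches in
  # the numerator; matches, mismatches and gap columns in the denominator
  out_len <- cols_outside(ops$ref_start, ops$len, nb[1], nb[2])
  ins <- ops$op == "I"
  out_len[ins] <- ifelse(ops$ref_start[ins] < nb[1] | ops$ref_start[ins] >= nb[2],
                         ops$len[ins], 0L)
  denom <- tapply_sum(ops$read, out_len, n)
  matches <- tapply_sum(ops$read[ops$op == "="], out_len[ops$op == "="], n)
  identity <- ifelse(denom > 0L, matches / denom, NA_real_)

  feat_lo <- min(ref$bsawi_span[1], ref$diag_subs$pos, ref$scid_pos)
  feat_hi <- max(ref$diag_subs$pos + 1L, ref$scid_pos + 1L, cw[2])
  span_ok <- !is.na(aln$summary$ref_start) &
    aln$summary$ref_start <= feat_lo & aln$summary$ref_end >= feat_hi

  pass <- aln$summary$aligned & span_ok &
    !is.na(identity) & identity >= thresholds$min_identity
  reason <- rep(NA_character_, n)
  reason[!aln$summary$aligned] <- "unaligned"
  reason[aln$summary$aligned & !span_ok] <- "span"
  reason[aln$summary$aligned & span_ok & (is.na(identity) |
           identity < thresholds$min_identity)] <- "identity"
  data.frame(read_id = aln$summary$read_id, pass = pass, reason = reason,
             identity = identity, stringsAsFactors = FALSE)
}

tapply_sum <- function(group, value, n) {
  out <- numeric(n)
  if (length(group)) {
    agg <- rowsum(as.numeric(value), group)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Classify aligned reads into editing outcomes
#'
#' Implements the per-read calling rules: a read whose alignment contains a
#' deletion or insertion involving any base of the ZFN cleavage window is an
#' NHEJ indel; a read carrying all three expected substitutions (scid
#' reversion plus the two diagnostic bases) is HDR-corrected, or
#' HDR-with-indel when a qualifying indel is also present; reads with a
#' partial diagnostic signature and no qualifying indel, or with too many
#' extra mismatches, are UNCLASSIFIED. Substitution-only changes inside the
#' cleavage window do not count as indels (only length-changing events do).
#'
#' @param aln An `amplicon_aln`.
#' @param ref The `amplicon_reference`.
#' @param tolerances A [classify_tolerances()].
#' @param thresholds A [filter_thresholds()]; the filter is applied first
#'   and non-passing reads receive `NA` category with their filter reason.
#' @return Data frame of per-read calls (class `outcome_calls`): read_id,
#'   passed_filter, filter_reason, category, indel_overlaps_cleavage,
#'   n_diag_subs_matched, extra_mismatches, indel_type, indel_start,
#'   indel_len (left-normalised coordinates of the qualifying indel).
#' @export
classify_reads <- function(aln, ref, tolerances = classify_tolerances(),
                           thresholds = filter_thresholds()) {
  stopifnot(inherits(aln, "amplicon_aln"))
  filt <- passes_quality_filter(aln, ref, thresholds)
  n <- nrow(aln$summary)
  cw <- ref$cleavage_window
  ops <- aln$ops

  # qualifying indels: deletions intersecting the half-open window;
  # insertions by anchor under the configured boundary rule
  is_del <- ops$op == "D"
  is_ins <- ops$op == "I"
  del_hit <- is_del & ops$ref_start < cw[2] & ops$ref_start + ops$len > cw[1]
  ins_hit <- if (tolerances$insertion_window_rule == "closed")
    is_ins & ops$ref_start >= cw[1] & ops$ref_start <= cw[2]
  else
    is_ins & ops$ref_start > cw[1] & ops$ref_start < cw[2]
  qual <- ops[del_hit | ins_hit, , drop = FALSE]
  # one descriptor per read: the longest qualifying event, deletions first
  if (nrow(qual)) {
    pref <- order(qual$read, qual$op != "D", -qual$len, qual$ref_start)
    qual <- qual[pref, , drop = FALSE]
    qual <- qual[!duplicated(qual$read), , drop = FALSE]
  }
  indel_overlaps <- logical(n)
  indel_overlaps[qual$read] <- TRUE
  indel_type <- rep(NA_character_, n)
  indel_type[qual$read] <- ifelse(qual$op == "D", "del", "ins")
  indel_start <- rep(NA_integer_, n); indel_start[qual$read] <- qual$ref_start
  indel_len <- rep(NA_integer_, n); indel_len[qual$read] <- qual$len

  # diagnostic positions: the read carries the corrected-state base at a
  # position iff a mismatch column covers it with exactly that base
  diag <- diagnostic_positions(ref)
  n_matched <- integer(n)
  mm <- ops[ops$op == "X", , drop = FALSE]
  for (k in seq_len(nrow(diag))) {
    p <- diag$pos[k]
    cover <- mm[mm$ref_start <= p & p < mm$ref_start + mm$len, , drop = FALSE]
    if (!nrow(cover)) next
    off <- p - cover$ref_start
    b <- substr(aln$oriented[cover$read], cover$read_start + off + 1L,
                cover$read_start + off + 1L)
    hit <- cover$read[b == diag$corrected_base[k]]
    n_matched[hit] <- n_matched[hit] + 1L
  }

  # mismatches away from the three diagnostic positions
  mm_tot <- tapply_sum(mm$read, mm$len, n)
  mm_diag <- numeric(n)
  for (p in diag$pos) {
    cover <- mm[mm$ref_start <= p & p < mm$ref_start + mm$len, , drop = FALSE]
    if (nrow(cover)) {
      cnt <- table(cover$read)
      mm_diag[as.integer(names(cnt))] <- mm_diag[as.integer(names(cnt))] + cnt
    }
  }
  extra_mm <- as.integer(mm_tot - mm_diag)

  category <- rep(NA_character_, n)
  pass <- filt$pass
  full <- n_matched == 3L
  category[pass & full & extra_mm > tolerances$max_extra_mismatches] <- "UNCLASSIFIED"
  category[pass & full & extra_mm <= tolerances$max_extra_mismatches &
             indel_overlaps] <- "HDR_WITH_INDEL"
  category[pass & full & extra_mm <= tolerances$max_extra_mismatches &
             !indel_overlaps] <- "HDR_CORRECTED"
  category[pass & !full & indel_overlaps] <- "NHEJ_INDEL"
  category[pass & n_matched %in% 1:2 & !indel_overlaps] <- "UNCLASSIFIED"
  category[pass & n_matched == 0L & !indel_overlaps] <- "WT"

  out <- data.frame(
    read_id = aln$summary$read_id, passed_filter = pass,
    filter_reason = filt$reason, category = category,
    indel_overlaps_cleavage = indel_overlaps,
    n_diag_subs_matched = n_matched, extra_mismatches = extra_mm,
    indel_type = indel_type, indel_start = indel_start,
    indel_len = indel_len, stringsAsFactors = FALSE)
  class(out) <- c("outcome_calls", "data.frame")
  out
}

CATEGORIES <- c("WT", "NHEJ_INDEL", "HDR_CORRECTED", "HDR_WITH_INDEL",
                "UNCLASSIFIED")

#' Summarise per-read calls for one sample
#'
#' Percentages use the passed-filter read count as denominator and are
#' reported to 2 decimals (half away from zero). The headline correction
#' percentage counts HDR-corrected reads only — correction events with an
#' associated indel are excluded from it and reported separately, both as a
#' percentage of passed reads and as a share of total correction.
#'
#' @param calls An `outcome_calls` table.
#' @param label Sample label.
#' @param include_hdr_indel_in_indels Count HDR-with-indel reads in
#'   `pct_indels` (default TRUE); a toggle is provided because published
#'   indel percentages do not state the convention.
#' @param recurrent_share Share of deletions at one (start, length) needed
#'   to flag it recurrent in the spectrum (default 0.2).
#' @return A `sample_summary` list.
#' @export
summarize_sample <- function(calls, label = "sample",
                             include_hdr_indel_in_indels = TRUE,
                             recurrent_share = 0.2) {
  stopifnot(is.data.frame(calls))
  passed <- calls[calls$passed_filter, , drop = FALSE]
  np <- nrow(passed)
  counts <- vapply(CATEGORIES, function(k) sum(passed$category == k), 0L)
  if (np == 0L) {
    return(structure(list(
      label = label, total_reads = nrow(calls), passed_filter = 0L,
      counts = counts, percentages = setNames(rep(NA_real_, 5), CATEGORIES),
      pct_indels = NA_real_, pct_corrected = NA_real_,
      pct_correction_with_indel_of_total_correction = NA_real_,
      deletion_spectrum = empty_spectrum(), empty = TRUE),
      class = "sample_summary"))
  }
  pct <- round_half_away(100 * counts / np)
  n_indel <- counts[["NHEJ_INDEL"]] +
    if (include_hdr_indel_in_indels) counts[["HDR_WITH_INDEL"]] else 0L
  corr_total <- counts[["HDR_CORRECTED"]] + counts[["HDR_WITH_INDEL"]]
  structure(list(
    label = label, total_reads = nrow(calls), passed_filter = np,
    counts = counts, percentages = pct,
    pct_indels = round_half_away(100 * n_indel / np),
    pct_corrected = round_half_away(100 * counts[["HDR_CORRECTED"]] / np),
    pct_correction_with_indel_of_total_correction =
      if (corr_total > 0) round_half_away(100 * counts[["HDR_WITH_INDEL"]] / corr_total)
      else NA_real_,
    deletion_spectrum = deletion_spectrum(calls, recurrent_share),
    include_hdr_indel_in_indels = include_hdr_indel_in_indels,
    empty = FALSE), class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("sample_summary '%s': %d reads, %d passed filter\n",
              x$label, x$total_reads, x$passed_filter))
  if (x$empty) { cat("  (no passed reads)\n"); return(invisible(x)) }
  for (k in CATEGORIES)
    cat(sprintf("  %-15s %6d  %6.2f%%\n", k, x$counts[[k]], x$percentages[[k]]))
  cat(sprintf("  indels %.2f%%; corrected (excluding indel) %.2f%%; ",
              x$pct_indels, x$pct_corrected))
  cat(sprintf("correction-with-indel %s%% of total correction\n",
              format(x$pct_correction_with_indel_of_total_correction)))
  invisible(x)
}

empty_spectrum <- function() {
  data.frame(del_start = integer(0), del_length = integer(0),
             count = integer(0), share = numeric(0), recurrent = logical(0))
}

#' Tally the deletion spectrum of a sample
#'
#' Counts qualifying (cleavage-window-overlapping, left-normalised)
#' deletions by (start, length) over the indel-bearing categories, sorted
#' by count; entries carrying at least `recurrent_share` of all deletions
#' are flagged recurrent.
#'
#' @param calls An `outcome_calls` table from one sample.
#' @param recurrent_share Flagging threshold (default 0.2).
#' @return Data frame: del_start, del_length, count, share, recurrent.
#' @export
deletion_spectrum <- function(calls, recurrent_share = 0.2) {
  dd <- calls[calls$passed_filter &
                calls$category %in% c("NHEJ_INDEL", "HDR_WITH_INDEL") &
                !is.na(calls$indel_type) & calls$indel_type == "del", ,
              drop = FALSE]
  if (nrow(dd) == 0L) return(empty_spectrum())
  tab <- aggregate(list(count = rep(1L, nrow(dd))),
                   by = list(del_start = dd$indel_start,
                             del_length = dd$indel_len), FUN = sum)
  tab <- tab[order(-tab$count, tab$del_start), , drop = FALSE]
  tab$share <- tab$count / sum(tab$count)
  tab$recurrent <- tab$share >= recurrent_share
  rownames(tab) <- NULL
  tab
}
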