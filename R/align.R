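#' Alignment scoring parameters
#'
#' Defaults (match +2, mismatch -4, gap open -10, gap extend -1, semi-global
#' with free end gaps on the reference) favour a single long deletion over a
#' scatter of mismatches, which is what recovers the recurrent 44-bp
#' deletion as one operation. A gap of length L costs `gap_open + L *
#' gap_extend`.
#'
#' @param match,mismatch,gap_open,gap_extend Integer scores/penalties
#'   (penalties given as positive numbers).
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(match = 2L, mismatch = -4L,
                             gap_open = 10L, gap_extend = 1L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "alignment_params")
}

op_types <- c("=", "X", "D", "I")

#' Align amplicon reads to the unedited (scid) allele
#'
#' Semi-global alignment of each read against the sample's own unedited
#' sequence: the read is aligned end-to-end while reference end gaps are
#' free. Both orientations are scored and the better one kept, so input
#' orientation does not matter. Indels are then left-normalised: every gap
#' is shifted to the leftmost position among score-equivalent placements,
#' giving each distinct event a canonical (start, length).
#'
#' Alignment is against the scid allele rather than the wild-type because
#' the sequenced amplicons derive from scid cells; the three diagnostic
#' positions (scid reversion plus the two silent substitutions) are
#' evaluated explicitly during classification instead of being scored as
#' mismatches.
#'
#' @param reads Character vector (optionally named with read ids), a
#'   `DNAStringSet`, or a FASTQ path.
#' @param ref An `amplicon_reference`.
#' @param params An [alignment_params()].
#' @return An `amplicon_aln` object: `summary` (read_id, aligned,
#'   orientation, score, ref_start, ref_end — reference span half-open,
#'   0-based), `ops` (one row per run: read_id, op in `=XDI`, ref_start,
#'   len, read_start), and `oriented` (read sequences in aligned
#'   orientation).
#' @export
align_reads <- function(reads, ref, params = alignment_params()) {
  stopifnot(inherits(ref, "amplicon_reference"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  if (inherits(reads, "DNAStringSet")) {
    nm <- names(reads); reads <- as.character(reads); names(reads) <- nm
  }
  if (length(reads) == 0L) stop("no reads supplied")
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(reads))
  reads <- toupper(unname(reads))
  if (any(nchar(reads) > ref$length))
    stop("read(s) longer than the reference")

  all_n <- grepl("^N+$", reads) | nchar(reads) == 0L
  res <- list(aligned = logical(length(reads)), score = rep(NA_integer_, length(reads)),
              orientation = rep(NA_integer_, length(reads)),
              ref_start = rep(NA_integer_, length(reads)),
              ref_end = rep(NA_integer_, length(reads)),
              op_read = integer(0), op_type = integer(0),
              op_ref_start = integer(0), op_len = integer(0),
              op_read_start = integer(0))
  keep <- which(!all_n)
  if (length(keep)) {
    rc <- revcomp(reads[keep])
    raw <- align_batch_cpp(reads[keep], rc, ref$sequence, params$match,
                           params$mismatch, params$gap_open, params$gap_extend)
    res$aligned[keep] <- raw$aligned
    res$score[keep] <- raw$score
    res$orientation[keep] <- raw$orientation
    res$ref_start[keep] <- raw$ref_start
    res$ref_end[keep] <- raw$ref_end
    res$op_read <- keep[raw$op_read]
    res$op_type <- raw$op_type
    res$op_ref_start <- raw$op_ref_start
    res$op_len <- raw$op_len
    res$op_read_start <- raw$op_read_start
  }

  oriented <- reads
  rcpick <- which(!is.na(res$orientation) & res$orientation == 1L)
  if (length(rcpick)) oriented[rcpick] <- revcomp(reads[rcpick])

  ops <- data.frame(read = res$op_read,
                    op = op_types[res$op_type + 1L],
                    ref_start = res$op_ref_start,
                    len = res$op_len,
                    read_start = res$op_read_start,
                    stringsAsFactors = FALSE)
  ops <- left_normalise_ops(ops, ref$sequence, oriented)

  summary <- data.frame(
    read_id = ids, aligned = res$aligned,
    orientation = c("forward", "revcomp")[res$orientation + 1L],
    score = res$score, ref_start = res$ref_start, ref_end = res$ref_end,
    stringsAsFactors = FALSE)
  structure(list(summary = summary, ops = ops, oriented = oriented,
                 params = params, ref_label = ref$label),
            class = "amplicon_aln")
}

#' @export
print.amplicon_aln <- function(x, ...) {
  cat(sprintf("amplicon_aln: %d reads vs '%s' (%d aligned, %d with indels)\n",
              nrow(x$summary), x$ref_label, sum(x$summary$aligned),
              length(unique(x$ops$read[x$ops$op %in% c("D", "I")]))))
  invisible(x)
}

# Shift every indel to its leftmost score-equivalent placement. A deletion
# [a, a+L) moves one step left when the preceding column is a match and
# ref[a-1] == ref[a+L-1]; an insertion moves when the preceding column is a
# match and its last inserted base equals ref[a-1] (gap rotation). Runs are
# re-linked so match runs shrink on the left of the gap and grow on its
# right; score is invariant by construction.
left_normalise_ops <- function(ops, refseq, oriented) {
  if (nrow(ops) == 0L || !any(ops$op %in% c("D", "I"))) return(ops)
  touch <- unique(ops$read[ops$op %in% c("D", "I")])
  sel <- ops$read %in% touch
  blocks <- split(ops[sel, , drop = FALSE], ops$read[sel])
  pieces <- lapply(blocks, function(block)
    normalise_read_ops(block, refseq, oriented[[block$read[1]]]))
  out <- rbind(ops[!sel, , drop = FALSE], do.call(rbind, pieces))
  rownames(out) <- NULL
  out[order(out$read, out$ref_start, out$read_start), , drop = FALSE]
}

normalise_read_ops <- function(block, refseq, readseq) {
  rows <- lapply(seq_len(nrow(block)), function(i) as.list(block[i, ]))
  k <- 2L
  while (k <= length(rows)) {
    op <- rows[[k]]
    if (!(op$op %in% c("D", "I"))) { k <- k + 1L; next }
    repeat {
      prev <- if (k > 1L) rows[[k - 1L]] else NULL
      if (is.null(prev) || prev$op != "=" || prev$len < 1L) break
      a <- op$ref_start; L <- op$len; r <- op$read_start
      shiftable <- if (op$op == "D") {
        base_at(refseq, a - 1L) == base_at(refseq, a + L - 1L)
      } else {
        substr(readseq, r + L, r + L) == base_at(refseq, a - 1L)
      }
      if (!shiftable) break
      # new match column appears just right of the gap
      new_ref <- if (op$op == "D") a + L - 1L else a - 1L
      new_read <- if (op$op == "D") r - 1L else r + L - 1L
      nxt <- if (k < length(rows)) rows[[k + 1L]] else NULL
      if (!is.null(nxt) && nxt$op == "=" &&
          nxt$ref_start == new_ref + 1L && nxt$read_start == new_read + 1L) {
        nxt$ref_start <- new_ref; nxt$read_start <- new_read
        nxt$len <- nxt$len + 1L
        rows[[k + 1L]] <- nxt
      } else {
        newrow <- list(read = op$read, op = "=", ref_start = new_ref,
                       len = 1L, read_start = new_read)
        rows <- append(rows, list(newrow), after = k)
      }
      op$ref_start <- a - 1L
      op$read_start <- r - 1L
      rows[[k]] <- op
      prev$len <- prev$len - 1L
      if (prev$len == 0L) {
        rows[[k - 1L]] <- NULL
        k <- k - 1L
      } else {
        rows[[k - 1L]] <- prev
      }
    }
    k <- k + 1L
  }
  data.frame(read = vapply(rows, `[[`, 0L, "read"),
             op = vapply(rows, `[[`, "", "op"),
             ref_start = vapply(rows, `[[`, 0L, "ref_start"),
             len = vapply(rows, `[[`, 0L, "len"),
             read_start = vapply(rows, `[[`, 0L, "read_start"),
             stringsAsFactors = FALSE)
}
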