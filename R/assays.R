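#' In-silico restriction digest of a molecule pool
#'
#' Cuts every molecule at each recognition site (cut placed `cut_offset`
#' bases into the site, default 1 for `W^CCGGW`) and aggregates fragment
#' lengths into a band table. The recognition pattern is matched on one
#' strand when it is its own reverse complement (as `WCCGGW` is); otherwise
#' both strands are scanned. Band intensity models densitometry as molecule
#' count times fragment length, alongside the raw counts.
#'
#' @param sequences Character vector or `DNAStringSet` of molecules
#'   (a multiset: duplicates represent abundance).
#' @param pattern IUPAC recognition pattern (default `"WCCGGW"`).
#' @param cut_offset Cut position within the pattern (default 1).
#' @return A `digest_result` list: `digested_fraction` (molecules cut at
#'   least once over total), `band_table` (length, count, intensity,
#'   intensity_fraction), `fragments` (per unique molecule class), and
#'   `n_molecules`.
#' @examples
#' digest_pool(c("AACCGGAATT", "TTTTTTTTTT"))$digested_fraction  # 0.5
#' @export
digest_pool <- function(sequences, pattern = BSAWI_PATTERN, cut_offset = 1L) {
  if (inherits(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop("empty molecule pool")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(pattern))
    stop("cut_offset must lie within the pattern")

  palindromic <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pattern))) == toupper(pattern)
  uniq <- unique(sequences)
  counts <- table(factor(sequences, levels = uniq))
  frag_list <- lapply(uniq, function(s) {
    sites <- find_recognition_sites(s, pattern)
    if (!palindromic) {
      rc_hits <- find_recognition_sites(s, as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(pattern))))
      sites <- sort(union(sites, rc_hits))
    }
    cuts <- sort(unique(sites + cut_offset))
    cuts <- cuts[cuts > 0L & cuts < nchar(s)]
    diff(c(0L, cuts, nchar(s)))
  })
  names(frag_list) <- uniq
  cut_class <- vapply(frag_list, function(f) length(f) > 1L, TRUE)
  digested_fraction <- sum(counts[cut_class]) / sum(counts)

  lens <- rep(unlist(frag_list, use.names = FALSE),
              rep(as.integer(counts), lengths(frag_list)))
  band <- aggregate(list(count = rep(1L, length(lens))),
                    by = list(length = lens), FUN = sum)
  band <- band[order(-band$length), , drop = FALSE]
  band$intensity <- band$count * band$length
  band$intensity_fraction <- band$intensity / sum(band$intensity)
  rownames(band) <- NULL
  structure(list(digested_fraction = unname(digested_fraction),
                 band_table = band, fragments = frag_list,
                 n_molecules = length(sequences)),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("digest_result: %d molecules, digested fraction %.4f\n",
              x$n_molecules, x$digested_fraction))
  print(utils::head(x$band_table, 10))
  invisible(x)
}

#' Surveyor/Cel-I indel-fraction estimate from a cleaved band fraction
#'
#' Under random reannealing of a pool with indel fraction p (all mutants
#' pairwise distinct), the heteroduplex (cleavable) fraction is
#' f = 1 - (1-p)^2 - p^2 ~ one minus the homoduplex fractions; neglecting
#' mutant:mutant homoduplexes this is f = 1 - (1-p)^2, inverted here as
#' p = 1 - sqrt(1 - f). The raw band fraction f is returned alongside the
#' corrected estimate since published gel quantifications do not always
#' state which convention was used.
#'
#' @param f Cleaved (heteroduplex) band fraction in `[0, 1]`.
#' @return A `surveyor_estimate` list: `cleaved_fraction`,
#'   `estimated_indel_fraction`.
#' @examples
#' surveyor_estimate(0.36)$estimated_indel_fraction  # 0.2
#' @export
surveyor_estimate <- function(f) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("cleaved fraction must be a single value in [0, 1]")
  structure(list(cleaved_fraction = f,
                 estimated_indel_fraction = 1 - sqrt(1 - f)),
            class = "surveyor_estimate")
}

#' @export
print.surveyor_estimate <- function(x, ...) {
  cat(sprintf("surveyor_estimate: cleaved fraction %.4f -> indel fraction %.4f\n",
              x$cleaved_fraction, x$estimated_indel_fraction))
  invisible(x)
}
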