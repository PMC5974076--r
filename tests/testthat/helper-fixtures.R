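# Shared fixtures and independent oracles used across test files.

.fixture_env <- new.env(parent = emptyenv())

# one moderately expensive reference shared by all tests
shared_ref <- function() {
  if (is.null(.fixture_env$ref))
    .fixture_env$ref <- build_reference(length = 1626, seed = 7)
  .fixture_env$ref
}

# Brute-force IUPAC pattern scan, independent of the package's matcher.
IUPAC <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

naive_scan <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  if (length(s) < length(p)) return(hits)
  for (i in 0:(length(s) - length(p))) {
    ok <- TRUE
    for (j in seq_along(p))
      if (!(s[i + j] %in% IUPAC[[p[j]]])) { ok <- FALSE; break }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# substring by 0-based half-open interval
slice0 <- function(seq, from, to) substr(seq, from + 1L, to)

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Leftmost score-equivalent placement of a deletion of length `len` whose
# removal from `refseq` reproduces `readseq` (exhaustive enumeration) —
# oracle for indel left-normalisation.
brute_leftmost_del <- function(refseq, readseq, len) {
  n <- nchar(refseq)
  for (d in 0:(n - len)) {
    cand <- paste0(substr(refseq, 1, d), substr(refseq, d + len + 1, n))
    if (cand == readseq) return(d)
  }
  NA_integer_
}

# Leftmost equivalent placement of an insertion: anchors d where removing
# `len` read bases starting at read position d - offset reproduces the
# reference slice.
brute_leftmost_ins <- function(refseq, readseq, len) {
  m <- nchar(readseq)
  for (d in 0:(m - len)) {
    cand <- paste0(substr(readseq, 1, d), substr(readseq, d + len + 1, m))
    if (cand == refseq) return(d)
  }
  NA_integer_
}
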