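#' @useDynLib editcall, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @importFrom stats runif rbinom rgeom aggregate setNames
#' @importFrom utils read.delim write.table
NULL

# Round half away from zero (commercial rounding), the convention used for
# all reported percentages; base round() rounds half to even.
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so seeded generators compose.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

BASES <- c("A", "C", "G", "T")

# 0-based single-base accessor/mutator on plain character sequences
base_at <- function(seq, pos0) substr(seq, pos0 + 1L, pos0 + 1L)
`base_at<-` <- function(seq, pos0, value) {
  substr(seq, pos0 + 1L, pos0 + 1L) <- value
  seq
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop(sprintf("'%s' must be a single non-negative integer", name), call. = FALSE)
}
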