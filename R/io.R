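#' Write a reference as FASTA plus a JSON coordinate sidecar
#'
#' The FASTA holds the scid-allele base sequence; the sidecar (written to
#' `<path>.json`) records every annotated coordinate in 0-based half-open
#' convention together with the RNG provenance, so simulator and classifier
#' runs agree on the same geometry.
#'
#' @param ref An `amplicon_reference`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  seqs <- Biostrings::DNAStringSet(ref$sequence)
  names(seqs) <- ref$label
  Biostrings::writeXStringSet(seqs, path)
  sidecar <- list(
    label = ref$label, length = ref$length,
    scid_pos = ref$scid_pos, scid_wt_base = ref$scid_wt_base,
    scid_mut_base = ref$scid_mut_base,
    cleavage_window = ref$cleavage_window,
    diag_subs = ref$diag_subs, bsawi_span = ref$bsawi_span,
    recurrent_del = as.list(ref$recurrent_del),
    layout = ref$layout, rng = ref$rng,
    coordinate_convention = ref$coordinate_convention)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a reference written by [write_reference()]
#' @param path FASTA path (sidecar expected at `<path>.json`).
#' @return An `amplicon_reference`.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ref <- structure(list(
    sequence = as.character(seqs[[1]]), length = side$length,
    scid_pos = as.integer(side$scid_pos),
    scid_wt_base = side$scid_wt_base, scid_mut_base = side$scid_mut_base,
    cleavage_window = as.integer(side$cleavage_window),
    diag_subs = as.data.frame(side$diag_subs),
    bsawi_span = as.integer(side$bsawi_span),
    recurrent_del = c(start = as.integer(side$recurrent_del$start),
                      length = as.integer(side$recurrent_del$length)),
    label = side$label, layout = side$layout, rng = side$rng,
    coordinate_convention = side$coordinate_convention),
    class = "amplicon_reference")
  validate_reference(ref)
  ref
}

#' Write simulated reads to FASTQ and their truth labels to TSV
#'
#' The truth table is deliberately kept out of the read names so that
#' classification cannot use it.
#'
#' @param sim A `simulated_reads` object from [simulate_reads()].
#' @param fastq,truth Output paths; a `.gz` suffix on `fastq` gzip-compresses.
#' @return Invisibly, a list with both paths.
#' @export
write_simulated_reads <- function(sim, fastq, truth) {
  qual <- strrep(rawToChar(as.raw(sim$config$base_quality + 33L)),
                 nchar(sim$reads))
  lines <- as.vector(rbind(paste0("@", sim$ids), sim$reads, "+", qual))
  con <- if (grepl("\\.gz$", fastq)) gzfile(fastq, "wb") else file(fastq, "wb")
  writeLines(lines, con)
  close(con)
  write.table(sim$truth, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fastq = fastq, truth = truth))
}

#' Read amplicon reads from a FASTQ file
#' @param path FASTQ path, optionally gzipped.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
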