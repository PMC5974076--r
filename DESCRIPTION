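Package: editcall
Title: Editing-Outcome Calling from Amplicon Deep Sequencing of
    Nuclease-Treated Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies targeted amplicon sequencing reads from zinc-finger
    nuclease (ZFN) gene-editing experiments into NHEJ indel, HDR-corrected,
    HDR-with-indel and unedited outcomes, using semi-global alignment with
    left-normalised indels against the sample's unedited allele. Includes a
    seeded read simulator with ground-truth labels for validation, in-silico
    models of the diagnostic BsaWI restriction (RFLP) assay and of the
    Surveyor/Cel-I heteroduplex-cleavage assay, per-sample editing-frequency
    summaries with deletion spectra, and off-target indel differential
    (nuclease minus mock) statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
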