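---
title: "Calling gene-editing outcomes from targeted amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling gene-editing outcomes from targeted amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editcall)
```

## The problem

Zinc-finger nucleases (ZFNs) repair a disease allele by cutting near the
mutation and letting the cell repair the break. Two outcomes compete at the
cut site: error-prone non-homologous end joining (NHEJ), which leaves small
insertions or deletions (indels), and homology-directed repair (HDR) from a
co-delivered template, which installs the intended substitutions. This
package implements the analysis used to quantify both outcomes from
targeted amplicon deep sequencing of a murine *Prkdc* scid model: per-read
classification against the sample's own unedited allele, per-sample editing
frequencies and deletion spectra, in-silico analogues of the two gel assays
used for orthogonal quantification (BsaWI RFLP and Surveyor/*Cel*-I), and
the per-site nuclease-minus-mock indel differentials used for off-target
assessment.

Because the underlying raw reads are not publicly deposited, the package
includes a first-class, seeded read simulator with ground-truth labels.
All validation claims below are exactly the properties the test suite and
`scripts/acceptance.R` compute.

## The modelled locus

`build_reference()` generates a random amplicon (default 1,626 bp, the
length of the short repair template) annotated with:

* the **scid position** (default index 800, 0-based), a T>A point mutation
  on the modelled strand;
* a **ZFN cleavage window**, default 5 bp starting 32 nt downstream of the
  scid base — the distance is stated for the locus, the window width is a
  modelling choice because the half-site/spacer geometry is not printed,
  and both are configurable in `reference_layout()`;
* two **silent diagnostic substitutions** 3 and 6 bp upstream of the scid
  base which, together with reversion of the scid base itself, create a
  single BsaWI site (`WCCGGW`) ending two bases upstream of the scid
  position — this reconciles the two published descriptions of the site's
  placement ("two nucleotides upstream" versus substitutions "3- and 6-bp
  upstream");
* a fixed **recurrent 44-bp deletion** centred on the cleavage window. Its
  true breakpoints are not printed (only that the 3′ end of the exon is
  lost), so the package fixes canonical breakpoints in the reference
  sidecar, and both simulator and classifier use the same left-normalised
  convention.

The construction guarantees a clean diagnostic readout: the corrected
allele contains exactly one `WCCGGW` occurrence, the scid and wild-type
alleles none, and the recurrent-deletion junction cannot form one either;
chance occurrences in the random background are locally rewritten. All
coordinates are 0-based half-open internally; printed reports are 1-based.

```{r}
ref <- build_reference(length = 1626, seed = 7)
ref
```

## Read classification

Reads are aligned semi-globally (read end-to-end, reference end gaps free)
to the **scid allele**, not the wild-type: the sequenced amplicons come
from scid cells, so their unedited state carries the scid base, and
scoring it as a mismatch would penalise every read. The three diagnostic
positions are instead evaluated explicitly after alignment.

Scoring defaults are match +2, mismatch −4, gap open −10, gap extend −1 (a
gap of length L costs 10 + L). This deliberately favours one long deletion
over a scatter of mismatches so that the 44-bp event is recovered as a
single operation. Both read orientations are scored and the better kept.
After alignment every indel is **left-normalised**: shifted to the leftmost
placement among score-equivalent ones (gap rotation for insertions), giving
each distinct molecular event one canonical `(start, length)` — the basis
of the deletion spectrum and of window-overlap decisions.

The aligner is a k-mer-seeded, banded, affine-gap dynamic program written
in C++; seeding only restricts the search band, and tests verify the band
reproduces the scores of an unconstrained alignment oracle.

A read passes the **high-quality filter** when (a) its alignment identity
over columns outside the cleavage neighbourhood (window padded by 50 bp,
wide enough to contain any qualifying indel) is ≥ 0.90, and (b) its aligned
span covers all three diagnostic positions and the full cleavage window.
The published criteria are unstated, so these are declared defaults, not
reconstructions; percentages are always computed on the passed-filter
denominator, so the filter's effect is fully visible in the per-read table.

Passed reads are called by two orthogonal features:

* **indel involvement** — any deletion overlapping the half-open window, or
  any insertion anchored in the closed window. The closed-interval rule for
  insertions interprets "involve any base of the cleavage site"
  inclusively; a toggle (`insertion_window_rule = "half-open"`) is
  provided.
* **diagnostic signature** — how many of the three expected substitutions
  the read carries (0–3).

| signature | no qualifying indel | qualifying indel |
|---|---|---|
| 0/3 | WT | NHEJ_INDEL |
| 1–2/3 | UNCLASSIFIED (partial HDR) | NHEJ_INDEL |
| 3/3 | HDR_CORRECTED | HDR_WITH_INDEL |

All three diagnostic bases must match exactly; up to 2 additional
mismatches elsewhere are tolerated before a diagnostic-complete read is
demoted to UNCLASSIFIED (at Q30 error rates this keeps the HDR
false-negative rate below 1%; the source analysis states no tolerance).
Substitution-only damage inside the window is *not* an indel: only
length-changing events count, matching the published definition.
Partial-HDR reads are never counted as corrected.

The headline correction percentage (`pct_corrected`) deliberately excludes
HDR_WITH_INDEL, matching the published convention that quoted correction
frequencies exclude indel-associated events; the excluded share is reported
separately as a fraction of total correction. `pct_indels` includes
HDR_WITH_INDEL by default, with a toggle, because the published indel
percentages do not state their convention.

## The simulator

`simulate_reads()` emulates the statistical structure of the study's MiSeq
amplicon data: single-end reads (default 150 bp, within the 100–200 bp
amplicon range), orientation randomised 50/50, constant Q30 qualities and
independent per-base substitution errors (default 0.001, the
Q30-consistent rate). Default outcome proportions are the deep-sequenced
ZFN + template condition: 18% NHEJ indels, 1.53% HDR-corrected, and an
HDR-with-indel share equal to 11.25% of total correction. Half of indel
events are the recurrent 44-bp deletion ("a significant proportion" is the
only published statement; the share is configurable and every acceptance
property is measured against the configured value, not an assumed one).
Non-recurrent deletions draw geometric lengths of mean 4 bp truncated at
60, insertions mean 2 bp, with insertions 25% of non-recurrent events —
all assumptions exposed in `simulation_config()`.

Three design rules keep truth labels well-defined:

* **Canonical placement.** An indel is labelled at its left-normalised
  position, and must involve the cleavage window *in canonical form*;
  a draw whose canonical placement slides out of the window is redrawn
  (such a molecule is indistinguishable from a non-window event). Whether
  an event is the recurrent deletion is decided once per read, before any
  redraw, so redraws cannot skew the recurrent fraction.
* **Diagnostic survival.** In HDR-with-indel molecules, non-recurrent
  deletions never reach the diagnostic bases — a read that lost them would
  be correctly indistinguishable from a pure NHEJ read. The recurrent
  deletion itself starts well downstream of the scid base.
* **Site-free junctions.** Edits whose junction would create a chance
  `WCCGGW` are redrawn, so in error-free pools the in-silico BsaWI digest
  signal equals the HDR truth fraction exactly.

The default sampling window guarantees that every read covers the
diagnostic positions and the full cleavage window, starts upstream of any
possible deletion breakpoint, and retains at least 20 bp of aligned
sequence beyond the window so indels stay recoverable by alignment;
configurations violating these are rejected rather than silently producing
unclassifiable reads.

Not modelled: PCR bias and chimeras, paired-end overlap, quality-score
degradation along the read, error correlation, and any locus-specific
sequence context (the reference background is random). Passing tests
therefore demonstrate correctness of the calling rules and arithmetic
under the stated error model — not robustness to artefacts real amplicon
libraries may contain.

## Assay models

`digest_pool()` cuts each molecule at every recognition site (cut offset 1
for `W^CCGGW`, which is its own reverse complement; non-palindromic
patterns are scanned on both strands) and reports the digested fraction,
fragment lengths and a band table with a densitometry proxy (count ×
length). Molecules whose indel destroyed the site count as undigested,
modelling the coupling between the recurrent deletion and loss of the
RFLP signal.

`make_heteroduplex_pool()` models the Surveyor/*Cel*-I reannealing step:
strand pairs drawn i.i.d. from allele fractions, cleavable iff the strands
differ. `surveyor_estimate()` converts a cleaved band fraction f to an
indel fraction via p = 1 − √(1 − f), the inverse of f = 1 − (1 − p)² for
random reannealing with pairwise-distinct mutants. The published
quantification ("Image J" band intensities) does not state whether this
correction was applied, so both the raw fraction and the corrected
estimate are always reported.

## Off-target differentials

`compute_differential()` is nuclease-minus-mock, rounded half away from
zero to 2 decimals — the convention consistent with the published
on-target rows — applied to unrounded summaries when available and to
printed values when reproducing the tables. Not-determined (ND) cells
propagate and are excluded from aggregation. The published aggregate
("average 0.03%, range −0.88 to 1.34%") is interpreted as the mean over
all non-ND off-target differentials pooled across the cultured-cell and
mouse tables (36 cells), since the sentence cites both; on-target rows are
excluded by default and negative differentials are reported as-is, never
clipped. The mouse table uses one animal's spleen as a shared background
column rather than paired mocks — `build_offtarget_table()` accepts any
site-keyed mock vector, so both designs are expressible.

## Validation sizes and numerical notes

The test suite checks per-read truth agreement on five category mixes of
10,000 error-free reads (expected: 100%), rate recovery within 3 binomial
standard errors at error rate 0.005, the deletion-spectrum share at
recurrent fraction 0.5, exact digest/truth equality on 8,000-read pools,
heteroduplex recovery at p ∈ {0.05, 0.18, 0.20} with 30,000 duplexes, and
byte-identical reproduction of FASTQ/truth outputs under fixed seeds.
Alignment scores are cross-checked against an independent
dynamic-programming implementation, left-normalisation against exhaustive
enumeration of equivalent placements, and pattern matching against a
brute-force IUPAC scan.

Percentages use half-away-from-zero rounding at 2 decimals throughout
(base R's `round()` rounds half to even). Ties between equally scoring
alignments are broken toward the leftmost indel placement. Degenerate
inputs — all-N reads, empty pools, zero passed reads, all-ND tables —
produce explicit results or errors, never division by zero.

## Limitations

The classifier is a single-amplicon caller: no genome-wide mapping, UMI
handling, paired-end merging, or base-quality recalibration. The true
locus sequence, primer sites and ZFN half-site geometry are not
reconstructed; conclusions about the real locus rest on the annotation
conventions above. The published sequencing-derived percentages are not
recomputable without the undeposited reads; what the package reproduces
exactly is the printed table arithmetic, and what it validates
statistically is its own calling machinery on ground-truth data emulating
the study's stated conditions.
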