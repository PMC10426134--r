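---
title: "mapquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mapquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapquant)
```

## The model

`mapquant` treats a peptide's RNA expression as a property of its *coding
sequences*, not of any annotated transcript. For a MAP (MHC-I-associated
peptide) of 8–11 residues, the set of MAP-coding sequences (MCS) is the
exhaustive reverse translation under the standard genetic code; its size is
the product of per-residue codon degeneracies (1 for M/W up to 6 for
L/R/S). The method then makes three assumptions, each of which shapes an
algorithmic contract:

* **Any perfect genomic origin may contribute.** A placement is retained
  iff every base matches the reference, or mismatches only at catalogued
  SNV positions with the matching alternate allele. This is an exact,
  enumerable rule, so the locator is implemented as exhaustive
  string matching (Biostrings `matchPattern`/`matchPDict`) rather than
  heuristic alignment: the contract *is* exhaustive perfect matching, and
  an exact search has no mapping failure modes in repetitive or
  hypervariable regions.
* **A read is evidence only if it spans the whole coding sequence.** A
  primary alignment record counts iff its aligned bases cover every
  genomic position of every block of the placement with the expected base
  at each, with no insertion, deletion or clipping inside the span. Reads,
  not fragments, are the counting unit (a pair whose two mates both span
  counts twice); `fragment_collapse = TRUE` switches to fragment counting.
* **Expression must be comparable across libraries of very different
  depth.** Totals are normalized to reads per hundred million
  (`RPHM = tr / R_t * 1e8`, `R_t` = total primary reads) and log-scaled as
  `log10(RPHM + 1)` before averaging.

## Coordinates

All internal coordinates are 1-based inclusive, the convention of the
IRanges/GenomicRanges/Biostrings stack this package is built on; GTF and
VCF inputs already use it, and BED (0-based half-open) is converted at the
parser boundary in both directions. Committing to the native convention of
the underlying containers avoids the off-by-one drift that mixing
conventions invites.

## The locator

`locate()` scans each chromosome with `matchPattern` (the reverse
complement of the query is matched for `-` strand placements, so all
comparisons happen on the `+` reference), allowing up to `max_mismatch`
mismatches (default 3, roughly one per codon on the shortest MCS) which
must all be SNV-licensed. When no SNV catalog is supplied the search is
exact and constant-width MCS pools are matched in one pass per chromosome
with `matchPDict`. A seed index (`build_index()`) is available as an
accelerator for exact lookup; it cannot shortcut the SNV-tolerant search,
because two licensed mismatches can shadow every seed window of a 24-nt
query.

Spliced placements are searched only across *annotated* junctions: the
exon chain of every multi-exon transcript is concatenated and matched, and
hits crossing at least one junction become multi-block locations.
De-novo junction discovery is out of scope; fully-exonic hits are left to
the contiguous search so the two paths never duplicate a placement.
`N` bases never match any query base, and soft-masked (lowercase)
reference bases are folded to uppercase at load so that repeat-derived
peptides remain findable.

## Counting and the strand table

Stranded selection implements the eight layout/chemistry/strand cases as
flag-bit tests: for a paired-end forward-chemistry library at a `+`
location, keep R1 carrying `0x60` (first-in-pair, mate-reverse) and R2
carrying `0x90`; at a `-` location, R1 `0x50` and R2 `0xA0`; reverse
chemistry swaps the two cases; single-end keeps reads whose alignment
orientation matches (forward chemistry) or opposes (reverse) the location
strand. Unstranded counting is exactly the union of the two stranded
selections, a property the test suite pins. Duplicate-marked reads
(0x400) are counted, since only 0x100 is filtered; supplementary records
(0x800) count toward `R_t` and toward spanning counts if they qualify.

## Biotype attribution and the EM

Each placement is intersected (strand-agnostic by default, `stranded =
TRUE` for strict matching) with transcript-derived features — CDS, UTRs,
non-coding and pseudogene exons, introns derived as inter-exon gaps — and
with a RepeatMasker-style repeat track grouped into ERE_LINE / ERE_SINE /
ERE_LTR / ERE_other. A placement overlapping both exonic and intronic
parts of one transcript is an exon–intron junction; one overlapping
nothing is intergenic. CDS overlaps are split into in-frame and
out-of-frame by an explicit frame check: all blocks inside the CDS,
splice-consistent with the transcript, same strand, and first base (in
coding order) on a codon boundary.

The EM estimates one coefficient per biotype class shared across all
queried peptides, every class starting at 0.1. E-step: peptide *i*'s reads
are distributed over classes, each location *k* contributing its reads
`r_k` split proportionally to the current coefficients of the classes
present at *k*, normalized by the peptide total `R_i`. M-step: the new
coefficient of class *j* is the mean over peptides of these distributions.
The printed form of the M-step sums the *parameters* rather than the
E-step distributions; summing parameters would make the E-step dead code,
so this package uses the only reading in which the update consumes the
E-step, and verifies it against closed-form degenerate cases (single-class
inputs recover exact read proportions; symmetric two-class locations give
equal shares). Convergence, printed as exact equality of successive
coefficient sets, is implemented as max-absolute-change `< 1e-8` with a
10,000-iteration cap — exact float equality is fragile; peptides with zero
reads are excluded from fitting, and classes absent from the data keep
coefficient 0.

Reporting follows three scopes: per-location shares (coefficients
restricted to the classes at the location and renormalized), a global
read-weighted profile, and the same per sample cohort; percentages sum to
100 at every scope. The best guess is in-frame whenever any in-frame
origin exists (with certainty equal to its percentage), otherwise the
argmax, with exact ties all reported.

## Prioritization

The tumor-specific-antigen cascade applies, in order: a no-location drop;
a tolerance filter (discard at mean RPHM ≥ 8.55 in any mTEC/DC group — the
8.55 RPHM default is the minimum expression conferring > 5% probability of
generating a MAP); a normal-tissue filter with the same rule; a ≥ 5-fold
tumor/normal change; and, when ribosome-profiling counts are supplied, a
requirement of at least one elongation read. Each discarded peptide
records exactly the stage that removed it. Thresholds apply to group
means by default, with a per-sample-maximum variant exposed. Three
choices were genuinely open and are this package's:

* Fold change adds a 0.5 pseudocount to the normal-mean denominator, the
  same offset used for log-scale plotting conventions, so a zero normal
  mean requires a tumor mean of at least `fold × 0.5`.
* The testis (cancer-testis) exemption uses the same 8.55 threshold as
  the filters — survivors hot only in exempt groups are flagged CTA —
  and exempt groups are also excluded from the fold-change denominator,
  since a candidate highly expressed in testis could otherwise never
  reach a fivefold ratio over "normal".
* The tolerance filter treats mTEC and DC groups as a union.

The immunogenicity model is an L2-regularized logistic regression
(glmnet, ridge, `lambda = 1/n`, the counterpart of a unit-cost liblinear
configuration; features unstandardized) on two features: mean RPHM in
mTEC and in DC samples. The cross-validation harness draws stratified
random splits, 10 repeats with 20% held out, and reports mean ROC-AUC.

## The synthetic-data generator

The fixtures emulate exactly the properties the method's contracts depend
on: planted coding sequences at known loci (contiguous, reverse-strand,
SNV-bearing, spliced), reads with correct mate/orientation flag patterns
per library configuration, decoy classes that must never count (off-by-one
near-spans, one-mismatch spans, clipped-inside-span, secondary records),
and background reads rejection-sampled clear of planted spans. Genomes are
rejection-screened so the only occurrences of any queried coding sequence
are the planted ones, making every ground-truth table exact. What the
generator does *not* emulate: sequencing error models, quality scores,
coverage biases, indel-containing alignments that real aligners produce,
paralog structure, or cohort-scale sample sizes — so passing tests
demonstrate correctness of the counting and attribution rules, not
robustness to noisy real-world alignment artifacts.

Simulation scales were chosen to exercise the contracts while keeping the
suite fast on one CPU: panel fixtures use 50 nine-residue peptides with
Poisson(12) spanning-read depth (10% of loci at zero) over ~15 kb of
genome with 300 background reads; locator-oracle fixtures use 100 seeded
~1 kb genomes; per-peptide MCS pools are capped at 32,768 (peptides above
the cap are redrawn, which slightly biases panels toward low-degeneracy
residues — acceptable, since pool size only scales the search, it does not
change any counting rule). The classifier checks use a 400-peptide
separable panel, and estimate the null as the mean CV AUC over ten label
permutations: a single permutation carries a spurious association of
order `1/sqrt(n)` and is not a stable estimate of chance performance.

## Numerical and degenerate-input choices

* Ties in the best guess are exact ties (tolerance 1e-9) and all tied
  classes are reported.
* A location whose classes all have zero coefficient falls back to uniform
  shares (only reachable for zero-read peptides excluded from fitting).
* `R_t = 0` (empty BAM) is an error, not a zero; "no genomic location" is
  a reported status distinct from "locations but zero reads".
* Cohort scopes with zero reads yield an undefined profile, reported as
  absent rather than fabricated.
* Manual-mode placements failing the perfect-alignment rule are rejected
  with a diagnostic; out-of-bounds coordinates are errors.
* Reports round log-RPHM to 4 decimals; reruns of the same configuration
  are byte-identical, and multi-worker counting reduces in sample order so
  results are independent of the worker count.

## Known limitations

* Spliced placements are limited to annotated junctions; a peptide
  spanning an unannotated junction is found only in contiguous form (or
  not at all).
* Indel-containing placements are not searched; only substitutions can be
  SNV-licensed.
* Biotype attributions are predictions about the likely origin of RNA
  reads, not evidence of translation; ribosome-profiling evidence enters
  only as a late cascade filter.
* Per-cell (barcode-split) counts are produced on request but their
  normalization is delegated downstream.
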