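# mapquant

Annotation-independent RNA-seq expression and probabilistic biotype
attribution for MHC-I-associated peptides (MAPs).

## The problem

MHC class I molecules present 8–11-residue peptides at the cell surface.
Many of these peptides do not come from annotated protein-coding exons —
they arise from introns, UTRs, non-coding RNAs, endogenous retroelements
(EREs) and intergenic regions — so transcript-level quantification tied to a
gene annotation systematically misses or mis-assigns their expression.
`mapquant` quantifies a peptide's RNA expression without assuming anything
about where it comes from:

1. **Reverse translation.** Each queried peptide is expanded into the
   complete set of MAP-coding sequences (MCS): every 24–33-nt nucleotide
   sequence whose translation equals the peptide
   (`∏ codon degeneracies` members, up to six codons per residue for L/R/S).
2. **Genomic placement.** Every MCS is matched exhaustively against both
   strands of the reference genome, and across annotated splice junctions.
   A placement is *perfect* when every base matches the reference or is a
   catalogued single-nucleotide variant whose alternate allele equals the
   query base; all other mismatches discard the placement.
3. **Read counting.** In each coordinate-sorted BAM/CRAM, primary alignment
   records (SAM flag 0x100 unset) that *exactly span* a placement — every
   genomic position covered, every aligned base equal to the expected base,
   no indel or clipping inside the span — are counted. Stranded libraries
   use the full eight-case selection table over library layout
   (single/paired), chemistry (forward/reverse) and location strand.
4. **Normalization.** Per-peptide totals are scaled to reads per hundred
   million, `RPHM = tr / R_t × 1e8`, where `R_t` is the sample's total
   primary reads, and reported alongside `log10(RPHM + 1)`.
5. **Biotype attribution.** Each placement is intersected with the gene
   annotation (with reading-frame checking inside CDS) and a RepeatMasker
   repeat track; reads of multi-mapping peptides are apportioned across
   biotype classes by expectation–maximization (coefficients initialized at
   0.1; E-step distributes each location's reads proportionally to the
   coefficients of the classes present there; M-step averages the
   distributions over peptides; iteration to a fixed point). Profiles are
   reported per location, per sample cohort and globally, plus a best guess:
   *in-frame* whenever any in-frame origin exists, otherwise the
   highest-share class, with exact ties reported jointly.
6. **Prioritization.** An expression matrix over sample groups feeds a
   tumor-specific-antigen cascade — thymic (mTEC/DC) tolerance filter at
   8.55 RPHM, normal-tissue filter with a cancer-testis (testis) exemption,
   ≥ 5-fold tumor/normal change, ribosome-profiling translation evidence —
   and an L2-regularized logistic immunogenicity model on mTEC and DC
   expression.

Everything is testable offline: the `fixtures` functions generate seeded
synthetic genomes, annotations, variant catalogs and BAM files with exact
ground truth.

## Worked example

A five-peptide synthetic experiment, end to end:

```r
library(mapquant)

dir <- file.path(tempdir(), "demo")
fx <- make_kmer_panel_fixture(dir, n_peptides = 5, seed = 42)
fx$peptides[, c("name", "peptide", "start", "expected")]
#>    name   peptide start expected
#> 1 pep01 EFQYVRDKE   200       13
#> 2 pep02 FPFYCIDAL   402       10
#> 3 pep03 MRIEEVPFE   604       19
#> 4 pep04 CVDTVGGCY   806       10
#> 5 pep05 DCGLIFATH  1008       11

samples <- data.frame(sample_name = "s1", bam = fx$bam,
                      layout = "single_end", chemistry = "forward",
                      strandedness = "stranded")
cfg <- run_config(genome = fx$genome_fa, peptide_file = fx$peptide_file,
                  samples = samples, output_dir = file.path(dir, "out"))
res <- run_query(cfg)
res$records[, c("peptide", "tr", "rphm", "log_rphm", "n_locations")]
#>   peptide tr    rphm log_rphm n_locations
#> 1   pep01 13 3581267 6.554037           1
#> 2   pep02 10 2754821 6.440094           1
#> 3   pep03 19 5234160 6.718847           1
#> 4   pep04 10 2754821 6.440094           1
#> 5   pep05 11 3030303 6.481486           1
```

Each peptide's total read count `tr` equals the number of spanning reads the
generator planted (`expected`); `rphm` is large because the fixture BAM is
tiny (363 primary reads), and `log_rphm` is the scale used for averaging
across samples. The output directory holds the expression grid,
per-location detail, a BED12 of all placements, the MCS pool as FASTQ, and
the run log.

A thin command-line front end with `query`, `fixtures`, `prioritize` and
`immunogenicity` subcommands is installed at `inst/cli/mapquant`.

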