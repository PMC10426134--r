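Package: mapquant
Title: Annotation-Independent RNA-Seq Expression and Biotype Attribution
    for MHC-I-Associated Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attributes an exhaustive RNA-seq expression level and a
    probabilistic biotype to MHC-I-associated peptides (MAPs, 8-11 residues).
    Each peptide is reverse-translated into every nucleotide sequence able to
    encode it (MCS); all perfect genomic origins are located on both strands,
    allowing mismatches only at catalogued single-nucleotide variants; reads
    that exactly span each coding sequence are counted in alignment files with
    full strand-chemistry awareness and normalized to reads per hundred
    million (RPHM); biotypes are apportioned across multi-mapping origins by
    expectation-maximization; and tumor-specific antigen candidates are
    prioritized by a thymic/normal-tissue filter cascade and a logistic
    immunogenicity model.  Ships a deterministic synthetic-fixture generator
    (genome, annotations, variants, alignments) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    data.table,
    glmnet,
    jsonlite,
    pROC,
    parallel,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
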