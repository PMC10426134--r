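# Standard genetic code, indexed codon -> residue and residue -> codons.
.GC <- Biostrings::GENETIC_CODE
.CODONS_BY_AA <- split(names(.GC), unname(.GC))

#' Number of synonymous codons for a residue
#'
#' @param amino_acid One of the 20 canonical one-letter amino-acid codes.
#' @return Integer count of standard-genetic-code codons encoding the
#'   residue (1 for M/W, up to 6 for L/R/S).
#' @examples
#' codon_degeneracy("L") # 6
#' codon_degeneracy("M") # 1
#' @export
codon_degeneracy <- function(amino_acid) {
  check_peptide_chars(amino_acid)
  vapply(strsplit(amino_acid, "")[[1]],
         function(a) length(.CODONS_BY_AA[[a]]), integer(1), USE.NAMES = FALSE)
}

check_peptide_chars <- function(peptide) {
  aas <- strsplit(peptide, "")[[1]]
  canonical <- setdiff(names(.CODONS_BY_AA), "*")
  bad <- setdiff(aas, canonical)
  if (length(bad))
    stop("Non-canonical residue(s) in peptide: ", paste(unique(bad), collapse = ", "))
  invisible(aas)
}

#' Reverse-translate a peptide into all coding sequences
#'
#' Enumerates every nucleotide sequence (MCS) whose translation under the
#' standard genetic code equals the peptide.  The result size is the product
#' of per-residue codon degeneracies; members are returned in lexicographic
#' order.
#'
#' @param peptide Uppercase peptide string; by default restricted to the
#'   8-11 residue range of MHC-I-associated peptides.
#' @param check_length Enforce the 8-11 residue envelope (`TRUE` for pipeline
#'   use; `FALSE` allows short test peptides).
#' @param max_mcs Safety cap on the enumeration size.
#' @return Character vector of MCS (each `3 * nchar(peptide)` nt).
#' @examples
#' length(reverse_translate("LL", check_length = FALSE)) # 36
#' @export
reverse_translate <- function(peptide, check_length = TRUE, max_mcs = 2^22) {
  aas <- check_peptide_chars(peptide)
  if (check_length && !(length(aas) >= 8L && length(aas) <= 11L))
    stop("Peptide '", peptide, "' has ", length(aas),
         " residues; supported range is 8-11")
  sizes <- vapply(aas, function(a) length(.CODONS_BY_AA[[a]]), integer(1))
  if (prod(sizes) > max_mcs)
    stop("Peptide '", peptide, "' expands to ", prod(sizes),
         " coding sequences (cap ", max_mcs, "); supply an MCS instead")
  out <- ""
  for (a in aas) out <- as.vector(outer(out, .CODONS_BY_AA[[a]], paste0))
  sort(out)
}

#' Translate a coding sequence
#'
#' @param mcs Nucleotide string over ACGT, length divisible by 3.
#' @param allow_stop If `FALSE` (default) a stop codon raises an error;
#'   otherwise stops appear as `*`.
#' @return Peptide string.
#' @export
translate_mcs <- function(mcs, allow_stop = FALSE) {
  if (nchar(mcs) %% 3L != 0L)
    stop("Sequence length ", nchar(mcs), " not divisible by 3")
  if (grepl("[^ACGT]", mcs))
    stop("Non-ACGT character in coding sequence")
  codons <- substring(mcs, seq(1L, nchar(mcs), 3L), seq(3L, nchar(mcs), 3L))
  pep <- paste(unname(.GC[codons]), collapse = "")
  if (!allow_stop && grepl("*", pep, fixed = TRUE))
    stop("Stop codon in coding sequence ", mcs)
  pep
}

#' Expand peptide queries into their MCS pools
#'
#' Peptide-mode queries are reverse-translated exhaustively; MCS-mode and
#' manual-mode queries contribute only their given coding sequence.
#'
#' @param queries Data frame from [parse_peptides()].
#' @return The input with a list-column `mcs_set`.
#' @export
expand_queries <- function(queries) {
  queries$mcs_set <- lapply(seq_len(nrow(queries)), function(i) {
    if (queries$mode[i] == "peptide") {
      reverse_translate(queries$peptide[i])
    } else {
      queries$mcs[i]
    }
  })
  queries
}

#' Write the MCS pool as FASTQ
#'
#' Compiles all coding sequences of peptide- and MCS-mode queries into a
#' FASTQ file (constant quality); manual-mode queries bypass the pool and go
#' straight to their stated location.
#'
#' @param queries Expanded queries (see [expand_queries()]).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
emit_mcs_fastq <- function(queries, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(queries))) {
    if (queries$mode[i] == "manual") next
    mcs <- queries$mcs_set[[i]]
    for (j in seq_along(mcs)) {
      writeLines(c(
        sprintf("@%s_%d", queries$name[i], j),
        mcs[j],
        "+",
        strrep("I", nchar(mcs[j]))
      ), con)
    }
  }
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' @param x Nucleotide string (ACGTN).
#' @return Reverse complement string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
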