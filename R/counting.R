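#' Describe an RNA-seq library
#'
#' @param layout `"single_end"` or `"paired_end"`.
#' @param chemistry `"forward"` (R1 is the sense mate) or `"reverse"`
#'   (R2 is the sense mate).  Ignored when `strandedness = "unstranded"`.
#' @param strandedness `"stranded"` (default) or `"unstranded"`.
#' @return A `LibraryConfig` list.
#' @export
lib_config <- function(layout = c("paired_end", "single_end"),
                       chemistry = c("forward", "reverse"),
                       strandedness = c("stranded", "unstranded")) {
  structure(list(layout = match.arg(layout), chemistry = match.arg(chemistry),
                 strandedness = match.arg(strandedness)),
            class = "LibraryConfig")
}

#' Total primary reads of a sample
#'
#' Counts alignment records with the secondary-alignment flag (0x100) unset
#' over the whole file; this equals the number of reads originally present in
#' the FASTQ files and is the RPHM denominator.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM/CRAM file.
#' @return Integer count (> 0).
#' @export
total_primary_reads <- function(bam) {
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE))
  n <- Rsamtools::countBam(bam, param = param)$records
  if (n <= 0L) stop("No primary reads in ", bam, "; cannot normalize")
  n
}

# The eight stranded-selection cases: which primary reads carry the
# transcription strand matching a location, by library layout, chemistry and
# location strand.  Bit tests reproduce the samtools -f masks:
#   paired/forward/- : R1 with 0x50, R2 with 0xA0
#   paired/forward/+ : R1 with 0x60, R2 with 0x90
#   single/forward/+ : 0x10 unset;  single/forward/- : 0x10 set
# and reverse chemistry swaps each pair of cases.
strand_keep <- function(flags, layout, chemistry, loc_strand) {
  bit <- function(mask) bitwAnd(flags, mask) == mask
  if (layout == "single_end") {
    fwd_reads <- bitwAnd(flags, 0x10) == 0L
    want_fwd <- (chemistry == "forward") == (loc_strand == "+")
    return(if (want_fwd) fwd_reads else !fwd_reads)
  }
  # paired end: "forward chemistry at a + location" selects R1 forward
  # (0x60 = first-in-pair + mate-reverse) and R2 reverse (0x90)
  r1_sense_fwd <- (chemistry == "forward") == (loc_strand == "+")
  if (r1_sense_fwd) {
    bit(0x60) | bit(0x90)
  } else {
    bit(0x50) | bit(0xA0)
  }
}

#' Retrieve candidate reads for a location
#'
#' Fetches primary alignment records overlapping the location span.  For
#' stranded libraries only reads whose inferred transcription strand equals
#' the location strand are kept, per the eight layout/chemistry/strand
#' selection cases; unstranded libraries keep all primary reads.
#'
#' @param bam Indexed BAM/CRAM path.
#' @param location One location row (see [locate()]).
#' @param config A `LibraryConfig`.
#' @param barcode_tag Optional BAM tag (e.g. `"CB"`) to retrieve for
#'   per-cell splitting.
#' @return Data frame of reads: `qname`, `flag`, `pos`, `cigar`, `seq`
#'   (and `barcode` if requested).
#' @export
select_reads <- function(bam, location, config, barcode_tag = NULL) {
  stopifnot(inherits(config, "LibraryConfig"))
  which <- GenomicRanges::GRanges(location$chrom,
                                  IRanges::IRanges(location$start, location$end))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE),
    what = c("qname", "flag", "pos", "cigar", "seq"),
    tag = if (is.null(barcode_tag)) character() else barcode_tag,
    which = which)
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  reads <- data.frame(qname = res$qname, flag = res$flag, pos = res$pos,
                      cigar = res$cigar, seq = as.character(res$seq),
                      stringsAsFactors = FALSE)
  if (!is.null(barcode_tag)) {
    bc <- res$tag[[barcode_tag]]
    reads$barcode <- if (is.null(bc)) NA_character_ else as.character(bc)
  }
  reads <- reads[!is.na(reads$pos) & !is.na(reads$cigar), , drop = FALSE]
  if (config$strandedness == "stranded" && nrow(reads) > 0L) {
    keep <- strand_keep(reads$flag, config$layout, config$chemistry,
                        location$strand)
    reads <- reads[keep, , drop = FALSE]
  }
  reads
}

# Walk one alignment's CIGAR: return the read base aligned to each requested
# genomic position (NA if unaligned there) and whether any insertion falls
# strictly inside a covered stretch of the requested blocks.
aligned_bases_at <- function(pos, cigar, seq, gpos) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  g <- pos        # next genomic position
  r <- 1L         # next read offset
  base <- rep(NA_character_, length(gpos))
  ins_breakpoints <- integer()
  seq_chars <- strsplit(seq, "")[[1]]
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      idx <- which(gpos >= g & gpos < g + len)
      if (length(idx)) base[idx] <- seq_chars[r + (gpos[idx] - g)]
      g <- g + len; r <- r + len
    } else if (op == "I") {
      ins_breakpoints <- c(ins_breakpoints, g)  # insertion between g-1 and g
      r <- r + len
    } else if (op %in% c("D", "N")) {
      g <- g + len
    } else if (op == "S") {
      r <- r + len
    }
    # H and P consume neither sequence we track
  }
  list(base = base, ins_breakpoints = ins_breakpoints)
}

#' Count reads exactly spanning a location
#'
#' A read counts if and only if its aligned bases cover every genomic
#' position of every block of the location and each aligned base equals the
#' location's strand-oriented expected base (the reference base, or the
#' licensed SNV alternate where the coding sequence carries one).  Reads with
#' indels or clipping inside the spanned positions do not count; each
#' alignment record counts at most once.
#'
#' @param reads Data frame from [select_reads()].
#' @param location One location row.
#' @return Integer count.
#' @export
count_mcs_reads <- function(reads, location) {
  sum(read_matches_location(reads, location))
}

read_matches_location <- function(reads, location) {
  if (nrow(reads) == 0L) return(logical(0))
  blocks <- location_blocks(location)
  gpos <- unlist(lapply(seq_len(nrow(blocks)),
                        function(i) blocks[i, "start"]:blocks[i, "end"]))
  expected <- if (location$strand == "+") location$mcs else revcomp(location$mcs)
  exp_chars <- strsplit(expected, "")[[1]]
  vapply(seq_len(nrow(reads)), function(j) {
    ab <- aligned_bases_at(reads$pos[j], reads$cigar[j], reads$seq[j], gpos)
    if (anyNA(ab$base) || !all(ab$base == exp_chars)) return(FALSE)
    for (p in ab$ins_breakpoints) {
      if (any(blocks[, "start"] < p & p <= blocks[, "end"])) return(FALSE)
    }
    TRUE
  }, logical(1))
}

#' Count a peptide's reads in one sample
#'
#' Applies [select_reads()] and [count_mcs_reads()] at every (deduplicated)
#' location of the peptide and sums the per-location counts into the
#' peptide's total read count.
#'
#' @param bam Indexed BAM/CRAM path.
#' @param locations Location data.frame for one peptide.
#' @param config A `LibraryConfig`.
#' @param fragment_collapse If `TRUE`, count fragments (unique read names)
#'   rather than reads, so a pair whose two mates both span a location
#'   contributes once.  Default `FALSE`: per-read counting.
#' @return List with `per_location` (location data.frame plus `count`) and
#'   `tr` (integer total).
#' @export
count_peptide <- function(bam, locations, config, fragment_collapse = FALSE) {
  locations <- locations[!duplicated(locations$loc_id), , drop = FALSE]
  if (nrow(locations) == 0L)
    return(list(per_location = cbind(empty_locations(), count = integer()),
                tr = 0L, no_location = TRUE))
  counts <- integer(nrow(locations))
  for (i in seq_len(nrow(locations))) {
    loc <- locations[i, , drop = FALSE]
    reads <- select_reads(bam, loc, config)
    hit <- read_matches_location(reads, loc)
    counts[i] <- if (fragment_collapse) {
      length(unique(reads$qname[hit]))
    } else {
      sum(hit)
    }
  }
  locations$count <- counts
  list(per_location = locations, tr = sum(counts), no_location = FALSE)
}

#' Per-cell-barcode counts at a location
#'
#' Splits the exact-spanning read count of one location by a cell-barcode
#' tag.  Normalization of the resulting per-cell table is left downstream.
#'
#' @inheritParams select_reads
#' @param barcode_tag BAM tag holding the cell barcode (default `"CB"`).
#' @return Named integer vector of counts per barcode (unbarcoded reads under
#'   `NA`).
#' @export
count_by_barcode <- function(bam, location, config, barcode_tag = "CB") {
  reads <- select_reads(bam, location, config, barcode_tag = barcode_tag)
  hit <- read_matches_location(reads, location)
  bc <- reads$barcode[hit]
  tab <- table(bc, useNA = "ifany")
  stats::setNames(as.integer(tab), names(tab))
}

#' Reads-per-hundred-million normalization
#'
#' `RPHM = tr / R_t * 1e8`, where `tr` is the peptide's total spanning-read
#' count and `R_t` the sample's total primary reads.
#'
#' @param tr Total read count for a peptide in a sample.
#' @param R_t Total primary reads of the sample.
#' @return RPHM value.
#' @export
rphm <- function(tr, R_t) {
  if (any(R_t <= 0)) stop("R_t must be > 0")
  tr / R_t * 1e8
}

#' Log-scale RPHM
#'
#' `log10(RPHM + 1)`, removing the bias of large values so samples can be
#' compared and averaged.
#'
#' @param rphm RPHM value(s).
#' @return `log10(rphm + 1)`.
#' @export
log_rphm <- function(rphm) log10(rphm + 1)

#' Expression records for peptides across samples
#'
#' @param peptide_locations Named list: peptide name -> location data.frame.
#' @param samples Data frame with columns `sample_name`, `bam`, and
#'   optionally `layout`, `chemistry`, `strandedness` (defaults: paired_end,
#'   forward, stranded).
#' @param fragment_collapse See [count_peptide()].
#' @return List with `records` (peptide x sample data.frame of `tr`, `rphm`,
#'   `log_rphm`, `n_locations`, `no_location`) and `per_location` (long
#'   data.frame of per-location counts).
#' @export
count_samples <- function(peptide_locations, samples, fragment_collapse = FALSE) {
  recs <- list(); locs <- list()
  for (s in seq_len(nrow(samples))) {
    cfg <- lib_config(
      layout = if ("layout" %in% names(samples)) samples$layout[s] else "paired_end",
      chemistry = if ("chemistry" %in% names(samples)) samples$chemistry[s] else "forward",
      strandedness = if ("strandedness" %in% names(samples)) samples$strandedness[s] else "stranded")
    R_t <- total_primary_reads(samples$bam[s])
    for (pep in names(peptide_locations)) {
      res <- count_peptide(samples$bam[s], peptide_locations[[pep]], cfg,
                           fragment_collapse = fragment_collapse)
      recs[[length(recs) + 1L]] <- data.frame(
        peptide = pep, sample_name = samples$sample_name[s],
        tr = res$tr, R_t = R_t, rphm = rphm(res$tr, R_t),
        log_rphm = log_rphm(rphm(res$tr, R_t)),
        n_locations = nrow(res$per_location),
        no_location = res$no_location, stringsAsFactors = FALSE)
      if (nrow(res$per_location) > 0L) {
        pl <- res$per_location
        pl$peptide <- pep
        pl$sample_name <- samples$sample_name[s]
        locs[[length(locs) + 1L]] <- pl
      }
    }
  }
  list(records = do.call(rbind, recs),
       per_location = if (length(locs)) do.call(rbind, locs) else NULL)
}
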