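#' Load a reference genome from FASTA
#'
#' Reads a (possibly soft-masked) FASTA file into an in-memory reference.
#' Lowercase (soft-masked) bases are folded to uppercase so that repeat
#' regions remain searchable; `N` bases are preserved and never match any
#' query base downstream.
#'
#' @param path Path to a FASTA file. An accompanying `.fai` index is not
#'   required.
#' @return A `ReferenceGenome` object: a list with `seq` (a named
#'   [Biostrings::DNAStringSet]) and `lengths` (named integer vector of
#'   chromosome lengths).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' g <- load_genome(fa)
#' genome_fetch(g, "chr1", 1, 8) # "ACGTACGT"
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no sequences: ", path)
  # FASTA description lines may carry annotations after the name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup)) stop("Duplicate chromosome name(s) in FASTA: ",
                        paste(unique(dup), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  structure(
    list(seq = seqs, lengths = stats::setNames(Biostrings::width(seqs), names(seqs))),
    class = "ReferenceGenome"
  )
}

#' Fetch a reference slice
#'
#' @param genome A `ReferenceGenome`.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return Uppercase nucleotide string of length `end - start + 1`.
#' @export
genome_fetch <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "ReferenceGenome"))
  if (!chrom %in% names(genome$seq)) stop("Unknown chromosome: ", chrom)
  len <- genome$lengths[[chrom]]
  if (start < 1L || end > len || start > end)
    stop(sprintf("Interval %s:%d-%d out of bounds (length %d)", chrom, start, end, len))
  as.character(Biostrings::subseq(genome$seq[[chrom]], start, end))
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat("ReferenceGenome:", length(x$seq), "sequence(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Load gene and repeat annotations into an interval index
#'
#' Parses a GENCODE-dialect GTF and a RepeatMasker-style BED6+2 repeat track
#' (columns 7-8 = repeat class, repeat family) into a queryable index.
#' Introns are derived as the gaps between consecutive exons of each
#' transcript; 5'/3' UTRs are derived as the exonic residue outside the CDS,
#' sided by the transcript strand.  Intergenic is represented by the absence
#' of any overlap.
#'
#' @param path_gtf GTF file with `exon` and `CDS` records carrying
#'   `transcript_id`, `gene_id` and a biotype attribute.
#' @param path_ere_bed Optional BED6+2 file of endogenous retroelements;
#'   `NULL` for none.
#' @return An `AnnotationIndex`: list with `features` (a
#'   [GenomicRanges::GRanges] of exon/CDS/UTR/intron spans with transcript
#'   metadata), `transcripts` (per-transcript models) and `ere` (GRanges of
#'   repeats with `repeat_name`, `repeat_class`, `repeat_family`).
#' @export
load_annotations <- function(path_gtf, path_ere_bed = NULL) {
  gtf <- rtracklayer::import(path_gtf, format = "gtf")
  keep <- gtf$type %in% c("exon", "CDS")
  gtf <- gtf[keep]
  need <- c("transcript_id", "gene_id")
  skipped <- 0L
  for (att in need) {
    if (is.null(S4Vectors::mcols(gtf)[[att]])) {
      S4Vectors::mcols(gtf)[[att]] <- NA_character_
    }
    bad <- is.na(S4Vectors::mcols(gtf)[[att]])
    if (any(bad)) {
      skipped <- skipped + sum(bad)
      gtf <- gtf[!bad]
    }
  }
  if (skipped > 0L)
    warning(skipped, " GTF record(s) without mandatory attributes skipped")
  if (length(gtf) == 0L) stop("No usable exon/CDS records in ", path_gtf)

  biotype <- S4Vectors::mcols(gtf)$transcript_biotype
  if (is.null(biotype)) biotype <- S4Vectors::mcols(gtf)$transcript_type
  if (is.null(biotype)) biotype <- S4Vectors::mcols(gtf)$gene_biotype
  if (is.null(biotype)) biotype <- rep("protein_coding", length(gtf))
  biotype[is.na(biotype)] <- "protein_coding"
  S4Vectors::mcols(gtf)$tx_biotype <- biotype

  gene_name <- S4Vectors::mcols(gtf)$gene_name
  if (is.null(gene_name)) gene_name <- S4Vectors::mcols(gtf)$gene_id
  S4Vectors::mcols(gtf)$gname <- gene_name

  txs <- split(gtf, S4Vectors::mcols(gtf)$transcript_id)
  transcripts <- lapply(txs, function(g) {
    ex <- g[g$type == "exon"]
    cds <- g[g$type == "CDS"]
    o <- order(GenomicRanges::start(ex))
    ex <- ex[o]
    cds <- cds[order(GenomicRanges::start(cds))]
    list(
      transcript_id = g$transcript_id[1],
      gene_id = g$gene_id[1],
      gene_name = g$gname[1],
      chrom = as.character(GenomicRanges::seqnames(g))[1],
      strand = as.character(GenomicRanges::strand(g))[1],
      biotype = g$tx_biotype[1],
      exons = IRanges::IRanges(GenomicRanges::start(ex), GenomicRanges::end(ex)),
      cds = IRanges::IRanges(GenomicRanges::start(cds), GenomicRanges::end(cds))
    )
  })

  feats <- do.call(rbind, lapply(transcripts, transcript_features))
  features <- GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand,
    feature = feats$feature,
    transcript_id = feats$transcript_id,
    gene_id = feats$gene_id,
    gene_name = feats$gene_name,
    tx_biotype = feats$biotype
  )

  ere <- GenomicRanges::GRanges()
  if (!is.null(path_ere_bed)) {
    ere <- rtracklayer::import(
      path_ere_bed, format = "BED",
      extraCols = c(repeat_class = "character", repeat_family = "character")
    )
    names(S4Vectors::mcols(ere))[names(S4Vectors::mcols(ere)) == "name"] <- "repeat_name"
    if (any(GenomicRanges::width(ere) < 1L)) stop("Empty repeat interval in ", path_ere_bed)
    if (any(is.na(ere$repeat_class) | ere$repeat_class == ""))
      stop("Repeat record without class in ", path_ere_bed)
  }

  structure(list(features = features, transcripts = transcripts, ere = ere),
            class = "AnnotationIndex")
}

# Flatten one transcript model into feature rows:
# CDS, UTR5/UTR3 (coding transcripts), exon (non-coding), intron.
transcript_features <- function(tx) {
  rows <- list()
  add <- function(feature, ir) {
    if (length(ir) == 0L) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = tx$chrom, start = IRanges::start(ir), end = IRanges::end(ir),
      strand = tx$strand, feature = feature,
      transcript_id = tx$transcript_id, gene_id = tx$gene_id,
      gene_name = tx$gene_name, biotype = tx$biotype,
      stringsAsFactors = FALSE
    )
  }
  exons <- IRanges::reduce(tx$exons)
  if (length(tx$cds) > 0L) {
    cds <- IRanges::reduce(tx$cds)
    add("CDS", cds)
    utr <- IRanges::setdiff(exons, cds)
    if (length(utr) > 0L) {
      cds_start <- min(IRanges::start(cds))
      cds_end <- max(IRanges::end(cds))
      left <- utr[IRanges::end(utr) < cds_start]
      right <- utr[IRanges::start(utr) > cds_end]
      if (tx$strand == "+") {
        add("UTR5", left); add("UTR3", right)
      } else {
        add("UTR3", left); add("UTR5", right)
      }
    }
  } else {
    add("exon", exons)
  }
  introns <- IRanges::setdiff(
    IRanges::IRanges(min(IRanges::start(exons)), max(IRanges::end(exons))), exons)
  add("intron", introns)
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Query annotation features overlapping an interval
#'
#' @param index An `AnnotationIndex`.
#' @param chrom,start,end 1-based inclusive query interval.
#' @return List with `features` (data.frame of transcript-derived features
#'   overlapping the query, with per-feature overlap width in bp) and `ere`
#'   (data.frame of overlapping repeats).  Both empty for intergenic queries.
#' @export
query_features <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "AnnotationIndex"))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  out_f <- data.frame()
  if (length(index$features) > 0L) {
    hits <- GenomicRanges::findOverlaps(q, index$features, ignore.strand = TRUE)
    f <- index$features[S4Vectors::subjectHits(hits)]
    if (length(f) > 0L) {
      ov <- GenomicRanges::pintersect(f, rep(q, length(f)), ignore.strand = TRUE)
      out_f <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(f)),
        start = GenomicRanges::start(f), end = GenomicRanges::end(f),
        strand = as.character(GenomicRanges::strand(f)),
        feature = f$feature, transcript_id = f$transcript_id,
        gene_id = f$gene_id, gene_name = f$gene_name,
        biotype = f$tx_biotype,
        overlap_bp = GenomicRanges::width(ov),
        stringsAsFactors = FALSE
      )
    }
  }
  out_e <- data.frame()
  if (length(index$ere) > 0L) {
    hits <- GenomicRanges::findOverlaps(q, index$ere, ignore.strand = TRUE)
    e <- index$ere[S4Vectors::subjectHits(hits)]
    if (length(e) > 0L) {
      ov <- GenomicRanges::pintersect(e, rep(q, length(e)), ignore.strand = TRUE)
      out_e <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(e)),
        start = GenomicRanges::start(e), end = GenomicRanges::end(e),
        strand = as.character(GenomicRanges::strand(e)),
        repeat_name = e$repeat_name, repeat_class = e$repeat_class,
        repeat_family = e$repeat_family,
        overlap_bp = GenomicRanges::width(ov),
        stringsAsFactors = FALSE
      )
    }
  }
  list(features = out_f, ere = out_e)
}

#' Load single-nucleotide variants from a VCF
#'
#' Only single-nucleotide substitutions are retained: indels and
#' multi-nucleotide variants are skipped.  Multiallelic SNVs keep every
#' single-base alternate allele.  Positions are 1-based as in the VCF.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param region_filter Optional `GRanges`; keep only variants overlapping it.
#' @return An `SNVCatalog`: a keyed [data.table::data.table] with columns
#'   `chrom`, `pos`, `ref`, `alt` (one row per alternate allele).
#' @export
load_snvs <- function(path, region_filter = NULL) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(empty_snv_catalog())
  }
  dt <- data.table::data.table(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = toupper(fix$REF), alt = toupper(fix$ALT)
  )
  dt <- dt[!is.na(pos) & !is.na(alt)]
  dt <- dt[, list(alt = unlist(strsplit(alt, ",", fixed = TRUE))),
           by = c("chrom", "pos", "ref")]
  dt <- dt[nchar(ref) == 1L & nchar(alt) == 1L &
             ref %chin% c("A", "C", "G", "T") & alt %chin% c("A", "C", "G", "T")]
  if (!is.null(region_filter)) {
    gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
    dt <- dt[S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, region_filter,
                                                              ignore.strand = TRUE))]
  }
  dt <- unique(dt)
  data.table::setkeyv(dt, c("chrom", "pos"))
  structure(list(table = dt), class = "SNVCatalog")
}

empty_snv_catalog <- function() {
  dt <- data.table::data.table(chrom = character(), pos = integer(),
                               ref = character(), alt = character())
  data.table::setkeyv(dt, c("chrom", "pos"))
  structure(list(table = dt), class = "SNVCatalog")
}

#' Alternate alleles catalogued at a position
#'
#' @param catalog An `SNVCatalog` (or `NULL`, treated as empty).
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @return Character vector of single-base alternate alleles (possibly empty).
#' @export
snv_alts <- function(catalog, chrom, pos) {
  if (is.null(catalog)) return(character())
  stopifnot(inherits(catalog, "SNVCatalog"))
  # query values must not share names with table columns or the join
  # would resolve them to the columns themselves
  .qchrom <- chrom
  .qpos <- as.integer(pos)
  hit <- catalog$table[list(.qchrom, .qpos), nomatch = NULL]
  hit$alt
}
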