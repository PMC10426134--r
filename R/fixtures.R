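# Synthetic-fixture generators: fully deterministic given a seed, each
# fixture ships its own ground truth so oracle comparisons are exact.

#' Write sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

#' Write transcript models as GENCODE-dialect GTF
#'
#' @param transcripts List of transcript descriptions: each a list with
#'   `transcript_id`, `gene_id`, `gene_name`, `chrom`, `strand`, `biotype`,
#'   `exons` (two-column matrix start/end) and optional `cds`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in transcripts) {
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_name "%s"; transcript_biotype "%s";',
      tx$gene_id, tx$transcript_id, tx$gene_name, tx$biotype)
    ex <- tx$exons
    for (i in seq_len(nrow(ex)))
      writeLines(paste(tx$chrom, "fixture", "exon", ex[i, 1], ex[i, 2], ".",
                       tx$strand, ".", attrs, sep = "\t"), con)
    if (!is.null(tx$cds) && nrow(tx$cds) > 0L) {
      cds <- tx$cds[order(tx$cds[, 1]), , drop = FALSE]
      ord <- if (tx$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
      cum <- 0L
      phase <- integer(nrow(cds))
      for (i in ord) {
        phase[i] <- (3L - cum %% 3L) %% 3L
        cum <- cum + cds[i, 2] - cds[i, 1] + 1L
      }
      for (i in seq_len(nrow(cds)))
        writeLines(paste(tx$chrom, "fixture", "CDS", cds[i, 1], cds[i, 2], ".",
                         tx$strand, phase[i], attrs, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a RepeatMasker-style BED6+2 repeat track
#' @param ere Data frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `name`, `strand`, `repeat_class`, `repeat_family`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ere_bed <- function(ere, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ere)))
    writeLines(paste(ere$chrom[i], ere$start[i] - 1L, ere$end[i], ere$name[i],
                     0L, ere$strand[i], ere$repeat_class[i],
                     ere$repeat_family[i], sep = "\t"), con)
  invisible(path)
}

#' Write an SNV catalog as VCF
#' @param snvs Data frame: `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(snvs)))
    writeLines(paste(snvs$chrom[i], snvs$pos[i], paste0("rs", i), snvs$ref[i],
                     snvs$alt[i], ".", "PASS", ".", sep = "\t"), con)
  invisible(path)
}

#' Write alignment records as SAM and convert to sorted, indexed BAM
#'
#' @param reads Data frame: `qname`, `flag`, `chrom`, `pos`, `cigar`, `seq`,
#'   and optionally `rnext`, `pnext`, `tlen`.
#' @param chrom_lengths Named integer vector for the header.
#' @param bam_path Destination BAM path (index written alongside).
#' @return `bam_path`, invisibly.
#' @export
write_bam <- function(reads, chrom_lengths, bam_path) {
  sam <- tempfile(fileext = ".sam")
  con <- file(sam, "w")
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(chrom_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, chrom_lengths[[nm]]), con)
  rnext <- if ("rnext" %in% names(reads)) reads$rnext else rep("*", nrow(reads))
  pnext <- if ("pnext" %in% names(reads)) reads$pnext else rep(0L, nrow(reads))
  tlen <- if ("tlen" %in% names(reads)) reads$tlen else rep(0L, nrow(reads))
  for (i in seq_len(nrow(reads)))
    writeLines(paste(reads$qname[i], reads$flag[i], reads$chrom[i],
                     reads$pos[i], 60L, reads$cigar[i], rnext[i], pnext[i],
                     tlen[i], reads$seq[i], strrep("I", nchar(reads$seq[i])),
                     sep = "\t"), con)
  close(con)
  tmp <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(tmp, sub("\\.bam$", "", bam_path))
  Rsamtools::indexBam(sorted)
  unlink(c(sam, tmp))
  invisible(sorted)
}

#' Random background genome
#'
#' @param lengths Named integer vector of chromosome lengths.
#' @return Named character vector of uniform-random ACGT sequences (uses the
#'   current RNG state; seed upstream for determinism).
#' @export
random_genome <- function(lengths) {
  vapply(lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
}

splice_in <- function(seq, at, piece) {
  paste0(substr(seq, 1L, at - 1L), piece,
         substr(seq, at + nchar(piece), nchar(seq)))
}

# Flags of a simulated read pair/single read.  `sense` means the fragment
# carries the transcription strand of the locus; forward chemistry sequences
# the sense strand as R1, reverse chemistry as R2.
sim_flags <- function(layout, chemistry, loc_strand, sense) {
  frag_strand <- if (sense) loc_strand else setdiff(c("+", "-"), loc_strand)
  if (layout == "single_end") {
    read_strand <- if (chemistry == "forward") frag_strand else
      setdiff(c("+", "-"), frag_strand)
    return(list(r1 = if (read_strand == "-") 0x10 else 0x0))
  }
  r1_strand <- if (chemistry == "forward") frag_strand else
    setdiff(c("+", "-"), frag_strand)
  if (r1_strand == "+") {
    list(r1 = bitwOr(bitwOr(0x1, 0x2), bitwOr(0x40, 0x20)),   # R1 fwd, mate rev
         r2 = bitwOr(bitwOr(0x1, 0x2), bitwOr(0x80, 0x10)))   # R2 rev
  } else {
    list(r1 = bitwOr(bitwOr(0x1, 0x2), bitwOr(0x40, 0x10)),
         r2 = bitwOr(bitwOr(0x1, 0x2), bitwOr(0x80, 0x20)))
  }
}

#' Simulate reads around one location
#'
#' Emits the requested number of exactly-spanning reads (read sequence taken
#' verbatim from the planted genome, so it matches the coding sequence), plus
#' optional decoy classes that must never be counted: off-by-one near-spans,
#' one-mismatch spans, reads soft-clipped inside the span, and secondary
#' duplicates.
#'
#' @param genome_seqs Named character vector (planted genome).
#' @param loc One location row (the planted placement).
#' @param n_sense,n_antisense Spanning fragments on the sense / antisense
#'   transcription strand of the location.
#' @param config A `LibraryConfig` (decides mate flags).
#' @param read_length Read length.
#' @param n_offby1,n_mismatch,n_clipped,n_secondary Decoy counts.
#' @param prefix Read-name prefix.
#' @return Read data.frame for [write_bam()].
#' @export
sim_location_reads <- function(genome_seqs, loc, n_sense, n_antisense = 0L,
                               config = lib_config("single_end", "forward"),
                               read_length = 51L, n_offby1 = 0L,
                               n_mismatch = 0L, n_clipped = 0L,
                               n_secondary = 0L, prefix = "r") {
  chrom <- loc$chrom
  s <- loc$start; e <- loc$end
  clen <- nchar(genome_seqs[[chrom]])
  L <- read_length
  slice <- function(p) substr(genome_seqs[[chrom]], p, p + L - 1L)
  rows <- list()
  emit <- function(qname, flag, pos, cigar, seq, rnext = "*", pnext = 0L) {
    rows[[length(rows) + 1L]] <<- data.frame(
      qname = qname, flag = flag, chrom = chrom, pos = pos, cigar = cigar,
      seq = seq, rnext = rnext, pnext = pnext, tlen = 0L,
      stringsAsFactors = FALSE)
  }
  span_start <- function() {
    lo <- max(1L, e - L + 1L); hi <- min(s, clen - L + 1L)
    if (hi < lo) stop("read_length too short to span the location")
    lo + sample.int(hi - lo + 1L, 1L) - 1L
  }
  emit_fragment <- function(qname, sense) {
    fl <- sim_flags(config$layout, config$chemistry, loc$strand, sense)
    p1 <- span_start()
    if (config$layout == "single_end") {
      emit(qname, fl$r1, p1, paste0(L, "M"), slice(p1))
    } else {
      # mate placed clear of the span so only R1 can count
      p2 <- if (p1 + 2L * L + 10L <= clen) p1 + L + 10L else max(1L, p1 - L - 10L)
      emit(qname, fl$r1, p1, paste0(L, "M"), slice(p1), rnext = "=", pnext = p2)
      emit(paste0(qname), fl$r2, p2, paste0(L, "M"), slice(p2), rnext = "=",
           pnext = p1)
    }
  }
  for (i in seq_len(n_sense)) emit_fragment(sprintf("%s_s%d", prefix, i), TRUE)
  for (i in seq_len(n_antisense)) emit_fragment(sprintf("%s_a%d", prefix, i), FALSE)
  fl_sense <- sim_flags(config$layout, config$chemistry, loc$strand, TRUE)
  for (i in seq_len(n_offby1)) {
    p <- e - L  # covers e-L .. e-1: misses the last spanned base
    if (p >= 1L) emit(sprintf("%s_ob%d", prefix, i), fl_sense$r1, p,
                      paste0(L, "M"), slice(p))
  }
  for (i in seq_len(n_mismatch)) {
    p <- span_start()
    sq <- slice(p)
    off <- s - p + 1L + ((i - 1L) %% (e - s + 1L))
    old <- substr(sq, off, off)
    substr(sq, off, off) <- setdiff(c("A", "C", "G", "T"), old)[1]
    emit(sprintf("%s_mm%d", prefix, i), fl_sense$r1, p, paste0(L, "M"), sq)
  }
  for (i in seq_len(n_clipped)) {
    # soft-clip the first bases of the span: aligned part starts inside it
    clip <- 5L
    p <- s + clip
    if (p + L - clip - 1L <= clen)
      emit(sprintf("%s_cl%d", prefix, i), fl_sense$r1, p,
           paste0(clip, "S", L - clip, "M"),
           paste0(strrep("A", clip),
                  substr(genome_seqs[[chrom]], p, p + L - clip - 1L)))
  }
  for (i in seq_len(n_secondary)) {
    p <- span_start()
    emit(sprintf("%s_sec%d", prefix, i), bitwOr(fl_sense$r1, 0x100), p,
         paste0(L, "M"), slice(p))
  }
  do.call(rbind, rows)
}

#' Simulate background reads clear of planted spans
#'
#' @param genome_seqs Named character vector.
#' @param n Number of reads.
#' @param avoid Data.frame of spans to avoid (`chrom`, `start`, `end`).
#' @param read_length Read length.
#' @param prefix Read-name prefix.
#' @return Read data.frame (plain forward single-end records).
#' @export
sim_background_reads <- function(genome_seqs, n, avoid = NULL,
                                 read_length = 51L, prefix = "bg") {
  rows <- list()
  chroms <- names(genome_seqs)
  for (i in seq_len(n)) {
    repeat {
      chrom <- sample(chroms, 1L)
      clen <- nchar(genome_seqs[[chrom]])
      p <- sample.int(clen - read_length + 1L, 1L)
      clash <- !is.null(avoid) && any(
        avoid$chrom == chrom & p <= avoid$end & p + read_length - 1L >= avoid$start)
      if (!clash) break
    }
    rows[[i]] <- data.frame(
      qname = sprintf("%s_%d", prefix, i), flag = 0L, chrom = chrom, pos = p,
      cigar = paste0(read_length, "M"),
      seq = substr(genome_seqs[[chrom]], p, p + read_length - 1L),
      rnext = "*", pnext = 0L, tlen = 0L, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Count k-mers across the primary reads of a BAM file
#'
#' Reproduces a Jellyfish-style database over the reads as sequenced:
#' alignment-reversed records are reverse-complemented back to their FASTQ
#' orientation, then every read is re-oriented to the transcription (sense)
#' strand implied by the library chemistry (for reverse-chemistry libraries
#' R1 is reverse-complemented; for forward chemistry R2 is), and all
#' overlapping k-mers are tabulated.
#'
#' @param bam Indexed BAM path.
#' @param k K-mer length (24, 27, 30 or 33).
#' @param config A `LibraryConfig`.
#' @return Keyed data.table `kmer`, `count`.
#' @export
kmer_oracle <- function(bam, k = 27L, config = lib_config("single_end", "forward")) {
  stopifnot(k %in% c(24L, 27L, 30L, 33L))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE),
    what = c("flag", "seq"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  seqs <- as.character(res$seq)
  flags <- res$flag
  # back to FASTQ orientation
  rev_aln <- bitwAnd(flags, 0x10) != 0L
  seqs[rev_aln] <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rev_aln])))
  # re-orient to the sense strand
  flip <- if (config$layout == "single_end") {
    rep(config$chemistry == "reverse", length(flags))
  } else {
    is_r1 <- bitwAnd(flags, 0x40) != 0L
    if (config$chemistry == "reverse") is_r1 else !is_r1
  }
  seqs[flip] <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[flip])))
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character())
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  }))
  dt <- data.table::data.table(kmer = kmers)[, list(count = .N), by = "kmer"]
  data.table::setkeyv(dt, "kmer")
  dt
}

#' Total k-mer occurrences of a coding-sequence pool
#'
#' @param kmer_counts Table from [kmer_oracle()].
#' @param mcs_set Character vector of coding sequences (length = k).
#' @return Integer total.
#' @export
kmer_query <- function(kmer_counts, mcs_set) {
  hit <- kmer_counts[list(unique(mcs_set)), nomatch = NULL]
  sum(hit$count)
}

#' Peptide-panel fixture for pipeline-versus-k-mer comparisons
#'
#' Builds a complete seeded fixture emulating a stranded single-end
#' sequencing experiment: a random genome with one randomly chosen coding
#' sequence per peptide planted at a unique locus, spanning sense reads per
#' locus (Poisson-distributed depth, some loci left at zero), background
#' reads clear of the planted spans, no clipping and no indels.  The genome
#' is rejection-screened so that the only occurrences of any queried coding
#' sequence are the planted ones.
#'
#' @param dir Output directory.
#' @param n_peptides Number of 9-residue peptides (panel size).
#' @param seed RNG seed; the fixture is byte-identical for a given seed.
#' @param mean_depth Mean spanning-read count per locus.
#' @param zero_fraction Fraction of loci left without spanning reads.
#' @param n_background Background read count.
#' @param max_pool Cap on the per-peptide coding-sequence pool size
#'   (peptides are redrawn above it to keep exhaustive search tractable).
#' @param read_length Read length.
#' @return List: `genome_fa`, `bam`, `peptide_file`, `peptides` (name,
#'   sequence, planted MCS, locus, expected count), `config`, `genome`.
#' @export
make_kmer_panel_fixture <- function(dir, n_peptides = 50L, seed = 1L,
                                    mean_depth = 12, zero_fraction = 0.1,
                                    n_background = 300L, max_pool = 32768,
                                    read_length = 51L) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aas <- setdiff(names(.CODONS_BY_AA), "*")
  peps <- character(0)
  while (length(peps) < n_peptides) {
    p <- paste(sample(aas, 9L, replace = TRUE), collapse = "")
    if (p %in% peps) next
    if (prod(codon_degeneracy(p)) > max_pool) next
    peps <- c(peps, p)
  }
  spacing <- 2L * read_length + 100L
  margin <- 200L
  glen <- margin * 2L + n_peptides * spacing
  loci <- margin + spacing * (seq_len(n_peptides) - 1L)

  pools <- lapply(peps, reverse_translate, check_length = FALSE)
  planted <- vapply(pools, function(x) x[sample.int(length(x), 1L)], character(1))
  all_mcs <- Biostrings::DNAStringSet(unique(unlist(pools)))
  pd <- Biostrings::PDict(all_mcs)

  repeat {
    g <- random_genome(c(chr1 = glen))
    for (i in seq_len(n_peptides)) g["chr1"] <- splice_in(g["chr1"], loci[i], planted[i])
    subj <- Biostrings::DNAString(g[["chr1"]])
    n_fwd <- sum(lengths(Biostrings::startIndex(Biostrings::matchPDict(pd, subj))))
    n_rev <- sum(lengths(Biostrings::startIndex(
      Biostrings::matchPDict(pd, Biostrings::reverseComplement(subj)))))
    if (n_fwd == n_peptides && n_rev == 0L) break
  }
  genome_fa <- file.path(dir, "genome.fa")
  write_genome_fasta(g, genome_fa)
  genome <- load_genome(genome_fa)

  config <- lib_config("single_end", "forward", "stranded")
  depth <- stats::rpois(n_peptides, mean_depth)
  depth[sample.int(n_peptides, max(0L, round(zero_fraction * n_peptides)))] <- 0L
  spans <- data.frame(chrom = "chr1", start = loci, end = loci + 26L)
  reads <- list()
  for (i in seq_len(n_peptides)) {
    loc <- make_location("chr1", "+", loci[i], loci[i] + 26L, planted[i])
    if (depth[i] > 0L)
      reads[[length(reads) + 1L]] <- sim_location_reads(
        g, loc, n_sense = depth[i], config = config,
        read_length = read_length, prefix = sprintf("p%02d", i))
  }
  reads[[length(reads) + 1L]] <- sim_background_reads(
    g, n_background, avoid = spans, read_length = read_length)
  bam <- write_bam(do.call(rbind, reads), c(chr1 = glen),
                   file.path(dir, "sample.bam"))

  peptide_file <- file.path(dir, "peptides.txt")
  writeLines(sprintf("pep%02d %s", seq_len(n_peptides), peps), peptide_file)

  list(genome_fa = genome_fa, bam = bam, peptide_file = peptide_file,
       peptides = data.frame(name = sprintf("pep%02d", seq_len(n_peptides)),
                             peptide = peps, mcs = planted, start = loci,
                             expected = depth, stringsAsFactors = FALSE),
       config = config, genome = genome)
}
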