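# Independent brute-force oracles.  These deliberately share no code with
# the implementation paths they check.

# Sliding-window scan of every offset on both strands with the
# SNV-licensing rule.
locate_oracle <- function(mcs, genome_seqs, snvs = NULL, max_mismatch = 3L) {
  revcomp_chr <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  hits <- list()
  for (chrom in names(genome_seqs)) {
    s <- genome_seqs[[chrom]]
    n <- nchar(s); k <- nchar(mcs)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") mcs else revcomp_chr(mcs)
      pc <- strsplit(pat, "")[[1]]
      for (start in seq_len(n - k + 1L)) {
        ref <- strsplit(substr(s, start, start + k - 1L), "")[[1]]
        mism <- which(ref != pc)
        if (length(mism) > max_mismatch) next
        ok <- TRUE
        for (m in mism) {
          if (ref[m] == "N") { ok <- FALSE; break }
          if (is.null(snvs)) { ok <- FALSE; break }
          row <- snvs[snvs$chrom == chrom & snvs$pos == start + m - 1L, ,
                      drop = FALSE]
          if (!any(row$alt == pc[m])) { ok <- FALSE; break }
        }
        if (ok) hits[[length(hits) + 1L]] <-
            data.frame(chrom = chrom, strand = strand, start = start,
                       stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(chrom = character(), strand = character(),
                      start = integer()))
  out <- do.call(rbind, hits)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# Exact-span rule evaluated read by read with an independent CIGAR walk.
count_oracle <- function(reads, loc, config) {
  blocks <- location_blocks(loc)
  gpos <- unlist(lapply(seq_len(nrow(blocks)),
                        function(i) blocks[i, "start"]:blocks[i, "end"]))
  expected <- if (loc$strand == "+") loc$mcs else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(loc$mcs)))
  expv <- strsplit(expected, "")[[1]]
  keep_strand <- function(flag) {
    if (config$strandedness == "unstranded") return(TRUE)
    rev_read <- bitwAnd(flag, 0x10) != 0L
    if (config$layout == "single_end") {
      sense_strand <- if (config$chemistry == "forward") {
        if (rev_read) "-" else "+"
      } else {
        if (rev_read) "+" else "-"
      }
      return(sense_strand == loc$strand)
    }
    is_r1 <- bitwAnd(flag, 0x40) != 0L
    read_is_sense <- (config$chemistry == "forward") == is_r1
    read_strand <- if (rev_read) "-" else "+"
    frag_strand <- if (read_is_sense) read_strand else
      setdiff(c("+", "-"), read_strand)
    frag_strand == loc$strand
  }
  total <- 0L
  for (j in seq_len(nrow(reads))) {
    if (bitwAnd(reads$flag[j], 0x100) != 0L) next
    if (reads$chrom[j] != loc$chrom) next
    if (!keep_strand(reads$flag[j])) next
    # independent walk: genomic position -> read base, insertions recorded
    ops <- regmatches(reads$cigar[j],
                      gregexpr("[0-9]+[MIDNSHP=X]", reads$cigar[j]))[[1]]
    g <- reads$pos[j]; r <- 1L
    bases <- character(0); pos <- integer(0); ins <- integer(0)
    sq <- strsplit(reads$seq[j], "")[[1]]
    for (o in ops) {
      len <- as.integer(sub("[A-Z=]", "", o))
      op <- sub("[0-9]+", "", o)
      if (op %in% c("M", "=", "X")) {
        pos <- c(pos, g:(g + len - 1L)); bases <- c(bases, sq[r:(r + len - 1L)])
        g <- g + len; r <- r + len
      } else if (op == "I") { ins <- c(ins, g); r <- r + len }
      else if (op %in% c("D", "N")) g <- g + len
      else if (op == "S") r <- r + len
    }
    got <- bases[match(gpos, pos)]
    if (anyNA(got) || !all(got == expv)) next
    bad_ins <- any(vapply(ins, function(p)
      any(blocks[, "start"] < p & p <= blocks[, "end"]), logical(1)))
    if (bad_ins) next
    total <- total + 1L
  }
  total
}
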