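# Genomic locations are plain data.frames, one row per placement:
#   chrom, strand, start, end        - span on the + reference (1-based incl.)
#   n_blocks, block_starts/block_ends- comma-joined per-block coordinates
#   mcs                              - query-oriented coding sequence
#   snv_pos/snv_alt                  - comma-joined licensed-mismatch support
#   spliced                          - TRUE for multi-block placements
#   loc_id                           - dedup/report key
empty_locations <- function() {
  data.frame(chrom = character(), strand = character(),
             start = integer(), end = integer(), n_blocks = integer(),
             block_starts = character(), block_ends = character(),
             mcs = character(), snv_pos = character(), snv_alt = character(),
             spliced = logical(), loc_id = character(),
             stringsAsFactors = FALSE)
}

make_location <- function(chrom, strand, block_starts, block_ends, mcs,
                          snv_pos = integer(), snv_alt = character()) {
  o <- order(block_starts)
  block_starts <- block_starts[o]; block_ends <- block_ends[o]
  data.frame(
    chrom = chrom, strand = strand,
    start = block_starts[1], end = block_ends[length(block_ends)],
    n_blocks = length(block_starts),
    block_starts = paste(block_starts, collapse = ","),
    block_ends = paste(block_ends, collapse = ","),
    mcs = mcs,
    snv_pos = paste(snv_pos, collapse = ","),
    snv_alt = paste(snv_alt, collapse = ","),
    spliced = length(block_starts) > 1L,
    loc_id = paste(chrom, strand, paste(block_starts, collapse = ","),
                   paste(block_ends, collapse = ","), mcs, sep = "|"),
    stringsAsFactors = FALSE
  )
}

#' Blocks of a location as a matrix
#'
#' @param loc One location row.
#' @return Two-column integer matrix (`start`, `end`), one row per block.
#' @export
location_blocks <- function(loc) {
  cbind(start = as.integer(strsplit(loc$block_starts, ",")[[1]]),
        end = as.integer(strsplit(loc$block_ends, ",")[[1]]))
}

sort_locations <- function(locs) {
  if (nrow(locs) == 0L) return(locs)
  locs <- locs[!duplicated(locs$loc_id), , drop = FALSE]
  locs <- locs[order(locs$chrom, locs$start, locs$strand, locs$mcs), , drop = FALSE]
  rownames(locs) <- NULL
  locs
}

# Check the perfect-alignment rule for one candidate placement: every
# mismatch against the + reference must be a catalogued SNV whose alternate
# allele equals the query base.  `N` in the reference never matches.
license_mismatches <- function(pat_chars, ref_chars, chrom, genome_pos, catalog) {
  mism <- which(pat_chars != ref_chars)
  if (length(mism) == 0L)
    return(list(ok = TRUE, snv_pos = integer(), snv_alt = character()))
  if (is.null(catalog)) return(list(ok = FALSE))
  for (i in mism) {
    if (ref_chars[i] == "N") return(list(ok = FALSE))
    if (!pat_chars[i] %in% snv_alts(catalog, chrom, genome_pos[i]))
      return(list(ok = FALSE))
  }
  list(ok = TRUE, snv_pos = genome_pos[mism], snv_alt = pat_chars[mism])
}

#' Locate all contiguous perfect placements of a coding sequence
#'
#' Scans both strands of the reference exhaustively for placements where the
#' coding sequence matches the genome, allowing mismatches only at positions
#' catalogued as single-nucleotide variants with the matching alternate
#' allele (the "perfect alignment" rule).  For `-` strand placements the
#' reverse complement of the query is compared against the + reference.
#'
#' @param mcs Coding sequence (ACGT).
#' @param genome A `ReferenceGenome`.
#' @param snv_catalog An `SNVCatalog` or `NULL` (no mismatches licensed).
#' @param max_mismatch Cap on licensed mismatches per placement.
#' @param index Optional `SeedIndex` from [build_index()]; accelerates the
#'   exact (no-SNV) search and is ignored when a catalog is supplied.
#' @return Location data.frame (possibly 0-row), deterministically ordered
#'   by chromosome, start, strand.
#' @export
locate <- function(mcs, genome, snv_catalog = NULL, max_mismatch = 3L,
                   index = NULL) {
  stopifnot(inherits(genome, "ReferenceGenome"))
  if (grepl("[^ACGT]", mcs)) stop("MCS must be ACGT only: ", mcs)
  has_snv <- !is.null(snv_catalog) && nrow(snv_catalog$table) > 0L
  mm <- if (has_snv) as.integer(max_mismatch) else 0L
  if (!has_snv && !is.null(index))
    return(locate_via_index(mcs, genome, index))
  out <- list()
  pats <- c(`+` = mcs, `-` = revcomp(mcs))
  for (chrom in names(genome$seq)) {
    subject <- genome$seq[[chrom]]
    for (strand in c("+", "-")) {
      pat <- pats[[strand]]
      hits <- Biostrings::matchPattern(pat, subject, max.mismatch = mm,
                                       with.indels = FALSE)
      if (length(hits) == 0L) next
      pat_chars <- strsplit(pat, "")[[1]]
      for (h in seq_along(hits)) {
        s <- Biostrings::start(hits)[h]
        e <- Biostrings::end(hits)[h]
        if (s < 1L || e > genome$lengths[[chrom]]) next
        ref_chars <- strsplit(as.character(hits[[h]]), "")[[1]]
        lic <- license_mismatches(pat_chars, ref_chars, chrom, s:e,
                                  if (has_snv) snv_catalog else NULL)
        if (!lic$ok) next
        out[[length(out) + 1L]] <- make_location(
          chrom, strand, s, e, mcs, lic$snv_pos, lic$snv_alt)
      }
    }
  }
  if (length(out) == 0L) return(empty_locations())
  sort_locations(do.call(rbind, out))
}

#' Locate a whole MCS pool
#'
#' Equivalent to calling [locate()] on every member; when no SNV catalog is
#' supplied the constant-width pool is matched in one pass per chromosome and
#' strand with [Biostrings::matchPDict()].
#'
#' @inheritParams locate
#' @param mcs_set Character vector of equal-length coding sequences.
#' @return Combined location data.frame.
#' @export
locate_set <- function(mcs_set, genome, snv_catalog = NULL, max_mismatch = 3L) {
  mcs_set <- unique(mcs_set)
  if (length(mcs_set) == 0L) return(empty_locations())
  has_snv <- !is.null(snv_catalog) && nrow(snv_catalog$table) > 0L
  if (has_snv || length(mcs_set) < 4L || length(unique(nchar(mcs_set))) != 1L) {
    out <- lapply(mcs_set, locate, genome = genome, snv_catalog = snv_catalog,
                  max_mismatch = max_mismatch)
    return(sort_locations(do.call(rbind, out)))
  }
  out <- list()
  for (strand in c("+", "-")) {
    pats <- if (strand == "+") mcs_set else
      as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(mcs_set)))
    pd <- Biostrings::PDict(pats)
    for (chrom in names(genome$seq)) {
      m <- Biostrings::matchPDict(pd, genome$seq[[chrom]])
      starts <- Biostrings::startIndex(m)
      for (i in seq_along(starts)) {
        for (s in starts[[i]]) {
          out[[length(out) + 1L]] <- make_location(
            chrom, strand, s, s + nchar(mcs_set[i]) - 1L, mcs_set[i])
        }
      }
    }
  }
  if (length(out) == 0L) return(empty_locations())
  sort_locations(do.call(rbind, out))
}

#' Build a seed index over the reference
#'
#' Hashes every fixed-length nucleotide window of the + strand to its
#' occurrence positions.  Queries look up both orientations, so only the
#' + strand is stored.  Seeds containing `N` are not indexed.
#'
#' @param genome A `ReferenceGenome`.
#' @param seed_length Window length; must be at least 8 (error below) and
#'   should be at least 12 (warning below, memory/speed trade-off), and at
#'   most 24 (the shortest possible coding sequence).
#' @return A `SeedIndex` (keyed data.table `seed`, `chrom`, `pos`).
#' @export
build_index <- function(genome, seed_length = 12L) {
  seed_length <- as.integer(seed_length)
  if (seed_length < 8L) stop("seed_length must be >= 8")
  if (seed_length < 12L) warning("seed_length < 12: index may be large and slow")
  if (seed_length > 24L) stop("seed_length must be <= 24 (shortest MCS)")
  parts <- lapply(names(genome$seq), function(chrom) {
    s <- as.character(genome$seq[[chrom]])
    n <- nchar(s) - seed_length + 1L
    if (n < 1L) return(NULL)
    pos <- seq_len(n)
    seeds <- substring(s, pos, pos + seed_length - 1L)
    keep <- !grepl("N", seeds, fixed = TRUE)
    if (!any(keep)) return(NULL)
    data.table::data.table(seed = seeds[keep], chrom = chrom, pos = pos[keep])
  })
  dt <- data.table::rbindlist(parts)
  if (nrow(dt) == 0L)
    dt <- data.table::data.table(seed = character(), chrom = character(),
                                 pos = integer())
  data.table::setkeyv(dt, "seed")
  structure(list(table = dt, seed_length = seed_length), class = "SeedIndex")
}

locate_via_index <- function(mcs, genome, index) {
  stopifnot(inherits(index, "SeedIndex"))
  k <- index$seed_length
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") mcs else revcomp(mcs)
    if (nchar(pat) < k) stop("MCS shorter than seed length")
    cand <- index$table[list(substr(pat, 1L, k)), nomatch = NULL]
    for (i in seq_len(nrow(cand))) {
      chrom <- cand$chrom[i]; s <- cand$pos[i]
      e <- s + nchar(pat) - 1L
      if (e > genome$lengths[[chrom]]) next
      if (genome_fetch(genome, chrom, s, e) == pat)
        out[[length(out) + 1L]] <- make_location(chrom, strand, s, e, mcs)
    }
  }
  if (length(out) == 0L) return(empty_locations())
  sort_locations(do.call(rbind, out))
}

#' Locate placements spanning annotated splice junctions
#'
#' Concatenates the exon sequence of every multi-exon transcript and searches
#' it for the coding sequence (both orientations, SNV-aware).  Matches whose
#' footprint crosses at least one exon-exon junction become multi-block
#' locations; fully-exonic single-block matches are left to [locate()] and
#' not duplicated here.  Only annotated junctions are searched.
#'
#' @inheritParams locate
#' @param annotation_index An `AnnotationIndex`.
#' @return Location data.frame of spliced (multi-block) placements.
#' @export
locate_spliced <- function(mcs, genome, annotation_index, snv_catalog = NULL,
                           max_mismatch = 3L) {
  stopifnot(inherits(annotation_index, "AnnotationIndex"))
  has_snv <- !is.null(snv_catalog) && nrow(snv_catalog$table) > 0L
  mm <- if (has_snv) as.integer(max_mismatch) else 0L
  out <- list()
  for (tx in annotation_index$transcripts) {
    if (length(tx$exons) < 2L) next
    if (!tx$chrom %in% names(genome$seq)) next
    ex_start <- IRanges::start(tx$exons)
    ex_end <- IRanges::end(tx$exons)
    # genomic + strand position of every base of the concatenated exon sequence
    pos_map <- unlist(lapply(seq_along(ex_start),
                             function(i) ex_start[i]:ex_end[i]))
    concat <- paste(vapply(seq_along(ex_start), function(i)
      genome_fetch(genome, tx$chrom, ex_start[i], ex_end[i]), character(1)),
      collapse = "")
    subject <- Biostrings::DNAString(concat)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") mcs else revcomp(mcs)
      hits <- Biostrings::matchPattern(pat, subject, max.mismatch = mm,
                                       with.indels = FALSE)
      if (length(hits) == 0L) next
      pat_chars <- strsplit(pat, "")[[1]]
      for (h in seq_along(hits)) {
        s <- Biostrings::start(hits)[h]; e <- Biostrings::end(hits)[h]
        if (s < 1L || e > length(pos_map)) next
        gpos <- pos_map[s:e]
        breaks <- which(diff(gpos) != 1L)
        if (length(breaks) == 0L) next  # contiguous: locate() territory
        ref_chars <- strsplit(as.character(hits[[h]]), "")[[1]]
        lic <- license_mismatches(pat_chars, ref_chars, tx$chrom, gpos,
                                  if (has_snv) snv_catalog else NULL)
        if (!lic$ok) next
        b_start <- gpos[c(1L, breaks + 1L)]
        b_end <- gpos[c(breaks, length(gpos))]
        out[[length(out) + 1L]] <- make_location(
          tx$chrom, strand, b_start, b_end, mcs, lic$snv_pos, lic$snv_alt)
      }
    }
  }
  if (length(out) == 0L) return(empty_locations())
  sort_locations(do.call(rbind, out))
}

#' Verify a manual-mode query against the reference
#'
#' Applies the same perfect-alignment rule as [locate()] at the single stated
#' location: every mismatch between the (strand-oriented) coding sequence and
#' the reference must be a catalogued SNV.  A placement failing the rule is
#' rejected with a diagnostic warning and an empty result.
#'
#' @param query One row of a parsed query table in manual mode.
#' @inheritParams locate
#' @return Location data.frame with one row, or 0 rows on rejection.
#' @export
resolve_manual <- function(query, genome, snv_catalog = NULL) {
  stopifnot(query$mode == "manual")
  pat <- if (query$strand == "+") query$mcs else revcomp(query$mcs)
  ref <- genome_fetch(genome, query$chrom, query$start, query$end)  # bounds-checked
  lic <- license_mismatches(strsplit(pat, "")[[1]], strsplit(ref, "")[[1]],
                            query$chrom, query$start:query$end, snv_catalog)
  if (!lic$ok) {
    warning("Manual location ", query$chrom, ":", query$start, "-", query$end,
            "(", query$strand, ") for '", query$name,
            "' has mismatches not supported by catalogued SNVs; rejected")
    return(empty_locations())
  }
  make_location(query$chrom, query$strand, query$start, query$end, query$mcs,
                lic$snv_pos, lic$snv_alt)
}

#' Export locations as BED12
#'
#' @param locs Location data.frame.
#' @param path Output path.
#' @param names Optional per-row names (defaults to `loc_id`).
#' @return `path`, invisibly.
#' @export
locations_to_bed <- function(locs, path, names = NULL) {
  if (is.null(names)) names <- locs$loc_id
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(locs))) {
    b <- location_blocks(locs[i, ])
    sizes <- b[, "end"] - b[, "start"] + 1L
    rel <- b[, "start"] - locs$start[i]
    writeLines(paste(
      locs$chrom[i], locs$start[i] - 1L, locs$end[i], names[i], 0L,
      locs$strand[i], locs$start[i] - 1L, locs$end[i], 0L, nrow(b),
      paste0(paste(sizes, collapse = ","), ","),
      paste0(paste(rel, collapse = ","), ","),
      sep = "\t"), con)
  }
  invisible(path)
}
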