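pep9 <- "MWMWKMWMC"
mcs9 <- reverse_translate(pep9, check_length = FALSE)[1]

planted_genome <- function(seed = 31, at = 1000L, strand = "+") {
  set.seed(seed)
  g <- random_genome(c(chr1 = 3000))
  g["chr1"] <- splice_in(g["chr1"], at,
                         if (strand == "+") mcs9 else revcomp(mcs9))
  g
}

test_that("total primary reads excludes secondary, keeps supplementary", {
  g <- planted_genome()
  loc <- make_location("chr1", "+", 1000L, 1026L, mcs9)
  reads <- sim_location_reads(g, loc, n_sense = 10,
                              config = lib_config("single_end", "forward"),
                              n_secondary = 4)
  supp <- reads[1, ]
  supp$qname <- "supp1"
  supp$flag <- bitwOr(supp$flag, 0x800)
  bam <- write_bam(rbind(reads, supp), c(chr1 = 3000L),
                   tempfile(fileext = ".bam"))
  expect_equal(total_primary_reads(bam), 11L)  # 10 + supplementary
  empty <- write_bam(reads[0, ], c(chr1 = 3000L), tempfile(fileext = ".bam"))
  expect_error(total_primary_reads(empty), "No primary reads")
})

test_that("only exactly-spanning, base-perfect, unclipped reads count", {
  g <- planted_genome()
  loc <- make_location("chr1", "+", 1000L, 1026L, mcs9)
  cfg <- lib_config("single_end", "forward", "stranded")
  reads <- sim_location_reads(g, loc, n_sense = 6, n_offby1 = 3,
                              n_mismatch = 3, n_clipped = 3, n_secondary = 2,
                              config = cfg)
  # a read with an insertion inside the span must not count
  ins <- data.frame(qname = "ins1", flag = 0L, chrom = "chr1", pos = 995L,
                    cigar = "15M1I35M",
                    seq = paste0(substr(g[["chr1"]], 995, 1009), "A",
                                 substr(g[["chr1"]], 1010, 1044)),
                    rnext = "*", pnext = 0L, tlen = 0L)
  # a read with a deletion inside the span must not count
  del <- data.frame(qname = "del1", flag = 0L, chrom = "chr1", pos = 995L,
                    cigar = "15M1D36M",
                    seq = paste0(substr(g[["chr1"]], 995, 1009),
                                 substr(g[["chr1"]], 1011, 1046)),
                    rnext = "*", pnext = 0L, tlen = 0L)
  bam <- write_bam(rbind(reads, ins, del), c(chr1 = 3000L),
                   tempfile(fileext = ".bam"))
  res <- count_peptide(bam, loc, cfg)
  expect_equal(res$tr, 6L)
  # brute-force oracle agrees
  all_reads <- rbind(reads, ins, del)
  expect_equal(res$tr, count_oracle(all_reads, loc, cfg))
})

test_that("reads spanning a spliced location count through the N gap", {
  set.seed(32)
  g <- random_genome(c(chr1 = 3000))
  g["chr1"] <- splice_in(g["chr1"], 988, substr(mcs9, 1, 13))
  g["chr1"] <- splice_in(g["chr1"], 1201, substr(mcs9, 14, 27))
  loc <- make_location("chr1", "+", c(988L, 1201L), c(1000L, 1214L), mcs9)
  # spliced read: 20M 200N 31M starting at 981
  sq <- paste0(substr(g[["chr1"]], 981, 1000), substr(g[["chr1"]], 1201, 1231))
  reads <- data.frame(qname = "spl1", flag = 0L, chrom = "chr1", pos = 981L,
                      cigar = "20M200N31M", seq = sq, rnext = "*",
                      pnext = 0L, tlen = 0L)
  # same read but with the skip off by one: misses block positions
  reads <- rbind(reads, data.frame(qname = "spl2", flag = 0L, chrom = "chr1",
                                   pos = 981L, cigar = "20M201N31M", seq = sq,
                                   rnext = "*", pnext = 0L, tlen = 0L))
  bam <- write_bam(reads, c(chr1 = 3000L), tempfile(fileext = ".bam"))
  cfg <- lib_config("single_end", "forward", "stranded")
  expect_equal(count_peptide(bam, loc, cfg)$tr, 1L)
  expect_equal(count_oracle(reads, loc, cfg), 1L)
})

test_that("all eight layout/chemistry/strand cases match the oracle; stranded <= unstranded", {
  for (layout in c("single_end", "paired_end")) {
    for (chem in c("forward", "reverse")) {
      for (strand in c("+", "-")) {
        g <- planted_genome(seed = 33, strand = strand)
        loc <- make_location("chr1", strand, 1000L, 1026L,
                             if (strand == "+") mcs9 else mcs9)
        # the location's mcs is query-oriented: expected + strand sequence
        # is mcs for +, revcomp for -; the genome was planted accordingly
        cfgS <- lib_config(layout, chem, "stranded")
        cfgU <- lib_config(layout, chem, "unstranded")
        reads <- sim_location_reads(g, loc, n_sense = 5, n_antisense = 3,
                                    config = lib_config(layout, chem),
                                    n_offby1 = 1, n_mismatch = 1,
                                    prefix = paste0(layout, chem, strand))
        bam <- write_bam(reads, c(chr1 = 3000L), tempfile(fileext = ".bam"))
        s <- count_peptide(bam, loc, cfgS)$tr
        u <- count_peptide(bam, loc, cfgU)$tr
        expect_equal(s, 5L)
        expect_equal(u, 8L)
        expect_equal(s, count_oracle(reads, loc, cfgS))
        expect_equal(u, count_oracle(reads, loc, cfgU))
        expect_lte(s, u)
      }
    }
  }
})

test_that("unstranded counts are the union of the two stranded selections", {
  g <- planted_genome(seed = 34)
  loc <- make_location("chr1", "+", 1000L, 1026L, mcs9)
  reads <- sim_location_reads(g, loc, n_sense = 4, n_antisense = 6,
                              config = lib_config("paired_end", "forward"))
  bam <- write_bam(reads, c(chr1 = 3000L), tempfile(fileext = ".bam"))
  plus <- count_peptide(bam, loc, lib_config("paired_end", "forward", "stranded"))$tr
  loc_minus <- make_location("chr1", "-", 1000L, 1026L, revcomp(mcs9))
  minus <- count_peptide(bam, loc_minus,
                         lib_config("paired_end", "forward", "stranded"))$tr
  un <- count_peptide(bam, loc, lib_config("paired_end", "forward", "unstranded"))$tr
  expect_equal(plus + minus, un)
  expect_equal(plus, 4L)
  expect_equal(minus, 6L)
})

test_that("duplicating every read doubles tr and leaves rphm unchanged", {
  g <- planted_genome(seed = 35)
  loc <- make_location("chr1", "+", 1000L, 1026L, mcs9)
  cfg <- lib_config("single_end", "forward", "stranded")
  reads <- rbind(
    sim_location_reads(g, loc, n_sense = 7, config = cfg),
    sim_background_reads(g, 50, avoid = data.frame(chrom = "chr1",
                                                   start = 1000, end = 1026)))
  bam1 <- write_bam(reads, c(chr1 = 3000L), tempfile(fileext = ".bam"))
  dup <- reads
  dup$qname <- paste0(dup$qname, "_dup")
  bam2 <- write_bam(rbind(reads, dup), c(chr1 = 3000L),
                    tempfile(fileext = ".bam"))
  t1 <- count_peptide(bam1, loc, cfg)$tr
  t2 <- count_peptide(bam2, loc, cfg)$tr
  expect_equal(t2, 2L * t1)
  expect_equal(rphm(t1, total_primary_reads(bam1)),
               rphm(t2, total_primary_reads(bam2)))
})

test_that("normalization identities hold", {
  expect_equal(rphm(5e7, 5e7), 1e8)
  expect_equal(rphm(0, 1000), 0)
  expect_equal(log_rphm(0), 0)
  expect_equal(rphm(10, 2e8), 5)
  expect_equal(log_rphm(rphm(10, 2e8)), log10(6))
  expect_error(rphm(1, 0), "R_t")
})

test_that("duplicate locations are counted once; zero locations flagged", {
  g <- planted_genome(seed = 36)
  loc <- make_location("chr1", "+", 1000L, 1026L, mcs9)
  cfg <- lib_config("single_end", "forward", "stranded")
  reads <- sim_location_reads(g, loc, n_sense = 3, config = cfg)
  bam <- write_bam(reads, c(chr1 = 3000L), tempfile(fileext = ".bam"))
  res <- count_peptide(bam, rbind(loc, loc), cfg)
  expect_equal(res$tr, 3L)
  expect_equal(nrow(res$per_location), 1L)
  res0 <- count_peptide(bam, empty_locations(), cfg)
  expect_equal(res0$tr, 0L)
  expect_true(res0$no_location)
})

test_that("fragment collapsing counts a double-spanning pair once", {
  g <- planted_genome(seed = 37)
  loc <- make_location("chr1", "+", 1000L, 1026L, mcs9)
  # both mates span the location
  p1 <- 990L; p2 <- 998L
  sl <- function(p) substr(g[["chr1"]], p, p + 50L)
  reads <- data.frame(
    qname = c("pair1", "pair1"),
    flag = c(bitwOr(bitwOr(0x1, 0x2), bitwOr(0x40, 0x20)),
             bitwOr(bitwOr(0x1, 0x2), bitwOr(0x80, 0x10))),
    chrom = "chr1", pos = c(p1, p2), cigar = "51M",
    seq = c(sl(p1), sl(p2)), rnext = "=", pnext = c(p2, p1), tlen = 0L)
  bam <- write_bam(reads, c(chr1 = 3000L), tempfile(fileext = ".bam"))
  cfg <- lib_config("paired_end", "forward", "unstranded")
  expect_equal(count_peptide(bam, loc, cfg)$tr, 2L)
  expect_equal(count_peptide(bam, loc, cfg, fragment_collapse = TRUE)$tr, 1L)
})

test_that("per-barcode counting splits reads by the CB tag", {
  g <- planted_genome(seed = 38)
  loc <- make_location("chr1", "+", 1000L, 1026L, mcs9)
  cfg <- lib_config("single_end", "forward", "stranded")
  reads <- sim_location_reads(g, loc, n_sense = 4, config = cfg)
  sam <- tempfile(fileext = ".sam")
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:3000"), con)
  bcs <- c("AAAC", "AAAC", "GGGT", "GGGT")
  for (i in seq_len(nrow(reads)))
    writeLines(paste(reads$qname[i], reads$flag[i], "chr1", reads$pos[i], 60,
                     reads$cigar[i], "*", 0, 0, reads$seq[i],
                     strrep("I", nchar(reads$seq[i])),
                     paste0("CB:Z:", bcs[i]), sep = "\t"), con)
  close(con)
  tmp <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  bam <- Rsamtools::sortBam(tmp, tempfile())
  Rsamtools::indexBam(bam)
  counts <- count_by_barcode(bam, loc, cfg)
  expect_equal(counts[["AAAC"]], 2L)
  expect_equal(counts[["GGGT"]], 2L)
})
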