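pep9 <- "MWMWKMWMC"
mcs9 <- reverse_translate(pep9, check_length = FALSE)[1]

test_that("overlap annotation maps features to classes with frame checking", {
  ann <- tmp_annotation()
  g <- tmp_tx_genome()
  gen <- tmp_genome(g)
  # CDS starts at 601: codon-boundary start inside the CDS is in frame
  loc_if <- make_location("chr1", "+", 604L, 630L,
                          genome_fetch(gen, "chr1", 604, 630))
  ob <- overlap_biotypes(loc_if, ann)
  expect_equal(ob$class, "in_frame")
  expect_equal(ob$overlap_bp, 27L)
  # one-base shift: out of frame
  loc_of <- make_location("chr1", "+", 605L, 631L,
                          genome_fetch(gen, "chr1", 605, 631))
  expect_equal(overlap_biotypes(loc_of, ann)$class, "out_of_frame_exon")
  # antisense placement inside the CDS can never be in frame
  loc_as <- make_location("chr1", "-", 604L, 630L,
                          revcomp(genome_fetch(gen, "chr1", 604, 630)))
  expect_equal(overlap_biotypes(loc_as, ann)$class, "out_of_frame_exon")
  # exon/intron straddle
  loc_junc <- make_location("chr1", "+", 890L, 916L,
                            genome_fetch(gen, "chr1", 890, 916))
  expect_equal(overlap_biotypes(loc_junc, ann)$class, "exon_intron_junction")
  # intron, repeat, intergenic
  loc_int <- make_location("chr1", "+", 1050L, 1076L,
                           genome_fetch(gen, "chr1", 1050, 1076))
  expect_equal(overlap_biotypes(loc_int, ann)$class, "intron")
  loc_ere <- make_location("chr1", "+", 3100L, 3126L,
                           genome_fetch(gen, "chr1", 3100, 3126))
  expect_equal(overlap_biotypes(loc_ere, ann)$class, "ERE_SINE")
  loc_ig <- make_location("chr1", "+", 3600L, 3626L,
                          genome_fetch(gen, "chr1", 3600, 3626))
  ig <- overlap_biotypes(loc_ig, ann)
  expect_equal(ig$class, "intergenic")
  expect_equal(ig$overlap_bp, 27L)
})

test_that("overlap classes agree with a linear-scan intersection oracle", {
  ann <- tmp_annotation(extra_tx = list(list(
    transcript_id = "nc1", gene_id = "g2", gene_name = "NC1", chrom = "chr1",
    strand = "-", biotype = "lncRNA", exons = cbind(3050, 3250), cds = NULL)))
  g <- tmp_tx_genome()
  gen <- tmp_genome(g)
  # inside both the lncRNA exon and the Alu element
  loc <- make_location("chr1", "+", 3100L, 3126L,
                       genome_fetch(gen, "chr1", 3100, 3126))
  ob <- overlap_biotypes(loc, ann)
  expect_setequal(ob$class, c("non_coding_exon", "ERE_SINE"))
  expect_equal(ob$overlap_bp, c(27L, 27L))
  # strict-strand policy drops the + strand repeat for a - location
  loc_m <- make_location("chr1", "-", 3100L, 3126L,
                         revcomp(genome_fetch(gen, "chr1", 3100, 3126)))
  ob_m <- overlap_biotypes(loc_m, ann, stranded = TRUE)
  expect_equal(ob_m$class, "non_coding_exon")
})

test_that("in-frame spliced placements translate within the protein", {
  ann <- tmp_annotation()
  g <- tmp_tx_genome()
  # plant the MCS across the CDS junction at a codon boundary:
  # CDS1 601-900 (300 nt, 100 codons), so a placement starting 15 nt before
  # the junction end (886 = 601 + 285, 285 %% 3 == 0) is in frame
  g["chr1"] <- splice_in(g["chr1"], 886, substr(mcs9, 1, 15))
  g["chr1"] <- splice_in(g["chr1"], 1201, substr(mcs9, 16, 27))
  gen <- tmp_genome(g)
  loc <- locate_spliced(mcs9, gen, ann)
  loc <- loc[loc$strand == "+", , drop = FALSE]
  expect_equal(nrow(loc), 1L)
  expect_equal(frame_status(loc[1, ], ann$transcripts[["tx1"]]), "in_frame")
  # independent check: the peptide appears in the translated CDS
  tx <- ann$transcripts[["tx1"]]
  cds_seq <- paste0(genome_fetch(gen, "chr1", 601, 900),
                    genome_fetch(gen, "chr1", 1201, 1400))
  prot <- translate_mcs(substr(cds_seq, 1, 498), allow_stop = TRUE)
  expect_true(grepl(pep9, prot, fixed = TRUE))
})

test_that("EM recovers closed-form solutions on degenerate inputs", {
  # single class everywhere: immediate fixed point
  tbl <- data.frame(peptide = c("a", "b"), loc_id = c("l1", "l2"),
                    reads = c(10, 30))
  tbl$classes <- list("intron", "intron")
  em <- em_fit(tbl)
  expect_true(em$converged)
  expect_lte(em$iterations, 2L)
  expect_equal(unname(em$phi["intron"]), 1)
  expect_equal(unname(em$Z[, "intron"]), c(1, 1))
  # disjoint single-class locations: Z rows are point masses
  tbl2 <- data.frame(peptide = c("a", "b"), loc_id = c("l1", "l2"),
                     reads = c(75, 25))
  tbl2$classes <- list("in_frame", "intron")
  em2 <- em_fit(tbl2)
  expect_equal(unname(em2$Z["a", "in_frame"]), 1)
  expect_equal(unname(em2$Z["b", "intron"]), 1)
  expect_equal(unname(em2$phi), c(0.5, 0.5))
  # symmetric two-class location: equal shares by symmetry
  tbl3 <- data.frame(peptide = "a", loc_id = "l1", reads = 8)
  tbl3$classes <- list(c("intron", "ERE_LTR"))
  em3 <- em_fit(tbl3)
  sh <- location_shares(em3, c("intron", "ERE_LTR"))
  expect_equal(unname(sh), c(0.5, 0.5))
  # no reads anywhere: undefined
  tbl0 <- data.frame(peptide = "a", loc_id = "l1", reads = 0)
  tbl0$classes <- list("intron")
  expect_error(em_fit(tbl0), "EM undefined")
})

test_that("EM is a fixed point after convergence and conserves percentages", {
  set.seed(61)
  classes <- c("in_frame", "intron", "ERE_LINE", "non_coding_exon")
  tbl <- do.call(rbind, lapply(1:6, function(i) {
    k <- sample(2:3, 1)
    data.frame(peptide = paste0("p", i), loc_id = paste0("l", i, "_", 1:k),
               reads = sample(0:40, k))
  }))
  tbl$classes <- lapply(seq_len(nrow(tbl)), function(i)
    sample(classes, sample(1:3, 1)))
  em <- em_fit(tbl)
  expect_true(em$converged)
  # one more E/M cycle moves nothing beyond tolerance
  Z2 <- sapply(em$classes, function(j) 0)
  tbl_fit <- tbl[tapply(tbl$reads, tbl$peptide, sum)[tbl$peptide] > 0, ]
  em_cont <- em_fit(tbl, tol = 1e-8)
  expect_lt(max(abs(em_cont$phi - em$phi)), 1e-7)
  # percentages sum to 100 at the global scope for every fitted peptide
  for (p in unique(tbl$peptide)) {
    sub <- tbl[tbl$peptide == p, , drop = FALSE]
    pct <- peptide_biotype_pct(em, sub)
    if (!is.null(pct)) expect_equal(sum(pct), 100, tolerance = 1e-6)
  }
  # Z rows sum to 1 for peptides with reads
  expect_equal(unname(rowSums(em$Z)), rep(1, nrow(em$Z)), tolerance = 1e-9)
})

test_that("adding a zero-read location changes no percentage", {
  tbl <- data.frame(peptide = c("a", "a"), loc_id = c("l1", "l2"),
                    reads = c(90, 10))
  tbl$classes <- list("in_frame", "intron")
  em <- em_fit(tbl)
  base <- peptide_biotype_pct(em, tbl)
  tbl2 <- data.frame(peptide = "a", loc_id = c("l1", "l2", "l3"),
                     reads = c(90, 10, 0))
  tbl2$classes <- list("in_frame", "intron", "ERE_LTR")
  em2 <- em_fit(tbl2)
  got <- peptide_biotype_pct(em2, tbl2)
  expect_equal(got[c("in_frame", "intron")], base[c("in_frame", "intron")],
               tolerance = 1e-9)
  expect_equal(unname(got["ERE_LTR"]), 0)
})

test_that("read-weighted scope percentages follow the distribute-normalize rule", {
  tbl <- data.frame(peptide = c("a", "a"), loc_id = c("l1", "l2"),
                    reads = c(90, 10))
  tbl$classes <- list("in_frame", "intron")
  em <- em_fit(tbl)
  pct <- peptide_biotype_pct(em, tbl)
  expect_equal(unname(pct["in_frame"]), 90)
  expect_equal(unname(pct["intron"]), 10)
})

test_that("best-guess rules: in-frame override, argmax, ties", {
  expect_equal(best_guess(c(in_frame = 5, intron = 95), TRUE)$best, "in_frame")
  expect_equal(best_guess(c(in_frame = 5, intron = 95), TRUE)$certainty, 5)
  expect_equal(best_guess(c(intron = 60, ERE_LTR = 40), FALSE)$best, "intron")
  tie <- best_guess(c(non_coding_exon = 50, intron = 50), FALSE)
  expect_setequal(tie$best, c("non_coding_exon", "intron"))
})

test_that("three-scope profile: per-location, global, per-cohort", {
  locs <- rbind(make_location("chrA", "+", 100L, 126L, mcs9),
                make_location("chrA", "+", 500L, 526L, mcs9))
  locs$peptide <- "a"
  locs$classes <- list("in_frame", "intron")
  locs$class_overlaps <- list(c(in_frame = 27), c(intron = 27))
  counts <- data.frame(peptide = "a",
                       loc_id = rep(locs$loc_id, each = 2),
                       sample_name = rep(c("s1", "s2"), 2),
                       count = c(60, 30, 5, 5))
  prof <- biotype_profile(locs, counts,
                          cohorts = list(c1 = "s1", c2 = "s2"))
  expect_equal(prof$global$in_frame, 90)
  expect_equal(prof$global$intron, 10)
  expect_equal(prof$cohort$c1$in_frame, 60 / 65 * 100)
  expect_equal(prof$cohort$c2$in_frame, 30 / 35 * 100)
  expect_equal(prof$best$best_guess, "in_frame")
  # per-location shares are degenerate for single-class locations
  expect_equal(unname(prof$per_location[[paste0("a::", locs$loc_id[1])]]), 1)
  # empty cohort errors
  expect_error(biotype_profile(locs, counts, cohorts = list(bad = "nope")),
               "Empty cohort")
})
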