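# Shared in-code fixtures: every test builds its inputs programmatically.

write_tmp_fasta <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(seqs, fa)
  fa
}

tmp_genome <- function(seqs) load_genome(write_tmp_fasta(seqs))

tmp_snvs <- function(df) {
  vcf <- tempfile(fileext = ".vcf")
  write_snv_vcf(df, vcf)
  load_snvs(vcf)
}

# One protein-coding 2-exon transcript plus a repeat track, reused by
# annotation/biotype tests.  CDS starts at 601 so position 601+3k is a codon
# boundary.
tmp_annotation <- function(extra_tx = list()) {
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(c(list(list(
    transcript_id = "tx1", gene_id = "g1", gene_name = "G1", chrom = "chr1",
    strand = "+", biotype = "protein_coding",
    exons = cbind(c(501, 1201), c(900, 1500)),
    cds = cbind(c(601, 1201), c(900, 1400)))), extra_tx), gtf)
  bed <- tempfile(fileext = ".bed")
  write_ere_bed(data.frame(chrom = "chr1", start = 3001L, end = 3300L,
                           name = "AluY", strand = "+",
                           repeat_class = "SINE", repeat_family = "Alu"), bed)
  load_annotations(gtf, bed)
}

# A genome large enough to host the tmp_annotation() transcript and repeat.
tmp_tx_genome <- function(seed = 11) {
  set.seed(seed)
  random_genome(c(chr1 = 4000))
}
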