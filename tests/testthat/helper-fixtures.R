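# Hand-built two-gene genome for exact annotation assertions.
#
# chr "c1" layout (1-based):
#   1-10    intergenic                  GCGCGCGCGC
#   11-39   gene gA, plus strand
#             exon1 11-20  = TTTTTATGAA   (mRNA 1-10)
#             intron 21-28 = CCCCCCCC
#             exon2 29-39  = ATACTAAGGGG  (mRNA 11-21)
#           mRNA: utr5 TTTTT | CDS ATG AAA TAC TAA | utr3 GGGG
#           CDS genomic positions: 16-20 (cds_pos 1-5), 29-35 (cds_pos 6-12)
#   40-49   intergenic                  GCGCGCGCGC
#   50-62   gene gB, minus strand, single exon
#           mRNA: utr5 AA | CDS ATG GCT TAA | utr3 TT  -> genomic revcomp
#           genomic 50-62 = AATTAAGCCATTT ; CDS genomic 52-60 (cds_pos 9..1)
#   63-72   intergenic                  ATATATATAT
# gene gC: noncoding (exons only), plus strand, exons 11-39 (overlaps gA)
fixture_models <- function(with_noncoding_overlap = FALSE) {
  genes <- data.frame(
    gene_id = c("gA", "gB"), transcript_id = c("tA", "tB"),
    chrom = "c1", strand = c("+", "-"), is_flagged = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB"),
    start = c(11L, 29L, 50L), end = c(20L, 39L, 62L))
  cds <- data.frame(
    gene_id = c("gA", "gA", "gB"),
    start = c(16L, 29L, 52L), end = c(20L, 35L, 60L))
  if (with_noncoding_overlap) {
    genes <- rbind(genes, data.frame(
      gene_id = "gC", transcript_id = "tC", chrom = "c1", strand = "+",
      is_flagged = FALSE, stringsAsFactors = FALSE))
    exons <- rbind(exons, data.frame(gene_id = "gC", start = 11L, end = 39L))
  }
  gene_models(genes, exons, cds)
}

fixture_genome <- function() {
  c(c1 = paste0("GCGCGCGCGC",
                "TTTTTATGAA", "CCCCCCCC", "ATACTAAGGGG",
                "GCGCGCGCGC",
                "AATTAAGCCATTT",
                "ATATATATAT"))
}

fixture_snp <- function(snp_id, pos, ref, alt, og1 = NA, og2 = NA,
                        cons = NA_real_) {
  data.frame(snp_id = snp_id, chrom = "c1", pos = pos, ref = ref, alt = alt,
             og1 = og1, og2 = og2, cons = cons, stringsAsFactors = FALSE)
}

# small simulation shared by property tests (cheap: ~0.2 s)
small_sim <- function(seed = 11, n_snps = 1200, ...) {
  cfg <- sim_config(seed = seed, n_genes = 50,
                    n_codons_meanlog = log(150), n_snps_target = n_snps,
                    ...)
  simulate_snps(simulate_genome(cfg))
}
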