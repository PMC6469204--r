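test_that("ancestral filter matches the reference allele against either
           outgroup", {
  snps <- data.frame(ref = c("A", "A", "A", "A"),
                     og1 = c("A", "C", NA, NA),
                     og2 = c("G", "G", "A", NA),
                     stringsAsFactors = FALSE)
  expect_equal(filter_ancestral(snps), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("uni-mutation filter keeps exactly single-alt records", {
  snps <- data.frame(alt = c("G", "G,T", "", NA), stringsAsFactors = FALSE)
  expect_equal(filter_uni_mutation(snps), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(filter_uni_mutation(data.frame(alt = I(list("G", c("G", "T"),
                                                           character())))),
               c(TRUE, FALSE, FALSE))
})

test_that("filter order does not change the retained set", {
  sim <- small_sim()
  s <- sim$snps
  a_then_u <- s[filter_ancestral(s), ]
  a_then_u <- a_then_u[filter_uni_mutation(a_then_u), ]
  u_then_a <- s[filter_uni_mutation(s), ]
  u_then_a <- u_then_a[filter_ancestral(u_then_a), ]
  expect_equal(a_then_u$snp_id, u_then_a$snp_id)
})

test_that("canonical transcript selection prefers the longest CDS with a
           deterministic tie-break", {
  tx <- data.frame(gene_id = c("g1", "g1", "g2", "g2", "g3", "g4"),
                   transcript_id = c("t1a", "t1b", "T2", "T1", "t3", "t4"),
                   cds_length = c(300, 450, 300, 300, 99, NA),
                   stringsAsFactors = FALSE)
  got <- select_canonical(tx)
  expect_equal(got$transcript_id[got$gene_id == "g1"], "t1b")
  expect_equal(got$transcript_id[got$gene_id == "g2"], "T1")
  expect_equal(got$transcript_id[got$gene_id == "g3"], "t3")
  expect_equal(attr(got, "excluded_noncoding"), "g4")
})

test_that("annotation assigns categories and codon context on both strands", {
  models <- fixture_models()
  genome <- fixture_genome()
  snps <- rbind(
    fixture_snp("s_inter", 5L, "G", "A"),
    fixture_snp("s_utr", 13L, "T", "C"),
    fixture_snp("s_intron", 25L, "C", "T"),
    fixture_snp("s_nsy_splice", 31L, "A", "T"),
    fixture_snp("s_nonsense", 32L, "C", "A"),
    fixture_snp("s_stopret", 35L, "A", "G"),
    fixture_snp("s_minus", 58L, "C", "T"))
  ann <- annotate_snps(snps, models, genome)
  a <- function(id) ann[ann$snp_id == id, ]
  expect_equal(a("s_inter")$category, "intergenic")
  expect_equal(a("s_utr")$category, "utr")
  expect_equal(a("s_intron")$category, "intron")
  # plus-strand CDS arithmetic: genomic 32 is cds_pos 9 of 12
  x <- a("s_nonsense")
  expect_equal(x$category, "cds")
  expect_equal(x$cds_pos, 9L)
  expect_equal(x$codon_index, 3L)
  expect_equal(x$pos_in_codon, 3L)
  expect_equal(x$ref_codon, "TAC")
  expect_equal(x$alt_codon, "TAA")
  expect_equal(x$effect, "nonsense")
  expect_equal(x$relative_cds_position, 9 / 12)
  expect_true(x$is_flagged)
  # splice window: genomic 31 sits within 3 nt of the exon2 acceptor
  y <- a("s_nsy_splice")
  expect_true(y$in_splice_region)
  expect_true(is.na(y$effect))
  expect_false(a("s_nonsense")$in_splice_region)
  # terminal stop codon mutations are classified, not counted as nonsense
  expect_equal(a("s_stopret")$effect, "stop_retained")
  # minus-strand gene: genomic C at 58 is coding G (codon 1, position 3)
  z <- a("s_minus")
  expect_equal(z$gene_id, "gB")
  expect_equal(z$cds_pos, 3L)
  expect_equal(z$ref_codon, "ATG")
  expect_equal(z$alt_codon, "ATA")
  expect_equal(z$effect, "nonsynonymous")
})

test_that("reference mismatches are rejected and counted", {
  models <- fixture_models()
  genome <- fixture_genome()
  snps <- rbind(fixture_snp("ok", 32L, "C", "A"),
                fixture_snp("bad", 32L, "G", "A"))
  expect_message(ann <- annotate_snps(snps, models, genome), "rejected")
  expect_equal(nrow(ann), 1)
  expect_equal(attr(ann, "n_ref_mismatch"), 1L)
})

test_that("a SNP over several genes is reported once per gene", {
  models <- fixture_models(with_noncoding_overlap = TRUE)
  genome <- fixture_genome()
  ann <- annotate_snps(fixture_snp("s_multi", 25L, "C", "T"), models, genome)
  expect_equal(nrow(ann), 2)
  expect_setequal(ann$gene_id, c("gA", "gC"))
  expect_equal(ann$category[ann$gene_id == "gA"], "intron")
  expect_equal(ann$category[ann$gene_id == "gC"], "noncoding_other")
  expect_true(all(ann$multi_gene))
})

test_that("evolutionary classes follow the directional definitions", {
  snps <- data.frame(ref = c("G", "T", "A", "A"),
                     alt = c("T", "G", "C", "C"),
                     og1 = c("T", "T", "A", NA),
                     og2 = c("G", "G", "A", "C"),
                     stringsAsFactors = FALSE)
  expect_equal(classify_evolutionary(snps),
               c("to_outgroup1", "to_outgroup2", "other", "other"))
})

test_that("mutation spectrum covers the 12 substitution types and sums to
           the record count", {
  sim <- small_sim()
  s <- sim$snps[filter_uni_mutation(sim$snps) & filter_ancestral(sim$snps), ]
  spec <- mutation_spectrum(s)
  expect_equal(length(spec), 12)
  expect_equal(sum(spec), nrow(s))
  # transition excess from the proposal kernel
  ts <- spec[c("A>G", "G>A", "C>T", "T>C")]
  expect_gt(sum(ts), sum(spec) / 2)
})

test_that("category partition: every retained SNP gets one category per
           overlapping gene", {
  sim <- small_sim()
  s <- sim$snps[filter_uni_mutation(sim$snps) & filter_ancestral(sim$snps), ]
  ann <- annotate_snps(s, sim$models, sim$genome)
  expect_equal(nrow(ann), length(unique(ann$snp_id)))  # genes never overlap
  expect_true(all(ann$category %in%
                    c("intergenic", "intron", "utr", "cds")))
  expect_equal(sum(table(ann$category)), nrow(ann))
})

test_that("annotation recovers the generator's ground truth exactly", {
  sim <- small_sim(seed = 23)
  s <- sim$snps[filter_uni_mutation(sim$snps), ]
  ann <- annotate_snps(s, sim$models, sim$genome)
  expect_equal(attr(ann, "n_ref_mismatch"), 0L)
  tr <- sim$truth[!sim$truth$is_multi, ]
  m <- match(tr$snp_id, ann$snp_id)
  expect_false(anyNA(m))
  expect_equal(ann$category[m], tr$category)
  cds <- tr$category == "cds" & !tr$in_splice_region
  expect_equal(ann$effect[m][cds], tr$effect[cds])
  expect_equal(ann$in_splice_region[m][tr$category == "cds"],
               tr$in_splice_region[tr$category == "cds"])
  expect_equal(ann$relative_cds_position[m][cds],
               tr$relative_cds_position[cds])
  expect_equal(ann$evo_class[m], tr$evo_class)
})

test_that("double-mutation pairing uses codons with exactly two SNPs", {
  base <- data.frame(
    snp_id = c("a", "b", "c", "d", "e", "f", "g"),
    gene_id = c("g1", "g1", "g1", "g2", "g2", "g2", "g3"),
    is_flagged = FALSE,
    category = "cds", in_splice_region = FALSE,
    codon_index = c(2L, 2L, 5L, 7L, 7L, 7L, 1L),
    pos_in_codon = c(1L, 3L, 2L, 1L, 2L, 3L, 1L),
    cds_pos = c(4L, 6L, 14L, 19L, 20L, 21L, 1L),
    ref_codon = c("AAT", "AAT", "GGG", "CCC", "CCC", "CCC", "ATG"),
    alt_codon = c("TAT", "AAA", "GAG", "ACC", "CAC", "CCA", "CTG"),
    relative_cds_position = c(4, 6, 14, 19, 20, 21, 1) / 30,
    stringsAsFactors = FALSE)
  cases <- pair_double_mutations(base)
  expect_equal(nrow(cases), 1)        # only gene g1 codon 2 has exactly two
  expect_equal(attr(cases, "n_skipped_multi"), 1L)  # g2 codon 7 has three
  expect_equal(cases$combined, "TAA")
  expect_true(cases$distinct_combined)
  expect_true(cases$combined_is_nonsense)
  expect_equal(cases$snp_id1, "a")
  expect_equal(cases$snp_id2, "b")
  expect_equal(cases$relative_cds_position, 6 / 30)
})
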