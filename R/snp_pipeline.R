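# SNP filtering and annotation: ancestral and uni-mutation filters,
# functional category against canonical transcripts, codon context on the
# coding strand, splice-window exclusion, evolutionary class, and pairing of
# two mutations within one codon.

#' Ancestral SNP filter
#'
#' A SNP is retained when its reference allele matches the orthologous base
#' of at least one of the two outgroup species (missing bases never match).
#'
#' @param snps data frame with columns `ref`, `og1`, `og2` (outgroup bases,
#'   `NA` when missing).
#' @return logical vector, `TRUE` for retained records.
#' @export
filter_ancestral <- function(snps) {
  m1 <- !is.na(snps$og1) & snps$ref == snps$og1
  m2 <- !is.na(snps$og2) & snps$ref == snps$og2
  m1 | m2
}

#' Uni-mutation SNP filter
#'
#' Retains records with exactly one alternative allele; multi-allelic
#' ("multi-mutation") sites conflict in functional annotation and are
#' discarded, as are monomorphic records.
#'
#' @param snps data frame whose `alt` column holds comma-separated
#'   alternative alleles (or a list column).
#' @return logical vector, `TRUE` for retained records.
#' @export
filter_uni_mutation <- function(snps) {
  alt <- snps$alt
  if (is.list(alt)) return(lengths(alt) == 1L)
  alt <- as.character(alt)
  !is.na(alt) & alt != "" & !grepl(",", alt, fixed = TRUE)
}

#' Directional evolutionary class of a SNP
#'
#' With outgroup 1 in the near-outgroup role (monkey) and outgroup 2 in the
#' far role (mouse): a SNP whose reference allele matches the far outgroup
#' and whose alternative allele matches the near outgroup is a "mutation to
#' outgroup 1" (reversal toward the near species); the opposite
#' configuration is a "mutation to outgroup 2" (novel change matching the
#' far species). Everything else, including records with missing outgroup
#' bases, is `"other"`.
#'
#' @param snps data frame with `ref`, `alt` (single allele), `og1`, `og2`.
#' @return character vector: `"to_outgroup1"`, `"to_outgroup2"` or
#'   `"other"`.
#' @export
classify_evolutionary <- function(snps) {
  has <- !is.na(snps$og1) & !is.na(snps$og2)
  out <- rep("other", nrow(snps))
  out[has & snps$ref == snps$og2 & snps$alt == snps$og1] <- "to_outgroup1"
  out[has & snps$ref == snps$og1 & snps$alt == snps$og2] <- "to_outgroup2"
  out
}

#' Mutation spectrum of retained SNPs
#'
#' @param snps data frame with single-allele `ref` and `alt` columns.
#' @return named integer vector over the 12 ref>alt substitution types.
#' @export
mutation_spectrum <- function(snps) {
  types <- outer(.nucs, .nucs, function(a, b) paste0(a, ">", b))
  types <- types[as.vector(outer(.nucs, .nucs, "!="))]
  tab <- table(factor(paste0(snps$ref, ">", snps$alt), levels = sort(types)))
  v <- as.integer(tab)
  names(v) <- names(tab)
  v
}

#' Annotate filtered SNPs against canonical gene models
#'
#' Assigns each SNP a functional category (intergenic, intron, UTR, CDS or
#' other noncoding) per overlapping canonical transcript; a SNP hitting
#' several genes yields one row per gene, flagged `multi_gene`. CDS hits get
#' their codon context on the coding strand (alleles reverse-complemented
#' for minus-strand genes), a mutation-effect class, and a splice-window
#' flag; effects are withheld (`NA`) inside splice windows so that
#' effect-based statistics are not confounded by selection on splicing.
#' Records whose reference allele disagrees with the genome are rejected
#' and counted (attribute `n_ref_mismatch`).
#'
#' @param snps data frame of filtered SNPs: `snp_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt` (single base), optional `og1`, `og2`, `cons`.
#' @param models a [gene_models()] object (canonical transcripts).
#' @param genome named character vector of chromosome sequences or a
#'   `DNAStringSet`.
#' @param splice_window CDS positions within this many nucleotides of an
#'   exon-intron junction are flagged (default 3).
#' @return data frame of class `annotated_snps`: one row per (SNP, gene)
#'   pair plus one row per genic-miss SNP, with columns `snp_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `og1`, `og2`, `cons`, `category`, `gene_id`,
#'   `is_flagged`, `multi_gene`, `cds_pos`, `codon_index`, `pos_in_codon`,
#'   `ref_codon`, `alt_codon`, `effect`, `in_splice_region`, `evo_class`,
#'   `relative_cds_position`.
#' @export
annotate_snps <- function(snps, models, genome, splice_window = 3L) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  snps <- as.data.frame(snps)
  for (col in c("og1", "og2")) if (!col %in% names(snps)) snps[[col]] <- NA_character_
  if (!"cons" %in% names(snps)) snps$cons <- NA_real_
  # consistency guard: reference allele must match the genome
  gbase <- substring(genome[snps$chrom], snps$pos, snps$pos)
  ok <- !is.na(gbase) & gbase == snps$ref
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(n_bad, " SNP(s) rejected: reference allele disagrees with genome")
    snps <- snps[ok, , drop = FALSE]
  }
  g <- models$genes
  # gene bodies span first to last exon
  body <- do.call(rbind, lapply(split(models$exons, models$exons$gene_id),
    function(e) data.frame(gene_id = e$gene_id[1], start = min(e$start),
                           end = max(e$end))))
  body$chrom <- g$chrom[match(body$gene_id, g$gene_id)]
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  body_gr <- GenomicRanges::GRanges(body$chrom,
                                    IRanges::IRanges(body$start, body$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, body_gr)
  si <- S4Vectors::queryHits(hits)
  gene_hit <- body$gene_id[S4Vectors::subjectHits(hits)]
  # genic rows + one intergenic row per unhit SNP
  miss <- setdiff(seq_len(nrow(snps)), unique(si))
  idx <- c(si, miss)
  ann <- snps[idx, , drop = FALSE]
  ann$gene_id <- c(gene_hit, rep(NA_character_, length(miss)))
  n_hits <- table(si)
  ann$multi_gene <- FALSE
  ann$multi_gene[seq_along(si)] <- as.integer(n_hits[as.character(si)]) > 1L
  # category: cds > utr/noncoding_other > intron, per gene
  # (numeric gene-index x position keys, as in the model validation)
  ew <- models$exons$end - models$exons$start + 1L
  ekey <- rep(match(models$exons$gene_id, g$gene_id), ew) * 2^40 +
    .expand_pos(models$exons$start, models$exons$end)
  cmap <- .cds_position_map(models)
  ckey <- match(cmap$gene_id, g$gene_id) * 2^40 + cmap$gpos
  akey <- match(ann$gene_id, g$gene_id) * 2^40 + ann$pos
  has_cds <- stats::setNames(g$cds_length > 0, g$gene_id)
  in_cds <- akey %in% ckey
  in_exon <- akey %in% ekey
  ann$category <- ifelse(is.na(ann$gene_id), "intergenic",
                  ifelse(in_cds, "cds",
                  ifelse(in_exon & has_cds[ann$gene_id], "utr",
                  ifelse(in_exon, "noncoding_other", "intron"))))
  # codon context for CDS rows
  ann$cds_pos <- ann$codon_index <- ann$pos_in_codon <- NA_integer_
  ann$ref_codon <- ann$alt_codon <- NA_character_
  ann$effect <- NA_character_
  ann$in_splice_region <- FALSE
  ann$relative_cds_position <- NA_real_
  ci <- which(ann$category == "cds")
  if (length(ci)) {
    cds_pos <- cmap$cds_pos[match(akey[ci], ckey)]
    strand <- stats::setNames(g$strand, g$gene_id)[ann$gene_id[ci]]
    cds_len <- stats::setNames(g$cds_length, g$gene_id)[ann$gene_id[ci]]
    codon_index <- (cds_pos - 1L) %/% 3L + 1L
    pos_in_codon <- (cds_pos - 1L) %% 3L + 1L
    seqs <- cds_sequences(models, genome)
    ref_codon <- substring(seqs[ann$gene_id[ci]], (codon_index - 1L) * 3L + 1L,
                           codon_index * 3L)
    alt_coding <- ifelse(strand == "+", ann$alt[ci], .complement(ann$alt[ci]))
    alt_codon <- ref_codon
    substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_coding
    ann$cds_pos[ci] <- cds_pos
    ann$codon_index[ci] <- codon_index
    ann$pos_in_codon[ci] <- pos_in_codon
    ann$ref_codon[ci] <- ref_codon
    ann$alt_codon[ci] <- alt_codon
    ann$relative_cds_position[ci] <- cds_pos / cds_len
    ann$in_splice_region[ci] <- akey[ci] %in% .splice_keys(models,
                                                           splice_window)
    eff_ok <- !ann$in_splice_region[ci]
    ann$effect[ci[eff_ok]] <- effect_from_codons(ref_codon[eff_ok],
                                                 alt_codon[eff_ok])
  }
  ann$is_flagged <- stats::setNames(g$is_flagged, g$gene_id)[ann$gene_id]
  ann$is_flagged[is.na(ann$is_flagged)] <- FALSE
  ann$evo_class <- classify_evolutionary(ann)
  rownames(ann) <- NULL
  class(ann) <- c("annotated_snps", "data.frame")
  attr(ann, "n_ref_mismatch") <- n_bad
  ann
}

#' Pair two mutations falling in the same codon
#'
#' Codons of one canonical CDS carrying exactly two (non-splice-window) SNPs
#' yield one double-mutation case each, with the combined product compared
#' to both single-mutation products; codons with three or more SNPs are
#' skipped and counted (attribute `n_skipped_multi`).
#'
#' @param ann an [annotate_snps()] result (any subset of its rows).
#' @return data frame: `gene_id`, `is_flagged`, `codon_index`,
#'   `snp_id1`, `snp_id2`, the [combined_double_effect()] columns, and
#'   `relative_cds_position` (codon end over CDS length).
#' @export
pair_double_mutations <- function(ann) {
  cds <- ann[ann$category == "cds" & !ann$in_splice_region &
               !is.na(ann$codon_index), , drop = FALSE]
  # only sense reference codons can combine into new products
  cds <- cds[!.is_stop(cds$ref_codon), , drop = FALSE]
  key <- paste(cds$gene_id, cds$codon_index)
  n_in_codon <- table(key)
  skipped <- sum(n_in_codon >= 3)
  pairs <- names(n_in_codon)[n_in_codon == 2]
  empty <- data.frame(gene_id = character(), is_flagged = logical(),
                      codon_index = integer(), snp_id1 = character(),
                      snp_id2 = character(), stringsAsFactors = FALSE)
  if (length(pairs) == 0)
    return(structure(empty, n_skipped_multi = skipped))
  cds <- cds[key %in% pairs, , drop = FALSE]
  cds <- cds[order(cds$gene_id, cds$codon_index, cds$pos_in_codon), ]
  i1 <- seq(1, nrow(cds), 2)
  i2 <- i1 + 1
  alt_coding <- substring(cds$alt_codon, cds$pos_in_codon, cds$pos_in_codon)
  case <- combined_double_effect(cds$ref_codon[i1],
                                 cds$pos_in_codon[i1], alt_coding[i1],
                                 cds$pos_in_codon[i2], alt_coding[i2])
  out <- cbind(data.frame(gene_id = cds$gene_id[i1],
                          is_flagged = cds$is_flagged[i1],
                          codon_index = cds$codon_index[i1],
                          snp_id1 = cds$snp_id[i1],
                          snp_id2 = cds$snp_id[i2],
                          stringsAsFactors = FALSE),
               case)
  cds_len <- round(cds$cds_pos[i1] / cds$relative_cds_position[i1])
  out$relative_cds_position <- pmin(1, (out$codon_index * 3) / cds_len)
  rownames(out) <- NULL
  structure(out, n_skipped_multi = skipped)
}
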