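# Readers and writers for the dialects the pipeline consumes and emits:
# FASTA genomes, GFF3 gene models, VCF SNPs (with OG1/OG2/CONS INFO keys or
# sidecar tables), bedGraph conservation, and plain TSVs.

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return named character vector of chromosome sequences (names truncated
#'   at the first whitespace).
#' @export
read_genome_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Write a genome FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features with ID/Parent attributes.
#'
#' @param models a [gene_models()] object.
#' @param path output file.
#' @export
write_gene_models_gff3 <- function(models, path) {
  g <- models$genes
  rows <- list()
  body <- lapply(split(models$exons, models$exons$gene_id), function(e)
    c(min(e$start), max(e$end)))
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]; tid <- g$transcript_id[i]
    b <- body[[gid]]
    rows[[length(rows) + 1L]] <- sprintf(
      "%s\tcodonsel\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$chrom[i], b[1], b[2], g$strand[i], gid)
    rows[[length(rows) + 1L]] <- sprintf(
      "%s\tcodonsel\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
      g$chrom[i], b[1], b[2], g$strand[i], tid, gid)
    ex <- models$exons[models$exons$gene_id == gid, ]
    rows[[length(rows) + 1L]] <- sprintf(
      "%s\tcodonsel\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
      g$chrom[i], ex$start, ex$end, g$strand[i], tid)
    cd <- models$cds[models$cds$gene_id == gid, ]
    if (nrow(cd))
      rows[[length(rows) + 1L]] <- sprintf(
        "%s\tcodonsel\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
        g$chrom[i], cd$start, cd$end, g$strand[i], tid)
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps one canonical transcript per gene (longest CDS, ties to the
#' lexicographically smallest transcript id).
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS features linked by
#'   ID/Parent attributes.
#' @param flagged character vector of flagged gene ids.
#' @return a [gene_models()] object.
#' @export
read_gene_models_gff3 <- function(path, flagged = character()) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  if (anyDuplicated(mrna$ID))
    stop("duplicated transcript IDs in GFF3", call. = FALSE)
  if (anyDuplicated(df$ID[df$type == "gene"]))
    stop("duplicated gene IDs in GFF3", call. = FALSE)
  cds <- df[df$type == "CDS", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cds_len <- tapply(cds$end - cds$start + 1, cds$Parent, sum)
  tx <- data.frame(gene_id = mrna$Parent, transcript_id = mrna$ID,
                   cds_length = as.integer(cds_len[mrna$ID]),
                   stringsAsFactors = FALSE)
  canon <- select_canonical(tx)
  keep_tx <- canon$transcript_id
  mrna <- mrna[mrna$ID %in% keep_tx, , drop = FALSE]
  genes <- data.frame(gene_id = mrna$Parent, transcript_id = mrna$ID,
                      chrom = as.character(mrna$seqnames),
                      strand = as.character(mrna$strand),
                      is_flagged = mrna$Parent %in% flagged,
                      stringsAsFactors = FALSE)
  tx2gene <- stats::setNames(genes$gene_id, genes$transcript_id)
  ex <- exons[exons$Parent %in% keep_tx, c("Parent", "start", "end")]
  cd <- cds[cds$Parent %in% keep_tx, c("Parent", "start", "end")]
  ex$gene_id <- tx2gene[ex$Parent]; cd$gene_id <- tx2gene[cd$Parent]
  gene_models(genes, ex[, c("gene_id", "start", "end")],
              cd[, c("gene_id", "start", "end")])
}

#' Write SNPs as a minimal VCF
#'
#' Outgroup bases and conservation scores travel in the INFO keys `OG1`,
#' `OG2` and `CONS`.
#'
#' @param snps data frame: `snp_id`, `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated for multi-allelic records), optional `og1`, `og2`,
#'   `cons`.
#' @param path output file.
#' @export
write_snps_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=OG1,Number=1,Type=Character,Description=\"Near outgroup base\">",
           "##INFO=<ID=OG2,Number=1,Type=Character,Description=\"Far outgroup base\">",
           "##INFO=<ID=CONS,Number=1,Type=Float,Description=\"Conservation score\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- character(nrow(snps))
  add <- function(info, key, val) {
    has <- !is.na(val)
    piece <- paste0(key, "=", val)
    ifelse(has, ifelse(info == "", piece, paste0(info, ";", piece)), info)
  }
  if (!is.null(snps$og1)) info <- add(info, "OG1", snps$og1)
  if (!is.null(snps$og2)) info <- add(info, "OG2", snps$og2)
  if (!is.null(snps$cons)) info <- add(info, "CONS", snps$cons)
  info[info == ""] <- "."
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                  snps$chrom, snps$pos, snps$snp_id, snps$ref, snps$alt,
                  info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SNPs from VCF
#'
#' Indels and other non-SNV records are dropped with a message. Outgroup
#' bases and conservation scores come from the INFO keys `OG1`/`OG2`/`CONS`
#' when present, else from sidecar tables.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param ortholog_path optional TSV sidecar: `chrom`, `pos`, `og1`, `og2`.
#' @param conservation_path optional bedGraph sidecar of per-base scores.
#' @return data frame: `snp_id`, `chrom`, `pos`, `ref`, `alt`, `og1`,
#'   `og2`, `cons`; attribute `n_dropped_non_snv`.
#' @export
read_snps_vcf <- function(path, ortholog_path = NULL,
                          conservation_path = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF,
                     alt = fix$ALT, stringsAsFactors = FALSE)
  alts <- strsplit(ifelse(is.na(snps$alt), "", snps$alt), ",", fixed = TRUE)
  is_snv <- nchar(snps$ref) == 1 &
    vapply(alts, function(a) length(a) > 0 && all(nchar(a) == 1), logical(1))
  n_drop <- sum(!is_snv)
  if (n_drop > 0)
    message(n_drop, " non-SNV record(s) dropped")
  snps <- snps[is_snv, , drop = FALSE]
  get_info <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    x[is_snv]
  }
  snps$og1 <- get_info("OG1")
  snps$og2 <- get_info("OG2")
  snps$cons <- suppressWarnings(as.numeric(get_info("CONS")))
  if (!is.null(ortholog_path) && all(is.na(snps$og1))) {
    ot <- utils::read.delim(ortholog_path, stringsAsFactors = FALSE)
    i <- match(paste(snps$chrom, snps$pos), paste(ot$chrom, ot$pos))
    snps$og1 <- ot$og1[i]; snps$og2 <- ot$og2[i]
  }
  if (!is.null(conservation_path) && all(is.na(snps$cons))) {
    ct <- read_conservation_bedgraph(conservation_path)
    i <- match(paste(snps$chrom, snps$pos), paste(ct$chrom, ct$pos))
    snps$cons <- ct$score[i]
  }
  rownames(snps) <- NULL
  structure(snps, n_dropped_non_snv = n_drop)
}

#' Read a per-base conservation track from bedGraph
#'
#' @param path bedGraph file.
#' @return data frame `chrom`, `pos` (1-based), `score`, one row per base.
#' @export
read_conservation_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  w <- GenomicRanges::width(gr)
  data.frame(chrom = rep(as.character(GenomicRanges::seqnames(gr)), w),
             pos = .expand_pos(GenomicRanges::start(gr),
                               GenomicRanges::end(gr)),
             score = rep(gr$score, w), stringsAsFactors = FALSE)
}

#' Read a flagged-gene list (one id per line, first column of a TSV)
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_flagged_genes <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  unique(as.character(x[[1]]))
}

#' Read a gene-level read-count table
#'
#' @param path TSV with columns `gene_id` and `count` (header optional).
#' @return named numeric vector of counts.
#' @export
read_counts_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "count") %in% names(x))) {
    x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(x)[1:2] <- c("gene_id", "count")
  }
  stats::setNames(as.numeric(x$count), x$gene_id)
}

#' Write a simulation bundle to disk
#'
#' Emits every input dialect the pipeline consumes, plus the ground truth
#' and the resolved configuration.
#'
#' @param sim a [simulate_snps()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "codonsel_sim"), !is.null(sim$snps))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_genome_fasta(sim$genome, fp("genome.fa"))
  write_gene_models_gff3(sim$models, fp("genes.gff3"))
  write_snps_vcf(sim$snps, fp("snps.vcf"))
  writeLines(sim$flagged, fp("flagged_genes.tsv"))
  utils::write.table(
    data.frame(chrom = sim$snps$chrom, pos = sim$snps$pos,
               og1 = sim$snps$og1, og2 = sim$snps$og2),
    fp("orthologs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- sprintf("%s\t%d\t%d\t%s", sim$snps$chrom, sim$snps$pos - 1L,
                 sim$snps$pos, format(sim$snps$cons, trim = TRUE))
  writeLines(bed, fp("conservation.bedGraph"))
  utils::write.table(
    data.frame(gene_id = names(sim$read_counts),
               count = as.numeric(sim$read_counts)),
    fp("read_counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, fp("ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  class(cfg) <- NULL
  cfg$acceptance <- lapply(cfg$acceptance, as.list)
  yaml::write_yaml(cfg, fp("config.yaml"))
  invisible(dir)
}
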