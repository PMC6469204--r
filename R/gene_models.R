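# Canonical-transcript gene models: validated container plus the coordinate
# machinery (CDS position maps, coding-strand sequences, splice windows)
# shared by the annotator and the simulator. Coordinates are 1-based closed
# on the genome; interval arithmetic happens on expanded position vectors.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.complement <- function(base) chartr("ACGT", "TGCA", base)

# fast conversions between a sequence string and a per-base character vector
.base_codes <- c(A = 65L, C = 67L, G = 71L, T = 84L)
.bases_to_str <- function(bases) {
  rawToChar(as.raw(.base_codes[match(bases, .nucs)]))
}
.str_to_bases <- function(s) {
  .nucs[match(as.integer(charToRaw(s)), .base_codes)]
}

#' Construct a validated set of canonical gene models
#'
#' @param genes data frame with one row per gene: `gene_id`,
#'   `transcript_id`, `chrom`, `strand` (`"+"`/`"-"`), `is_flagged`
#'   (membership in the flagged gene set).
#' @param exons,cds data frames of 1-based closed intervals: `gene_id`,
#'   `start`, `end`. Every CDS base must fall inside an exon; intervals per
#'   gene must be non-overlapping. `cds` may omit genes (noncoding genes).
#' @return object of class `gene_models` with derived `cds_length` and
#'   `mrna_length` columns on `$genes`.
#' @export
gene_models <- function(genes, exons, cds) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "strand") %in%
                  names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id in gene models", call. = FALSE)
  if (!"is_flagged" %in% names(genes)) genes$is_flagged <- FALSE
  for (d in list(exons, cds))
    stopifnot(all(c("gene_id", "start", "end") %in% names(d)),
              all(d$end >= d$start))
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
  cds <- cds[order(match(cds$gene_id, genes$gene_id), cds$start), ]
  check_disjoint <- function(d, what) {
    if (nrow(d) < 2) return(invisible())
    same <- d$gene_id[-1] == d$gene_id[-nrow(d)]
    if (any(same & d$start[-1] <= d$end[-nrow(d)]))
      stop("overlapping ", what, " intervals within a gene", call. = FALSE)
  }
  check_disjoint(exons, "exon")
  check_disjoint(cds, "CDS")
  cds_len <- tapply(cds$end - cds$start + 1, cds$gene_id, sum)
  mrna_len <- tapply(exons$end - exons$start + 1, exons$gene_id, sum)
  genes$cds_length <- as.integer(cds_len[genes$gene_id])
  genes$cds_length[is.na(genes$cds_length)] <- 0L
  genes$mrna_length <- as.integer(mrna_len[genes$gene_id])
  if (any(genes$cds_length %% 3 != 0))
    stop("CDS length not divisible by 3 for: ",
         paste(utils::head(genes$gene_id[genes$cds_length %% 3 != 0], 5),
               collapse = ", "), call. = FALSE)
  # CDS within exons: every CDS position must be exon-covered
  # (numeric gene x position keys; exact for genomes below 2^40 bases)
  gidx <- function(id) match(id, genes$gene_id)
  key <- function(d) {
    w <- d$end - d$start + 1L
    rep(gidx(d$gene_id), w) * 2^40 + (sequence(w) + rep(d$start - 1L, w))
  }
  if (!all(key(cds) %in% key(exons)))
    stop("CDS intervals extend outside exons", call. = FALSE)
  rownames(genes) <- rownames(exons) <- rownames(cds) <- NULL
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes (",
      sum(x$genes$is_flagged), "flagged ),",
      nrow(x$exons), "exons,", nrow(x$cds), "CDS intervals\n")
  invisible(x)
}

#' Pick the canonical transcript of each gene (longest CDS)
#'
#' @param transcripts data frame with `gene_id`, `transcript_id`,
#'   `cds_length` (0 or `NA` for noncoding isoforms).
#' @return data frame with one chosen row per coding gene; ties on CDS
#'   length break to the lexicographically smallest `transcript_id`. Genes
#'   with no coding transcript are dropped (ids in attribute
#'   `excluded_noncoding`).
#' @export
select_canonical <- function(transcripts) {
  t <- transcripts
  t$cds_length[is.na(t$cds_length)] <- 0L
  coding <- t[t$cds_length > 0, , drop = FALSE]
  excluded <- setdiff(unique(t$gene_id), unique(coding$gene_id))
  if (nrow(coding) == 0) {
    out <- coding
  } else {
    coding <- coding[order(coding$gene_id, -coding$cds_length,
                           coding$transcript_id), , drop = FALSE]
    out <- coding[!duplicated(coding$gene_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "excluded_noncoding") <- excluded
  out
}

# expand 1-based closed intervals to a position vector
.expand_pos <- function(start, end) {
  w <- end - start + 1L
  sequence(w) + rep(start - 1L, w)
}

# per-gene map genomic position -> CDS offset (1-based, coding orientation)
.cds_position_map <- function(models) {
  cds <- models$cds
  if (nrow(cds) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      gpos = integer(), cds_pos = integer()))
  g <- models$genes
  w <- cds$end - cds$start + 1L
  gi <- match(cds$gene_id, g$gene_id)
  gi_of <- rep(gi, w)
  gpos <- .expand_pos(cds$start, cds$end)
  # plus-orientation offset along the genome within each gene (rows are
  # sorted by gene then start, so a grouped cumsum suffices)
  cum <- cumsum(w) - w
  first <- !duplicated(cds$gene_id)
  base <- rep(cum[first], times = rle(cds$gene_id)$lengths)
  plus_pos <- rep(cum - base, w) + sequence(w)
  minus <- g$strand[gi_of] == "-"
  cds_pos <- plus_pos
  cds_pos[minus] <- g$cds_length[gi_of[minus]] - plus_pos[minus] + 1L
  data.frame(gene_id = g$gene_id[gi_of], chrom = g$chrom[gi_of],
             gpos = gpos, cds_pos = as.integer(cds_pos),
             stringsAsFactors = FALSE, row.names = NULL)
}

# numeric (gene-index * 2^40 + position) keys of genomic positions within
# `window` nt of an internal exon-intron junction
.splice_keys <- function(models, window = 3L) {
  ex <- models$exons
  n_ex <- table(ex$gene_id)
  multi <- names(n_ex)[n_ex > 1]
  ex <- ex[ex$gene_id %in% multi, , drop = FALSE]
  if (nrow(ex) == 0) return(numeric())
  first <- !duplicated(ex$gene_id)
  last <- !duplicated(ex$gene_id, fromLast = TRUE)
  gi <- match(ex$gene_id, models$genes$gene_id)
  keys <- numeric()
  don <- which(!last)   # exon end abuts the next intron
  if (length(don))
    keys <- c(keys, rep(gi[don], each = window) * 2^40 +
                (rep(ex$end[don], each = window) - (seq_len(window) - 1L)))
  acc <- which(!first)  # exon start abuts the previous intron
  if (length(acc))
    keys <- c(keys, rep(gi[acc], each = window) * 2^40 +
                (rep(ex$start[acc], each = window) + (seq_len(window) - 1L)))
  unique(keys)
}

#' Extract coding-strand CDS sequences from a genome
#'
#' @param models a [gene_models()] object.
#' @param genome named character vector of chromosome sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @return named character vector of CDS sequences (coding strand, start
#'   codon first), one per coding gene.
#' @export
cds_sequences <- function(models, genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  cds <- models$cds
  g <- models$genes
  chrom <- stats::setNames(g$chrom, g$gene_id)
  pieces <- substring(genome[chrom[cds$gene_id]], cds$start, cds$end)
  seqs <- vapply(split(pieces, factor(cds$gene_id, unique(cds$gene_id))),
                 paste0, character(1), collapse = "")
  minus <- names(seqs)[stats::setNames(g$strand, g$gene_id)[names(seqs)] == "-"]
  if (length(minus)) seqs[minus] <- .revcomp(seqs[minus])
  seqs
}

#' CDS G+C content per gene
#'
#' @inheritParams cds_sequences
#' @return named numeric vector of GC proportions over the full CDS.
#' @export
cds_gc_content <- function(models, genome) {
  seqs <- cds_sequences(models, genome)
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs),
                                        baseOnly = TRUE)
  stats::setNames((freq[, "C"] + freq[, "G"]) / rowSums(freq[, 1:4]),
                  names(seqs))
}
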