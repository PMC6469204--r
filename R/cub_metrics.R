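# Gene-level codon usage bias (scaled chi-square against intronic A/T
# content), per-codon preference (Spearman rho across genes) and delta
# metrics for synonymous changes.

#' Count codons per gene from canonical CDS sequences
#'
#' The initiator codon and the terminal stop codon are excluded from the
#' counts. Codons containing non-ACGT characters are skipped with a warning.
#'
#' @param cds named character vector (or `Biostrings::DNAStringSet`) of CDS
#'   sequences, one per canonical transcript, each a multiple of 3 long with
#'   at least 3 codons.
#' @return object of class `gene_codon_counts`: list with `counts` (integer
#'   matrix, genes x 64 codons) and `peptide_length` (codons minus the stop).
#' @export
gene_codon_counts <- function(cds) {
  if (inherits(cds, "DNAStringSet")) cds <- as.character(cds)
  seqs <- toupper(cds)
  if (is.null(names(seqs))) names(seqs) <- paste0("gene", seq_along(seqs))
  L <- nchar(seqs)
  if (any(L %% 3 != 0))
    stop("CDS length must be a multiple of 3 (offenders: ",
         paste(utils::head(names(seqs)[L %% 3 != 0], 5), collapse = ", "),
         ")", call. = FALSE)
  nc <- L %/% 3
  if (any(nc < 3))
    stop("each CDS needs at least 3 codons", call. = FALSE)
  # internal codons only: drop the initiator and the stop
  starts <- unlist(lapply(nc, function(k) seq.int(4L, (k - 2L) * 3L + 1L, 3L)),
                   use.names = FALSE)
  gene_of <- rep(names(seqs), nc - 2L)
  codons <- substring(rep(seqs, nc - 2L), starts, starts + 2L)
  bad <- grepl("[^ACGT]", codons)
  if (any(bad)) {
    warning(sum(bad), " codon(s) containing non-ACGT characters skipped")
    codons <- codons[!bad]
    gene_of <- gene_of[!bad]
  }
  counts <- table(factor(gene_of, levels = names(seqs)),
                  factor(codons, levels = names(.codon_table)))
  counts <- matrix(as.integer(counts), nrow = length(seqs),
                   dimnames = list(names(seqs), names(.codon_table)))
  structure(list(counts = counts,
                 peptide_length = stats::setNames(nc - 1L, names(seqs))),
            class = "gene_codon_counts")
}

# chi-square of (O_AT, O_GC) against the intronic A/T expectation, vectorised
# over genes. gof: classic goodness of fit against E_AT = N*p, E_GC = N*(1-p).
# r2x2: Pearson statistic with continuity correction on the 2x2 table whose
# columns are the observed and the expected counts.
.chi2_cells <- function(o_at, o_gc, at3_content, mode) {
  n <- o_at + o_gc
  out <- numeric(length(n))
  nz <- n > 0
  if (mode == "gof") {
    e_at <- n[nz] * at3_content
    e_gc <- n[nz] * (1 - at3_content)
    out[nz] <- (o_at[nz] - e_at)^2 / e_at + (o_gc[nz] - e_gc)^2 / e_gc
  } else {
    a <- o_at[nz]; b <- n[nz] * at3_content
    c_ <- o_gc[nz]; d <- n[nz] * (1 - at3_content)
    tot <- a + b + c_ + d
    e11 <- (a + b) * (a + c_) / tot
    e12 <- (a + b) * (b + d) / tot
    e21 <- (c_ + d) * (a + c_) / tot
    e22 <- (c_ + d) * (b + d) / tot
    dev <- cbind(abs(a - e11), abs(b - e12), abs(c_ - e21), abs(d - e22))
    yates <- pmin(0.5, apply(dev, 1, min))
    out[nz] <- (dev[, 1] - yates)^2 / e11 + (dev[, 2] - yates)^2 / e12 +
      (dev[, 3] - yates)^2 / e21 + (dev[, 4] - yates)^2 / e22
  }
  attr(out, "absent") <- !nz
  out
}

#' Chi-square deviation of a codon family's third-position A/T content
#'
#' For one synonymous codon family in one gene, measures the deviation of the
#' third-position A/T share from the intronic A/T content. Families with more
#' than two codons are collapsed to two cells (A/T-ending versus G/C-ending).
#'
#' @param family a family id (see [codon_families()]).
#' @param counts named integer vector of codon counts for one gene, or a
#'   `gene_codon_counts` object holding a single gene.
#' @param at3_content expected A/T proportion at codon position 3 (intronic
#'   A/T content; 0.59 in human).
#' @param mode `"gof"` for the classic goodness-of-fit statistic;
#'   `"r2x2"` for the Pearson statistic with continuity correction on the
#'   2x2 table of observed versus expected counts.
#' @return the chi-square value (0 for a family absent from the gene, with
#'   attribute `absent = TRUE`).
#' @examples
#' family_chi_square("K", c(AAA = 59, AAG = 41))       # 0: matches 0.59
#' family_chi_square("K", c(AAA = 0, AAG = 100))       # strong GC3 excess
#' @export
family_chi_square <- function(family, counts, at3_content = 0.59,
                              mode = c("gof", "r2x2")) {
  mode <- match.arg(mode)
  if (!(at3_content > 0 && at3_content < 1))
    stop("at3_content must lie in (0,1)", call. = FALSE)
  if (inherits(counts, "gene_codon_counts")) counts <- counts$counts[1, ]
  fam <- codon_families()
  fam <- fam[fam$family_id == family, , drop = FALSE]
  if (nrow(fam) == 0) stop("unknown family id: ", family, call. = FALSE)
  cnt <- counts[fam$codon]
  cnt[is.na(cnt)] <- 0
  o_at <- sum(cnt[!fam$ends_gc])
  o_gc <- sum(cnt[fam$ends_gc])
  val <- .chi2_cells(o_at, o_gc, at3_content, mode)
  if (any(attr(val, "absent")))
    structure(as.numeric(val), absent = TRUE)
  else as.numeric(val)
}

#' Gene-level codon usage bias: the scaled chi-square
#'
#' Sums the per-family chi-square deviations of third-position A/T content
#' from the intronic A/T content and normalises by peptide length.
#'
#' @param counts a `gene_codon_counts` object (or bare codon-count matrix
#'   with genes as rows).
#' @param peptide_length required when `counts` is a bare matrix.
#' @inheritParams family_chi_square
#' @return object of class `cub_profile`: list with `genes` (data frame:
#'   `gene_id`, `peptide_length`, `scaled_chi2`), `family_chi2` (genes x
#'   families matrix) and `absent` (logical matrix of families with no
#'   occurrences).
#' @export
gene_scaled_chi2 <- function(counts, at3_content = 0.59,
                             mode = c("gof", "r2x2"), peptide_length = NULL) {
  mode <- match.arg(mode)
  if (inherits(counts, "gene_codon_counts")) {
    peptide_length <- counts$peptide_length
    counts <- counts$counts
  }
  if (is.null(peptide_length))
    stop("peptide_length required with a bare count matrix", call. = FALSE)
  if (any(peptide_length <= 0))
    stop("peptide_length must be positive", call. = FALSE)
  fam <- codon_families()
  fam_ids <- unique(fam$family_id)
  chi2 <- matrix(0, nrow(counts), length(fam_ids),
                 dimnames = list(rownames(counts), fam_ids))
  absent <- chi2 > 0
  for (f in fam_ids) {
    fc <- fam[fam$family_id == f, ]
    o_at <- rowSums(counts[, fc$codon[!fc$ends_gc], drop = FALSE])
    o_gc <- rowSums(counts[, fc$codon[fc$ends_gc], drop = FALSE])
    v <- .chi2_cells(o_at, o_gc, at3_content, mode)
    chi2[, f] <- v
    absent[, f] <- attr(v, "absent")
  }
  genes <- data.frame(
    gene_id = rownames(counts),
    peptide_length = as.integer(peptide_length),
    scaled_chi2 = rowSums(chi2) / peptide_length,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(genes = genes, family_chi2 = chi2, absent = absent,
                 at3_content = at3_content, mode = mode),
            class = "cub_profile")
}

#' @export
print.cub_profile <- function(x, ...) {
  cat("Codon usage bias profile (", nrow(x$genes), " genes, mode ", x$mode,
      ", intronic A/T ", x$at3_content, ")\n", sep = "")
  cat("scaled chi-square: median ",
      signif(stats::median(x$genes$scaled_chi2), 4), ", range [",
      signif(min(x$genes$scaled_chi2), 4), ", ",
      signif(max(x$genes$scaled_chi2), 4), "]\n", sep = "")
  invisible(x)
}

#' Per-codon preference across genes
#'
#' For each of the 59 family codons, correlates (Spearman) the codon's
#' within-family usage share per gene against the gene's scaled chi-square.
#' A positive rho marks a preferred codon, a negative rho an unpreferred one.
#'
#' @param counts a `gene_codon_counts` object.
#' @param profile optional precomputed [gene_scaled_chi2()] result for the
#'   same genes.
#' @param min_genes minimum number of genes carrying the family for a codon's
#'   rho to be defined (default 3).
#' @inheritParams family_chi_square
#' @return object of class `codon_preference`: data frame with one row per
#'   family codon: `codon`, `family_id`, `amino_acid`, `ends_gc`, `rho`,
#'   `p_value`, `n_genes`, `family_freq` (pooled within-family usage share)
#'   and `global_freq` (pooled share among all counted codons).
#' @export
codon_preference <- function(counts, profile = NULL, at3_content = 0.59,
                             mode = c("gof", "r2x2"), min_genes = 3) {
  mode <- match.arg(mode)
  if (is.null(profile))
    profile <- gene_scaled_chi2(counts, at3_content, mode)
  stopifnot(inherits(counts, "gene_codon_counts"))
  cm <- counts$counts
  chi <- profile$genes$scaled_chi2[match(rownames(cm), profile$genes$gene_id)]
  fam <- codon_families()
  pooled <- colSums(cm)
  total_counted <- sum(pooled)
  res <- fam
  res$rho <- NA_real_
  res$p_value <- NA_real_
  res$n_genes <- 0L
  res$family_freq <- NA_real_
  res$global_freq <- pooled[fam$codon] / total_counted
  for (f in unique(fam$family_id)) {
    idx <- which(res$family_id == f)
    cods <- res$codon[idx]
    fam_tot <- rowSums(cm[, cods, drop = FALSE])
    use <- fam_tot > 0
    pool_f <- sum(pooled[cods])
    res$family_freq[idx] <- pooled[cods] / pool_f
    if (sum(use) < min_genes) next
    for (j in seq_along(idx)) {
      freq <- cm[use, cods[j]] / fam_tot[use]
      res$n_genes[idx[j]] <- sum(use)
      if (stats::sd(freq) == 0 || stats::sd(chi[use]) == 0) next
      ct <- suppressWarnings(stats::cor.test(
        freq, chi[use], method = "spearman",
        exact = sum(use) <= 9))
      res$rho[idx[j]] <- unname(ct$estimate)
      res$p_value[idx[j]] <- ct$p.value
    }
  }
  row.names(res) <- NULL
  class(res) <- c("codon_preference", "data.frame")
  attr(res, "at3_content") <- at3_content
  attr(res, "mode") <- mode
  res
}

#' Delta codon bias and delta codon frequency for coding changes
#'
#' The delta of a metric is its post-mutation value minus its pre-mutation
#' value; for a synonymous change both codons lie in the same family, making
#' within-family frequency deltas directly comparable.
#'
#' @param pre_codon,post_codon codon vectors (recycled to a common length).
#' @param pref a [codon_preference()] table.
#' @param freq_kind `"family"` (within-family usage share, default) or
#'   `"global"` (share among all counted codons).
#' @return data frame with `pre_codon`, `post_codon`, `delta_bias`,
#'   `delta_freq`, `same_family`, `ok` and `reason` (`NA` when usable; a
#'   record is skipped when either codon lacks a defined rho).
#' @export
delta_for_snp <- function(pre_codon, post_codon, pref,
                          freq_kind = c("family", "global")) {
  freq_kind <- match.arg(freq_kind)
  n <- max(length(pre_codon), length(post_codon))
  pre_codon <- toupper(rep_len(pre_codon, n))
  post_codon <- toupper(rep_len(post_codon, n))
  i_pre <- match(pre_codon, pref$codon)
  i_post <- match(post_codon, pref$codon)
  fcol <- if (freq_kind == "family") pref$family_freq else pref$global_freq
  rho_pre <- pref$rho[i_pre]; rho_post <- pref$rho[i_post]
  ok <- !is.na(rho_pre) & !is.na(rho_post)
  out <- data.frame(
    pre_codon = pre_codon, post_codon = post_codon,
    delta_bias = rho_post - rho_pre,
    delta_freq = fcol[i_post] - fcol[i_pre],
    same_family = !is.na(i_pre) & !is.na(i_post) &
      pref$family_id[i_pre] == pref$family_id[i_post],
    ok = ok,
    reason = ifelse(ok, NA_character_, "undefined rho"),
    stringsAsFactors = FALSE
  )
  out$delta_bias[!ok] <- NA_real_
  out$delta_freq[!ok] <- NA_real_
  out
}

#' Per-gene mean delta of coding SNPs
#'
#' @param records data frame of delta records carrying `gene_id`,
#'   `delta_bias`, `delta_freq`, `ok` and (when `scope = "synonymous"`) an
#'   `effect` column.
#' @param scope `"synonymous"` (default: rho differences across families are
#'   not comparable, so only same-family changes enter the gene mean) or
#'   `"all"` for every CDS record with defined rho on both codons.
#' @return data frame: `gene_id`, `n_delta`, `mean_delta_bias`,
#'   `mean_delta_freq`. Genes without usable records are absent.
#' @export
gene_mean_delta <- function(records, scope = c("synonymous", "all")) {
  scope <- match.arg(scope)
  keep <- records$ok
  if (scope == "synonymous") keep <- keep & records$effect == "synonymous"
  r <- records[keep & !is.na(keep), , drop = FALSE]
  if (nrow(r) == 0)
    return(data.frame(gene_id = character(), n_delta = integer(),
                      mean_delta_bias = numeric(),
                      mean_delta_freq = numeric(), stringsAsFactors = FALSE))
  agg <- function(v) tapply(v, r$gene_id, mean)
  mb <- agg(r$delta_bias)
  data.frame(gene_id = names(mb),
             n_delta = as.integer(tapply(r$delta_bias, r$gene_id, length)),
             mean_delta_bias = as.numeric(mb),
             mean_delta_freq = as.numeric(agg(r$delta_freq)),
             stringsAsFactors = FALSE, row.names = NULL)
}
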