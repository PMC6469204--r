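# Comparative statistics between flagged and other genes: pooled 2x2 exact
# tests, per-gene rank-sum comparisons, decile binning of delta metrics,
# nonsense positional bias, and stratified controls.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value sums the point probabilities of all tables (under
#' the conditional hypergeometric distribution with fixed margins) no more
#' probable than the observed one. The odds ratio is the sample
#' cross-product by default; the conditional maximum-likelihood estimate is
#' available via `or = "cmle"`.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param or `"sample"` (ad/bc) or `"cmle"`.
#' @return list with `table`, `odds_ratio`, `p_value`, and `p_lower` (the
#'   largest achievable p-value strictly below `p_value`; 0 when none).
#'   `p_lower` supports calibration checks: under the null,
#'   `p_lower + U * (p_value - p_lower)` with `U ~ Unif(0,1)` is exactly
#'   uniform, which removes the inherent super-uniformity of discrete exact
#'   tests.
#' @export
fisher_exact_2x2 <- function(tab, or = c("sample", "cmle")) {
  or <- match.arg(or)
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  in_tail <- probs <= p_obs * (1 + 1e-7)
  p <- min(1, sum(probs[in_tail]))
  p_lower <- min(1, sum(probs[probs < p_obs / (1 + 1e-7)]))
  oddsr <- if (or == "sample") {
    if (b * c_ == 0) {
      if (a * d == 0) NA_real_ else Inf
    } else (a * d) / (b * c_)
  } else unname(stats::fisher.test(tab)$estimate)
  list(table = tab, odds_ratio = oddsr, p_value = p, p_lower = p_lower)
}

#' Wilcoxon rank-sum comparison
#'
#' Exact enumeration for small untied samples (both groups at most 50,
#' no ties), otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric samples.
#' @return list with `n`, `median_x`, `median_y`, `p_value`, `statistic`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    return(list(n = c(length(x), length(y)), median_x = NA_real_,
                median_y = NA_real_, p_value = NA_real_,
                statistic = NA_real_))
  exact <- max(length(x), length(y)) <= 50 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(n = c(length(x), length(y)),
       median_x = stats::median(x), median_y = stats::median(y),
       p_value = wt$p.value, statistic = unname(wt$statistic))
}

#' Per-gene and pooled nonsynonymous/synonymous ratios
#'
#' @param summaries data frame of per-gene SNP summaries (see
#'   [gene_snp_summaries()]): needs `gene_id`, `is_flagged`, `n_nsy`,
#'   `n_syn`.
#' @return list: `per_gene` (ratios for genes with at least one synonymous
#'   SNP), `n_excluded_zero_syn`, `pooled` (class sums and ratios), `table`
#'   (2x2 of pooled nsy/syn counts, flagged row first), `odds_ratio`,
#'   `fisher_p`, `ranksum_p` (per-gene ratios flagged vs other).
#' @export
nsy_syn_ratios <- function(summaries) {
  s <- summaries
  usable <- s$n_syn > 0
  per_gene <- data.frame(gene_id = s$gene_id[usable],
                         is_flagged = s$is_flagged[usable],
                         ratio = s$n_nsy[usable] / s$n_syn[usable],
                         stringsAsFactors = FALSE)
  pooled <- data.frame(
    class = c("flagged", "other"),
    n_nsy = c(sum(s$n_nsy[s$is_flagged]), sum(s$n_nsy[!s$is_flagged])),
    n_syn = c(sum(s$n_syn[s$is_flagged]), sum(s$n_syn[!s$is_flagged])),
    stringsAsFactors = FALSE
  )
  pooled$ratio <- ifelse(pooled$n_syn > 0, pooled$n_nsy / pooled$n_syn, NA)
  tab <- matrix(c(pooled$n_nsy[1], pooled$n_syn[1],
                  pooled$n_nsy[2], pooled$n_syn[2]),
                2, 2, byrow = TRUE,
                dimnames = list(c("flagged", "other"), c("nsy", "syn")))
  ft <- fisher_exact_2x2(tab)
  rs <- rank_sum_test(per_gene$ratio[per_gene$is_flagged],
                      per_gene$ratio[!per_gene$is_flagged])
  list(per_gene = per_gene, n_excluded_zero_syn = sum(!usable),
       pooled = pooled, table = tab, odds_ratio = ft$odds_ratio,
       fisher_p = ft$p_value, fisher_p_lower = ft$p_lower,
       ranksum_p = rs$p_value, ranksum = rs)
}

#' Per-gene SNP densities (per Kb) and their class comparison
#'
#' Exonic density is the number of exonic SNPs divided by the mRNA length in
#' Kb; CDS density is the number of CDS SNPs over the CDS length in Kb.
#'
#' @param summaries per-gene summaries with `exonic_snps`, `cds_snps`,
#'   `mrna_length`, `cds_length`, `is_flagged`.
#' @return list: `per_gene` densities and rank-sum comparisons
#'   (`exonic_ranksum`, `cds_ranksum`).
#' @export
density_stats <- function(summaries) {
  s <- summaries[summaries$mrna_length > 0 & summaries$cds_length > 0, ]
  per_gene <- data.frame(
    gene_id = s$gene_id, is_flagged = s$is_flagged,
    exonic_density = s$exonic_snps / (s$mrna_length / 1000),
    cds_density = s$cds_snps / (s$cds_length / 1000),
    stringsAsFactors = FALSE
  )
  list(per_gene = per_gene,
       exonic_ranksum = rank_sum_test(
         per_gene$exonic_density[per_gene$is_flagged],
         per_gene$exonic_density[!per_gene$is_flagged]),
       cds_ranksum = rank_sum_test(
         per_gene$cds_density[per_gene$is_flagged],
         per_gene$cds_density[!per_gene$is_flagged]))
}

#' Conservation comparison at SNP sites
#'
#' For each effect class, compares conservation scores of flagged-gene SNP
#' sites against other-gene sites (rank-sum), and compares the fraction of
#' conserved orthologous sites (reference base identical to the far-outgroup
#' base) by Fisher's exact test.
#'
#' @param ann annotated SNPs (CDS rows with defined effects are used).
#' @param effects effect classes to compare.
#' @return named list per effect class: `scores` (rank-sum result or a skip
#'   reason), `conserved` (2x2 table, odds ratio, p).
#' @export
conservation_compare <- function(ann,
                                 effects = c("nonsynonymous", "synonymous")) {
  out <- list()
  for (e in effects) {
    rows <- ann[!is.na(ann$effect) & ann$effect == e, , drop = FALSE]
    res <- list()
    sc <- rows$cons
    if (all(is.na(sc))) {
      res$scores <- list(skipped = "no conservation scores")
    } else {
      res$scores <- rank_sum_test(sc[rows$is_flagged], sc[!rows$is_flagged])
    }
    has_og <- !is.na(rows$og2)
    if (!any(has_og)) {
      res$conserved <- list(skipped = "no far-outgroup bases")
    } else {
      conserved <- has_og & rows$ref == rows$og2
      tab <- matrix(c(sum(conserved & rows$is_flagged),
                      sum(has_og & !conserved & rows$is_flagged),
                      sum(conserved & !rows$is_flagged),
                      sum(has_og & !conserved & !rows$is_flagged)),
                    2, 2, byrow = TRUE,
                    dimnames = list(c("flagged", "other"),
                                    c("conserved", "not_conserved")))
      ft <- fisher_exact_2x2(tab)
      res$conserved <- list(table = tab, fraction_flagged =
                              tab[1, 1] / sum(tab[1, ]),
                            fraction_other = tab[2, 1] / sum(tab[2, ]),
                            odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                            p_lower = ft$p_lower)
    }
    out[[e]] <- res
  }
  out
}

#' Fractions of directional evolutionary classes per gene set
#'
#' The denominator is all retained CDS SNPs of the gene class.
#'
#' @param ann annotated SNPs.
#' @return list per evolutionary class (`to_outgroup1`, `to_outgroup2`):
#'   fractions, 2x2 table, odds ratio and exact-test p.
#' @export
evo_class_fractions <- function(ann) {
  cds <- ann[ann$category == "cds", , drop = FALSE]
  out <- list()
  for (cl in c("to_outgroup1", "to_outgroup2")) {
    is_cl <- cds$evo_class == cl
    tab <- matrix(c(sum(is_cl & cds$is_flagged),
                    sum(!is_cl & cds$is_flagged),
                    sum(is_cl & !cds$is_flagged),
                    sum(!is_cl & !cds$is_flagged)),
                  2, 2, byrow = TRUE,
                  dimnames = list(c("flagged", "other"), c(cl, "rest")))
    ft <- fisher_exact_2x2(tab)
    out[[cl]] <- list(table = tab,
                      fraction_flagged = tab[1, 1] / sum(tab[1, ]),
                      fraction_other = tab[2, 1] / sum(tab[2, ]),
                      odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                      p_lower = ft$p_lower)
  }
  out
}

#' Decile binning of synonymous sites by a delta metric
#'
#' Records are sorted by increasing delta (ties broken by id for
#' determinism) and split into near-equal bins; each bin reports the
#' fraction of records from flagged genes, and the bin index is correlated
#' (Spearman) with that fraction.
#'
#' @param delta numeric delta values (one per SNP record).
#' @param is_flagged logical flag of the record's gene.
#' @param id optional record ids for deterministic tie-breaking.
#' @param n_bins number of bins (default 10).
#' @return object of class `bin_table`: data frame with `bin`, `delta_min`,
#'   `delta_max`, `n_snps`, `n_flagged`, `fraction_flagged`; attributes
#'   `rho`, `p_value` (NA with attribute `rho_reason` when the fractions
#'   are constant).
#' @export
decile_bin_fraction <- function(delta, is_flagged, id = NULL, n_bins = 10) {
  keep <- !is.na(delta)
  delta <- delta[keep]; is_flagged <- is_flagged[keep]
  if (!is.null(id)) id <- id[keep]
  n <- length(delta)
  if (n < n_bins)
    stop("fewer records (", n, ") than bins (", n_bins,
         "); reduce n_bins", call. = FALSE)
  ord <- if (is.null(id)) order(delta) else order(delta, id)
  delta <- delta[ord]; is_flagged <- is_flagged[ord]
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- rep(seq_len(n_bins), times = sizes)
  tab <- data.frame(
    bin = seq_len(n_bins),
    delta_min = tapply(delta, bin, min),
    delta_max = tapply(delta, bin, max),
    n_snps = as.integer(tapply(delta, bin, length)),
    n_flagged = as.integer(tapply(is_flagged, bin, sum)),
    row.names = NULL
  )
  tab$fraction_flagged <- tab$n_flagged / tab$n_snps
  rho <- NA_real_; p <- NA_real_; reason <- NA_character_
  if (stats::sd(tab$fraction_flagged) == 0) {
    reason <- "constant fractions"
  } else {
    ct <- suppressWarnings(stats::cor.test(tab$bin, tab$fraction_flagged,
                                           method = "spearman",
                                           exact = n_bins <= 9))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  structure(tab, class = c("bin_table", "data.frame"),
            rho = rho, p_value = p, rho_reason = reason)
}

#' Nonsense positional bias and nonsense-derived ratio tests
#'
#' Compares the relative CDS positions of nonsense SNPs (and of stops
#' created by two mutations in one codon) between flagged and other genes,
#' and tests pooled nonsense/synonymous and double-mutation/synonymous
#' ratios by Fisher's exact test.
#'
#' @param ann annotated SNPs.
#' @param doubles a [pair_double_mutations()] result (optional).
#' @return list: `position` (rank-sum on single-SNP nonsense positions),
#'   `double_position` (rank-sum on combined-stop positions),
#'   `nonsense_syn` and `double_syn` (each: 2x2 table, odds ratio, p).
#' @export
nonsense_position_stats <- function(ann, doubles = NULL) {
  eff <- ann[!is.na(ann$effect), , drop = FALSE]
  non <- eff[eff$effect == "nonsense", , drop = FALSE]
  syn_f <- sum(eff$effect == "synonymous" & eff$is_flagged)
  syn_o <- sum(eff$effect == "synonymous" & !eff$is_flagged)
  out <- list()
  out$position <- if (sum(non$is_flagged) == 0 || sum(!non$is_flagged) == 0)
    list(skipped = "a class has no nonsense SNPs")
  else rank_sum_test(non$relative_cds_position[non$is_flagged],
                     non$relative_cds_position[!non$is_flagged])
  tab <- matrix(c(sum(non$is_flagged), syn_f,
                  sum(!non$is_flagged), syn_o), 2, 2, byrow = TRUE,
                dimnames = list(c("flagged", "other"),
                                c("nonsense", "syn")))
  ft <- fisher_exact_2x2(tab)
  out$nonsense_syn <- list(table = tab, odds_ratio = ft$odds_ratio,
                           p_value = ft$p_value, p_lower = ft$p_lower)
  if (!is.null(doubles) && nrow(doubles) > 0) {
    dd <- doubles[doubles$distinct_combined, , drop = FALSE]
    dn <- dd[dd$combined_is_nonsense, , drop = FALSE]
    out$double_position <-
      if (sum(dn$is_flagged) == 0 || sum(!dn$is_flagged) == 0)
        list(skipped = "a class has no double-mutation stops")
      else rank_sum_test(dn$relative_cds_position[dn$is_flagged],
                         dn$relative_cds_position[!dn$is_flagged])
    tab2 <- matrix(c(sum(dd$is_flagged), syn_f,
                     sum(!dd$is_flagged), syn_o), 2, 2, byrow = TRUE,
                   dimnames = list(c("flagged", "other"),
                                   c("double_distinct", "syn")))
    ft2 <- fisher_exact_2x2(tab2)
    out$double_syn <- list(table = tab2, odds_ratio = ft2$odds_ratio,
                           p_value = ft2$p_value, p_lower = ft2$p_lower,
                           n_distinct = nrow(dd),
                           n_combined_nonsense = nrow(dn),
                           fraction_nonsense =
                             if (nrow(dd) > 0) nrow(dn) / nrow(dd) else NA)
  }
  out
}

#' Stratified control panels (expression and GC content)
#'
#' Re-runs the headline comparisons inside strata chosen to control
#' confounders: highly expressed genes (read count above a threshold) and
#' the top and bottom GC-content quantiles.
#'
#' @param summaries per-gene summaries with `read_count` and `gc_content`.
#' @param ann annotated SNPs.
#' @param delta_records synonymous delta records (`gene_id`, `delta_bias`,
#'   `is_flagged`, `snp_id`, `ok`, `effect`) for the bin panel.
#' @param expression_threshold genes with `read_count` strictly above this
#'   enter the expression stratum (default 100).
#' @param gc_quantile width of the GC strata (default 0.2: top and bottom
#'   20%).
#' @param n_bins bins for the delta panel.
#' @return named list of strata (`expression`, `gc_high`, `gc_low`), each
#'   with `genes` (ids), `nsy_syn`, `conservation`, `bins`, or a `skipped`
#'   reason when the stratum holds fewer than 2 flagged genes.
#' @export
stratified_controls <- function(summaries, ann, delta_records = NULL,
                                expression_threshold = 100,
                                gc_quantile = 0.2, n_bins = 10) {
  strata <- list()
  if (!all(is.na(summaries$read_count)))
    strata$expression <-
      summaries$gene_id[!is.na(summaries$read_count) &
                          summaries$read_count > expression_threshold]
  if (!all(is.na(summaries$gc_content))) {
    gc <- summaries$gc_content
    hi <- stats::quantile(gc, 1 - gc_quantile, na.rm = TRUE, names = FALSE)
    lo <- stats::quantile(gc, gc_quantile, na.rm = TRUE, names = FALSE)
    strata$gc_high <- summaries$gene_id[!is.na(gc) & gc >= hi]
    strata$gc_low <- summaries$gene_id[!is.na(gc) & gc <= lo]
  }
  out <- list()
  for (nm in names(strata)) {
    ids <- strata[[nm]]
    s_sub <- summaries[summaries$gene_id %in% ids, , drop = FALSE]
    if (sum(s_sub$is_flagged) < 2) {
      out[[nm]] <- list(skipped = "fewer than 2 flagged genes in stratum",
                        genes = ids)
      next
    }
    a_sub <- ann[!is.na(ann$gene_id) & ann$gene_id %in% ids, , drop = FALSE]
    panel <- list(genes = ids,
                  nsy_syn = nsy_syn_ratios(s_sub),
                  conservation = conservation_compare(a_sub))
    if (!is.null(delta_records)) {
      d_sub <- delta_records[delta_records$gene_id %in% ids &
                               delta_records$ok &
                               delta_records$effect == "synonymous", ,
                             drop = FALSE]
      panel$bins <- if (nrow(d_sub) >= n_bins)
        decile_bin_fraction(d_sub$delta_bias, d_sub$is_flagged,
                            d_sub$snp_id, n_bins)
      else list(skipped = "too few synonymous delta records")
    }
    out[[nm]] <- panel
  }
  out
}

#' Rank flagged genes caught between low nsy/syn and high delta bias
#'
#' Selects flagged genes with at most 2 nonsynonymous and at least 2
#' synonymous SNPs and returns the top `k` by mean delta codon bias.
#'
#' @param summaries per-gene summaries with `n_nsy`, `n_syn`,
#'   `mean_delta_bias`.
#' @param k number of genes to return (default 20).
#' @return data frame of the selected genes, sorted by decreasing
#'   `mean_delta_bias` (ties by `gene_id`).
#' @export
select_dilemma_genes <- function(summaries, k = 20) {
  s <- summaries[summaries$is_flagged & summaries$n_nsy <= 2 &
                   summaries$n_syn >= 2 & !is.na(summaries$mean_delta_bias), ,
                 drop = FALSE]
  s <- s[order(-s$mean_delta_bias, s$gene_id), , drop = FALSE]
  out <- utils::head(s[, c("gene_id", "n_nsy", "n_syn", "mean_delta_bias",
                           "mean_delta_freq")], k)
  rownames(out) <- NULL
  out
}

#' Per-gene SNP summaries feeding the comparative statistics
#'
#' @param ann annotated SNPs.
#' @param models a [gene_models()] object.
#' @param mean_deltas optional [gene_mean_delta()] result.
#' @param read_counts optional named numeric vector of per-gene read counts.
#' @param gc_content optional named numeric vector (see [cds_gc_content()]).
#' @param doubles optional [pair_double_mutations()] result.
#' @return data frame with one row per coding gene: `gene_id`,
#'   `is_flagged`, `n_nsy`, `n_syn`, `n_nonsense`, `n_double_distinct`,
#'   `cds_length`, `mrna_length`, `exonic_snps`, `cds_snps`, `gc_content`,
#'   `read_count`, `mean_delta_bias`, `mean_delta_freq`.
#' @export
gene_snp_summaries <- function(ann, models, mean_deltas = NULL,
                               read_counts = NULL, gc_content = NULL,
                               doubles = NULL) {
  g <- models$genes[models$genes$cds_length > 0, , drop = FALSE]
  cnt <- function(cond) {
    v <- table(factor(ann$gene_id[cond], levels = g$gene_id))
    as.integer(v)
  }
  eff <- !is.na(ann$effect)
  out <- data.frame(
    gene_id = g$gene_id, is_flagged = g$is_flagged,
    n_nsy = cnt(eff & ann$effect == "nonsynonymous"),
    n_syn = cnt(eff & ann$effect == "synonymous"),
    n_nonsense = cnt(eff & ann$effect == "nonsense"),
    n_double_distinct = 0L,
    cds_length = g$cds_length, mrna_length = g$mrna_length,
    exonic_snps = cnt(ann$category %in% c("cds", "utr", "noncoding_other")),
    cds_snps = cnt(ann$category == "cds"),
    stringsAsFactors = FALSE
  )
  if (!is.null(doubles) && nrow(doubles) > 0) {
    dt <- table(factor(doubles$gene_id[doubles$distinct_combined],
                       levels = g$gene_id))
    out$n_double_distinct <- as.integer(dt)
  }
  out$gc_content <- if (is.null(gc_content)) NA_real_ else
    unname(gc_content[out$gene_id])
  out$read_count <- if (is.null(read_counts)) NA_real_ else
    unname(read_counts[out$gene_id])
  out$mean_delta_bias <- NA_real_
  out$mean_delta_freq <- NA_real_
  if (!is.null(mean_deltas) && nrow(mean_deltas) > 0) {
    i <- match(out$gene_id, mean_deltas$gene_id)
    out$mean_delta_bias <- mean_deltas$mean_delta_bias[i]
    out$mean_delta_freq <- mean_deltas$mean_delta_freq[i]
  }
  out
}
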