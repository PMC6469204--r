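# End-to-end analysis: filter funnel, annotation, codon usage bias, delta
# metrics, and all comparative panels assembled into one report object.

#' Run the full comparative analysis on in-memory inputs
#'
#' Applies the ancestral and uni-mutation filters, annotates the retained
#' SNPs, computes codon-usage-bias metrics and synonymous deltas, and
#' assembles every comparative panel (ratios, densities, conservation,
#' evolutionary classes, delta bins, nonsense positions, stratified
#' controls, dilemma genes) into a `selection_report`.
#'
#' @param snps data frame of SNP records (`snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`, optional `og1`, `og2`, `cons`); `alt` may be comma-separated.
#' @param models a [gene_models()] object (canonical transcripts, flags
#'   set).
#' @param genome named character vector of chromosome sequences.
#' @param read_counts optional named per-gene read counts.
#' @param splice_window splice-region window in nt (default 3).
#' @param at3_content intronic A/T content (default 0.59).
#' @param chi2_mode `"gof"` or `"r2x2"` (see [family_chi_square()]).
#' @param n_bins bins for the delta panels (default 10).
#' @param expression_threshold,gc_quantile stratified-control settings.
#' @param freq_kind delta-frequency flavour (see [delta_for_snp()]).
#' @param delta_scope scope of the per-gene mean delta (see
#'   [gene_mean_delta()]).
#' @return object of class `selection_report`.
#' @export
analyze_snps <- function(snps, models, genome, read_counts = NULL,
                         splice_window = 3L, at3_content = 0.59,
                         chi2_mode = c("gof", "r2x2"), n_bins = 10,
                         expression_threshold = 100, gc_quantile = 0.2,
                         freq_kind = c("family", "global"),
                         delta_scope = c("synonymous", "all")) {
  chi2_mode <- match.arg(chi2_mode)
  freq_kind <- match.arg(freq_kind)
  delta_scope <- match.arg(delta_scope)
  n_input <- nrow(snps)
  anc <- filter_ancestral(snps)
  uni <- filter_uni_mutation(snps)
  kept <- snps[anc & uni, , drop = FALSE]
  kept$alt <- vapply(strsplit(kept$alt, ",", fixed = TRUE), `[`, "", 1)
  ann <- annotate_snps(kept, models, genome, splice_window)
  funnel <- data.frame(
    stage = c("input", "dropped_non_ancestral", "dropped_multi_mutation",
              "dropped_ref_mismatch", "retained"),
    n = c(n_input, sum(!anc), sum(anc & !uni),
          attr(ann, "n_ref_mismatch"),
          n_input - sum(!anc) - sum(anc & !uni) -
            attr(ann, "n_ref_mismatch")),
    stringsAsFactors = FALSE
  )
  spectrum <- mutation_spectrum(kept[!duplicated(kept$snp_id), ])
  # codon usage bias
  counts <- gene_codon_counts(cds_sequences(models, genome))
  profile <- gene_scaled_chi2(counts, at3_content, chi2_mode)
  pref <- codon_preference(counts, profile, at3_content, chi2_mode)
  # delta records for CDS SNPs with defined effect
  crow <- ann[!is.na(ann$effect), , drop = FALSE]
  deltas <- cbind(
    data.frame(snp_id = crow$snp_id, gene_id = crow$gene_id,
               is_flagged = crow$is_flagged, effect = crow$effect,
               stringsAsFactors = FALSE),
    delta_for_snp(crow$ref_codon, crow$alt_codon, pref, freq_kind))
  mean_deltas <- gene_mean_delta(deltas, delta_scope)
  doubles <- pair_double_mutations(ann)
  summaries <- gene_snp_summaries(
    ann, models, mean_deltas, read_counts,
    cds_gc_content(models, genome), doubles)
  syn_deltas <- deltas[deltas$ok & deltas$effect == "synonymous", ,
                       drop = FALSE]
  bins_bias <- bins_freq <- NULL
  if (nrow(syn_deltas) >= n_bins) {
    bins_bias <- decile_bin_fraction(syn_deltas$delta_bias,
                                     syn_deltas$is_flagged,
                                     syn_deltas$snp_id, n_bins)
    bins_freq <- decile_bin_fraction(syn_deltas$delta_freq,
                                     syn_deltas$is_flagged,
                                     syn_deltas$snp_id, n_bins)
  }
  category_counts <- local({
    cat_tab <- table(ifelse(ann$is_flagged, "flagged", "other"),
                     ann$category)
    as.data.frame.matrix(cat_tab)
  })
  no_flag <- sum(models$genes$is_flagged) == 0
  report <- list(
    funnel = funnel,
    spectrum = spectrum,
    category_counts = category_counts,
    annotated = ann,
    cub = list(counts = counts, profile = profile, preference = pref),
    deltas = deltas,
    doubles = doubles,
    summaries = summaries,
    panels = if (no_flag) list(
      skipped = "empty flagged gene set: class comparisons not possible")
    else list(
      nsy_syn = nsy_syn_ratios(summaries),
      density = density_stats(summaries),
      conservation = conservation_compare(ann),
      evo = evo_class_fractions(ann),
      bins_bias = bins_bias,
      bins_freq = bins_freq,
      nonsense = nonsense_position_stats(ann, doubles),
      strata = stratified_controls(summaries, ann, deltas,
                                   expression_threshold, gc_quantile,
                                   n_bins),
      dilemma = select_dilemma_genes(summaries)
    ),
    settings = list(splice_window = splice_window,
                    at3_content = at3_content, chi2_mode = chi2_mode,
                    n_bins = n_bins,
                    expression_threshold = expression_threshold,
                    gc_quantile = gc_quantile, freq_kind = freq_kind,
                    delta_scope = delta_scope)
  )
  class(report) <- "selection_report"
  report
}

#' @export
print.selection_report <- function(x, ...) {
  f <- x$funnel
  cat("selection_report\n")
  cat("  funnel:", paste(f$stage, f$n, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$panels$skipped)) {
    cat("  panels skipped:", x$panels$skipped, "\n")
    return(invisible(x))
  }
  p <- x$panels$nsy_syn
  cat(sprintf("  pooled nsy/syn: flagged %.3f vs other %.3f (OR %.3f, Fisher p %.3g)\n",
              p$pooled$ratio[1], p$pooled$ratio[2], p$odds_ratio,
              p$fisher_p))
  if (!is.null(x$panels$bins_bias))
    cat(sprintf("  delta-bias bins: Spearman rho %.3f (p %.3g)\n",
                attr(x$panels$bins_bias, "rho"),
                attr(x$panels$bins_bias, "p_value")))
  nn <- x$panels$nonsense
  cat(sprintf("  nonsense/syn OR %.3f (p %.3g)\n",
              nn$nonsense_syn$odds_ratio, nn$nonsense_syn$p_value))
  invisible(x)
}

#' @export
summary.selection_report <- function(object, ...) {
  print(object)
  cat("\nCategory counts (rows: gene class):\n")
  print(object$category_counts)
  invisible(object)
}

#' Configuration for a file-based pipeline run
#'
#' @param genome,gene_models,snps,flagged paths to the genome FASTA, GFF3
#'   gene models, VCF SNPs and flagged-gene list.
#' @param orthologs,conservation,read_counts optional sidecar paths.
#' @param out_dir optional output directory for the report and panels.
#' @param ... analysis settings passed to [analyze_snps()].
#' @return validated list of class `run_config`.
#' @export
run_config <- function(genome, gene_models, snps, flagged,
                       orthologs = NULL, conservation = NULL,
                       read_counts = NULL, out_dir = NULL, ...) {
  cfg <- list(genome = genome, gene_models = gene_models, snps = snps,
              flagged = flagged, orthologs = orthologs,
              conservation = conservation, read_counts = read_counts,
              out_dir = out_dir, settings = list(...))
  for (nm in c("genome", "gene_models", "snps", "flagged")) {
    if (!file.exists(cfg[[nm]]))
      stop("input file missing for '", nm, "': ", cfg[[nm]], call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the pipeline from files
#'
#' Reads every input, checks genome/VCF contig consistency, runs
#' [analyze_snps()] and (when `out_dir` is set) writes the JSON report and
#' the TSV panels.
#'
#' @param config a [run_config()].
#' @return the `selection_report`, invisibly when writing to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  genome <- read_genome_fasta(config$genome)
  flagged <- read_flagged_genes(config$flagged)
  models <- read_gene_models_gff3(config$gene_models, flagged)
  snps <- read_snps_vcf(config$snps, config$orthologs, config$conservation)
  bad_contig <- setdiff(unique(snps$chrom), names(genome))
  if (length(bad_contig))
    stop("VCF contigs absent from the genome: ",
         paste(bad_contig, collapse = ", "), call. = FALSE)
  rc <- if (is.null(config$read_counts)) NULL else
    read_counts_tsv(config$read_counts)
  report <- do.call(analyze_snps,
                    c(list(snps = snps, models = models, genome = genome,
                           read_counts = rc), config$settings))
  report$funnel$n[report$funnel$stage == "input"] <-
    nrow(snps) + attr(snps, "n_dropped_non_snv")
  report$funnel <- rbind(
    data.frame(stage = "dropped_non_snv",
               n = attr(snps, "n_dropped_non_snv")),
    report$funnel)
  report$funnel <- report$funnel[match(
    c("input", "dropped_non_snv", "dropped_non_ancestral",
      "dropped_multi_mutation", "dropped_ref_mismatch", "retained"),
    report$funnel$stage), ]
  rownames(report$funnel) <- NULL
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
    # echo the resolved configuration next to the outputs
    cfg <- config
    class(cfg) <- NULL
    cfg$settings <- report$settings
    yaml::write_yaml(cfg, file.path(config$out_dir, "run_config.yaml"))
    return(invisible(report))
  }
  report
}

.write_tsv <- function(x, path)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Write the report JSON and the per-figure TSV panels
#'
#' @param report a `selection_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  .write_tsv(report$funnel, fp("funnel.tsv"))
  .write_tsv(data.frame(type = names(report$spectrum),
                        n = as.integer(report$spectrum)),
             fp("mutation_spectrum.tsv"))
  cc <- report$category_counts
  heat <- log2(as.matrix(cc) + 1)
  .write_tsv(cbind(class = rownames(cc), as.data.frame(heat)),
             fp("category_counts_log2.tsv"))
  .write_tsv(report$cub$preference, fp("codon_preference.tsv"))
  gm <- merge(report$cub$profile$genes,
              report$summaries[, c("gene_id", "mean_delta_bias",
                                   "mean_delta_freq")],
              by = "gene_id", all.x = TRUE)
  .write_tsv(gm, fp("gene_cub.tsv"))
  .write_tsv(as.data.frame(report$annotated), fp("annotated_snps.tsv"))
  p <- report$panels
  json <- list(funnel = report$funnel, settings = report$settings)
  if (is.null(p$skipped)) {
    .write_tsv(data.frame(
      class = c("to_outgroup1_flagged", "to_outgroup1_other",
                "to_outgroup2_flagged", "to_outgroup2_other"),
      fraction = c(p$evo$to_outgroup1$fraction_flagged,
                   p$evo$to_outgroup1$fraction_other,
                   p$evo$to_outgroup2$fraction_flagged,
                   p$evo$to_outgroup2$fraction_other)),
      fp("fig2_fractions.tsv"))
    .write_tsv(p$nsy_syn$per_gene, fp("fig3_ratios.tsv"))
    if (!is.null(p$bins_bias))
      .write_tsv(as.data.frame(p$bins_bias), fp("fig4_bins.tsv"))
    .write_tsv(data.frame(
      panel = c("nonsense_syn_or", "nonsense_syn_p", "double_syn_or",
                "double_syn_p"),
      value = c(p$nonsense$nonsense_syn$odds_ratio,
                p$nonsense$nonsense_syn$p_value,
                if (is.null(p$nonsense$double_syn)) c(NA, NA) else
                  c(p$nonsense$double_syn$odds_ratio,
                    p$nonsense$double_syn$p_value))),
      fp("fig5_nonsense.tsv"))
    .write_tsv(p$density$per_gene, fp("s1_density.tsv"))
    .write_tsv(p$dilemma, fp("s2_dilemma.tsv"))
    for (nm in names(p$strata)) {
      st <- p$strata[[nm]]
      f <- fp(paste0("strata_", nm, ".tsv"))
      if (!is.null(st$skipped)) {
        .write_tsv(data.frame(skipped = st$skipped), f)
      } else {
        .write_tsv(data.frame(
          metric = c("pooled_or", "fisher_p", "ranksum_p"),
          value = c(st$nsy_syn$odds_ratio, st$nsy_syn$fisher_p,
                    st$nsy_syn$ranksum_p)), f)
      }
    }
    raw_p <- c(
      nsy_syn_fisher = p$nsy_syn$fisher_p,
      nsy_syn_ranksum = p$nsy_syn$ranksum_p,
      cons_scores_nsy = p$conservation$nonsynonymous$scores$p_value,
      cons_scores_syn = p$conservation$synonymous$scores$p_value,
      conserved_fraction_nsy = p$conservation$nonsynonymous$conserved$p_value,
      conserved_fraction_syn = p$conservation$synonymous$conserved$p_value,
      evo_to_outgroup1 = p$evo$to_outgroup1$p_value,
      evo_to_outgroup2 = p$evo$to_outgroup2$p_value,
      bins_bias = if (!is.null(p$bins_bias)) attr(p$bins_bias, "p_value")
        else NA,
      bins_freq = if (!is.null(p$bins_freq)) attr(p$bins_freq, "p_value")
        else NA,
      nonsense_syn = p$nonsense$nonsense_syn$p_value,
      nonsense_position = if (is.null(p$nonsense$position$skipped))
        p$nonsense$position$p_value else NA,
      double_syn = if (!is.null(p$nonsense$double_syn))
        p$nonsense$double_syn$p_value else NA)
    # supplementary multiple-testing column; the headline panels report
    # raw p-values only
    json$supplementary_bh_adjusted_p <-
      as.list(stats::p.adjust(raw_p, method = "BH"))
    json$headline <- list(
      pooled_nsy_syn = p$nsy_syn$pooled,
      odds_ratio = p$nsy_syn$odds_ratio,
      fisher_p = p$nsy_syn$fisher_p,
      ranksum_p = p$nsy_syn$ranksum_p,
      bins_bias_rho = if (!is.null(p$bins_bias))
        attr(p$bins_bias, "rho") else NA,
      nonsense_syn = p$nonsense$nonsense_syn[c("odds_ratio", "p_value")],
      double_syn = if (!is.null(p$nonsense$double_syn))
        p$nonsense$double_syn[c("odds_ratio", "p_value",
                                "fraction_nonsense")] else NULL)
  } else {
    json$skipped <- p$skipped
  }
  jsonlite::write_json(json, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(dir)
}
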