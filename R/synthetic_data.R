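# Synthetic genomes, gene models, outgroup orthologs, conservation scores,
# read counts and SNPs with ground truth. The generator is an inverse model
# of the analysis: a single ancestor sequence is evolved to the focal
# species and two outgroups, candidate SNVs are proposed with a transition
# excess, and acceptance probabilities depend on the true mutation effect,
# the gene's flag status, the codon-frequency delta of synonymous changes,
# and the relative CDS position of nonsense changes.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is meant to detect: a
#' fifth of the genes flagged, purifying selection on nonsynonymous and
#' nonsense changes concentrated in flagged genes, synonymous changes in
#' flagged genes biased toward more frequent codons, nonsense changes in
#' flagged genes biased toward the 3' end of the CDS, and conservation
#' scores elevated in flagged-gene coding regions.
#'
#' @param seed integer; the single source of randomness.
#' @param n_genes,fraction_flagged gene count and flagged share.
#' @param n_codons_meanlog,n_codons_sdlog,n_codons_range lognormal codon
#'   count per CDS (initiator and stop included), clamped to the range.
#' @param exons_per_gene_lambda exons per gene = 1 + Poisson(lambda), capped
#'   at `max_exons`.
#' @param max_exons cap on exons per gene.
#' @param utr5_range,utr3_range,intron_range,intergenic_range uniform length
#'   ranges (nt).
#' @param intronic_at_content A/T proportion of noncoding sequence (0.59,
#'   the human intronic value).
#' @param cds_gc3_mean population-average G/C share at codon position 3 of
#'   coding sequence (0.55: coding third positions are G/C-richer than
#'   introns, which makes preferred codons also the frequent ones within
#'   their family, as observed in real genomes).
#' @param expression_gc3_coupling strength of the link between a gene's
#'   expression rank and its third-position G/C share; positive coupling
#'   makes G/C-ending codons preferred in highly expressed genes, which is
#'   what the codon-preference rho recovers.
#' @param read_count_meanlog,read_count_sdlog lognormal read counts tied to
#'   the same expression latent.
#' @param divergence per-branch substitution probabilities from the common
#'   ancestor (focal species, near outgroup, far outgroup); each < 0.5.
#' @param transition_transversion_kappa weight of the transition relative to
#'   either transversion, used for both divergence and SNP proposal.
#' @param acceptance per-class acceptance probabilities, each a
#'   `c(flagged=, other=)` pair, for classes `synonymous`, `nonsynonymous`,
#'   `nonsense`, `noncoding`.
#' @param syn_preference_beta logistic weight on the within-family
#'   codon-frequency delta of synonymous candidates, per flag status.
#' @param nonsense_position_gamma exponent on the relative CDS position of
#'   nonsense candidates, per flag status (gamma >= 0).
#' @param conservation_mean,conservation_sd normal score parameters per
#'   (region x flag status): names `cds_flagged`, `cds_other`,
#'   `noncoding_flagged`, `noncoding_other`.
#' @param n_snps_target number of SNPs to emit.
#' @param multi_mutation_rate probability that an emitted record carries a
#'   second alternative allele (removed downstream by the uni-mutation
#'   filter).
#' @param max_batches proposal batches before giving up with a warning.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 500L,
                       fraction_flagged = 0.2,
                       n_codons_meanlog = log(300),
                       n_codons_sdlog = 0.35,
                       n_codons_range = c(60L, 1500L),
                       exons_per_gene_lambda = 2,
                       max_exons = 8L,
                       utr5_range = c(50L, 150L),
                       utr3_range = c(100L, 300L),
                       intron_range = c(80L, 400L),
                       intergenic_range = c(300L, 800L),
                       intronic_at_content = 0.59,
                       cds_gc3_mean = 0.55,
                       expression_gc3_coupling = 1.5,
                       read_count_meanlog = 3.5,
                       read_count_sdlog = 1.5,
                       divergence = c(human = 0.01, outgroup1 = 0.03,
                                      outgroup2 = 0.15),
                       transition_transversion_kappa = 3,
                       acceptance = list(
                         synonymous = c(flagged = 1, other = 1),
                         nonsynonymous = c(flagged = 0.35, other = 0.7),
                         nonsense = c(flagged = 0.1, other = 0.3),
                         noncoding = c(flagged = 1, other = 1)),
                       syn_preference_beta = c(flagged = 8, other = 0),
                       nonsense_position_gamma = c(flagged = 2, other = 0.5),
                       conservation_mean = c(cds_flagged = 2, cds_other = 1,
                                             noncoding_flagged = 0.5,
                                             noncoding_other = 0.2),
                       conservation_sd = 1,
                       n_snps_target = 10000L,
                       multi_mutation_rate = 0.1,
                       max_batches = 30L) {
  cfg <- as.list(environment())
  stopifnot(fraction_flagged >= 0, fraction_flagged <= 1,
            intronic_at_content > 0, intronic_at_content < 1,
            cds_gc3_mean > 0, cds_gc3_mean < 1,
            all(divergence >= 0), all(divergence < 0.5),
            transition_transversion_kappa > 0,
            all(unlist(acceptance) >= 0), all(unlist(acceptance) <= 1),
            all(nonsense_position_gamma >= 0),
            multi_mutation_rate >= 0, multi_mutation_rate <= 1,
            n_genes >= 2, n_snps_target >= 1)
  for (nm in c("synonymous", "nonsynonymous", "nonsense", "noncoding"))
    stopifnot(all(c("flagged", "other") %in% names(acceptance[[nm]])))
  if (cfg$n_codons_range[1] < 10)
    stop("minimum CDS of 10 codons required", call. = FALSE)
  if (min(utr5_range) < 10 || min(intron_range) < 20)
    stop("UTR/intron minimum lengths too small for exon construction",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

# noncoding bases at the configured A/T content
.rand_bases <- function(n, at) {
  sample(.nucs, n, replace = TRUE,
         prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2))
}

# mutate a base vector: per-site Bernoulli(p), transition weighted kappa : 1 : 1
.evolve <- function(bases, p, kappa) {
  if (p <= 0) return(bases)
  n_hit <- stats::rbinom(1L, length(bases), p)
  if (n_hit == 0) return(bases)
  hit <- sample.int(length(bases), n_hit)
  old <- bases[hit]
  r <- stats::runif(length(hit)) * (kappa + 2)
  ts <- chartr("ACGT", "GTAC", old)   # transitions: A<->G, C<->T
  tv1 <- chartr("ACGT", "CACA", old)  # one transversion per base
  tv2 <- chartr("ACGT", "TGTG", old)  # the other transversion
  new <- ifelse(r < kappa, ts, ifelse(r < kappa + 1, tv1, tv2))
  bases[hit] <- new
  bases
}

# sample internal codons for all genes at once, with per-gene GC3 propensity
.sample_codons <- function(gene_of, p_gc3) {
  fam_aa <- split(names(.codon_table), unname(.codon_table))
  fam_aa[["*"]] <- NULL
  aas <- names(fam_aa)
  at_set <- lapply(fam_aa, function(cs) cs[substr(cs, 3, 3) %in% c("A", "T")])
  gc_set <- lapply(fam_aa, function(cs) cs[substr(cs, 3, 3) %in% c("G", "C")])
  n <- length(gene_of)
  aa <- sample(aas, n, replace = TRUE)
  want_gc <- stats::runif(n) < p_gc3[gene_of]
  # fall back to the other ending set when the chosen one is empty
  use_gc <- ifelse(want_gc, lengths(gc_set)[aa] > 0, lengths(at_set)[aa] == 0)
  codon <- character(n)
  for (a in aas) {
    for (gcflag in c(TRUE, FALSE)) {
      set <- if (gcflag) gc_set[[a]] else at_set[[a]]
      idx <- which(aa == a & use_gc == gcflag)
      if (length(idx) == 0) next
      codon[idx] <- set[ceiling(stats::runif(length(idx)) * length(set))]
    }
  }
  codon
}

.runif_int <- function(n, range) {
  as.integer(range[1] + floor(stats::runif(n) * (range[2] - range[1] + 1)))
}

#' Simulate a multi-gene genome with outgroups and gene-level covariates
#'
#' Builds an ancestral chromosome of intron-containing genes whose
#' third-position G/C usage is coupled to a simulated expression level, then
#' evolves it independently to the focal species and two outgroups. The
#' focal CDSs are repaired to keep the initiator, the terminal stop and no
#' in-frame stops.
#'
#' @param config a [sim_config()].
#' @return object of class `codonsel_sim`: list with `genome` (named string,
#'   the focal species), `models` ([gene_models()]), `og1`, `og2` (outgroup
#'   base vectors along the chromosome), `ancestor` (base vector),
#'   `read_counts`, `expression_z`, `flagged` (gene ids), `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  n <- cfg$n_genes
  gene_id <- sprintf("g%04d", seq_len(n))
  flagged <- sort(sample(n, round(cfg$fraction_flagged * n)))
  is_flagged <- seq_len(n) %in% flagged
  z <- stats::rnorm(n)
  read_counts <- round(exp(cfg$read_count_meanlog +
                             cfg$read_count_sdlog * z))
  n_codons <- pmin(pmax(round(stats::rlnorm(n, cfg$n_codons_meanlog,
                                            cfg$n_codons_sdlog)),
                        cfg$n_codons_range[1]), cfg$n_codons_range[2])
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_exons <- pmin(1L + stats::rpois(n, cfg$exons_per_gene_lambda),
                  cfg$max_exons)
  p_gc3 <- stats::plogis(stats::qlogis(cfg$cds_gc3_mean) +
                           cfg$expression_gc3_coupling * z)
  # ancestral internal codons for all genes at once
  n_internal <- n_codons - 2L
  gene_of <- rep(seq_len(n), n_internal)
  internal <- .sample_codons(gene_of, p_gc3)
  stops <- sample(c("TAA", "TAG", "TGA"), n, replace = TRUE)
  cds_str <- vapply(split(internal, factor(gene_of, seq_len(n))), paste0,
                    character(1), collapse = "")
  cds_str <- paste0("ATG", cds_str, stops)
  utr5_len <- .runif_int(n, cfg$utr5_range)
  utr3_len <- .runif_int(n, cfg$utr3_range)
  gaps <- .runif_int(n + 1L, cfg$intergenic_range)
  at <- cfg$intronic_at_content
  pieces <- vector("list", 2L * n + 1L)   # alternating gap, gene, gap, ...
  ex_gene <- ex_start <- ex_end <- vector("list", n)
  cd_gene <- cd_start <- cd_end <- vector("list", n)
  offset <- 0L
  pieces[[1]] <- .rand_bases(gaps[1], at)
  offset <- gaps[1]
  for (i in seq_len(n)) {
    cds_len <- 3L * n_codons[i]
    mrna_len <- utr5_len[i] + cds_len + utr3_len[i]
    k <- n_exons[i]
    # exon lengths along the mRNA: each at least half the equal share
    w <- stats::rexp(k)
    prop <- 0.5 / k + 0.5 * w / sum(w)
    bnd <- round(cumsum(prop) * mrna_len)
    bnd[k] <- mrna_len
    ex_m_end <- bnd
    ex_m_start <- c(1L, utils::head(bnd, -1) + 1L)
    intron_len <- if (k > 1) .runif_int(k - 1L, cfg$intron_range) else integer()
    # local (gene-plus-orientation) genomic coordinates
    shift <- c(0L, cumsum(intron_len))
    ex_l_start <- ex_m_start + shift
    ex_l_end <- ex_m_end + shift
    gene_len <- ex_l_end[k]
    # CDS sub-intervals: mRNA range intersected with exons
    cds_m <- c(utr5_len[i] + 1L, utr5_len[i] + cds_len)
    cs <- pmax(ex_m_start, cds_m[1]); ce <- pmin(ex_m_end, cds_m[2])
    keep <- cs <= ce
    cds_l_start <- cs[keep] + shift[keep]
    cds_l_end <- ce[keep] + shift[keep]
    # assemble the gene's base vector in mRNA orientation with introns
    mrna <- c(.rand_bases(utr5_len[i], at),
              strsplit(cds_str[i], "")[[1]],
              .rand_bases(utr3_len[i], at))
    seg <- vector("list", 2L * k - 1L)
    for (e in seq_len(k)) {
      seg[[2L * e - 1L]] <- mrna[ex_m_start[e]:ex_m_end[e]]
      if (e < k) seg[[2L * e]] <- .rand_bases(intron_len[e], at)
    }
    gene_vec <- unlist(seg, use.names = FALSE)
    if (strand[i] == "-") {
      gene_vec <- rev(chartr("ACGT", "TGCA", gene_vec))
      flip <- function(s, e) list(start = gene_len - e + 1L,
                                  end = gene_len - s + 1L)
      fe <- flip(ex_l_start, ex_l_end)
      ex_l_start <- rev(fe$start); ex_l_end <- rev(fe$end)
      fc <- flip(cds_l_start, cds_l_end)
      cds_l_start <- rev(fc$start); cds_l_end <- rev(fc$end)
    }
    ex_gene[[i]] <- rep(gene_id[i], length(ex_l_start))
    ex_start[[i]] <- offset + ex_l_start
    ex_end[[i]] <- offset + ex_l_end
    cd_gene[[i]] <- rep(gene_id[i], length(cds_l_start))
    cd_start[[i]] <- offset + cds_l_start
    cd_end[[i]] <- offset + cds_l_end
    pieces[[2L * i]] <- gene_vec
    pieces[[2L * i + 1L]] <- .rand_bases(gaps[i + 1L], at)
    offset <- offset + gene_len + gaps[i + 1L]
  }
  anc <- unlist(pieces, use.names = FALSE)
  genes <- data.frame(gene_id = gene_id,
                      transcript_id = sub("^g", "t", gene_id),
                      chrom = "chr1", strand = strand,
                      is_flagged = is_flagged, stringsAsFactors = FALSE)
  models <- gene_models(
    genes,
    data.frame(gene_id = unlist(ex_gene), start = unlist(ex_start),
               end = unlist(ex_end), stringsAsFactors = FALSE),
    data.frame(gene_id = unlist(cd_gene), start = unlist(cd_start),
               end = unlist(cd_end), stringsAsFactors = FALSE))
  kappa <- cfg$transition_transversion_kappa
  hum <- .evolve(anc, cfg$divergence[["human"]], kappa)
  og1 <- .evolve(anc, cfg$divergence[["outgroup1"]], kappa)
  og2 <- .evolve(anc, cfg$divergence[["outgroup2"]], kappa)
  hum <- .repair_cds(hum, anc, models)
  sim <- list(genome = c(chr1 = .bases_to_str(hum)),
              models = models, og1 = og1, og2 = og2, ancestor = anc,
              read_counts = stats::setNames(read_counts, gene_id),
              expression_z = stats::setNames(z, gene_id),
              flagged = gene_id[is_flagged], config = cfg)
  class(sim) <- "codonsel_sim"
  sim
}

# keep focal CDSs clean: initiator ATG, terminal stop, no in-frame stops;
# offending codons revert to the ancestral bases (sense by construction)
.repair_cds <- function(hum, anc, models) {
  map <- .cds_position_map(models)
  g <- models$genes
  gi <- match(map$gene_id, g$gene_id)
  ord <- order(gi, map$cds_pos)
  gpos <- map$gpos[ord]
  gi <- gi[ord]
  coding <- hum[gpos]
  minus <- g$strand[gi] == "-"
  coding[minus] <- .complement(coding[minus])
  n3 <- length(coding)
  i1 <- seq(1L, n3, 3L)
  b1 <- coding[i1]; b2 <- coding[i1 + 1L]; b3 <- coding[i1 + 2L]
  is_stop <- b1 == "T" & ((b2 == "A" & (b3 == "A" | b3 == "G")) |
                            (b2 == "G" & b3 == "A"))
  is_atg <- b1 == "A" & b2 == "T" & b3 == "G"
  gene_c <- gi[i1]
  first <- !duplicated(gene_c)
  last <- !duplicated(gene_c, fromLast = TRUE)
  bad <- (first & !is_atg) | (last & !is_stop) | (!first & !last & is_stop)
  if (any(bad)) {
    rows <- as.vector(rbind(i1[bad], i1[bad] + 1L, i1[bad] + 2L))
    hum[gpos[rows]] <- anc[gpos[rows]]
  }
  hum
}

#' @export
print.codonsel_sim <- function(x, ...) {
  cat("codonsel_sim: genome of", nchar(x$genome), "nt,",
      nrow(x$models$genes), "genes (", length(x$flagged), "flagged ), seed",
      x$config$seed, "\n")
  if (!is.null(x$snps))
    cat("  ", nrow(x$snps), "SNPs emitted\n")
  invisible(x)
}

#' Simulate SNPs over a simulated genome
#'
#' Candidate single-nucleotide variants are proposed uniformly along the
#' chromosome with a transition excess, internally annotated for their true
#' effect, and accepted with probability
#' `acceptance[class, flag] * logistic(beta * delta_freq)` (synonymous) or
#' `acceptance[class, flag] * relative_position^gamma` (nonsense). A
#' configured fraction of emitted records carries a second alternative
#' allele to exercise the uni-mutation filter.
#'
#' @param sim a [simulate_genome()] result.
#' @param config optional [sim_config()]; defaults to `sim$config`.
#' @return `sim`, extended with `snps` (data frame: `snp_id`, `chrom`,
#'   `pos`, `ref`, `alt` (comma-separated when multi-allelic), `og1`,
#'   `og2`, `cons`) and `truth` (one row per SNP: true category, gene,
#'   effect, splice flag, relative CDS position, evolutionary class,
#'   acceptance probability used).
#' @export
simulate_snps <- function(sim, config = NULL) {
  stopifnot(inherits(sim, "codonsel_sim"))
  cfg <- if (is.null(config)) sim$config else config
  set.seed(cfg$seed + 1L)
  hum <- .str_to_bases(sim$genome[[1]])
  glen <- length(hum)
  models <- sim$models
  g <- models$genes
  # O(1) per-position region lookup
  region <- integer(glen)               # 0 intergenic 1 intron 2 utr 3 cds
  gene_idx <- integer(glen)
  for (i in seq_len(nrow(g))) {
    ex <- models$exons[models$exons$gene_id == g$gene_id[i], ]
    body <- min(ex$start):max(ex$end)
    region[body] <- 1L; gene_idx[body] <- i
  }
  epos <- .expand_pos(models$exons$start, models$exons$end)
  region[epos] <- 2L
  cmap <- .cds_position_map(models)
  region[cmap$gpos] <- 3L
  cds_pos_of <- integer(glen); cds_pos_of[cmap$gpos] <- cmap$cds_pos
  splice_keys <- .splice_keys(models, 3L)
  cds_seqs <- cds_sequences(models, sim$genome)
  counts <- gene_codon_counts(cds_seqs)
  pref_freq <- local({
    fam <- codon_families()
    pooled <- colSums(counts$counts)
    ff <- stats::setNames(rep(NA_real_, 64), names(.codon_table))
    for (f in unique(fam$family_id)) {
      cods <- fam$codon[fam$family_id == f]
      ff[cods] <- pooled[cods] / sum(pooled[cods])
    }
    ff
  })
  kappa <- cfg$transition_transversion_kappa
  acc <- cfg$acceptance
  flag_of <- c("other", "flagged")
  target <- cfg$n_snps_target
  got_pos <- integer(); got_alt <- character(); got_truth <- list()
  batch <- 0L
  while (length(got_pos) < target && batch < cfg$max_batches) {
    batch <- batch + 1L
    B <- max(2L * (target - length(got_pos)), 1000L)
    pos <- sample.int(glen, min(B, glen))
    pos <- setdiff(pos, got_pos)
    ref <- hum[pos]
    r <- stats::runif(length(pos)) * (kappa + 2)
    alt <- ifelse(r < kappa, chartr("ACGT", "GTAC", ref),
                  ifelse(r < kappa + 1, chartr("ACGT", "CACA", ref),
                         chartr("ACGT", "TGTG", ref)))
    reg <- region[pos]
    gi <- gene_idx[pos]
    flag <- ifelse(gi > 0 & g$is_flagged[pmax(gi, 1)], "flagged", "other")
    p <- numeric(length(pos))
    effect <- rep(NA_character_, length(pos))
    relpos <- rep(NA_real_, length(pos))
    noncds <- reg < 3L
    p[noncds] <- acc$noncoding[flag[noncds]]
    ci <- which(reg == 3L)
    if (length(ci)) {
      cp <- cds_pos_of[pos[ci]]
      gene <- g$gene_id[gi[ci]]
      strandc <- g$strand[gi[ci]]
      len <- g$cds_length[gi[ci]]
      codon_index <- (cp - 1L) %/% 3L + 1L
      pic <- (cp - 1L) %% 3L + 1L
      ref_codon <- substring(cds_seqs[gene], (codon_index - 1L) * 3L + 1L,
                             codon_index * 3L)
      altc <- ifelse(strandc == "+", alt[ci], .complement(alt[ci]))
      alt_codon <- ref_codon
      substr(alt_codon, pic, pic) <- altc
      eff <- effect_from_codons(ref_codon, alt_codon)
      effect[ci] <- eff
      relpos[ci] <- cp / len
      cls <- ifelse(eff %in% c("stop_lost", "stop_retained"),
                    "nonsynonymous", eff)
      p[ci] <- mapply(function(cl, fl) acc[[cl]][[fl]], cls, flag[ci])
      syn <- eff == "synonymous"
      if (any(syn)) {
        dfreq <- pref_freq[alt_codon[syn]] - pref_freq[ref_codon[syn]]
        dfreq[is.na(dfreq)] <- 0
        p[ci[syn]] <- p[ci[syn]] *
          stats::plogis(cfg$syn_preference_beta[flag[ci[syn]]] * dfreq)
      }
      non <- eff == "nonsense"
      if (any(non))
        p[ci[non]] <- p[ci[non]] *
          relpos[ci[non]] ^ cfg$nonsense_position_gamma[flag[ci[non]]]
    }
    keep <- stats::runif(length(pos)) < p
    if (!any(keep)) next
    got_pos <- c(got_pos, pos[keep])
    got_alt <- c(got_alt, alt[keep])
    got_truth[[batch]] <- data.frame(
      pos = pos[keep],
      category = c("intergenic", "intron", "utr", "cds")[reg[keep] + 1L],
      gene_id = ifelse(gi[keep] > 0, g$gene_id[pmax(gi[keep], 1)],
                       NA_character_),
      is_flagged = flag[keep] == "flagged",
      effect = effect[keep],
      relative_cds_position = relpos[keep],
      acceptance_p = p[keep],
      stringsAsFactors = FALSE
    )
  }
  if (length(got_pos) < target)
    warning("SNP target unreachable: emitted ", length(got_pos), " of ",
            target)
  truth <- do.call(rbind, got_truth)
  sel <- seq_len(min(target, length(got_pos)))
  pos <- got_pos[sel]; alt1 <- got_alt[sel]; truth <- truth[sel, ]
  o <- order(pos)
  pos <- pos[o]; alt1 <- alt1[o]; truth <- truth[o, ]
  n <- length(pos)
  ref <- hum[pos]
  # multi-allelic records
  multi <- stats::runif(n) < cfg$multi_mutation_rate
  alt2 <- vapply(seq_len(n), function(i) {
    if (!multi[i]) return(NA_character_)
    sample(setdiff(.nucs, c(ref[i], alt1[i])), 1)
  }, character(1))
  alt <- ifelse(multi, paste0(alt1, ",", alt2), alt1)
  # conservation scores per region x flag
  regkey <- paste0(ifelse(truth$category == "cds", "cds", "noncoding"), "_",
                   ifelse(truth$is_flagged, "flagged", "other"))
  cons <- stats::rnorm(n, cfg$conservation_mean[regkey], cfg$conservation_sd)
  snps <- data.frame(
    snp_id = sprintf("rs%07d", seq_len(n)),
    chrom = "chr1", pos = pos, ref = ref, alt = alt,
    og1 = sim$og1[pos], og2 = sim$og2[pos], cons = round(cons, 4),
    stringsAsFactors = FALSE
  )
  truth$snp_id <- snps$snp_id
  truth$alt1 <- alt1
  truth$is_multi <- multi
  truth$in_splice_region <- truth$category == "cds" &
    (match(truth$gene_id, g$gene_id) * 2^40 + truth$pos) %in% splice_keys
  truth$evo_class <- classify_evolutionary(
    data.frame(ref = ref, alt = alt1, og1 = snps$og1, og2 = snps$og2))
  rownames(truth) <- NULL
  sim$snps <- snps
  sim$truth <- truth
  sim
}
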