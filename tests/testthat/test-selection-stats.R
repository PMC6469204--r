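test_that("authored exact test matches the stock implementation and its
           symmetries", {
  set.seed(2)
  for (i in 1:25) {
    tab <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- fisher_exact_2x2(tab)
    want <- stats::fisher.test(tab)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-9)
    # transposing preserves p; swapping rows inverts the odds ratio
    expect_equal(fisher_exact_2x2(t(tab))$p_value, got$p_value,
                 tolerance = 1e-12)
    swapped <- fisher_exact_2x2(tab[2:1, ])
    if (is.finite(got$odds_ratio) && got$odds_ratio > 0)
      expect_equal(swapped$odds_ratio, 1 / got$odds_ratio,
                   tolerance = 1e-12)
  }
  # conditional-MLE odds ratio available behind a flag
  tab <- matrix(c(10, 20, 30, 20), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tab, or = "cmle")$odds_ratio,
               unname(stats::fisher.test(tab)$estimate))
})

test_that("pooled nsy/syn panel reproduces worked 2x2 cases", {
  s <- data.frame(
    gene_id = c("f1", "f2", "o1", "o2"),
    is_flagged = c(TRUE, TRUE, FALSE, FALSE),
    n_nsy = c(6, 4, 15, 15), n_syn = c(10, 10, 10, 10),
    stringsAsFactors = FALSE)
  r <- nsy_syn_ratios(s)
  expect_equal(r$pooled$ratio, c(0.5, 1.5))
  expect_equal(r$odds_ratio, 1 / 3)
  # identical classes: no association
  s2 <- data.frame(gene_id = c("a", "b"), is_flagged = c(TRUE, FALSE),
                   n_nsy = c(10, 10), n_syn = c(20, 20))
  r2 <- nsy_syn_ratios(s2)
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$fisher_p, 1)
  # zero-synonymous genes leave the per-gene panel but stay in the pool
  s3 <- rbind(s, data.frame(gene_id = "f3", is_flagged = TRUE,
                            n_nsy = 5, n_syn = 0))
  r3 <- nsy_syn_ratios(s3)
  expect_equal(r3$n_excluded_zero_syn, 1)
  expect_false("f3" %in% r3$per_gene$gene_id)
  expect_equal(r3$pooled$n_nsy[1], 15)
})

test_that("densities are counts per Kb", {
  s <- data.frame(gene_id = c("a", "b"), is_flagged = c(TRUE, FALSE),
                  exonic_snps = c(30, 0), cds_snps = c(12, 0),
                  mrna_length = c(1500, 800), cds_length = c(600, 300))
  d <- density_stats(s)
  expect_equal(d$per_gene$exonic_density, c(20, 0))
  expect_equal(d$per_gene$cds_density, c(20, 0))
})

test_that("rank-sum comparison is direction-free on identical samples", {
  rs <- rank_sum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(rs$p_value, 0.99)
  expect_true(is.na(rank_sum_test(numeric(), 1:3)$p_value))
})

test_that("conserved-site comparison reproduces the worked odds ratio", {
  ann <- data.frame(
    effect = "synonymous",
    is_flagged = rep(c(TRUE, FALSE), c(100, 100)),
    ref = "A",
    og2 = c(rep("A", 80), rep("G", 20), rep("A", 60), rep("G", 40)),
    cons = NA_real_, stringsAsFactors = FALSE)
  cc <- conservation_compare(ann, effects = "synonymous")
  expect_equal(cc$synonymous$conserved$odds_ratio, 8 / 3)
  expect_equal(cc$synonymous$conserved$fraction_flagged, 0.8)
  expect_equal(cc$synonymous$scores$skipped, "no conservation scores")
})

test_that("decile bins order by delta and report flagged fractions", {
  b <- decile_bin_fraction(1:20, rep(c(FALSE, TRUE), each = 10),
                           sprintf("s%02d", 1:20))
  expect_equal(b$fraction_flagged, c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1))
  expect_gt(attr(b, "rho"), 0)
  expect_equal(sum(b$n_snps), 20)
  expect_true(all(abs(diff(b$n_snps)) <= 1))
  # constant fractions leave rho undefined with a reason
  b2 <- decile_bin_fraction(1:20, rep(TRUE, 20))
  expect_true(is.na(attr(b2, "rho")))
  expect_equal(attr(b2, "rho_reason"), "constant fractions")
  expect_error(decile_bin_fraction(1:5, rep(TRUE, 5)), "n_bins")
})

test_that("random flags center the bin correlation on zero", {
  set.seed(31)
  rhos <- replicate(200, {
    b <- decile_bin_fraction(runif(200), sample(c(TRUE, FALSE), 200,
                                                replace = TRUE))
    attr(b, "rho")
  })
  expect_lt(abs(mean(rhos, na.rm = TRUE)),
            3 * stats::sd(rhos, na.rm = TRUE) / sqrt(sum(!is.na(rhos))))
})

test_that("nonsense panel computes positions and ratio tables", {
  ann <- data.frame(
    effect = rep(c("nonsense", "synonymous"), c(6, 40)),
    is_flagged = c(rep(c(TRUE, FALSE), 3), rep(c(TRUE, FALSE), 20)),
    relative_cds_position = c(0.9, 0.3, 0.95, 0.4, 0.85, 0.5,
                              runif(40)),
    stringsAsFactors = FALSE)
  out <- nonsense_position_stats(ann)
  expect_equal(out$nonsense_syn$table["flagged", "nonsense"], 3)
  expect_equal(out$nonsense_syn$table["other", "syn"], 20)
  expect_gt(out$position$median_x, out$position$median_y)
  # equal double/syn rates give an odds ratio of one
  doubles <- data.frame(gene_id = "g", is_flagged = rep(c(TRUE, FALSE),
                                                        c(10, 10)),
                        distinct_combined = TRUE,
                        combined_is_nonsense = FALSE,
                        relative_cds_position = runif(20))
  ann2 <- data.frame(effect = "synonymous",
                     is_flagged = rep(c(TRUE, FALSE), c(10, 10)),
                     relative_cds_position = runif(20))
  out2 <- nonsense_position_stats(ann2, doubles)
  expect_equal(out2$double_syn$odds_ratio, 1)
})

test_that("stratified controls follow the threshold and quantile rules", {
  set.seed(8)
  n <- 10
  s <- data.frame(
    gene_id = sprintf("g%02d", 1:n),
    is_flagged = rep(c(TRUE, FALSE), c(4, 6)),
    n_nsy = rpois(n, 5), n_syn = rpois(n, 5) + 1,
    exonic_snps = 5, cds_snps = 3, mrna_length = 1000, cds_length = 600,
    read_count = c(50, 150, 1000, 120, 200, 500, 30, 99, 101, 400),
    gc_content = seq(0.3, 0.75, length.out = n),
    mean_delta_bias = NA, mean_delta_freq = NA,
    stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = s$gene_id, effect = "synonymous",
                    is_flagged = s$is_flagged, ref = "A", og2 = "A",
                    cons = rnorm(n), category = "cds",
                    stringsAsFactors = FALSE)
  st <- stratified_controls(s, ann, expression_threshold = 100,
                            gc_quantile = 0.2)
  expect_setequal(st$expression$genes,
                  s$gene_id[!is.na(s$read_count) & s$read_count > 100])
  expect_equal(length(st$gc_high$genes), 2)   # top 20% of 10 genes
  expect_equal(length(st$gc_low$genes), 2)
  # a stratum with fewer than two flagged genes is skipped with a reason
  s2 <- s; s2$is_flagged <- c(TRUE, rep(FALSE, 9))
  st2 <- stratified_controls(s2, ann, expression_threshold = 100)
  expect_match(st2$expression$skipped, "fewer than 2 flagged")
})

test_that("dilemma gene selection applies the nsy/syn bounds and ordering", {
  s <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    is_flagged = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    n_nsy = c(3, 2, 2, 1, 0),
    n_syn = c(5, 2, 4, 1, 9),
    mean_delta_bias = c(0.9, 0.1, 0.3, 0.8, 0.99),
    mean_delta_freq = 0, stringsAsFactors = FALSE)
  got <- select_dilemma_genes(s)
  # a: nsy > 2 excluded; d: syn < 2 excluded; e: not flagged
  expect_equal(got$gene_id, c("c", "b"))
})
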