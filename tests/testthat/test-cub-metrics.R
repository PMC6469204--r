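test_that("codon counting excludes the initiator and the stop codon", {
  cc <- gene_codon_counts(c(gX = "ATGAAAAAGTAA"))
  expect_equal(unname(cc$peptide_length), 3L)
  expect_equal(unname(cc$counts[1, "AAA"]), 1L)
  expect_equal(unname(cc$counts[1, "AAG"]), 1L)
  expect_equal(unname(cc$counts[1, "ATG"]), 0L)  # initiator excluded
  expect_equal(unname(cc$counts[1, "TAA"]), 0L)  # stop excluded
  expect_equal(sum(cc$counts), 2)
  expect_error(gene_codon_counts("ATGAA"), "multiple of 3")
  expect_warning(gene_codon_counts(c(g = "ATGAANAAGTAA")), "skipped")
})

test_that("family chi-square reproduces the expectation formula exactly", {
  # observed equal to expected at 59% A/T ending
  expect_equal(family_chi_square("K", c(AAA = 59, AAG = 41)), 0)
  # all G/C-ending: 59^2/59 + 59^2/41 = 5900/41
  expect_equal(family_chi_square("K", c(AAA = 0, AAG = 100)), 5900 / 41)
  # empty family contributes zero and is flagged absent
  v <- family_chi_square("K", c(AAA = 0, AAG = 0))
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "absent"))
  expect_error(family_chi_square("K", c(AAA = 1), at3_content = 1.2),
               "at3_content")
  expect_error(family_chi_square("ZZ", c(AAA = 1)), "unknown family")
})

test_that("r2x2 mode matches the stock 2x2 chi-square with continuity
           correction on the observed-vs-expected table", {
  set.seed(4)
  for (i in 1:20) {
    o <- sample(0:80, 2)
    if (sum(o) == 0) o <- c(5, 5)
    at <- runif(1, 0.2, 0.8)
    e <- c(sum(o) * at, sum(o) * (1 - at))
    want <- suppressWarnings(
      stats::chisq.test(matrix(c(o, e), ncol = 2))$statistic)
    got <- family_chi_square("K", c(AAA = o[1], AAG = o[2]), at, "r2x2")
    expect_equal(as.numeric(got), unname(want), tolerance = 1e-12)
  }
})

test_that("gof chi-square is invariant under swapping a 2-codon family with
           its complementary A/T content", {
  set.seed(5)
  for (i in 1:25) {
    o <- sample(0:60, 2)
    at <- runif(1, 0.1, 0.9)
    a <- family_chi_square("K", c(AAA = o[1], AAG = o[2]), at)
    b <- family_chi_square("K", c(AAA = o[2], AAG = o[1]), 1 - at)
    expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
  }
})

test_that("scaled chi-square sums family deviations over peptide length", {
  # only family codons are 59 AAA + 41 AAG: zero deviation
  s0 <- paste0("ATG", strrep("AAA", 59), strrep("AAG", 41),
               strrep("ATG", 2), "TAA")
  p0 <- gene_scaled_chi2(gene_codon_counts(c(g = s0)))
  expect_equal(p0$genes$scaled_chi2, 0)
  # 100 AAG only at peptide length 100: 5900/41 scaled by 1/100
  cm <- matrix(0L, 1, 64,
               dimnames = list("g", chartr("U", "T",
                                           names(Biostrings::GENETIC_CODE))))
  cm[1, "AAG"] <- 100L
  pr <- gene_scaled_chi2(cm, peptide_length = 100)
  expect_equal(pr$genes$scaled_chi2, 5900 / 41 / 100)
  # halving peptide length doubles the scaled value for equal raw sums
  pr2 <- gene_scaled_chi2(rbind(g1 = cm[1, ], g2 = cm[1, ]),
                          peptide_length = c(100, 200))
  expect_equal(pr2$genes$scaled_chi2[1] / pr2$genes$scaled_chi2[2], 2)
  expect_error(gene_scaled_chi2(cm, peptide_length = 0), "positive")
})

test_that("codon preference recovers monotone relationships and family
           antisymmetry", {
  mk_counts <- function(fr) {
    # three genes using only the Lys family, 100 codons each
    cm <- matrix(0L, 3, 64,
                 dimnames = list(paste0("g", 1:3),
                                 chartr("U", "T",
                                        names(Biostrings::GENETIC_CODE))))
    cm[, "AAG"] <- as.integer(round(100 * fr))
    cm[, "AAA"] <- 100L - cm[, "AAG"]
    structure(list(counts = cm,
                   peptide_length = c(g1 = 101L, g2 = 101L, g3 = 101L)),
              class = "gene_codon_counts")
  }
  cc <- mk_counts(c(0.2, 0.5, 0.8))
  prof <- gene_scaled_chi2(cc)
  # force a strictly increasing chi2 so the relationship is monotone
  prof$genes$scaled_chi2 <- c(0.1, 0.5, 2.0)
  pref <- codon_preference(cc, prof)
  expect_equal(pref$rho[pref$codon == "AAG"], 1)
  expect_equal(pref$rho[pref$codon == "AAA"], -1)
  # reversed frequencies flip the sign
  cc2 <- mk_counts(c(0.8, 0.5, 0.2))
  pref2 <- codon_preference(cc2, prof)
  expect_equal(pref2$rho[pref2$codon == "AAG"], -1)
  # family frequencies sum to one within every family
  fam_sum <- tapply(pref$family_freq, pref$family_id, sum)
  expect_true(all(abs(fam_sum - 1) < 1e-12 | is.na(fam_sum)))
  # fewer than 3 usable genes leaves rho undefined
  cc3 <- mk_counts(c(0.2, 0.8, 0.5))
  cc3$counts[3, c("AAA", "AAG")] <- 0L
  pref3 <- codon_preference(cc3, gene_scaled_chi2(cc3))
  expect_true(is.na(pref3$rho[pref3$codon == "AAG"]))
})

test_that("spearman rho equals a midrank brute-force oracle", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- sample(1:8, n, replace = TRUE) + runif(n) * 0.01
    y <- sample(1:8, n, replace = TRUE)
    oracle <- stats::cor(rank(x), rank(y))   # rank-then-Pearson with midranks
    got <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE)$estimate)
    expect_equal(unname(got), oracle, tolerance = 1e-12)
  }
})

test_that("delta records subtract post- from pre-mutation metrics", {
  pref <- data.frame(
    codon = c("AAA", "AAG"), family_id = "K", amino_acid = "K",
    ends_gc = c(FALSE, TRUE), rho = c(-0.30, 0.74), p_value = NA,
    n_genes = 10L, family_freq = c(0.6, 0.4), global_freq = c(0.03, 0.02),
    stringsAsFactors = FALSE)
  d <- delta_for_snp("AAA", "AAG", pref)
  expect_equal(d$delta_bias, 1.04)
  expect_equal(d$delta_freq, -0.2)
  expect_true(d$same_family)
  # antisymmetry and identity
  expect_equal(delta_for_snp("AAG", "AAA", pref)$delta_bias, -1.04)
  expect_equal(delta_for_snp("AAA", "AAA", pref)$delta_bias, 0)
  # undefined rho on either side skips the record with a reason
  pref$rho[1] <- NA
  d2 <- delta_for_snp("AAA", "AAG", pref)
  expect_false(d2$ok)
  expect_equal(d2$reason, "undefined rho")
  expect_true(is.na(d2$delta_bias))
})

test_that("gene mean delta averages usable synonymous records", {
  rec <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g3", "g3"),
    delta_bias = c(0.2, -0.2, 0.5, 1.04, 0, -0.04),
    delta_freq = c(0.1, -0.1, 0.2, 0.3, 0, -0.1),
    ok = TRUE, effect = "synonymous", stringsAsFactors = FALSE)
  md <- gene_mean_delta(rec)
  expect_equal(md$mean_delta_bias[md$gene_id == "g1"], 0)
  expect_equal(md$mean_delta_bias[md$gene_id == "g2"], 0.5)
  expect_equal(md$mean_delta_bias[md$gene_id == "g3"], 1 / 3)
  # nonsynonymous records enter only under scope = "all"
  rec$effect[3] <- "nonsynonymous"
  expect_false("g2" %in% gene_mean_delta(rec)$gene_id)
  expect_true("g2" %in% gene_mean_delta(rec, scope = "all")$gene_id)
})
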