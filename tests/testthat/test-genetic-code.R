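test_that("codon families partition the 59 sense codons into 21 families", {
  fam <- codon_families()
  expect_equal(nrow(fam), 59)
  expect_equal(length(unique(fam$family_id)), 21)
  expect_false(anyDuplicated(fam$codon) > 0)
  # excluded codons: single-codon amino acids and stops
  expect_false(any(c("ATG", "TGG", "TAA", "TAG", "TGA") %in% fam$codon))
  # every codon translates to its family's amino acid
  expect_equal(translate_codon(fam$codon), fam$amino_acid)
  # codons within a family share their first two nucleotides
  prefixes <- tapply(substr(fam$codon, 1, 2), fam$family_id,
                     function(p) length(unique(p)))
  expect_true(all(prefixes == 1))
  # Lys family is exactly {AAA, AAG}
  expect_setequal(fam$codon[fam$amino_acid == "K"], c("AAA", "AAG"))
  # the six-codon amino acids split into two families each
  for (aa in c("L", "R", "S"))
    expect_equal(length(unique(fam$family_id[fam$amino_acid == aa])), 2)
  expect_setequal(fam$codon[fam$family_id == "S.TC"],
                  c("TCT", "TCC", "TCA", "TCG"))
  expect_setequal(fam$codon[fam$family_id == "S.AG"], c("AGT", "AGC"))
})

test_that("embedded code agrees with the reference translation table", {
  ref <- Biostrings::GENETIC_CODE
  names(ref) <- chartr("U", "T", names(ref))
  expect_equal(translate_codon(names(ref)), as.character(ref))
})

test_that("single-effect classification matches a brute-force oracle on all
           codon x position x alt combinations", {
  ref <- Biostrings::GENETIC_CODE
  names(ref) <- chartr("U", "T", names(ref))
  grid <- expand.grid(codon = names(ref), pos = 1:3,
                      alt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  grid <- grid[substr(grid$codon, grid$pos, grid$pos) != grid$alt, ]
  expect_equal(nrow(grid), 576)
  oracle <- function(codon, pos, alt) {
    mut <- codon
    substr(mut, pos, pos) <- alt
    a1 <- ref[codon]; a2 <- ref[mut]
    if (a1 == "*" && a2 == "*") "stop_retained"
    else if (a1 == "*") "stop_lost"
    else if (a2 == "*") "nonsense"
    else if (a1 == a2) "synonymous" else "nonsynonymous"
  }
  want <- mapply(oracle, grid$codon, grid$pos, grid$alt)
  got <- classify_single_effect(grid$codon, grid$pos, grid$alt)
  expect_equal(got, unname(want))
})

test_that("classification validates its inputs", {
  expect_error(classify_single_effect("AAA", 3, "A"), "alt base equals")
  expect_error(classify_single_effect("AAA", 4, "G"), "pos")
  expect_error(classify_single_effect("AAN", 3, "G"), "invalid codon")
  expect_error(classify_single_effect("AAA", 3, "X"), "invalid")
  # lower-case input is up-cased
  expect_equal(classify_single_effect("aaa", 3, "g"), "synonymous")
})

test_that("combined double-mutation effects follow the worked cases", {
  # AAT: singles TAT (Tyr), AAA (Lys); combined TAA is a novel stop
  c1 <- combined_double_effect("AAT", 1, "T", 3, "A")
  expect_equal(c1$single1, "TAT")
  expect_equal(c1$single2, "AAA")
  expect_equal(c1$combined, "TAA")
  expect_true(c1$distinct_combined)
  expect_true(c1$combined_is_nonsense)
  # CGA: all products Arg, nothing new
  c2 <- combined_double_effect("CGA", 1, "A", 3, "G")
  expect_equal(c2$combined, "AGG")
  expect_false(c2$distinct_combined)
  expect_false(c2$combined_is_nonsense)
  # AAA: combined CAG repeats the second single product (Gln)
  c3 <- combined_double_effect("AAA", 3, "G", 1, "C")
  expect_equal(c3$combined, "CAG")
  expect_equal(c3$product2, "Q")
  expect_false(c3$distinct_combined)
  expect_error(combined_double_effect("AAA", 1, "C", 1, "G"),
               "different codon positions")
  expect_error(combined_double_effect("TAA", 1, "C", 2, "G"), "sense")
})

test_that("exhaustive double-mutation enumeration matches the oracle", {
  ref <- Biostrings::GENETIC_CODE
  names(ref) <- chartr("U", "T", names(ref))
  sense <- names(ref)[ref != "*"]
  nucs <- c("A", "C", "G", "T")
  rows <- list()
  for (cod in sense) for (p1 in 1:2) for (p2 in (p1 + 1):3)
    for (a1 in setdiff(nucs, substr(cod, p1, p1)))
      for (a2 in setdiff(nucs, substr(cod, p2, p2)))
        rows[[length(rows) + 1]] <- c(cod, p1, a1, p2, a2)
  m <- do.call(rbind, rows)
  cases <- combined_double_effect(m[, 1], as.integer(m[, 2]), m[, 3],
                                  as.integer(m[, 4]), m[, 5])
  expect_equal(nrow(cases), 1647)
  # oracle recomputation, independent of the implementation
  mut <- function(cod, p, a) { substr(cod, p, p) <- a; cod }
  s1 <- mapply(mut, m[, 1], as.integer(m[, 2]), m[, 3])
  s2 <- mapply(mut, m[, 1], as.integer(m[, 4]), m[, 5])
  cb <- mapply(mut, s1, as.integer(m[, 4]), m[, 5])
  want_distinct <- unname(ref[cb] != ref[s1] & ref[cb] != ref[s2])
  expect_equal(cases$distinct_combined, want_distinct)
  expect_equal(cases$combined_is_nonsense, unname(ref[cb] == "*"))
  # a combined stop from two non-stop singles is always a distinct product
  novel <- cases$combined_is_nonsense & cases$product1 != "*" &
    cases$product2 != "*"
  expect_true(all(cases$distinct_combined[novel]))
  # frozen regression constant from the enumeration
  expect_equal(sum(cases$distinct_combined & cases$combined_is_nonsense), 58)
})
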