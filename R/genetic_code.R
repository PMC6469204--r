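# Standard genetic code (NCBI translation table 1), embedded: codons in the
# canonical T/C/A/G nesting order, stops as "*".
.codon_table <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  # canonical order is first base slowest: rebuild explicitly
  codons <- apply(expand.grid(b3 = b, b2 = b, b1 = b)[, 3:1], 1, paste0,
                  collapse = "")
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "")[[1]]
  stats::setNames(aa, codons)
})

.nucs <- c("A", "C", "G", "T")

#' Translate codons under the standard genetic code
#'
#' @param codon character vector of length-3 DNA codons (upper or lower case).
#' @return single-letter amino acids, `"*"` for stop, `NA` for codons
#'   containing non-ACGT characters.
#' @examples
#' translate_codon(c("ATG", "TAA", "aag"))
#' @export
translate_codon <- function(codon) {
  unname(.codon_table[toupper(codon)])
}

.is_stop <- function(codon) !is.na(codon) & .codon_table[codon] == "*"

.check_nuc <- function(x, what = "base") {
  x <- toupper(x)
  bad <- !(x %in% .nucs)
  if (any(bad))
    stop("invalid ", what, ": ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  x
}

#' Partition sense codons into synonymous codon families
#'
#' The 59 sense codons (all but ATG, TGG and the three stops) fall into 21
#' families of single-mutation-interconvertible synonymous codons: codons are
#' grouped by amino acid and shared first two nucleotides, which splits the
#' six-codon amino acids Leu, Arg and Ser into two families each.
#'
#' @return data frame with one row per codon: `codon`, `amino_acid`,
#'   `family_id` (amino-acid letter, with the first two codon nucleotides
#'   appended for split families), and `ends_gc` (TRUE when the third base is
#'   G or C).
#' @examples
#' fam <- codon_families()
#' subset(fam, amino_acid == "K")
#' @export
codon_families <- function() {
  codons <- names(.codon_table)
  aa <- unname(.codon_table)
  sense <- aa != "*" & !(codons %in% c("ATG", "TGG"))
  codons <- codons[sense]
  aa <- aa[sense]
  prefix <- substr(codons, 1, 2)
  key <- paste(aa, prefix, sep = ".")
  split_aa <- names(which(tapply(prefix, aa, function(p) length(unique(p))) > 1))
  family_id <- ifelse(aa %in% split_aa, paste0(aa, ".", prefix), aa)
  out <- data.frame(
    codon = codons,
    amino_acid = aa,
    family_id = family_id,
    ends_gc = substr(codons, 3, 3) %in% c("G", "C"),
    stringsAsFactors = FALSE
  )
  out[order(out$family_id, out$codon), , drop = FALSE]
}

#' Classify the effect of a single mutation within a codon
#'
#' @param ref_codon reference codon(s), sense or stop.
#' @param pos position within the codon, 1-3.
#' @param alt_base replacement base at `pos` (must differ from the reference
#'   base there).
#' @return factor-free character vector: `"synonymous"`, `"nonsynonymous"`,
#'   `"nonsense"` (sense to stop), `"stop_lost"` (stop to sense) or
#'   `"stop_retained"` (stop to stop). Vectorised; arguments are recycled.
#' @examples
#' classify_single_effect("AAA", 3, "G")  # synonymous
#' classify_single_effect("TAC", 3, "A")  # nonsense
#' @export
classify_single_effect <- function(ref_codon, pos, alt_base) {
  ref_codon <- toupper(ref_codon)
  alt_base <- .check_nuc(alt_base, "alt base")
  if (!all(pos %in% 1:3)) stop("pos must be in 1..3", call. = FALSE)
  n <- max(length(ref_codon), length(pos), length(alt_base))
  ref_codon <- rep_len(ref_codon, n)
  pos <- rep_len(pos, n)
  alt_base <- rep_len(alt_base, n)
  if (any(is.na(.codon_table[ref_codon])))
    stop("invalid codon: ",
         paste(unique(ref_codon[is.na(.codon_table[ref_codon])]),
               collapse = ", "), call. = FALSE)
  if (any(substr(ref_codon, pos, pos) == alt_base))
    stop("alt base equals the reference base at pos", call. = FALSE)
  alt_codon <- ref_codon
  substr(alt_codon, pos, pos) <- alt_base
  effect_from_codons(ref_codon, alt_codon)
}

#' @rdname classify_single_effect
#' @param alt_codon full alternative codon (for callers that already hold
#'   both codons).
#' @export
effect_from_codons <- function(ref_codon, alt_codon) {
  aa_ref <- unname(.codon_table[toupper(ref_codon)])
  aa_alt <- unname(.codon_table[toupper(alt_codon)])
  ifelse(aa_ref == "*" & aa_alt == "*", "stop_retained",
  ifelse(aa_ref == "*", "stop_lost",
  ifelse(aa_alt == "*", "nonsense",
  ifelse(aa_ref == aa_alt, "synonymous", "nonsynonymous"))))
}

#' Combined effect of two mutations within one codon
#'
#' Two SNPs in the same codon can jointly produce a codon that neither single
#' mutation yields; in particular the combination can create a premature stop
#' even when neither single change is nonsense.
#'
#' @param ref_codon sense codon(s).
#' @param pos1,alt1 first mutation: codon position (1-3) and replacement base.
#' @param pos2,alt2 second mutation at a different position.
#' @return data frame with one row per case: the reference codon, both single
#'   mutation products and their amino acids, the combined product,
#'   `distinct_combined` (combined translation differs from both single
#'   products) and `combined_is_nonsense` (combined product is a stop codon).
#' @examples
#' combined_double_effect("AAT", 1, "T", 3, "A")  # combines to TAA (stop)
#' @export
combined_double_effect <- function(ref_codon, pos1, alt1, pos2, alt2) {
  ref_codon <- toupper(ref_codon)
  alt1 <- .check_nuc(alt1); alt2 <- .check_nuc(alt2)
  n <- max(length(ref_codon), length(pos1), length(pos2))
  ref_codon <- rep_len(ref_codon, n)
  pos1 <- rep_len(pos1, n); alt1 <- rep_len(alt1, n)
  pos2 <- rep_len(pos2, n); alt2 <- rep_len(alt2, n)
  if (any(pos1 == pos2))
    stop("the two mutations must hit different codon positions", call. = FALSE)
  if (any(.codon_table[ref_codon] == "*"))
    stop("ref_codon must be a sense codon", call. = FALSE)
  single1 <- ref_codon; substr(single1, pos1, pos1) <- alt1
  single2 <- ref_codon; substr(single2, pos2, pos2) <- alt2
  combined <- single1; substr(combined, pos2, pos2) <- alt2
  p_comb <- .codon_table[combined]
  p1 <- .codon_table[single1]
  p2 <- .codon_table[single2]
  data.frame(
    ref_codon = ref_codon,
    pos1 = pos1, alt1 = alt1, pos2 = pos2, alt2 = alt2,
    single1 = single1, single2 = single2,
    product1 = unname(p1), product2 = unname(p2),
    combined = combined, combined_product = unname(p_comb),
    distinct_combined = unname(p_comb != p1 & p_comb != p2),
    combined_is_nonsense = unname(p_comb == "*"),
    stringsAsFactors = FALSE
  )
}
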