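---
title: "Detecting purifying selection on coding SNPs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting purifying selection on coding SNPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonsel)
```

## The scientific question

Genes under unusual selective regimes — cancer-related genes are the
motivating example — should carry a distinctive footprint in standing
polymorphism. `codonsel` quantifies that footprint by contrasting a flagged
gene set against all other genes across several axes: the
nonsynonymous/synonymous (nsy/syn) ratio, conservation of the mutated
sites, the direction of synonymous changes through codon-usage space, the
position of premature stop codons along the CDS, and the joint effect of
two mutations sharing a codon.

All statistics work on *polymorphism* (segregating SNPs), not on fixed
interspecific differences: depressed nsy/syn here reflects purifying
selection on amino-acid changes within the species.

## SNP filtering and annotation

Raw SNPs pass two filters before annotation:

* **Ancestral filter** — the reference allele must equal the orthologous
  base of at least one of two outgroup genomes (a near outgroup in the
  monkey role, a far outgroup in the mouse role). This discards sites where
  the reference itself is likely derived.
* **Uni-mutation filter** — only biallelic records are kept; multi-allelic
  sites give conflicting functional annotations.

Annotation is against one *canonical transcript* per gene, the isoform
with the longest CDS (ties broken lexicographically by transcript id so
runs are reproducible). Each SNP receives a category (intergenic, intron,
UTR, CDS, other noncoding) per overlapping gene; CDS hits get their codon
context on the coding strand, with alleles reverse-complemented for
minus-strand genes. Two conventions matter:

* **Splice windows.** CDS positions within 3 nt of an exon–intron junction
  are flagged and excluded from effect-based statistics, so that apparent
  selection on coding changes is not confounded by selection on splicing.
  The window width is configurable; 3 nt on the exonic side follows the
  convention of the standard variant-effect annotators.
* **Terminal stop codons.** Mutations inside the annotated stop codon are
  classified `stop_lost`/`stop_retained` and excluded from nsy/syn
  counting; they are neither nonsynonymous nor synonymous in the usual
  sense and the source analyses never count them.

A consistency guard rejects (and counts) records whose reference allele
disagrees with the genome sequence; the filter funnel in every report
accounts for each record of the input exactly once.

## Codon usage bias

The codon-level machinery follows the scaled chi-square framework of the
classic codon-preference literature.

The 59 sense codons (all but ATG, TGG and the three stops) partition into
**21 synonymous codon families**: codons grouped by amino acid *and* shared
first two nucleotides. This rule reproduces the required split of the
six-codon amino acids Leu, Arg and Ser into two families each — within a
family, any two codons are interconvertible by a single third-position
mutation.

For one family in one gene, the observed A/T-ending versus G/C-ending
third-position counts are compared with the neutral expectation given by
the intronic A/T content (0.59 in human; the `at3_content` parameter). For
the Lys family: `E_AAA = (O_AAA + O_AAG) * 0.59`, and the family's
chi-square is the deviation of observed from expected. Two modes are
exposed because the named statistic and the literal published construction
disagree:

* `gof` (default) — the classic goodness-of-fit statistic
  `sum((O - E)^2 / E)` over the two cells, matching the "scaled
  chi-square" definition;
* `r2x2` — the Pearson statistic with continuity correction on the 2x2
  table whose *columns* are the observed and the expected counts, which is
  what the published `chisq.test(matrix(c(O, E), ncol = 2))` call computes.

Reports name the mode; all defaults use `gof`. Families with more than two
codons are collapsed to the two cells A/T-ending versus G/C-ending — the
only reading consistent with a deviation "of A/T content at position 3".
The gene-level CUB is the sum of family chi-squares divided by peptide
length (codons minus the stop); the initiator and the stop are excluded
from all counts.

**Codon preference** is measured per codon as the Spearman correlation,
across genes, between the codon's within-family usage share and the
gene's scaled chi-square; positive rho marks a preferred codon. A codon's
rho is defined only when at least 3 genes carry its family. Ties use
midranks; p-values (exact for 9 or fewer genes, asymptotic otherwise) are
reported but never used for filtering.

For a synonymous SNP, **delta codon bias** is rho(post) − rho(pre) and
**delta codon frequency** is the within-family share difference. The
within-family share is the default frequency flavour because deltas of a
global per-64 frequency are not comparable between families; the global
flavour is available behind a flag. Per-gene mean deltas default to
synonymous SNPs only (rho values are not comparable across families); a
flag widens the scope to all CDS SNPs with defined rho, which the
gene-level dilemma panel uses.

## Comparative statistics

Pooled 2x2 comparisons (nsy/syn, nonsense/syn, double-mutation/syn,
directional evolutionary classes, conserved-site fractions) use a
two-sided Fisher's exact test implemented by point-probability summation;
the odds ratio reported is the sample cross-product (the conditional MLE
is available behind a flag). Distribution comparisons (per-gene ratios,
densities, conservation scores, relative stop positions) use the Wilcoxon
rank-sum test: exact enumeration when both groups have at most 50 untied
observations, otherwise the normal approximation with tie and continuity
corrections. No multiple-testing correction is applied to the headline
panels — raw p-values mirror the source analyses — but the report JSON
carries a clearly-labelled supplementary Benjamini–Hochberg column over
the headline p-values, an addition of this package.

The decile panels sort synonymous records by increasing delta, split them
into ten near-equal bins (ties broken by record id for determinism), and
correlate bin index with the per-bin fraction of flagged-gene records.
Each record carries its gene's flag, so genes with many SNPs weigh more;
a per-gene-unique variant can be had by deduplicating the input records.

Stratified controls re-run the headline comparisons inside (a) highly
expressed genes, read count > 100 by default, and (b) the top and bottom
20% of genes by CDS GC content, controlling expression and composition
confounders. Strata with fewer than two flagged genes are skipped with a
recorded reason.

## The synthetic-data generator

`sim_config()`/`simulate_genome()`/`simulate_snps()` generate study
conditions with known ground truth. The generator is an inverse model of
the analysis:

* One chromosome of `n_genes` (default 500, 20% flagged) intron-containing
  genes on random strands. Noncoding sequence has A/T content 0.59, the
  intronic value the chi-square expects.
* Each gene's third-position G/C share is a logistic function of a
  simulated expression latent (`expression_gc3_coupling`, default 1.5,
  around a coding mean GC3 of 0.55). Coding third positions are G/C-richer
  than introns in real genomes, and coupling GC3 to expression is what
  makes G/C-ending codons *recoverably preferred* without hard-coding any
  rho; read counts are drawn from the same latent so expression strata are
  meaningful. With coupling 0 there is no preference signal at all.
* An ancestral sequence is evolved independently to the focal species and
  two outgroups (default per-branch substitution probabilities 0.01, 0.03
  and 0.15) under a single-nucleotide process with transition weight
  `kappa = 3` — the simplest process that reproduces the observed
  transition excess and the directional evolutionary classes. Focal CDSs
  are repaired to keep a clean reading frame.
* Candidate SNVs are proposed uniformly with the same transition excess
  and accepted with probability `acceptance[class, flag]`, times
  `plogis(beta * delta_freq)` for synonymous candidates, times
  `relative_position^gamma` for nonsense candidates. Defaults encode the
  structure the analysis is designed to detect: nonsynonymous acceptance
  0.35 (flagged) vs 0.7 (other), nonsense 0.1 vs 0.3, beta 8 vs 0, gamma
  2 vs 0.5, equal synonymous acceptance, conservation scores drawn higher
  in flagged CDS (mean 2 vs 1, sd 1). A 10% multi-allelic rate exercises
  the uni-mutation filter. Splice-window CDS SNPs arise naturally from the
  uniform proposal over intron-containing genes; no separate knob places
  them.

What the generator does **not** emulate: demography, linkage and
recombination, empirical mutation signatures, rate heterogeneity along the
genome, gene families, and — importantly — any class difference in
outgroup divergence, so the conserved-orthologous-site *fraction* carries
no class signal at defaults even though conservation *scores* do. Passing
recovery tests therefore show the pipeline's wiring is correct under the
stated model, not that real genomes satisfy the model.

## Calibration experiments and their operating characteristics

`experiment_*()` functions rerun the generator-plus-pipeline loop under
known signals:

* `experiment_codon_preference()` — 100 replicates at full generator
  defaults; success means every defined rho has its construction sign.
  The no-signal control sets coupling to 0 *and* the coding composition to
  the chi-square's neutral reference (GC3 = 1 − 0.59): if coding GC3 and
  the intronic reference differ, a gene's own-family deviation correlates
  mechanically with its codon share and rho is displaced from zero even
  without any expression coupling. Even at neutral composition the
  per-codon rho is not exactly unbiased: within-family shares are
  right-skewed in short genes while the null scaled chi-square behaves as
  roughly 21/length, which leaves codons of 3- and 4-codon families with a
  residual bias of about −0.02 to −0.035 at the default gene-length scale.
  This is a finite-sample property of the estimator itself (the same
  counts enter both axes of the correlation), detectable only because the
  Monte Carlo standard error of 100 replicates (~0.005 per codon) is far
  smaller; it is negligible relative to any real preference signal.
* `experiment_or_recovery()` — a single 10,000-SNP run with nonsynonymous
  acceptance 0.2 (flagged) versus 1.0, equal synonymous acceptance; the
  pooled odds ratio estimates 0.2 with a delta-method standard error.
* `experiment_nonsense_position()` — gamma 2 vs 0 with *equal* nonsense
  base acceptance (1 vs 1), isolating the positional exponent; 200 genes,
  10,000 SNPs per replicate, a scale chosen so each replicate has enough
  nonsense records in both classes for a stable median.
* `experiment_delta_bins()` — beta 16 vs 0. The effect size is a package
  choice: the within-family frequency deltas of this generator have a
  standard deviation near 0.09, and beta 16 produces a tilt of roughly
  five-fold across the decile range — a strong, clearly visible trend of
  the kind the analysis targets. The check is the sign of the bin
  correlation, asserted on the delta-frequency ordering that beta acts on.
* `experiment_null_calibration()` — all class parameters equal; 500
  replicates at 250 genes / 6,000 SNPs. This scale keeps the per-gene SNP
  load near one record per gene. That choice is substantive: at dense
  per-gene loads the pooled tests are *genuinely* anti-conservative,
  because records from one gene share its flag and composition
  (gene-level clustering the pooled 2x2 and bin tests ignore). The
  calibration documents the regime in which the wiring is calibrated.

One numerical point deserves emphasis. Exact tests on discrete tables are
*super-uniform* under the null: their p-values have point masses of order
0.1 at any table size reachable here, so a raw Kolmogorov–Smirnov
uniformity check must fail no matter how correct the implementation is.
The calibration therefore checks raw-p uniformity for the comparisons with
continuous null distributions (rank-sum on continuous scores, the bin
Spearman), and for the Fisher panels checks uniformity of the
discreteness-corrected p-value `p_lower + U * (p - p_lower)`, which is
exactly uniform if and only if the test is validly calibrated.
`fisher_exact_2x2()` returns `p_lower` for this purpose.

## Numerical and degenerate-input choices

* Coordinates: VCF and all reported positions are 1-based; interval
  arithmetic uses expanded position vectors keyed numerically.
* DNA is upper-cased on input; codons containing N are skipped with a
  warning.
* A family absent from a gene contributes chi-square 0 and is flagged.
* Genes with no synonymous SNP are excluded from per-gene ratio panels but
  retained in pooled sums; a class with zero pooled synonymous count
  reports an undefined ratio rather than infinity.
* Constant bin fractions leave the bin correlation undefined with a
  recorded reason; fewer records than bins is an error advising fewer
  bins.
* Codons with three or more SNPs are excluded from double-mutation pairing
  and counted; splice-window SNPs do not pair.
* An empty flagged set skips all class comparisons with a reason and exits
  successfully.

## Known limitations

* The ancestral filter matches the *reference* allele only; matching
  either allele is a defensible alternative reading and would retain more
  derived-reference sites.
* Pooled 2x2 tests assume independent records; under heavy per-gene SNP
  loads they are anti-conservative (see the calibration section). The
  per-gene rank-sum panels are the robust companion in that regime.
* The canonical-transcript reduction discards isoform-specific coding
  regions; the expression stratification only partially controls this.
* Conservation scores are consumed as an input track; the package neither
  computes alignments nor lifts coordinates between assemblies.
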