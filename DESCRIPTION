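Package: codonsel
Title: Purifying Selection on Coding SNPs via Codon Usage Bias and
    Functional Class Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates single-nucleotide polymorphisms against canonical
    gene models and quantifies purifying selection on a flagged gene set
    (for example cancer-related genes) relative to all other genes. The
    pipeline applies ancestral and uni-mutation filters, classifies
    nonsynonymous, synonymous and nonsense changes (including combined
    effects of two mutations in one codon), computes gene-level codon
    usage bias as a scaled chi-square against intronic A/T content,
    per-codon preference as a Spearman correlation across genes, and
    delta codon bias/frequency for synonymous variants. Comparative
    statistics include pooled and per-gene nonsynonymous/synonymous
    ratios, conservation-score comparisons, decile binning of delta
    metrics, nonsense positional bias, and expression- or GC-stratified
    controls. A synthetic-data generator emits genomes, gene models,
    orthologous bases, conservation tracks and SNPs with known ground
    truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
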