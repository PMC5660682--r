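Package: sqtlgxe
Title: Gene-by-Environment Splicing QTL Mapping in Multiparental Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps environment-responsive splicing quantitative trait loci
    (sQTLs) in multiparental recombinant inbred panels genotyped as founder
    haplotype probabilities. Builds two splicing phenotypes from exon- and
    transcript-level RNA-seq counts (exon/gene read fractions and per-gene
    isoform dosage), quantile-normalizes them and removes principal-component
    confounders, fits nested genotype-by-environment linear models at every
    (phenotype, locus) pair with partial F-tests, controls the false discovery
    rate with Storey q-values, classifies cis versus trans sQTLs, and detects
    trans-sQTL hotspots by permutation. Includes a synthetic data generator
    that emulates an eight-founder Drosophila Synthetic Population Resource
    style design with planted cis G-by-E effects and trans hotspots, a
    simplified alternative-splicing event classifier (exon skipping, intron
    retention, alternative donor/acceptor), and a paired differential
    expression contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rtracklayer,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
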