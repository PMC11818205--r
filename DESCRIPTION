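Package: panhap
Title: Pangenome K-mer Diagnostics, Haplotype Homozygosity, Recombination
    Landscapes and Bulk Segregant Analysis for Phased Plant Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of panels of phased plant genome
    assemblies. Builds a canonical k-mer presence/absence pangenome index
    with unique-k-mer extraction, Jaccard clustering, collector's curves and
    binned unique-k-mer density tracks; detects aligned runs of homozygosity
    (AROH) from pairwise alignments (PAF) between the two haplotypes of a
    diploid assembly; estimates recombination-rate landscapes from Marey
    maps of F2 linkage markers by LOESS smoothing and numerical
    differentiation, with marker quality control (segregation distortion,
    missingness, duplicate collapse) and suppressed-recombination calling;
    and performs G-statistic bulk segregant analysis with sliding-window
    smoothing, simulation-based significance thresholds, interval liftover
    across reference assemblies and consensus-peak narrowing. A synthetic
    data module generates diploid haplotype pairs, assembly panels, F2
    genotype matrices under a specified crossover-density landscape, and
    bulk allele-count tables around a planted causal locus, each with a
    machine-readable truth set for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
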