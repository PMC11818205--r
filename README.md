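# panhap

Comparative analysis of panels of phased plant genome assemblies, built
for the situation hemp and other dioecious-crop breeding programs now
face: dozens of haplotype-resolved assemblies, bi-parental linkage maps,
and bulk segregant experiments that each tell part of the same story.
`panhap` implements four analyses end-to-end, plus synthetic-data
generators with planted ground truth so every stage is testable at desk
scale:

1. **K-mer pangenome index** — canonical k-mer (lexicographic min of a
   k-mer and its reverse complement, default k = 31) presence/absence
   over a panel; unique k-mers (present in exactly one genome); Jaccard
   similarity J(a,b) = |K_a ∩ K_b| / |K_a ∪ K_b| with UPGMA clustering;
   collector's curves; unique-k-mer density in 1 Mb bins.
2. **Aligned runs of homozygosity (AROH)** — from PAF alignments between
   the two haplotypes of a diploid assembly: heal artificially split
   collinear alignments, keep primary alignments with span > 50 kb and
   per-base divergence < 0.01, and summarize the genome fraction covered
   by AROH above a ladder of length thresholds.
3. **Recombination landscape** — F2 marker QC (1:2:1 segregation
   chi-square with df = 2, missingness > 0.35, duplicate collapse),
   family-level MAF, Marey-map LOESS (span 0.25, degree 1, isotonic
   monotonization) and the rate profile
   rate_i = |fit_{i+1} − fit_i| / (p_{i+1} − p_i) · 10⁶ cM/Mb, with
   calling of suppressed regions (≥ 40 Mb below 0.5 cM/Mb).
4. **Bulk segregant analysis** — per-SNP G statistic
   G = 2 Σ o_ij ln(o_ij / e_ij) contrasting allele counts between two
   bulks, 2 Mb sliding-window mean on a 10 kb grid, simulation-based
   99.5%-ile significance thresholds that model both finite-bulk and
   read sampling, projection of peak intervals across reference
   assemblies through PAF chains (inversion-aware), and consensus-peak
   narrowing with diagnostic-SNP selection.

## Worked example

Two toy genomes indexed at k = 3:

```r
library(panhap)
idx <- buildKmerIndex(c(g1 = "ACGTAC", g2 = "ACGTTT"), k = 3)
idx
#> KmerIndex with 4 canonical 3 -mers over 2 genomes
#>   genomes: g1, g2
uniqueKmers(idx, "g1")   # "GTA"
uniqueKmers(idx, "g2")   # "AAA" "AAC"
jaccardMatrix(idx)
#>      g1   g2
#> g1 1.00 0.25
#> g2 0.25 1.00
collectorsCurve(idx)$cumulative
#> [1] 2 4
clusterTree(jaccardMatrix(idx))
#> [1] "(g1:0.375,g2:0.375);"
```

The four distinct canonical 3-mers are AAA, AAC, ACG, GTA; only ACG is
shared, hence J = 1/4, and the collector's curve climbs 2 → 4 as the
second genome is added. The cherry height 0.375 is (1 − J)/2 under
average linkage.

A full synthetic AROH round trip:

```r
sim <- simulateDiploid(c(c1 = 1e6), backgroundDivergence = 0.02,
                       rohSegments = data.frame(chrom = "c1",
                                                start = 2e5, end = 5e5),
                       seed = 7)
ar <- classifyAroh(sim$alignment)   # span > 50 kb, divergence < 0.01
ar
#> GRanges object with 1 range and 2 metadata columns:
#>       seqnames        ranges strand | divergence     n_aln
#>   [1]       c1 200001-500000      * |          0         1
arohCoverage(ar, 1e6, thresholds = 5e4)$proportion
#> [1] 0.3
```

The planted 300 kb identical segment is recovered exactly; the 2%
diverged background is rejected by the divergence cutoff.

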