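---
title: "Methods: pangenome k-mer diagnostics, AROH, recombination landscapes and BSA"
author: "panhap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome k-mer diagnostics, AROH, recombination landscapes and BSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panhap)
```

# Scope

`panhap` packages four analyses that recur in comparative work on panels
of phased plant genome assemblies — most prominently dioecious crops such
as hemp, where breeding programs juggle dozens of haplotype-resolved
assemblies at once:

1. a canonical **k-mer presence/absence pangenome index** with
   unique-k-mer extraction, Jaccard clustering, collector's curves and
   binned unique-k-mer tracks;
2. **aligned runs of homozygosity (AROH)** called from pairwise
   alignments (PAF) between the two haplotypes of one diploid assembly;
3. a **Marey-map recombination landscape**: marker QC, LOESS smoothing of
   genetic-vs-physical position, and an absolute-derivative rate profile
   with suppressed-region calling;
4. **G-statistic bulk segregant analysis (BSA)** with sliding-window
   smoothing, simulation-based significance thresholds, liftover of peak
   intervals across reference assemblies, and consensus-peak narrowing.

Each stage consumes standard plain-text formats (FASTA, PAF, TSV) and can
be exercised end-to-end on synthetic inputs with known planted truth from
the `simulate*()` generators. Assembly, annotation, read alignment,
variant calling and linkage-map construction are out of scope: the
package begins where those published tools end (FASTA, PAF, marker and
SNP tables).

# K-mer pangenome index

Every window of k consecutive bases is replaced by its *canonical* form,
the lexicographic minimum of the window and its reverse complement, so
all set relations are strand-neutral; windows containing a non-ACGT base
are skipped. The index stores, per canonical k-mer, a presence bit-vector
over the panel — presence only, not multiplicity, as appropriate for a
presence/absence pangenome index. The default k = 31 balances specificity
against memory for gigabase plant genomes and is the conventional choice
for pangenome indexing; it is exposed as an argument everywhere.

From the index derive:

* **unique k-mers** (`uniqueKmers`): k-mers whose bit-vector has exactly
  one bit set — haplotype sequence unrepresented elsewhere in the panel;
* **Jaccard similarity** (`jaccardMatrix`),
  \(J(a,b) = |K_a \cap K_b| / |K_a \cup K_b|\), clustered by UPGMA on
  \(1 - J\) (`clusterTree`, Newick output). Any consistent
  canonicalization yields identical set relations, so the choice of
  lexicographic minimum is immaterial to J;
* the **collector's curve** (`collectorsCurve`): cumulative distinct
  k-mers over an ordering of the panel. Its terminal value is
  order-invariant and equals the index size; a plateau indicates the
  panel has saturated the k-mer diversity of the population sampled;
* the **unique-k-mer track** (`uniqueKmerTrack`): the source genome is
  rescanned and every occurrence of a unique k-mer increments the 1 Mb
  bin (default) containing its leftmost base. Localization is by exact
  lookup rather than re-alignment: the k-mers originate from this very
  genome, so exact rescan is lossless, and multi-occurrence k-mers are
  counted at every occurrence.

A practical note from clustering sex-chromosome-bearing panels: shared
sex chromosomes dominate Jaccard similarity and pull haplotypes together
by sex rather than ancestry. The remedy is to restrict the index to
autosomal sequence, which callers do here by passing per-chromosome
sequence lists with the relevant chromosomes dropped.

# Aligned runs of homozygosity

For a phased diploid assembly, a long, low-divergence primary alignment
between the two haplotypes is an alignment-based proxy for a homozygous
segment. The pipeline consumes PAF (12 mandatory columns; the `de:f`
gap-compressed divergence and `tp:A` type tags are honored when present;
secondary alignments are dropped).

Aligners routinely fracture very long near-identical alignments, so
`mergeCollinear` first heals collinear splits: records on the same
query/target pair and strand are chained when both coordinates advance
across gaps of at most `maxGap` (default 100 kb) per side and the two
gap lengths agree within `gapDiffTol` (default 20 kb). The defaults are
generous relative to real aligner break artifacts yet far below the
multi-Mb scale of the alignments being healed; both are arguments, and
`minMergedSpan` optionally restricts healing to long chains. Merging is
applied globally by default because restricting it to chains above a
span cutoff changes nothing for chains that would not merge anyway.
Merged divergence is the alignment-length-weighted mean of member
divergences, ignoring gap bases — conservative, since unaligned gap bases
are not counted as divergent.

`classifyAroh` then keeps records with target span strictly greater than
`minLength` (default 50 kb) and divergence strictly less than
`maxDivergence` (default 0.01) — both bounds strict, matching the
convention that an AROH must *exceed* 50 kb and stay *under* 1%
divergence. Overlapping survivors are resolved by keeping the longer and
trimming the shorter. Coordinates are reported on the target haplotype;
by convention haplotype 1 is the target. `arohCoverage` summarizes the
proportion of the assembly covered by AROH of length at least t for a
ladder of thresholds; it is non-increasing in t by construction.

# Recombination landscape

The module consumes markers that already carry genetic (cM) and physical
(bp) positions — from an external linkage map or from the simulator's
truth — because map construction, marker ordering and double-crossover
pruning are published algorithms in their own right and are not
re-implemented here.

**Marker QC** (`filterMarkers`) applies three filters: a 1:2:1
goodness-of-fit chi-square (df = 2) against the Mendelian F2 expectation
with a per-family p-value threshold (default 1e-5; heavily distorted
families warrant far stricter thresholds such as 1e-17, both standard
choices for array-genotyped F2 families of a few hundred plants);
a missing-fraction cutoff (default 0.35); and collapse of markers whose
genotype vectors are identical (complete linkage disequilibrium) to one
representative. Family-level MAF is \((2 n_{AA} + n_{AB}) / 2n\) folded
to the minor allele; long runs of MAF ≈ 0 flag monomorphic regions that
no linkage map can cover.

**Marey map** (`mareyFit`): genetic position is regressed on physical
position by LOESS with span 0.25 (fraction-of-markers bandwidth, so the
physical scale — bp vs Mb — is immaterial) and local degree 1 (tricube
weights; degree is an argument). A Marey map is physically
non-decreasing, but a raw local fit can wiggle, and taking the absolute
derivative would fold each wiggle into spurious positive recombination;
the fitted sequence is therefore projected onto the nearest
non-decreasing sequence by isotonic regression before differentiation.
`monotone = FALSE` reproduces the raw-derivative computation exactly.
Markers sharing a physical position are collapsed to their mean genetic
position first.

**Rate profile** (`recombinationRate`):
\(\mathrm{rate}_i = |f_{i+1} - f_i| / (p_{i+1} - p_i) \times 10^6\)
cM/Mb, attached to the inter-marker midpoint, since a two-point
difference estimates the rate between markers, not at either one. On a
monotonized fit the rate integral telescopes to the fitted map length, a
conservation identity the tests verify to well under 1%.
`suppressedRegions` reports maximal runs of midpoints below a rate
threshold (default 0.5 cM/Mb) spanning at least `minSpan` (default
40 Mb) — the signature of pericentromeric crossover suppression in large
plant chromosomes.

# Bulk segregant analysis

Per SNP, `gStatistic` computes the 2×2 log-likelihood-ratio statistic
\(G = 2\sum o_{ij} \ln(o_{ij}/e_{ij})\) contrasting allele counts
between two bulks; zero cells contribute zero, and a zero row or column
total (no reads, or a monomorphic site) yields G = 0. SNPs are
pre-filtered to a minimum depth of 10 reads in each bulk (inclusive).
`smoothG` takes the unweighted moving average over SNPs within a window
(default 2 Mb wide) centered on a 10 kb grid.

**Allele coding.** Bulk counts are reported for the segregating
(F1-derived) allele. Under this coding an unselected bulk sits at
frequency 0.5 at every SNP, and a bulk selected for the causal allele
sits at \(1 - r\) at recombination fraction r from the locus — which is
what makes the closed-form checks in the tests possible. The null
frequencies used for thresholds default to 0.5/0.5 accordingly and are
overridable for data coded on the total-allele convention (where a
backcross population sits at 0.75/0.25).

**Significance** (`nullThreshold`): each simulation redraws every SNP
under no linkage, preserving observed depths, and the per-window
threshold is the 99.5th percentile (default) of the simulated smoothed
G. The null mirrors both sampling stages of a real bulk: bulk allele
frequency drawn from the finite pool of informative gametes
(`nPlants` per bulk; twice that for an F2 design), then read counts
binomial at that frequency. Skipping the bulk-composition stage
(`nPlants = NULL`) under-disperses the null noticeably — with 50-plant
bulks at depth 40 the bulk stage contributes comparably to the read
stage — and makes the threshold anti-conservative, so supplying
`nPlants` is strongly recommended whenever bulks are finite.

**Consensus across references** (`projectInterval`,
`consensusInterval`): significant intervals called against different
reference assemblies are projected through pairwise alignment chains
(linear interpolation within blocks; minus-strand blocks reverse
orientation, so a peak inside an inversion lands where the inversion
places it) onto a user-chosen anchor reference, and intersected. An
empty intersection falls back to the region covered by the most
projections (majority rule), with per-reference support and unmappable
references reported. Anchoring on one reference keeps all coordinates
well-defined without a graph model. `selectDiagnosticSnps` then ranks
SNPs in the consensus interval by depth among those matching the
design's expected bulk frequencies within a tolerance.

# Synthetic data with planted truth

Every generator returns a `truth` element (serializable with
`writeTruthSet` as BED/TSV plus a YAML sidecar) so downstream recovery
is testable without external data.

* `simulateDiploid` plants identical segments on a background of i.i.d.
  substitutions between two haplotypes. Divergence is substitution-only
  (no indels), so the true alignment between haplotypes is the identity
  and is returned exactly, one PAF record per planted/background segment
  with realized divergence. This gives AROH recovery tests an exact
  oracle; healing of aligner splits is exercised separately on
  constructed records.
* `simulatePanel` concatenates blocks drawn from a shared pool with
  genome-private blocks mixed in at a set rate — the planted source of
  unique k-mers.
* `simulateF2` draws, per gamete, a Poisson(map length / 100) number of
  crossovers with positions i.i.d. from a chosen density ("uniform",
  "periphery" ∝ (2x−1)², or a custom table). No crossover interference
  is modeled: the sources being emulated state none, and independent
  positions are the simplest defensible null. Segregation distortion is
  applied as viability selection after gamete union — agnostic among
  mechanisms (e.g. a recessive lethal) — and monomorphic regions and
  missingness are overlaid afterwards.
* `simulateBulks` emulates a backcross (default) or F2 BSA: the
  selected bulk's informative gametes are non-recombinant with
  probability 1 − r at distance d (r = rate·d, capped at 0.5), the
  unselected bulk is Mendelian, and counts pass through both
  finite-bulk and Poisson-depth/binomial-read sampling. The default
  design is a backcross because that is the standard design for a
  dominant early-flowering locus.

What the generators deliberately do *not* emulate: sequencing error,
read-level artifacts, indels and structural variation (beyond planted
identity segments and minus-strand alignment blocks supplied in PAF),
crossover interference, and linkage disequilibrium between the plants of
a bulk across SNPs (each SNP's bulk composition is drawn independently).
Passing tests therefore demonstrate correctness of the statistics and
interval algebra under the stated sampling models, not robustness to
aligner or caller artifacts on real reads.

# Numerical choices and problem sizes

* String comparison for canonicalization uses the fixed A<C<G<T byte
  order; ties cannot occur between a k-mer and its reverse complement
  unless they are equal (palindromes), which canonicalize to themselves.
* UPGMA ties are broken deterministically by input order via
  `stats::hclust`.
* LOESS uses the exact ("direct") surface so fitted values at marker
  positions are reproducible to machine precision; isotonic projection
  uses `stats::isoreg` (least-squares monotone fit).
* Per-window thresholds use the type-7 empirical quantile; with
  `nSim = 1000` the 99.5th percentile carries a finite-simulation
  exceedance allowance of order 1/nSim, visible in calibration tests.
* Zero-gap marker pairs are skipped (with a message) in rate profiles;
  zero-depth SNPs yield G = 0 rather than NaN; empty windows are NA and
  never significant.
* Test and validation problem sizes were chosen so each stage's
  statistical target is measurable while the whole suite stays
  desk-scale: 10 Mb diploid chromosomes with five planted ROH of
  0.1–2 Mb; 500 markers × 300 F2 individuals for landscape recovery;
  20 Mb BSA chromosomes with 20,000 SNPs (≈ 1 SNP / kb, a typical
  whole-genome-sequencing marker density in a heterozygous cross) and
  50-plant bulks at depth
  40; 200 replicate null data sets for threshold calibration. These are
  the package's reference conditions; all are arguments.

# Known limitations

* The k-mer index is in-memory and suited to panels up to tens of Mb
  per genome at full resolution; disk-backed indexing of gigabase
  panels is out of scope.
* AROH coordinates anchor on one haplotype; reciprocal analysis
  requires swapping query and target.
* The rate profile inherits LOESS edge bias in the outermost span/2 of
  each chromosome; suppressed-region calls there deserve skepticism.
* Cross-assembly genotyping of diagnostic SNPs (validating a panel
  against many assemblies) is not implemented; `selectDiagnosticSnps`
  implements the depth/frequency criteria only.
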