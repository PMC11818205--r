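# Synthetic inputs with known ground truth for every pipeline stage:
# diploid haplotype pairs with planted identical segments, panels of
# genomes sharing blocks from a pool, F2 genotype matrices under a chosen
# crossover-density landscape, and BSA bulk allele counts around a planted
# causal locus. Each simulator returns a `truth` element recording the
# planted parameters for recovery testing.

BASES <- c("A", "C", "G", "T")

#' Substitute bases of a sequence at a fixed per-bp rate
#'
#' Each A/C/G/T position is substituted independently with probability
#' `rate` by a base drawn uniformly from the three alternatives. N bases
#' are left untouched; any other character is rejected. Length is
#' preserved; deterministic given the seed.
#'
#' @param seq nucleotide string (A/C/G/T/N, case-insensitive).
#' @param rate substitution probability per bp, in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return the mutated sequence (upper case).
#' @export
mutateSeq <- function(seq, rate, seed = NULL) {
  stopifnot(length(seq) == 1L, rate >= 0, rate <= 1)
  s <- charToRaw(toupper(seq))
  baseRaw <- charToRaw("ACGT")
  if (!all(as.integer(s) %in% as.integer(charToRaw("ACGTN"))))
    stop("sequence contains a base other than ACGTN")
  if (rate == 0) return(rawToChar(s))
  withSeed(seed, {
    idx <- match(as.integer(s), as.integer(baseRaw))  # NA for N
    hit <- which(!is.na(idx) & runif(length(s)) < rate)
    if (length(hit)) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      newidx <- (idx[hit] - 1L + shift) %% 4L + 1L  # uniform over the others
      s[hit] <- baseRaw[newidx]
    }
    rawToChar(s)
  })
}

# Count of mismatching positions between two equal-length sequences,
# cumulative from the left (for per-segment divergence bookkeeping).
mismatchCumsum <- function(a, b) {
  cumsum(charToRaw(a) != charToRaw(b))
}

#' Simulate a diploid genome: two haplotypes with planted identical runs
#'
#' Haplotype 2 equals haplotype 1 with i.i.d. substitutions at
#' `backgroundDivergence` per bp outside the planted `rohSegments` and
#' zero substitutions inside them, emulating the homozygous tracts that a
#' pairwise alignment of the two haplotypes of a phased assembly reveals
#' as aligned runs of homozygosity. No indels are introduced, so the truth
#' alignment between haplotypes is the identity and is returned exactly.
#'
#' @param chromLengths named numeric vector, chromosome name -> length bp.
#' @param backgroundDivergence substitutions per bp between haplotypes
#'   outside ROH, in `[0, 0.2]`.
#' @param rohSegments NULL or data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open bp); segments must be non-overlapping and
#'   within their chromosome.
#' @param seed RNG seed.
#' @return list with elements `hap1`, `hap2` (named character vectors of
#'   chromosome sequences), `alignment` (truth alignment as a PAF-layout
#'   data.frame, one record per planted/background segment, with realized
#'   `de` divergence), and `truth` (list: `roh` data.frame, `config`).
#' @export
simulateDiploid <- function(chromLengths, backgroundDivergence = 0.01,
                            rohSegments = NULL, seed = NULL) {
  stopifnot(backgroundDivergence >= 0, backgroundDivergence <= 0.2,
            !is.null(names(chromLengths)), all(chromLengths >= 1))
  if (is.null(rohSegments))
    rohSegments <- data.frame(chrom = character(), start = numeric(),
                              end = numeric())
  stopifnot(all(c("chrom", "start", "end") %in% names(rohSegments)))
  for (ch in unique(rohSegments$chrom)) {
    if (!ch %in% names(chromLengths)) stop("ROH on unknown chromosome ", ch)
    seg <- rohSegments[rohSegments$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (any(seg$start < 0) || any(seg$end > chromLengths[[ch]]) ||
        any(seg$end <= seg$start))
      stop("ROH segment outside [0, length) on ", ch)
    if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)]))
      stop("overlapping ROH segments on ", ch)
  }
  withSeed(seed, {
    hap1 <- vapply(chromLengths, randomSequence, character(1))
    hap2 <- character(length(hap1)); names(hap2) <- names(hap1)
    aln <- list()
    for (ch in names(chromLengths)) {
      L <- chromLengths[[ch]]
      mut <- mutateSeq(hap1[[ch]], backgroundDivergence)
      seg <- rohSegments[rohSegments$chrom == ch, , drop = FALSE]
      seg <- seg[order(seg$start), , drop = FALSE]
      # restore identity inside planted ROH
      if (nrow(seg)) {
        m <- charToRaw(mut); h <- charToRaw(hap1[[ch]])
        for (i in seq_len(nrow(seg)))
          m[(seg$start[i] + 1):seg$end[i]] <- h[(seg$start[i] + 1):seg$end[i]]
        mut <- rawToChar(m)
      }
      hap2[[ch]] <- mut
      # truth alignment: one record per alternating background/ROH segment
      bks <- sort(unique(c(0, seg$start, seg$end, L)))
      cs <- mismatchCumsum(hap1[[ch]], mut)
      for (i in seq_len(length(bks) - 1L)) {
        s0 <- bks[i]; e0 <- bks[i + 1L]
        mm <- cs[e0] - if (s0 > 0) cs[s0] else 0
        aln[[length(aln) + 1L]] <- data.frame(
          qname = ch, qlen = L, qstart = s0, qend = e0, strand = "+",
          tname = ch, tlen = L, tstart = s0, tend = e0,
          nmatch = e0 - s0 - mm, alen = e0 - s0, mapq = 60,
          de = mm / (e0 - s0), tp = "P")
      }
    }
    list(hap1 = hap1, hap2 = hap2,
         alignment = do.call(rbind, aln),
         truth = list(roh = rohSegments,
                      config = list(chrom_lengths = as.list(chromLengths),
                                    background_divergence = backgroundDivergence,
                                    seed = seed)))
  })
}

#' Simulate a panel of genomes sharing haplotype blocks from a pool
#'
#' Each genome is a concatenation of `nBlocks` blocks of `blockLength` bp.
#' Each block slot is filled either by a block drawn (with replacement)
#' from a shared pool of `poolSize` blocks, or, with probability
#' `privateRate`, by a freshly generated genome-private block. Private
#' blocks are the planted source of unique k-mers downstream.
#'
#' @param nGenomes number of genomes.
#' @param blockLength block length in bp.
#' @param poolSize number of blocks in the shared pool.
#' @param privateRate probability that a block slot is genome-private.
#' @param nBlocks blocks per genome (default `poolSize`).
#' @param seed RNG seed.
#' @return list with `genomes` (named character vector g1..gN) and `truth`
#'   (data.frame: genome, slot, source "pool"/"private", pool_id,
#'   start/end bp of the block in its genome; plus `config`).
#' @export
simulatePanel <- function(nGenomes, blockLength, poolSize, privateRate,
                          nBlocks = poolSize, seed = NULL) {
  stopifnot(nGenomes >= 1, blockLength >= 1, poolSize >= 0,
            privateRate >= 0, privateRate <= 1, nBlocks >= 1)
  if (poolSize == 0 && privateRate < 1)
    stop("poolSize = 0 requires privateRate = 1")
  withSeed(seed, {
    pool <- if (poolSize > 0)
      vapply(seq_len(poolSize), function(i) randomSequence(blockLength),
             character(1)) else character(0)
    names <- paste0("g", seq_len(nGenomes))
    rows <- list(); genomes <- character(nGenomes)
    for (g in seq_len(nGenomes)) {
      src <- runif(nBlocks) < privateRate
      poolId <- ifelse(src, NA_integer_,
                       if (poolSize > 0) sample.int(poolSize, nBlocks,
                                                    replace = TRUE) else NA)
      blocks <- character(nBlocks)
      for (b in seq_len(nBlocks))
        blocks[b] <- if (src[b]) randomSequence(blockLength)
                     else pool[[poolId[b]]]
      genomes[g] <- paste(blocks, collapse = "")
      rows[[g]] <- data.frame(
        genome = names[g], slot = seq_len(nBlocks),
        source = ifelse(src, "private", "pool"), pool_id = poolId,
        start = (seq_len(nBlocks) - 1) * blockLength,
        end = seq_len(nBlocks) * blockLength)
    }
    names(genomes) <- names
    list(genomes = genomes,
         truth = list(blocks = do.call(rbind, rows),
                      config = list(n_genomes = nGenomes,
                                    block_length = blockLength,
                                    pool_size = poolSize,
                                    private_rate = privateRate,
                                    n_blocks = nBlocks, seed = seed)))
  })
}

# Inverse-CDF samplers and CDFs for crossover-position densities on [0,1].
# "periphery" is proportional to (2x-1)^2, the U-shape of chromosomes
# whose crossovers concentrate near the telomeres.
densitySpec <- function(density) {
  if (is.character(density) && length(density) == 1L) {
    switch(density,
      uniform = list(
        sample = function(n) runif(n),
        cdf = function(x) x,
        pdf = function(x) rep(1, length(x))),
      periphery = list(
        sample = function(n) {
          u <- 2 * runif(n) - 1
          (sign(u) * abs(u)^(1 / 3) + 1) / 2
        },
        cdf = function(x) (1 + (2 * x - 1)^3) / 2,
        pdf = function(x) 3 * (2 * x - 1)^2),
      stop("unknown density preset: ", density))
  } else if (is.data.frame(density)) {
    stopifnot(all(c("x", "density") %in% names(density)))
    x0 <- density$x; d0 <- density$density
    if (any(!is.finite(d0)) || any(d0 < 0) || sum(d0) == 0)
      stop("density table is not normalizable")
    o <- order(x0)
    # refine onto a fine grid so inverse-CDF sampling respects the
    # within-segment shape of the table, then trapezoid CDF
    x <- seq(min(x0), max(x0), length.out = 1024L)
    d <- stats::approx(x0[o], d0[o], x)$y
    cdf <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 * diff(x)))
    if (max(cdf) == 0) stop("density table is not normalizable")
    pdf0 <- d / max(cdf)
    cdf <- cdf / max(cdf)
    list(
      sample = function(n) stats::approx(cdf, x, runif(n), ties = min)$y,
      cdf = function(q) stats::approx(x, cdf, q, rule = 2)$y,
      pdf = function(q) stats::approx(x, pdf0, q, rule = 2)$y)
  } else stop("density must be a preset name or a data.frame(x, density)")
}

#' Simulate an F2 marker genotype matrix under a crossover landscape
#'
#' Gametes receive a Poisson(`mapLength`/100) number of crossovers with
#' positions drawn i.i.d. from `crossoverDensity` (no interference).
#' Genotypes are coded AA/AB/BB with the A allele contributed by parent 1.
#' An optional distortion locus applies viability selection against one
#' homozygote after gamete union; markers inside an optional monomorphic
#' region are emitted with a single genotype; entries are set missing at
#' `missingRate`.
#'
#' @param mapLength genetic map length in cM (single chromosome, or named
#'   vector per chromosome).
#' @param nMarkers markers per chromosome (recycled).
#' @param nIndividuals number of F2 individuals (>= 2).
#' @param chromLength physical chromosome length bp (recycled; default
#'   100 Mb).
#' @param crossoverDensity "uniform", "periphery" (proportional to
#'   `(2x-1)^2`), or a data.frame(x, density) over relative position.
#' @param distortionLocus NULL or list(chrom, pos (relative, in `[0,1]`),
#'   s (selection coefficient in `[0,1]` against one homozygote),
#'   against ("AA" or "BB")).
#' @param monomorphicRegion NULL or list(chrom, start, end) in relative
#'   coordinates; markers inside are monomorphic.
#' @param missingRate per-entry missing probability, in `[0, 1)`.
#' @param seed RNG seed.
#' @return list with `markers` (data.frame: marker, chrom, pos_bp,
#'   cM_true), `geno` (character matrix markers x individuals with values
#'   AA/AB/BB or NA), and `truth` (crossover positions per chromosome,
#'   density table, config).
#' @export
simulateF2 <- function(mapLength, nMarkers, nIndividuals,
                       chromLength = 1e8, crossoverDensity = "uniform",
                       distortionLocus = NULL, monomorphicRegion = NULL,
                       missingRate = 0, seed = NULL) {
  stopifnot(nIndividuals >= 2, missingRate >= 0, missingRate < 1)
  if (is.null(names(mapLength)))
    names(mapLength) <- paste0("chr", seq_along(mapLength))
  chroms <- names(mapLength)
  nMarkers <- rep(nMarkers, length.out = length(chroms))
  chromLength <- rep(chromLength, length.out = length(chroms))
  dens <- densitySpec(crossoverDensity)
  withSeed(seed, {
    markers <- list(); genos <- list(); cxlog <- list()
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]; L <- mapLength[[ci]]; nm <- nMarkers[ci]
      mx <- sort(runif(nm))  # relative marker positions
      distHere <- !is.null(distortionLocus) && distortionLocus$chrom == ch
      qx <- if (distHere) c(mx, distortionLocus$pos) else mx
      cxlist <- list(); cxn <- 0L
      gameteAllele <- function() {
        ncx <- rpois(1L, L / 100)
        start <- sample(0:1, 1L)
        if (ncx == 0L) return(rep(start, length(qx)))
        cx <- sort(dens$sample(ncx))
        cxn <<- cxn + 1L
        cxlist[[cxn]] <<- cx
        (start + findInterval(qx, cx)) %% 2L
      }
      gm <- matrix(NA_integer_, nrow = length(qx), ncol = nIndividuals)
      filled <- 0L; tries <- 0L
      while (filled < nIndividuals) {
        tries <- tries + 1L
        if (tries > 50L * nIndividuals)
          stop("viability selection too strong to fill the family")
        g <- gameteAllele() + gameteAllele()  # copies of the B allele
        if (distHere) {
          gd <- g[length(qx)]
          against <- if (distortionLocus$against == "AA") 0L else 2L
          if (gd == against && runif(1) < distortionLocus$s) next
        }
        filled <- filled + 1L
        gm[, filled] <- g
      }
      gm <- gm[seq_len(nm), , drop = FALSE]
      gchar <- matrix(c("AA", "AB", "BB")[gm + 1L], nrow = nm)
      if (!is.null(monomorphicRegion) && monomorphicRegion$chrom == ch) {
        inreg <- mx >= monomorphicRegion$start & mx <= monomorphicRegion$end
        gchar[inreg, ] <- "AA"
      }
      if (missingRate > 0)
        gchar[matrix(runif(length(gchar)) < missingRate,
                     nrow = nrow(gchar))] <- NA_character_
      cxlog[[ch]] <- unlist(cxlist)
      rownames(gchar) <- paste0(ch, "_m", seq_len(nm))
      markers[[ch]] <- data.frame(
        marker = rownames(gchar), chrom = ch,
        pos_bp = round(mx * chromLength[ci]),
        cM_true = L * dens$cdf(mx))
      genos[[ch]] <- gchar
    }
    geno <- do.call(rbind, genos)
    colnames(geno) <- paste0("ind", seq_len(nIndividuals))
    dgrid <- seq(0, 1, length.out = 201)
    list(markers = do.call(rbind, c(markers, make.row.names = FALSE)),
         geno = geno,
         truth = list(
           crossovers = cxlog,
           density = data.frame(x = dgrid, density = dens$pdf(dgrid)),
           config = list(map_length_cM = as.list(mapLength),
                         n_markers = as.list(setNames(as.list(nMarkers), chroms)),
                         n_individuals = nIndividuals,
                         crossover_density = if (is.character(crossoverDensity))
                           crossoverDensity else "custom table",
                         distortion = distortionLocus,
                         monomorphic_region = monomorphicRegion,
                         missing_rate = missingRate, seed = seed)))
  })
}

#' Simulate BSA bulk allele counts around a planted causal locus
#'
#' The selected bulk is composed of plants that all carry the selected
#' parental allele at `causalPos`; at a SNP at distance d bp the
#' informative gamete is non-recombinant with probability 1 - r, with
#' r = min(0.5, `recombRate` * d / 1e6 / 100). Counts are reported for the
#' segregating (F1-derived) allele: the unselected bulk sits at its
#' Mendelian expectation of 0.5 at every SNP. Read depths are
#' Poisson(`meanDepth`) and allele counts binomial at the plant-derived
#' bulk frequency, so both finite-bulk and finite-depth sampling noise are
#' present. With `causalPos = NULL` both bulks are at 0.5 everywhere (null
#' data).
#'
#' @param chromLength chromosome length bp.
#' @param nSnps number of SNPs (positions uniform on the chromosome).
#' @param causalPos causal locus position bp in `[0, chromLength)`, or
#'   NULL for null data.
#' @param design "backcross" (one informative meiosis per plant) or "f2"
#'   (two; the selected bulk is the homozygous class).
#' @param nPlants plants per bulk.
#' @param meanDepth mean sequencing depth per SNP per bulk.
#' @param recombRate recombination rate in cM/Mb (uniform).
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return list with `snps` (data.frame: chrom, pos, bulk1_ref, bulk1_alt,
#'   bulk2_ref, bulk2_alt; bulk1 is the selected bulk and `alt` counts the
#'   selected allele) and `truth` (causal_pos, config).
#' @export
simulateBulks <- function(chromLength, nSnps, causalPos, design = "backcross",
                          nPlants = 50, meanDepth = 40, recombRate = 1,
                          chrom = "chr1", seed = NULL) {
  stopifnot(nPlants >= 1, meanDepth > 0, nSnps >= 1,
            design %in% c("backcross", "f2"))
  if (!is.null(causalPos))
    stopifnot(causalPos >= 0, causalPos < chromLength)
  withSeed(seed, {
    pos <- sort(round(runif(nSnps, 1, chromLength)))
    if (is.null(causalPos)) {
      fsel <- rep(0.5, nSnps)
      r <- rep(NA_real_, nSnps)
    } else {
      d <- abs(pos - causalPos)
      r <- pmin(0.5, recombRate * d / 1e6 / 100)
      fsel <- 1 - r
    }
    nGam <- if (design == "f2") 2L * nPlants else nPlants
    freq1 <- rbinom(nSnps, nGam, fsel) / nGam       # selected bulk
    freq2 <- rbinom(nSnps, nGam, 0.5) / nGam        # unselected bulk
    dp1 <- rpois(nSnps, meanDepth); dp2 <- rpois(nSnps, meanDepth)
    alt1 <- rbinom(nSnps, dp1, freq1)
    alt2 <- rbinom(nSnps, dp2, freq2)
    list(snps = data.frame(chrom = chrom, pos = pos,
                           bulk1_ref = dp1 - alt1, bulk1_alt = alt1,
                           bulk2_ref = dp2 - alt2, bulk2_alt = alt2),
         truth = list(causal_pos = causalPos,
                      config = list(chrom_length = chromLength,
                                    n_snps = nSnps, design = design,
                                    n_plants = nPlants,
                                    mean_depth = meanDepth,
                                    recomb_rate = recombRate, seed = seed)))
  })
}
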