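# G-statistic bulk segregant analysis: per-SNP 2x2 log-likelihood-ratio
# statistic contrasting allele counts between two bulks, sliding-window
# smoothing, simulation-based significance thresholds, liftover of
# significant intervals across reference assemblies, and consensus-peak
# narrowing.

#' G statistic of a 2x2 bulk-by-allele table
#'
#' G = 2 * sum o_ij ln(o_ij / e_ij), with expected counts e_ij from the
#' row/column totals under independence. Cells with o_ij = 0 contribute 0.
#' A table with a zero row or column total carries no information and is
#' assigned G = 0. Vectorized over SNPs.
#'
#' @param n1ref,n1alt ref/alt read counts in bulk 1.
#' @param n2ref,n2alt ref/alt read counts in bulk 2.
#' @return numeric vector of G statistics (>= 0).
#' @examples
#' gStatistic(10, 10, 10, 10)  # 0
#' gStatistic(20, 0, 0, 20)    # 80 * log(2)
#' @export
gStatistic <- function(n1ref, n1alt, n2ref, n2alt) {
  o <- cbind(n1ref, n1alt, n2ref, n2alt)
  stopifnot(all(o >= 0))
  r1 <- n1ref + n1alt; r2 <- n2ref + n2alt
  c1 <- n1ref + n2ref; c2 <- n1alt + n2alt
  tot <- r1 + r2
  e <- cbind(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / tot
  term <- o * log(o / e)
  term[o == 0] <- 0
  g <- 2 * rowSums(term)
  g[r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0 | tot == 0] <- 0
  unname(pmax(g, 0))
}

#' Add per-SNP G statistics to a bulk allele-count table
#'
#' @param snps data.frame with columns `bulk1_ref`, `bulk1_alt`,
#'   `bulk2_ref`, `bulk2_alt` (e.g. from [simulateBulks()] or
#'   [readSnpTable()]).
#' @return `snps` with an added numeric `g` column.
#' @export
addG <- function(snps) {
  snps$g <- gStatistic(snps$bulk1_ref, snps$bulk1_alt,
                       snps$bulk2_ref, snps$bulk2_alt)
  snps
}

#' Filter SNPs on minimum depth in both bulks
#'
#' Retains SNPs with read depth at least `minDepth` in each bulk
#' (inclusive bound).
#'
#' @param snps bulk allele-count data.frame.
#' @param minDepth minimum per-bulk depth, default 10.
#' @return the filtered data.frame.
#' @export
filterSnps <- function(snps, minDepth = 10) {
  if (!nrow(snps)) return(snps)
  d1 <- snps$bulk1_ref + snps$bulk1_alt
  d2 <- snps$bulk2_ref + snps$bulk2_alt
  snps[d1 >= minDepth & d2 >= minDepth, , drop = FALSE]
}

# Regular grid of window centers covering the SNP positions.
windowGrid <- function(pos, step) {
  lo <- floor(min(pos) / step) * step
  hi <- ceiling(max(pos) / step) * step
  seq(lo, hi, by = step)
}

# Per-window mean of `values` over SNPs within halfWidth of each center.
# pos must be sorted. Returns NA for empty windows. Works on a matrix of
# values (one column per replicate) via cumulative sums.
windowMeans <- function(pos, values, centers, halfWidth) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  lo <- findInterval(centers - halfWidth, pos, left.open = TRUE)   # pos >  c-hw  starts at lo+1
  hi <- findInterval(centers + halfWidth, pos)                     # pos <= c+hw  ends at hi
  nIn <- hi - lo
  cs <- rbind(0, apply(values, 2, cumsum))
  sums <- cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  out <- sums / nIn
  out[nIn == 0L, ] <- NA_real_
  out
}

#' Sliding-window moving average of per-SNP G statistics
#'
#' At each center on a regular grid of spacing `step`, the smoothed G is
#' the unweighted mean of G over SNPs within `windowWidth / 2` of the
#' center; windows holding no SNP are emitted as NA.
#'
#' @param snps bulk allele-count data.frame with `chrom` and `pos`; a `g`
#'   column is computed via [addG()] if absent.
#' @param windowWidth full window width bp (default 2 Mb).
#' @param step grid spacing bp (default 10 kb).
#' @return a [GProfile-class].
#' @export
smoothG <- function(snps, windowWidth = 2e6, step = 1e4) {
  stopifnot(nrow(snps) > 0)
  if (length(unique(snps$chrom)) != 1L)
    stop("smoothG expects SNPs of a single chromosome")
  if (!"g" %in% names(snps)) snps <- addG(snps)
  o <- order(snps$pos); snps <- snps[o, , drop = FALSE]
  centers <- windowGrid(snps$pos, step)
  g <- windowMeans(snps$pos, snps$g, centers, windowWidth / 2)[, 1]
  new("GProfile", chrom = as.character(snps$chrom[1]), centers = centers,
      halfWidth = windowWidth / 2, step = step, g = g,
      threshold = numeric(0))
}

#' Simulation-based per-window significance threshold for smoothed G
#'
#' For each of `nSim` simulations, every SNP's allele counts are redrawn
#' under the null of no trait-allele linkage while preserving the observed
#' per-bulk depths; the smoothed-G profile is recomputed, and the
#' per-window threshold is the `percentile` quantile of the simulated
#' smoothed-G values for that window. The null model mirrors the two
#' sampling stages of a real bulk: when `nPlants` is given, each SNP's
#' bulk allele frequency is first drawn from the finite pool of
#' informative gametes (binomial over `nPlants` gametes per bulk, or twice
#' that for an F2 design) at the null frequency, and read counts are then
#' binomial at that bulk frequency. Omitting `nPlants` collapses the first
#' stage and draws read counts directly at the null frequencies, which
#' under-disperses the null and is anti-conservative whenever the
#' observed data come from finite bulks. Null frequencies default to 0.5
#' in both bulks, the expectation for the segregating-allele coding in
#' which bulk counts are reported here (an unlinked locus shows the
#' F1-derived allele in half the informative gametes of either bulk).
#'
#' @param snps bulk allele-count data.frame (single chromosome).
#' @param profile the observed [GProfile-class] from [smoothG()] (supplies
#'   the grid and window geometry).
#' @param nSim number of null simulations (default 1000; < 100 warns).
#' @param percentile threshold percentile in (0, 100], default 99.5.
#' @param design "backcross" (one informative gamete per plant) or "f2"
#'   (two).
#' @param nullFreqs length-2 numeric, null segregating-allele frequency in
#'   bulk 1 and bulk 2 (default c(0.5, 0.5)).
#' @param nPlants plants per bulk in the null's bulk-composition stage;
#'   NULL skips that stage.
#' @param seed RNG seed for the null simulations.
#' @return the profile with its per-window `threshold` slot filled.
#' @export
nullThreshold <- function(snps, profile, nSim = 1000, percentile = 99.5,
                          design = c("backcross", "f2"), nullFreqs = c(0.5, 0.5),
                          nPlants = NULL, seed = NULL) {
  design <- match.arg(design)
  stopifnot(is(profile, "GProfile"), length(nullFreqs) == 2,
            percentile > 0, percentile <= 100)
  if (nSim < 100) warning("nSim < 100 gives an unstable threshold")
  o <- order(snps$pos); snps <- snps[o, , drop = FALSE]
  dp1 <- snps$bulk1_ref + snps$bulk1_alt
  dp2 <- snps$bulk2_ref + snps$bulk2_alt
  n <- nrow(snps)
  gm <- withSeed(seed, {
    f1 <- nullFreqs[1]; f2 <- nullFreqs[2]
    if (!is.null(nPlants)) {
      nGam <- if (design == "f2") 2L * nPlants else nPlants
      f1 <- rbinom(n * nSim, nGam, f1) / nGam
      f2 <- rbinom(n * nSim, nGam, f2) / nGam
    }
    a1 <- matrix(rbinom(n * nSim, dp1, f1), nrow = n)
    a2 <- matrix(rbinom(n * nSim, dp2, f2), nrow = n)
    matrix(gStatistic(as.vector(dp1 - a1), as.vector(a1),
                      as.vector(dp2 - a2), as.vector(a2)), nrow = n)
  })
  sim <- windowMeans(snps$pos, gm, profile@centers, profile@halfWidth)
  thr <- apply(sim, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else
      unname(quantile(x, percentile / 100, type = 7))
  })
  methods::initialize(profile, threshold = as.numeric(thr))
}

#' Significant intervals of a smoothed G profile
#'
#' Maximal runs of consecutive windows with smoothed G above the
#' per-window threshold; runs separated by a single grid step (one
#' sub-threshold or empty window) are merged.
#'
#' @param profile a [GProfile-class] with thresholds (see
#'   [nullThreshold()]).
#' @param reference optional reference-assembly label carried into the
#'   output.
#' @return data.frame with columns `reference`, `chrom`, `start`, `end`
#'   (bp, outermost significant window centers), `max_g`.
#' @export
significantIntervals <- function(profile, reference = NA_character_) {
  stopifnot(is(profile, "GProfile"))
  thr <- gThreshold(profile)
  if (is.null(thr)) stop("profile has no threshold; run nullThreshold()")
  sig <- which(!is.na(profile@g) & !is.na(thr) & profile@g > thr)
  if (!length(sig))
    return(data.frame(reference = character(), chrom = character(),
                      start = numeric(), end = numeric(), max_g = numeric()))
  grp <- cumsum(c(1, diff(sig) > 2))  # allow one-window gaps
  out <- lapply(split(sig, grp), function(idx) {
    data.frame(reference = reference, chrom = profile@chrom,
               start = profile@centers[min(idx)],
               end = profile@centers[max(idx)],
               max_g = max(profile@g[idx]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Project an interval through a pairwise alignment chain
#'
#' Maps a half-open interval `[start, end)` from one assembly to another
#' through the overlapping alignment blocks of a PAF chain, by linear
#' interpolation within each block; minus-strand blocks reverse
#' orientation. The result is the minimal interval on the destination
#' covering all projected pieces. Projection through an identity chain is
#' exactly invertible, and through an inversion block projecting twice
#' returns the original interval.
#'
#' @param start,end interval on the source assembly (0-based half-open bp).
#' @param chain PAF data.frame ([readPaf()] layout) aligning query to
#'   target.
#' @param from "query" to project query -> target, "target" for the
#'   reverse.
#' @return list with `start`, `end` (projected interval), `n_blocks`
#'   (overlapping blocks used) and `unmapped_bp` (source bp of the
#'   interval not covered by any block), or NULL when the interval
#'   overlaps no block (unmappable).
#' @export
projectInterval <- function(start, end, chain, from = c("query", "target")) {
  from <- match.arg(from)
  stopifnot(end > start)
  if (from == "query") {
    s0 <- chain$qstart; e0 <- chain$qend
    s1 <- chain$tstart; e1 <- chain$tend
  } else {
    s0 <- chain$tstart; e0 <- chain$tend
    s1 <- chain$qstart; e1 <- chain$qend
  }
  pieces <- list(); covered <- 0
  for (i in seq_len(nrow(chain))) {
    a <- max(start, s0[i]); b <- min(end, e0[i])
    if (b <= a) next
    covered <- covered + (b - a)
    if (chain$strand[i] == "+") {
      p <- c(s1[i] + (a - s0[i]), s1[i] + (b - s0[i]))
    } else {
      p <- c(s1[i] + (e0[i] - b), s1[i] + (e0[i] - a))
    }
    pieces[[length(pieces) + 1L]] <- p
  }
  if (!length(pieces)) return(NULL)
  m <- do.call(rbind, pieces)
  list(start = min(m[, 1]), end = max(m[, 2]),
       n_blocks = nrow(m), unmapped_bp = (end - start) - covered)
}

#' Consensus peak interval across reference assemblies
#'
#' Projects each reference's top significant interval onto a chosen anchor
#' reference and intersects the projections. When the full intersection is
#' empty, the consensus falls back to the region covered by the largest
#' number of projections (majority rule). Per-reference support is
#' recorded; references whose interval cannot be projected are dropped
#' from the consensus and annotated.
#'
#' @param intervals named list; per reference, `c(start, end)` on that
#'   reference's coordinates (the anchor's own interval included).
#' @param chains named list of PAF chains, one per non-anchor reference,
#'   aligning that reference (query) to the anchor (target).
#' @param anchor name of the anchor reference.
#' @return list with `start`, `end`, `support` (character vector of
#'   references whose projection covers the consensus), `unmappable`
#'   (references that could not be projected) and `projections`
#'   (data.frame of per-reference projected intervals), or NULL when no
#'   two projections overlap.
#' @export
consensusInterval <- function(intervals, chains, anchor) {
  stopifnot(anchor %in% names(intervals), length(intervals) >= 2)
  proj <- list(); unmappable <- character(0)
  for (ref in names(intervals)) {
    iv <- intervals[[ref]]
    if (ref == anchor) {
      proj[[ref]] <- c(iv[1], iv[2])
    } else {
      p <- projectInterval(iv[1], iv[2], chains[[ref]], from = "query")
      if (is.null(p)) unmappable <- c(unmappable, ref)
      else proj[[ref]] <- c(p$start, p$end)
    }
  }
  if (length(proj) < 2) return(NULL)
  m <- do.call(rbind, proj)
  ptab <- data.frame(reference = rownames(m), start = m[, 1], end = m[, 2])
  lo <- max(m[, 1]); hi <- min(m[, 2])
  if (hi > lo) {
    return(list(start = lo, end = hi, support = rownames(m),
                unmappable = unmappable, projections = ptab))
  }
  # majority rule: maximal coverage over projection breakpoints
  bks <- sort(unique(c(m[, 1], m[, 2])))
  if (length(bks) < 2) return(NULL)
  mids <- (bks[-1] + bks[-length(bks)]) / 2
  cov <- vapply(mids, function(x) sum(m[, 1] <= x & x < m[, 2]), integer(1))
  if (max(cov) < 2) return(NULL)
  best <- which(cov == max(cov))
  runs <- split(best, cumsum(c(1, diff(best) > 1)))
  run <- runs[[which.max(vapply(runs, function(r)
    bks[max(r) + 1] - bks[min(r)], numeric(1)))]]
  lo <- bks[min(run)]; hi <- bks[max(run) + 1]
  support <- rownames(m)[m[, 1] <= lo & hi <= m[, 2]]
  list(start = lo, end = hi, support = support,
       unmappable = unmappable, projections = ptab)
}

#' Select diagnostic SNPs within a consensus peak
#'
#' Passes SNPs whose depth is at least `minDepth` in both bulks and whose
#' observed segregating-allele frequency lies within `tol` of the expected
#' frequency in each bulk; passing SNPs are ranked by their smaller bulk
#' depth, deepest first.
#'
#' @param snps bulk allele-count data.frame (typically restricted to the
#'   consensus interval).
#' @param expectedFreqs length-2 numeric: expected alt frequency in bulk 1
#'   and bulk 2.
#' @param minDepth minimum per-bulk depth (default 10).
#' @param tol frequency tolerance (default 0.1).
#' @return `snps` with added columns `freq1`, `freq2`, `pass`, `reason`
#'   ("", "depth" or "frequency") and `rank` (NA for failing SNPs).
#' @export
selectDiagnosticSnps <- function(snps, expectedFreqs, minDepth = 10,
                                 tol = 0.1) {
  stopifnot(length(expectedFreqs) == 2)
  d1 <- snps$bulk1_ref + snps$bulk1_alt
  d2 <- snps$bulk2_ref + snps$bulk2_alt
  f1 <- ifelse(d1 > 0, snps$bulk1_alt / d1, NA_real_)
  f2 <- ifelse(d2 > 0, snps$bulk2_alt / d2, NA_real_)
  depthOk <- d1 >= minDepth & d2 >= minDepth
  freqOk <- !is.na(f1) & !is.na(f2) &
    abs(f1 - expectedFreqs[1]) <= tol & abs(f2 - expectedFreqs[2]) <= tol
  snps$freq1 <- f1; snps$freq2 <- f2
  snps$pass <- depthOk & freqOk
  snps$reason <- ifelse(snps$pass, "",
                        ifelse(!depthOk, "depth", "frequency"))
  snps$rank <- NA_integer_
  if (any(snps$pass))
    snps$rank[snps$pass] <- rank(-pmin(d1, d2)[snps$pass],
                                 ties.method = "first")
  snps
}
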