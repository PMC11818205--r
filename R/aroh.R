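# Aligned runs of homozygosity (AROH) from pairwise alignment of the two
# haplotypes of a phased diploid assembly. Long, low-divergence primary
# alignments between haplotypes are an alignment-based proxy for
# homozygous genomic segments.

pafColumns <- c("qname", "qlen", "qstart", "qend", "strand",
                "tname", "tlen", "tstart", "tend", "nmatch", "alen", "mapq")

#' Read a PAF pairwise-alignment file
#'
#' Parses the 12 mandatory PAF columns (minimap2 dialect) plus the optional
#' `de:f` per-base divergence and `tp:A` alignment-type tags. Malformed
#' lines (wrong column count, non-numeric coordinates, end <= start) are
#' skipped with a warning that reports their line numbers.
#'
#' @param path path to a PAF file.
#' @return data.frame with columns qname, qlen, qstart, qend, strand,
#'   tname, tlen, tstart, tend, nmatch, alen, mapq, de (numeric, NA when
#'   the tag is absent), tp (character, NA when absent). Coordinates are
#'   0-based half-open as in the PAF standard.
#' @export
readPaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(emptyPaf())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- integer(0)
  rows <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 12L) { bad <- c(bad, i); next }
    num <- suppressWarnings(as.numeric(p[c(2:4, 7:12)]))
    if (anyNA(num)) { bad <- c(bad, i); next }
    if (num[3] <= num[2] || num[6] <= num[5]) { bad <- c(bad, i); next }
    de <- NA_real_; tp <- NA_character_
    if (length(p) > 12L) {
      tags <- p[13:length(p)]
      dehit <- grep("^de:f:", tags, value = TRUE)
      if (length(dehit)) de <- as.numeric(sub("^de:f:", "", dehit[1]))
      tphit <- grep("^tp:A:", tags, value = TRUE)
      if (length(tphit)) tp <- sub("^tp:A:", "", tphit[1])
    }
    rows[[i]] <- data.frame(
      qname = p[1], qlen = num[1], qstart = num[2], qend = num[3],
      strand = p[5], tname = p[6], tlen = num[4], tstart = num[5],
      tend = num[6], nmatch = num[7], alen = num[8], mapq = num[9],
      de = de, tp = tp)
  }
  if (length(bad))
    warning("skipped ", length(bad), " malformed PAF line(s): ",
            paste(head(bad, 10), collapse = ", "),
            if (length(bad) > 10) ", ..." else "")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(emptyPaf())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

emptyPaf <- function() {
  data.frame(qname = character(), qlen = numeric(), qstart = numeric(),
             qend = numeric(), strand = character(), tname = character(),
             tlen = numeric(), tstart = numeric(), tend = numeric(),
             nmatch = numeric(), alen = numeric(), mapq = numeric(),
             de = numeric(), tp = character())
}

#' Write alignment records as PAF
#'
#' @param paf data.frame in the layout returned by [readPaf()].
#' @param path output path.
#' @export
writePaf <- function(paf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(paf))) {
    fields <- c(paf$qname[i], format(paf$qlen[i], scientific = FALSE),
                format(paf$qstart[i], scientific = FALSE),
                format(paf$qend[i], scientific = FALSE), paf$strand[i],
                paf$tname[i], format(paf$tlen[i], scientific = FALSE),
                format(paf$tstart[i], scientific = FALSE),
                format(paf$tend[i], scientific = FALSE),
                format(paf$nmatch[i], scientific = FALSE),
                format(paf$alen[i], scientific = FALSE),
                format(paf$mapq[i], scientific = FALSE))
    if (!is.na(paf$tp[i])) fields <- c(fields, paste0("tp:A:", paf$tp[i]))
    if (!is.na(paf$de[i])) fields <- c(fields, sprintf("de:f:%.6g", paf$de[i]))
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

#' Per-base divergence of alignment records
#'
#' Uses the minimap2 `de:f` gap-compressed divergence tag when present,
#' falling back to 1 - nmatch / alignment block length.
#'
#' @param paf data.frame of alignment records ([readPaf()] layout).
#' @return numeric vector of per-base divergence estimates.
#' @export
estimateDivergence <- function(paf) {
  stopifnot(all(paf$alen > 0))
  ifelse(!is.na(paf$de), paf$de, 1 - paf$nmatch / paf$alen)
}

#' Merge artificially split collinear alignments
#'
#' Aligners frequently break very long (multi-Mb) alignments between
#' near-identical haplotypes into several collinear pieces. Consecutive
#' records on the same query/target chromosome pair and strand are chained
#' when query and target both advance across a gap of at most `maxGap` bp
#' on each side and the two gap lengths agree within `gapDiffTol` bp
#' (consistent diagonal). Merged records sum `nmatch` and `alen`; the
#' merged `de` divergence is the alignment-length-weighted mean of the
#' member divergences (gap bases are not counted as divergent). Records
#' flagged secondary (`tp:A:S`) are dropped first.
#'
#' @param paf data.frame of alignment records.
#' @param maxGap maximum query and target gap to bridge (bp).
#' @param gapDiffTol maximum |query gap - target gap| (bp).
#' @param minMergedSpan if positive, chains whose merged target span is
#'   below this value are left unmerged (restricts healing to long
#'   alignments).
#' @return data.frame of merged records, sorted by target name and start,
#'   with an `n_aln` column counting source alignments per record.
#'   Applying the function to its own output is a no-op.
#' @export
mergeCollinear <- function(paf, maxGap = 1e5, gapDiffTol = 2e4,
                           minMergedSpan = 0) {
  if (!nrow(paf)) return(cbind(paf, n_aln = integer(0)))
  paf <- paf[is.na(paf$tp) | paf$tp != "S", , drop = FALSE]
  if (!"n_aln" %in% names(paf)) paf$n_aln <- 1L
  paf$.div <- estimateDivergence(paf)
  key <- paste(paf$qname, paf$tname, paf$strand, sep = "\r")
  out <- lapply(split(paf, key), function(g) {
    g <- g[order(g$tstart), , drop = FALSE]
    chains <- list()
    cur <- g[1, , drop = FALSE]
    for (i in seq_len(nrow(g))[-1]) {
      nxt <- g[i, , drop = FALSE]
      tgap <- nxt$tstart - cur$tend[nrow(cur)]
      qgap <- if (cur$strand[1] == "+") nxt$qstart - cur$qend[nrow(cur)]
              else cur$qstart[nrow(cur)] - nxt$qend
      if (tgap >= 0 && tgap <= maxGap && qgap >= 0 && qgap <= maxGap &&
          abs(qgap - tgap) <= gapDiffTol) {
        cur <- rbind(cur, nxt)
      } else {
        chains <- c(chains, list(cur))
        cur <- nxt
      }
    }
    chains <- c(chains, list(cur))
    do.call(rbind, lapply(chains, collapseChain,
                          minMergedSpan = minMergedSpan))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$tname, out$tstart), , drop = FALSE]
  out$.div <- NULL
  rownames(out) <- NULL
  out
}

collapseChain <- function(chain, minMergedSpan = 0) {
  if (nrow(chain) == 1L) return(chain)
  span <- max(chain$tend) - min(chain$tstart)
  if (minMergedSpan > 0 && span < minMergedSpan) return(chain)
  m <- chain[1, , drop = FALSE]
  m$qstart <- min(chain$qstart); m$qend <- max(chain$qend)
  m$tstart <- min(chain$tstart); m$tend <- max(chain$tend)
  m$nmatch <- sum(chain$nmatch); m$alen <- sum(chain$alen)
  m$mapq <- min(chain$mapq)
  m$de <- sum(chain$.div * chain$alen) / sum(chain$alen)
  m$n_aln <- sum(chain$n_aln)
  m
}

#' Classify aligned runs of homozygosity (AROH)
#'
#' A (merged) primary alignment between the two haplotypes is classified
#' as an AROH when its target span is greater than `minLength` and its
#' estimated per-base divergence is less than `maxDivergence` (both
#' strict). Surviving intervals that overlap on the target are resolved by
#' keeping the longer and trimming the shorter (trimmed pieces that fall
#' to `minLength` or below are dropped); trims are reported via
#' `message()`.
#'
#' @param paf data.frame of (merged) alignment records.
#' @param minLength minimum target span in bp (default 50 kb).
#' @param maxDivergence maximum per-base divergence (default 0.01).
#' @return a [GenomicRanges::GRanges] of AROH on the target haplotype
#'   (1-based closed, converted from PAF half-open) with metadata columns
#'   `divergence` and `n_aln`.
#' @export
classifyAroh <- function(paf, minLength = 5e4, maxDivergence = 0.01) {
  if (!nrow(paf))
    return(GenomicRanges::GRanges())
  paf <- paf[is.na(paf$tp) | paf$tp != "S", , drop = FALSE]
  div <- estimateDivergence(paf)
  span <- paf$tend - paf$tstart
  keep <- span > minLength & div < maxDivergence
  paf <- paf[keep, , drop = FALSE]
  div <- div[keep]
  if (!nrow(paf)) return(GenomicRanges::GRanges())
  naln <- if ("n_aln" %in% names(paf)) paf$n_aln else rep(1L, nrow(paf))
  ord <- order(-(paf$tend - paf$tstart))
  res <- list()
  occupied <- list()  # per target chrom: IRanges of accepted intervals
  for (i in ord) {
    chrom <- paf$tname[i]
    ir <- IRanges::IRanges(start = paf$tstart[i] + 1, end = paf$tend[i])
    occ <- occupied[[chrom]]
    if (!is.null(occ)) {
      free <- IRanges::setdiff(ir, occ)
      if (length(free) == 0L) {
        message("AROH candidate on ", chrom, " [", paf$tstart[i], ",",
                paf$tend[i], ") fully shadowed by a longer AROH; dropped")
        next
      }
      widest <- which.max(IRanges::width(free))
      if (IRanges::width(free)[widest] < IRanges::width(ir))
        message("AROH candidate on ", chrom, " [", paf$tstart[i], ",",
                paf$tend[i], ") trimmed to avoid a longer AROH")
      ir <- free[widest]
      if (IRanges::width(ir) <= minLength) next
    }
    occupied[[chrom]] <- if (is.null(occ)) ir else c(occ, ir)
    res[[length(res) + 1L]] <- GenomicRanges::GRanges(
      chrom, ir, divergence = div[i], n_aln = naln[i])
  }
  if (!length(res)) return(GenomicRanges::GRanges())
  GenomicRanges::sort(do.call(c, res))
}

#' AROH coverage of an assembly by minimum-length threshold
#'
#' For each threshold t, the proportion of the assembly covered by AROH of
#' length >= t. The proportion is non-increasing in t.
#'
#' @param aroh `GRanges` of AROH intervals (from [classifyAroh()]), or a
#'   numeric vector of interval lengths.
#' @param assemblyLength total assembly length in bp.
#' @param thresholds numeric vector of minimum lengths (bp).
#' @return data.frame with columns `threshold` and `proportion`.
#' @export
arohCoverage <- function(aroh, assemblyLength,
                         thresholds = c(5e4, 1e5, 5e5, 1e6, 5e6, 1e7,
                                        2e7, 3e7)) {
  stopifnot(assemblyLength > 0)
  w <- if (is(aroh, "GRanges")) GenomicRanges::width(aroh) else as.numeric(aroh)
  if (sum(w) > assemblyLength)
    stop("AROH intervals exceed the assembly length")
  data.frame(
    threshold = thresholds,
    proportion = vapply(thresholds,
                        function(t) sum(w[w >= t]) / assemblyLength,
                        numeric(1)))
}

#' Total AROH bp above a length cutoff
#'
#' @param aroh `GRanges` of AROH intervals or numeric lengths.
#' @param minLength cutoff in bp (default 50 kb).
#' @return total basepairs in AROH longer than `minLength`.
#' @export
totalArohBp <- function(aroh, minLength = 5e4) {
  w <- if (is(aroh, "GRanges")) GenomicRanges::width(aroh) else as.numeric(aroh)
  sum(w[w > minLength])
}
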