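# Reverse complement of plain character sequences, without external
# dependencies so the Biostrings route stays available as an independent
# cross-check in the tests.
revComp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Canonicalize k-mers
#'
#' Returns the canonical form of each k-mer: the lexicographically smaller
#' of the k-mer and its reverse complement. Canonicalization makes k-mer
#' sets strand-neutral and is idempotent. K-mers containing a base other
#' than A, C, G, T cannot be canonicalized and are returned as `NA`, which
#' callers treat as "skip this window".
#'
#' @param kmer character vector of k-mers (upper case A/C/G/T).
#' @return character vector of canonical k-mers, `NA` where the input
#'   contains an ambiguous base.
#' @examples
#' canonicalKmer(c("ACG", "TTT"))  # "ACG", "AAA"
#' @export
canonicalKmer <- function(kmer) {
  out <- rep(NA_character_, length(kmer))
  ok <- !is.na(kmer) & !grepl("[^ACGT]", kmer)
  if (any(ok)) {
    f <- kmer[ok]
    r <- revComp(f)
    out[ok] <- ifelse(f <= r, f, r)
  }
  out
}

# All canonical k-mers of one sequence, in order of their leftmost base.
# Windows overlapping a non-ACGT base are NA. Vectorized: the reverse
# complement of the window starting at i is the window of the full-sequence
# reverse complement starting at L - k + 2 - i.
scanCanonicalKmers <- function(seq, k) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < k) return(character(0))
  n <- L - k + 1L
  starts <- seq_len(n)
  fwd <- substring(seq, starts, starts + k - 1L)
  rcseq <- intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", seq))))
  rstarts <- L - k + 2L - starts
  rc <- substring(rcseq, rstarts, rstarts + k - 1L)
  can <- ifelse(fwd <= rc, fwd, rc)
  bad <- utf8ToInt(seq)
  bad <- !(bad %in% utf8ToInt("ACGT"))
  if (any(bad)) {
    cs <- cumsum(bad)
    winbad <- cs[starts + k - 1L] - c(0L, cs)[starts]
    can[winbad > 0L] <- NA_character_
  }
  can
}

# Normalize a genome argument to one character string per genome.
# Accepts a named character vector, a named list of character vectors
# (multi-chromosome), or a DNAStringSet.
flattenGenomes <- function(genomes) {
  if (is(genomes, "DNAStringSet"))
    genomes <- as.list(as.character(genomes))
  if (is.character(genomes)) genomes <- as.list(genomes)
  stopifnot(is.list(genomes))
  if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
    stop("genomes must be named")
  lapply(genomes, function(g) {
    if (is(g, "DNAStringSet")) g <- as.character(g)
    paste(toupper(g), collapse = "N")  # chromosome junctions never yield k-mers
  })
}

#' Build a canonical k-mer presence/absence index over a genome panel
#'
#' Scans every genome for its canonical k-mers (lexicographic minimum of
#' forward and reverse-complement form) and records, for each k-mer seen in
#' at least one genome, which genomes contain it. Windows containing a
#' non-ACGT base are skipped. The index stores presence only, not
#' multiplicity, as appropriate for a presence/absence pangenome index.
#'
#' @param genomes named character vector, named list of character vectors
#'   (one element per chromosome), or a named `DNAStringSet`; one entry per
#'   genome.
#' @param k odd integer k-mer size, default 31.
#' @return a [KmerIndex-class] object.
#' @examples
#' idx <- buildKmerIndex(c(g1 = "ACGTAC", g2 = "ACGTTT"), k = 3)
#' length(idx)  # 4 distinct canonical 3-mers
#' @export
buildKmerIndex <- function(genomes, k = 31L) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L || k %% 2L == 0L)
    stop("k must be an odd integer >= 3")
  seqs <- flattenGenomes(genomes)
  if (anyDuplicated(names(seqs)))
    stop("duplicate genome names")
  if (any(!nzchar(unlist(seqs))))
    stop("empty genome sequence")
  sets <- lapply(seqs, function(s) {
    km <- scanCanonicalKmers(s, k)
    sort(unique(km[!is.na(km)]))
  })
  allk <- sort(unique(unlist(sets, use.names = FALSE)))
  presence <- vapply(sets, function(s) allk %in% s, logical(length(allk)))
  if (length(allk) == 0L)
    presence <- matrix(logical(0), nrow = 0, ncol = length(sets))
  if (is.null(dim(presence)))
    presence <- matrix(presence, nrow = length(allk))
  new("KmerIndex", k = k, genomeNames = names(seqs),
      kmers = allk, presence = presence)
}

#' Extract a genome's unique k-mers from a panel index
#'
#' A unique k-mer is present in exactly one genome of the panel; high
#' densities of unique k-mers flag haplotypes not represented elsewhere in
#' the panel.
#'
#' @param index a [KmerIndex-class].
#' @param genome genome name.
#' @return character vector of canonical k-mers private to `genome`.
#' @export
uniqueKmers <- function(index, genome) {
  stopifnot(is(index, "KmerIndex"))
  j <- match(genome, index@genomeNames)
  if (is.na(j)) stop("unknown genome: ", genome)
  if (!length(index@kmers)) return(character(0))
  index@kmers[index@presence[, j] & rowSums(index@presence) == 1L]
}

#' Pairwise Jaccard similarity of genome k-mer sets
#'
#' J(a, b) = |K_a intersect K_b| / |K_a union K_b| over the canonical
#' k-mer sets of each pair of genomes.
#'
#' @param index a [KmerIndex-class].
#' @param subset optional character vector of genome names to restrict to.
#' @return symmetric numeric matrix with unit diagonal, dimnames set to the
#'   genome names.
#' @export
jaccardMatrix <- function(index, subset = NULL) {
  stopifnot(is(index, "KmerIndex"))
  nms <- index@genomeNames
  if (!is.null(subset)) {
    if (!all(subset %in% nms)) stop("subset contains unknown genomes")
    nms <- subset
  }
  P <- index@presence[, match(nms, index@genomeNames), drop = FALSE]
  sizes <- colSums(P)
  if (any(sizes == 0L))
    stop("genome(s) with zero valid k-mers: ",
         paste(nms[sizes == 0L], collapse = ", "))
  inter <- crossprod(P)  # |Ka n Kb|
  un <- outer(sizes, sizes, "+") - inter
  J <- inter / un
  dimnames(J) <- list(nms, nms)
  diag(J) <- 1
  J
}

#' Average-linkage dendrogram of genomes from Jaccard similarities
#'
#' Agglomerative (UPGMA) clustering on the distance 1 - J. Ties are broken
#' deterministically by input order via `stats::hclust`.
#'
#' @param jaccard symmetric Jaccard similarity matrix (e.g. from
#'   [jaccardMatrix()]).
#' @param linkage agglomeration method, default "average".
#' @return a Newick string for the rooted dendrogram (also invisibly usable
#'   via [ape::read.tree]).
#' @export
clusterTree <- function(jaccard, linkage = "average") {
  stopifnot(is.matrix(jaccard), nrow(jaccard) == ncol(jaccard))
  if (nrow(jaccard) < 2L) stop("need at least two genomes to cluster")
  d <- stats::as.dist(1 - jaccard)
  hc <- stats::hclust(d, method = linkage)
  ape::write.tree(ape::as.phylo(hc))
}

#' Pangenome collector's curve
#'
#' Cumulative number of distinct canonical k-mers as genomes are added to
#' the index in a given order. The terminal value equals the total number
#' of distinct k-mers regardless of order; a plateau indicates the panel
#' has saturated the k-mer diversity.
#'
#' @param index a [KmerIndex-class].
#' @param orderings list of character vectors (genome orders), or NULL to
#'   use the index input order.
#' @param nRandom number of random orderings to draw (in addition to
#'   `orderings`).
#' @param seed RNG seed for the random orderings.
#' @return a data.frame with columns `ordering` (integer id), `step`,
#'   `genome`, `cumulative`.
#' @export
collectorsCurve <- function(index, orderings = NULL, nRandom = 0L,
                            seed = NULL) {
  stopifnot(is(index, "KmerIndex"))
  nms <- index@genomeNames
  if (is.null(orderings) && nRandom == 0L) orderings <- list(nms)
  if (nRandom > 0L) {
    rnd <- withSeed(seed, replicate(nRandom, sample(nms), simplify = FALSE))
    orderings <- c(orderings, rnd)
  }
  out <- lapply(seq_along(orderings), function(i) {
    ord <- orderings[[i]]
    if (!all(ord %in% nms)) stop("ordering contains unknown genomes")
    present <- rep(FALSE, length(index@kmers))
    cum <- integer(length(ord))
    for (j in seq_along(ord)) {
      present <- present | index@presence[, match(ord[j], nms)]
      cum[j] <- sum(present)
    }
    data.frame(ordering = i, step = seq_along(ord), genome = ord,
               cumulative = cum)
  })
  do.call(rbind, out)
}

#' Binned unique-k-mer occurrence track along a genome
#'
#' Rescans the genome sequence used to build the index: every position
#' whose canonical k-mer belongs to the genome's unique set increments the
#' bin containing the k-mer's leftmost base. Multi-occurrence k-mers count
#' every occurrence, so the track sums to at least the unique-set size.
#'
#' @param index a [KmerIndex-class].
#' @param genome genome name in the index.
#' @param seqs named character vector or `DNAStringSet` of that genome's
#'   chromosome sequences (the same sequence the index was built from).
#' @param binWidth bin width in bp, default 1 Mb.
#' @return data.frame with columns `genome`, `chrom`, `bin_start` (0-based),
#'   `bin_width`, `count`, tiling each chromosome.
#' @export
uniqueKmerTrack <- function(index, genome, seqs, binWidth = 1e6) {
  stopifnot(is(index, "KmerIndex"))
  if (!genome %in% index@genomeNames) stop("unknown genome: ", genome)
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) stop("chromosome sequences must be named")
  uk <- uniqueKmers(index, genome)
  gset <- index@kmers[index@presence[, match(genome, index@genomeNames)]]
  out <- lapply(names(seqs), function(chrom) {
    s <- toupper(seqs[[chrom]])
    L <- nchar(s)
    nbins <- max(1L, ceiling(L / binWidth))
    counts <- integer(nbins)
    km <- scanCanonicalKmers(s, index@k)
    keep <- !is.na(km)
    if (any(keep)) {
      if (!all(km[keep] %in% gset))
        stop("sequence/genome mismatch: scanned k-mers absent from the ",
             "index entry for ", genome)
      hit <- which(keep)[km[keep] %in% uk]
      if (length(hit)) {
        b <- ((hit - 1L) %/% binWidth) + 1L
        tb <- tabulate(b, nbins)
        counts <- counts + tb
      }
    }
    data.frame(genome = genome, chrom = chrom,
               bin_start = (seq_len(nbins) - 1L) * binWidth,
               bin_width = binWidth, count = counts)
  })
  do.call(rbind, out)
}
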