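#' KmerIndex: canonical k-mer presence/absence index over a genome panel
#'
#' Stores, for every canonical k-mer occurring in at least one genome of a
#' panel, a presence bit-vector over the genomes. Canonical means the
#' lexicographic minimum of a k-mer and its reverse complement, so the
#' index is strand-neutral. K-mers overlapping a non-ACGT base are skipped.
#'
#' @slot k odd integer k-mer size (31 by default in [buildKmerIndex()]).
#' @slot genomeNames ordered character vector of panel member names.
#' @slot kmers character vector of canonical k-mers (sorted, unique).
#' @slot presence logical matrix, rows parallel to `kmers`, one column per
#'   genome; `TRUE` iff the k-mer occurs in that genome.
#'
#' @aliases KmerIndex
#' @seealso [buildKmerIndex()], [uniqueKmers()], [jaccardMatrix()],
#'   [collectorsCurve()]
#' @exportClass KmerIndex
setClass("KmerIndex",
  representation(
    k = "integer",
    genomeNames = "character",
    kmers = "character",
    presence = "matrix"
  )
)

setValidity("KmerIndex", function(object) {
  msg <- character()
  if (length(object@k) != 1L || is.na(object@k) || object@k < 3L ||
      object@k %% 2L == 0L)
    msg <- c(msg, "k must be a single odd integer >= 3")
  if (anyDuplicated(object@genomeNames))
    msg <- c(msg, "genome names must be unique")
  if (!is.logical(object@presence))
    msg <- c(msg, "presence must be a logical matrix")
  if (nrow(object@presence) != length(object@kmers))
    msg <- c(msg, "presence rows must parallel kmers")
  if (ncol(object@presence) != length(object@genomeNames))
    msg <- c(msg, "presence columns must parallel genomeNames")
  if (length(object@kmers)) {
    if (any(nchar(object@kmers) != object@k))
      msg <- c(msg, "all k-mers must have length k")
    if (any(grepl("[^ACGT]", object@kmers)))
      msg <- c(msg, "k-mers must contain only A, C, G, T")
    if (nrow(object@presence) && any(rowSums(object@presence) == 0L))
      msg <- c(msg, "every k-mer must be present in at least one genome")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn KmerIndex number of distinct canonical k-mers in the index
#' @param object,x a `KmerIndex`
#' @export
setMethod("length", "KmerIndex", function(x) length(x@kmers))

#' @rdname KmerIndex
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @describeIn KmerIndex the k-mer size k
#' @export
setMethod("kmerSize", "KmerIndex", function(x) x@k)

#' @rdname KmerIndex
#' @export
setGeneric("genomeNames", function(x) standardGeneric("genomeNames"))

#' @describeIn KmerIndex panel member names, in input order
#' @export
setMethod("genomeNames", "KmerIndex", function(x) x@genomeNames)

#' @rdname KmerIndex
#' @export
setGeneric("kmers", function(x) standardGeneric("kmers"))

#' @describeIn KmerIndex canonical k-mer keys (sorted)
#' @export
setMethod("kmers", "KmerIndex", function(x) x@kmers)

#' @rdname KmerIndex
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @describeIn KmerIndex logical presence matrix (k-mers x genomes)
#' @export
setMethod("presenceMatrix", "KmerIndex", function(x) {
  m <- x@presence
  dimnames(m) <- list(x@kmers, x@genomeNames)
  m
})

setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex with", length(object@kmers), "canonical", object@k,
      "-mers over", length(object@genomeNames), "genomes\n")
  cat("  genomes:", paste(head(object@genomeNames, 5), collapse = ", "),
      if (length(object@genomeNames) > 5) "..." else "", "\n")
})

#' GProfile: smoothed G-statistic track from bulk segregant analysis
#'
#' Sliding-window moving average of per-SNP G statistics on a regular grid
#' of window centers, optionally with a per-window null significance
#' threshold obtained by simulation ([nullThreshold()]).
#'
#' @slot chrom chromosome name.
#' @slot centers window center positions (bp), strictly increasing on a
#'   regular grid of spacing `step`.
#' @slot halfWidth half of the smoothing window width (bp).
#' @slot step grid spacing (bp), 10 kb by default.
#' @slot g smoothed G per window (`NA` where the window holds no SNP).
#' @slot threshold per-window null threshold, or length-0 if not computed.
#'
#' @aliases GProfile
#' @seealso [smoothG()], [nullThreshold()], [significantIntervals()]
#' @exportClass GProfile
setClass("GProfile",
  representation(
    chrom = "character",
    centers = "numeric",
    halfWidth = "numeric",
    step = "numeric",
    g = "numeric",
    threshold = "numeric"
  )
)

setValidity("GProfile", function(object) {
  msg <- character()
  if (length(object@centers) != length(object@g))
    msg <- c(msg, "centers and g must have equal length")
  if (length(object@centers) > 1 &&
      any(diff(object@centers) <= 0))
    msg <- c(msg, "centers must be strictly increasing")
  if (any(object@g < 0, na.rm = TRUE))
    msg <- c(msg, "smoothed G must be non-negative")
  if (length(object@threshold) &&
      length(object@threshold) != length(object@centers))
    msg <- c(msg, "threshold must be empty or parallel to centers")
  if (length(msg)) msg else TRUE
})

#' @describeIn GProfile number of windows
#' @param x,object a `GProfile`
#' @export
setMethod("length", "GProfile", function(x) length(x@centers))

#' @rdname GProfile
#' @export
setGeneric("windowCenters", function(x) standardGeneric("windowCenters"))

#' @describeIn GProfile window center positions (bp)
#' @export
setMethod("windowCenters", "GProfile", function(x) x@centers)

#' @rdname GProfile
#' @export
setGeneric("smoothedG", function(x) standardGeneric("smoothedG"))

#' @describeIn GProfile smoothed G values per window
#' @export
setMethod("smoothedG", "GProfile", function(x) x@g)

#' @rdname GProfile
#' @export
setGeneric("gThreshold", function(x) standardGeneric("gThreshold"))

#' @describeIn GProfile per-window null threshold (NULL if absent)
#' @export
setMethod("gThreshold", "GProfile", function(x) {
  if (length(x@threshold)) x@threshold else NULL
})

setMethod("show", "GProfile", function(object) {
  cat("GProfile on", object@chrom, "|", length(object@centers),
      "windows every", object@step, "bp, width",
      2 * object@halfWidth, "bp\n")
  cat("  max smoothed G:",
      if (all(is.na(object@g))) NA else
        format(max(object@g, na.rm = TRUE), digits = 4),
      "| threshold:",
      if (length(object@threshold)) "computed" else "absent", "\n")
})

#' @describeIn GProfile flatten to a data.frame of
#'   (chrom, center, g, threshold)
#' @export
profileTable <- function(x) {
  stopifnot(is(x, "GProfile"))
  data.frame(
    chrom = x@chrom,
    center = x@centers,
    g = x@g,
    threshold = if (length(x@threshold)) x@threshold else NA_real_
  )
}
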