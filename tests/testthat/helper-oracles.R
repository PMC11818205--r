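# Independent oracles, deliberately implemented by different routes than
# the package code: Biostrings reverse complement per k-mer, explicit set
# algebra, and a direct likelihood evaluation for the 2x2 G test.

randomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracleCanonical <- function(kmer) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
  if (kmer <= rc) kmer else rc
}

# Canonical k-mer set of one sequence by brute force (per-window loop).
oracleKmerSet <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq) - k + 1
  if (n < 1) return(character(0))
  out <- character(0)
  for (i in seq_len(n)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("[^ACGT]", w)) next
    out <- c(out, oracleCanonical(w))
  }
  sort(unique(out))
}

oracleJaccard <- function(setA, setB) {
  length(intersect(setA, setB)) / length(union(setA, setB))
}

# 2x2 log-likelihood-ratio statistic by direct likelihood evaluation:
# G = 2 * (logLik of the saturated multinomial - logLik under row/column
# independence), with MLE cell probabilities evaluated explicitly.
oracleG <- function(o11, o12, o21, o22) {
  o <- c(o11, o12, o21, o22)
  n <- sum(o)
  if (n == 0) return(0)
  r <- c(o11 + o12, o21 + o22)
  cc <- c(o11 + o21, o12 + o22)
  if (any(r == 0) || any(cc == 0)) return(0)
  pSat <- o / n
  pInd <- c(r[1] * cc[1], r[1] * cc[2], r[2] * cc[1], r[2] * cc[2]) / n^2
  ll <- function(p) sum(ifelse(o == 0, 0, o * log(p)))
  2 * (ll(pSat) - ll(pInd))
}

# Random alignment record in PAF layout, collinear on a random diagonal.
randomPafRecords <- function(n, seed) {
  set.seed(seed)
  len <- 2e7
  data.frame(
    qname = "q1", qlen = len,
    qstart = s <- sort(sample.int(len - 2e5, n)),
    qend = s + sample(1e3:1.5e5, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    tname = "t1", tlen = len,
    tstart = ts <- sort(sample.int(len - 2e5, n)),
    tend = ts + sample(1e3:1.5e5, n, replace = TRUE),
    nmatch = nm <- sample(1e3:1e5, n, replace = TRUE),
    alen = nm + sample(0:5e3, n, replace = TRUE),
    mapq = 60, de = NA_real_, tp = NA_character_)
}
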