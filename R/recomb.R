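# Marey-map recombination landscape: marker QC, family-level MAF, LOESS
# fit of genetic on physical position, and a derivative-based
# recombination-rate profile with suppressed-region calling.

#' Chi-square test of F2 segregation against 1:2:1
#'
#' Goodness-of-fit of observed AA/AB/BB counts to the Mendelian 1:2:1
#' expectation, df = 2, upper-tail p-value.
#'
#' @param nAA,nAB,nBB genotype counts (vectors are accepted and recycled
#'   to equal length).
#' @return data.frame with columns `chi2` and `p`.
#' @examples
#' segregationChi2(30, 40, 30)  # chi2 = 4, p = exp(-2)
#' @export
segregationChi2 <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  if (any(n == 0)) stop("no genotyped individuals")
  e <- cbind(n / 4, n / 2, n / 4)
  o <- cbind(nAA, nAB, nBB)
  chi2 <- rowSums((o - e)^2 / e)
  data.frame(chi2 = chi2, p = pchisq(chi2, df = 2, lower.tail = FALSE))
}

#' Family-level minor allele frequency of an F2 marker
#'
#' p_A = (2 nAA + nAB) / (2 n); returns min(p_A, 1 - p_A).
#'
#' @inheritParams segregationChi2
#' @return numeric vector of minor allele frequencies.
#' @examples
#' markerMaf(81, 18, 1)  # 0.1
#' @export
markerMaf <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  if (any(n == 0)) stop("no genotyped individuals")
  pA <- (2 * nAA + nAB) / (2 * n)
  pmin(pA, 1 - pA)
}

#' Count genotype classes per marker
#'
#' @param geno character matrix (markers x individuals) with entries
#'   "AA", "AB", "BB" or NA.
#' @return data.frame with columns n_AA, n_AB, n_BB, n_missing.
#' @export
countGenotypes <- function(geno) {
  stopifnot(is.matrix(geno))
  data.frame(
    n_AA = rowSums(geno == "AA", na.rm = TRUE),
    n_AB = rowSums(geno == "AB", na.rm = TRUE),
    n_BB = rowSums(geno == "BB", na.rm = TRUE),
    n_missing = rowSums(is.na(geno)))
}

#' Filter F2 markers on distortion, missingness and duplication
#'
#' Drops markers whose 1:2:1 segregation test has p below `distortionP`,
#' markers whose missing fraction exceeds `maxMissing`, and collapses
#' groups of markers with identical genotype vectors (missing-tolerant
#' equality: two markers match if they never disagree on a co-typed
#' individual and their non-missing patterns are identical) to the first
#' member. Distortion thresholds of 1e-5 and 1e-17 are typical choices for
#' individual F2 families of a few hundred plants.
#'
#' @param markers data.frame with at least a `marker` column (ids, unique).
#' @param geno character genotype matrix, rows parallel to `markers`.
#' @param distortionP segregation-distortion p-value threshold
#'   (default 1e-5).
#' @param maxMissing maximum tolerated missing fraction (default 0.35).
#' @return list with `markers` and `geno` (the retained rows) and `report`
#'   (data.frame: marker, status "retained"/"dropped", reason
#'   "distortion"/"missingness"/"duplicate"/"", chi2, p, missing_frac,
#'   duplicate_of).
#' @export
filterMarkers <- function(markers, geno, distortionP = 1e-5,
                          maxMissing = 0.35) {
  stopifnot(nrow(markers) == nrow(geno), nrow(markers) > 0,
            distortionP > 0, distortionP < 1,
            maxMissing > 0, maxMissing < 1)
  cnt <- countGenotypes(geno)
  n <- cnt$n_AA + cnt$n_AB + cnt$n_BB
  missFrac <- cnt$n_missing / ncol(geno)
  chi2 <- p <- rep(NA_real_, nrow(markers))
  typed <- n > 0
  if (any(typed)) {
    sc <- segregationChi2(cnt$n_AA[typed], cnt$n_AB[typed], cnt$n_BB[typed])
    chi2[typed] <- sc$chi2; p[typed] <- sc$p
  }
  reason <- rep("", nrow(markers))
  reason[typed & p < distortionP] <- "distortion"
  reason[reason == "" & missFrac > maxMissing] <- "missingness"
  # collapse duplicates among the survivors, keeping the first of each group
  dupOf <- rep(NA_character_, nrow(markers))
  surv <- which(reason == "")
  key <- apply(geno, 1, function(r) paste(ifelse(is.na(r), ".", r),
                                          collapse = ""))
  seen <- character(0)
  for (i in surv) {
    j <- match(key[i], seen)
    if (!is.na(j)) {
      reason[i] <- "duplicate"
      dupOf[i] <- markers$marker[surv[j]]
    } else seen <- c(seen, key[i])
  }
  keep <- reason == ""
  report <- data.frame(
    marker = markers$marker,
    status = ifelse(keep, "retained", "dropped"),
    reason = reason, chi2 = chi2, p = p, missing_frac = missFrac,
    duplicate_of = dupOf)
  list(markers = markers[keep, , drop = FALSE],
       geno = geno[keep, , drop = FALSE],
       report = report)
}

#' LOESS fit of a Marey map (genetic on physical position)
#'
#' Fits a locally weighted degree-`degree` regression of genetic position
#' (cM) on physical position (bp) with fraction-of-data bandwidth `span`,
#' evaluates it at the marker positions, and (by default) projects the
#' fitted sequence onto the nearest non-decreasing sequence (isotonic
#' regression). A Marey map is physically non-decreasing, and raw LOESS
#' wiggle would otherwise fold into spurious positive rates when the
#' absolute derivative is taken. Markers sharing a physical position are
#' collapsed to their mean genetic position before fitting.
#'
#' @param physical physical positions bp (need not be pre-sorted).
#' @param genetic genetic positions cM.
#' @param span LOESS span as fraction of markers (default 0.25).
#' @param degree local polynomial degree (default 1).
#' @param monotone apply isotonic monotonization (default TRUE; FALSE
#'   reproduces the raw-derivative computation).
#' @return data.frame with columns `physical` (sorted, deduplicated) and
#'   `fitted` (cM).
#' @export
mareyFit <- function(physical, genetic, span = 0.25, degree = 1,
                     monotone = TRUE) {
  stopifnot(length(physical) == length(genetic))
  keep <- is.finite(physical) & is.finite(genetic)
  physical <- physical[keep]; genetic <- genetic[keep]
  if (length(unique(physical)) < 10)
    stop("need at least 10 markers with distinct physical positions")
  agg <- tapply(genetic, physical, mean)
  px <- as.numeric(names(agg)); gy <- as.numeric(agg)
  o <- order(px); px <- px[o]; gy <- gy[o]
  fit <- stats::loess(gy ~ px, span = span, degree = degree,
                      control = stats::loess.control(surface = "direct"))
  fitted <- stats::predict(fit, px)
  if (monotone) fitted <- stats::isoreg(px, fitted)$yf
  data.frame(physical = px, fitted = fitted)
}

#' Recombination-rate profile from a fitted Marey map
#'
#' rate_i = |fit_{i+1} - fit_i| / (p_{i+1} - p_i) * 1e6 cM/Mb, attached to
#' the inter-marker midpoint (p_i + p_{i+1}) / 2. Pairs with zero physical
#' gap are skipped with a message.
#'
#' @param fit data.frame from [mareyFit()] (columns `physical`, `fitted`),
#'   or a numeric vector of fitted cM values if `physical` is given.
#' @param physical physical positions bp (when `fit` is a vector).
#' @return data.frame with columns `midpoint` (bp), `left`, `right` (the
#'   flanking marker positions) and `rate` (cM/Mb).
#' @export
recombinationRate <- function(fit, physical = NULL) {
  if (is.data.frame(fit)) {
    physical <- fit$physical; fitted <- fit$fitted
  } else fitted <- fit
  stopifnot(length(physical) == length(fitted), length(fitted) >= 2)
  dp <- diff(physical)
  if (any(dp == 0)) {
    message("skipping ", sum(dp == 0), " marker pair(s) with zero physical gap")
    keep <- dp != 0
  } else keep <- rep(TRUE, length(dp))
  i <- which(keep)
  data.frame(
    midpoint = (physical[i] + physical[i + 1]) / 2,
    left = physical[i], right = physical[i + 1],
    rate = abs(diff(fitted))[i] / dp[i] * 1e6)
}

#' Call suppressed-recombination regions
#'
#' Maximal runs of consecutive rate midpoints below `rateThreshold` whose
#' physical span is at least `minSpan`. Pericentromeric regions of large
#' plant chromosomes commonly satisfy the default 40 Mb at < 0.5 cM/Mb.
#'
#' @param profile data.frame from [recombinationRate()].
#' @param rateThreshold cM/Mb cutoff (default 0.5).
#' @param minSpan minimum physical span bp (default 40 Mb).
#' @return data.frame with columns `start`, `end` (bp, span of the run's
#'   flanking markers), `span`, `mean_rate`, `n_windows`.
#' @export
suppressedRegions <- function(profile, rateThreshold = 0.5, minSpan = 4e7) {
  below <- profile$rate < rateThreshold
  r <- rle(below)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- list()
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    s <- profile$left[i0]; e <- profile$right[i1]
    if (e - s >= minSpan)
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = e, span = e - s,
        mean_rate = mean(profile$rate[i0:i1]),
        n_windows = i1 - i0 + 1L)
  }
  if (!length(out))
    return(data.frame(start = numeric(), end = numeric(), span = numeric(),
                      mean_rate = numeric(), n_windows = integer()))
  do.call(rbind, out)
}
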