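idChain <- function(len = 1e7, strand = "+", qname = "A", tname = "B") {
  data.frame(qname = qname, qlen = len, qstart = 0, qend = len,
             strand = strand, tname = tname, tlen = len, tstart = 0,
             tend = len, nmatch = len, alen = len, mapq = 60,
             de = NA_real_, tp = NA_character_)
}

test_that("gStatistic closed forms and degenerate tables", {
  expect_equal(gStatistic(10, 10, 10, 10), 0)
  expect_equal(gStatistic(20, 0, 0, 20), 80 * log(2))
  expect_equal(gStatistic(12, 8, 8, 12), oracleG(12, 8, 8, 12),
               tolerance = 1e-12)
  expect_equal(round(gStatistic(12, 8, 8, 12), 3), 1.611)
  # zero row or column total carries no information
  expect_equal(gStatistic(0, 0, 10, 10), 0)
  expect_equal(gStatistic(10, 0, 10, 0), 0)
  expect_equal(gStatistic(0, 0, 0, 0), 0)
})

test_that("gStatistic is symmetric and zero iff proportions are equal", {
  set.seed(1)
  for (i in 1:200) {
    o <- sample(0:60, 4, replace = TRUE)
    g <- gStatistic(o[1], o[2], o[3], o[4])
    expect_equal(g, gStatistic(o[3], o[4], o[1], o[2]))  # bulk swap
    expect_equal(g, gStatistic(o[2], o[1], o[4], o[3]))  # allele swap
    expect_lt(abs(g - oracleG(o[1], o[2], o[3], o[4])), 1e-9)
    r1 <- o[1] + o[2]; r2 <- o[3] + o[4]
    if (r1 > 0 && r2 > 0 && abs(o[2] / r1 - o[4] / r2) > 1e-12)
      expect_gt(g, 0)
    if (r1 > 0 && r2 > 0 && o[2] / r1 == o[4] / r2)
      expect_equal(g, 0)
  }
})

test_that("depth filter keeps the inclusive boundary", {
  snps <- data.frame(chrom = "c", pos = 1:3 * 100,
                     bulk1_ref = c(6, 5, 20), bulk1_alt = c(6, 5, 20),
                     bulk2_ref = c(5, 4, 20), bulk2_alt = c(5, 5, 20))
  f <- filterSnps(snps, minDepth = 10)
  expect_equal(f$pos, c(100, 300))  # depths (12,10) and (40,40) pass; (10,9) fails
  expect_equal(nrow(filterSnps(snps[0, , drop = FALSE])), 0L)
})

test_that("smoothG averages SNP G values within the window", {
  snps <- data.frame(chrom = "c", pos = c(1e4, 2e4),
                     bulk1_ref = c(20, 20), bulk1_alt = c(0, 0),
                     bulk2_ref = c(0, 10), bulk2_alt = c(20, 10))
  snps <- addG(snps)
  pr <- smoothG(snps, windowWidth = 2e6, step = 1e4)
  inwin <- abs(windowCenters(pr) - 1.5e4) < 9.9e5
  expect_true(all(abs(smoothedG(pr)[inwin] - mean(snps$g)) < 1e-12))
  one <- smoothG(snps[1, ], windowWidth = 2e6)
  expect_true(all(smoothedG(one) == snps$g[1], na.rm = TRUE))
  # windows far from any SNP are NA
  wide <- smoothG(rbind(snps, transform(snps[1, ], pos = 1e7, g = snps$g[1])),
                  windowWidth = 1e5)
  expect_true(anyNA(smoothedG(wide)))
})

test_that("null thresholds are finite, positive, and monotone in percentile", {
  b <- simulateBulks(5e6, 150, causalPos = NULL, nPlants = 50,
                     meanDepth = 40, seed = 51)
  pr <- smoothG(addG(b$snps), windowWidth = 5e5)
  t995 <- gThreshold(nullThreshold(b$snps, pr, nSim = 300, nPlants = 50,
                                   seed = 52))
  t80 <- gThreshold(nullThreshold(b$snps, pr, nSim = 300, percentile = 80,
                                  nPlants = 50, seed = 52))
  ok <- !is.na(t995)
  expect_true(all(is.finite(t995[ok])))
  expect_true(all(t995[ok] > 0))
  expect_true(all(t995[ok] >= t80[ok]))
  expect_warning(nullThreshold(b$snps, pr, nSim = 50, nPlants = 50, seed = 1),
                 "unstable")
})

test_that("significant intervals are maximal runs bridged across one-step gaps", {
  g <- c(1, 1, 9, 9, 1, 9, 1, 1, 1, 9, 9, 1)
  pr <- new("GProfile", chrom = "c", centers = seq_len(12) * 1e4,
            halfWidth = 1e5, step = 1e4, g = g,
            threshold = rep(5, 12))
  iv <- significantIntervals(pr)
  expect_equal(nrow(iv), 2L)  # windows 3,4,6 bridge; 10,11 separate
  expect_equal(iv$start, c(3e4, 1e5))
  expect_equal(iv$end, c(6e4, 1.1e5))
  prNone <- new("GProfile", chrom = "c", centers = seq_len(12) * 1e4,
                halfWidth = 1e5, step = 1e4, g = rep(1, 12),
                threshold = rep(5, 12))
  expect_equal(nrow(significantIntervals(prNone)), 0L)
  expect_error(significantIntervals(smoothG(addG(simulateBulks(
    1e6, 20, NULL, seed = 1)$snps))), "threshold")
})

test_that("planted causal loci are localized by the smoothed G peak", {
  hits <- vapply(1:5, function(s) {
    b <- simulateBulks(2e7, 20000, causalPos = 7.3e6, nPlants = 50,
                       meanDepth = 40, recombRate = 1, seed = 60 + s)
    pr <- smoothG(addG(b$snps))
    abs(windowCenters(pr)[which.max(smoothedG(pr))] - 7.3e6)
  }, numeric(1))
  expect_gte(mean(hits <= 5e5), 0.8)
})

test_that("projection through identity and inversion chains", {
  expect_equal(projectInterval(2e6, 3e6, idChain(), "query")[c("start", "end")],
               list(start = 2e6, end = 3e6))
  inv <- projectInterval(2e6, 3e6, idChain(strand = "-"), "query")
  expect_equal(c(inv$start, inv$end), c(7e6, 8e6))
  # involution: A -> B -> A returns the original interval
  for (strand in c("+", "-")) {
    p1 <- projectInterval(2.2e6, 3.7e6, idChain(strand = strand), "query")
    p2 <- projectInterval(p1$start, p1$end, idChain(strand = strand), "target")
    expect_equal(c(p2$start, p2$end), c(2.2e6, 3.7e6))
  }
  expect_null(projectInterval(1e6, 2e6,
                              transform(idChain(), qstart = 5e6, qend = 6e6,
                                        tstart = 5e6, tend = 6e6), "query"))
})

test_that("projection through split and offset chains tracks block arithmetic", {
  chain <- rbind(
    data.frame(qname = "A", qlen = 1e7, qstart = 0, qend = 4e6, strand = "+",
               tname = "B", tlen = 1.2e7, tstart = 1e6, tend = 5e6,
               nmatch = 4e6, alen = 4e6, mapq = 60, de = NA, tp = NA),
    data.frame(qname = "A", qlen = 1e7, qstart = 5e6, qend = 9e6, strand = "+",
               tname = "B", tlen = 1.2e7, tstart = 7e6, tend = 1.1e7,
               nmatch = 4e6, alen = 4e6, mapq = 60, de = NA, tp = NA))
  p <- projectInterval(3e6, 6e6, chain, "query")
  expect_equal(c(p$start, p$end), c(4e6, 8e6))
  expect_equal(p$n_blocks, 2L)
  expect_equal(p$unmapped_bp, 1e6)  # query [4,5) Mb falls between blocks
})

test_that("consensus interval is the intersection of projections", {
  ivs <- list(r1 = c(0, 3e6), r2 = c(1e6, 4e6), r3 = c(2e6, 5e6))
  chains <- list(r2 = idChain(qname = "r2", tname = "r1"),
                 r3 = idChain(qname = "r3", tname = "r1"))
  cons <- consensusInterval(ivs, chains, anchor = "r1")
  expect_equal(c(cons$start, cons$end), c(2e6, 3e6))
  expect_setequal(cons$support, c("r1", "r2", "r3"))
  # identical intervals: unchanged, support = all
  same <- list(r1 = c(1e6, 2e6), r2 = c(1e6, 2e6))
  cons2 <- consensusInterval(same, chains["r2"], anchor = "r1")
  expect_equal(c(cons2$start, cons2$end), c(1e6, 2e6))
  # order invariance
  cons3 <- consensusInterval(rev(ivs), chains, anchor = "r1")
  expect_equal(cons3[c("start", "end")], cons[c("start", "end")])
})

test_that("consensus degrades gracefully when a reference is unmappable", {
  ivs <- list(r1 = c(0, 3e6), r2 = c(1e6, 4e6), r3 = c(8e6, 9e6))
  offChain <- transform(idChain(qname = "r3", tname = "r1"),
                        qstart = 0, qend = 1e6, tstart = 0, tend = 1e6)
  chains <- list(r2 = idChain(qname = "r2", tname = "r1"), r3 = offChain)
  cons <- consensusInterval(ivs, chains, anchor = "r1")
  expect_equal(cons$unmappable, "r3")
  expect_equal(c(cons$start, cons$end), c(1e6, 3e6))
  # majority rule when the full intersection is empty
  ivs2 <- list(r1 = c(0, 2e6), r2 = c(1e6, 3e6), r3 = c(2.5e6, 4e6))
  chains2 <- list(r2 = idChain(qname = "r2", tname = "r1"),
                  r3 = idChain(qname = "r3", tname = "r1"))
  cons2 <- consensusInterval(ivs2, chains2, anchor = "r1")
  expect_equal(c(cons2$start, cons2$end), c(1e6, 2e6))
  expect_setequal(cons2$support, c("r1", "r2"))
})

test_that("diagnostic SNP selection applies depth then frequency criteria", {
  snps <- data.frame(
    chrom = "c", pos = c(1, 2, 3, 4) * 1e5,
    bulk1_ref = c(0, 0, 12, 0), bulk1_alt = c(30, 30, 18, 8),
    bulk2_ref = c(15, 6, 15, 10), bulk2_alt = c(15, 24, 15, 10))
  out <- selectDiagnosticSnps(snps, expectedFreqs = c(1.0, 0.5), tol = 0.1)
  expect_equal(out$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$reason, c("", "frequency", "frequency", "depth"))
  expect_equal(out$rank[1], 1L)
})
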