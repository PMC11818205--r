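test_that("mutateSeq zero-rate identity, forced change, and base validation", {
  s <- randomSeq(200, seed = 1)
  expect_equal(mutateSeq(s, 0), s)
  m <- mutateSeq("AAAA", 1, seed = 2)
  expect_equal(nchar(m), 4L)
  expect_false(grepl("A", m))
  expect_error(mutateSeq("ACGX", 0.1), "ACGTN")
  expect_equal(mutateSeq("NNNN", 1, seed = 3), "NNNN")  # N never mutated
})

test_that("mutateSeq hit count is binomial and reproducible", {
  s <- randomSeq(1e5, seed = 4)
  m <- mutateSeq(s, 0.01, seed = 5)
  mm <- sum(charToRaw(s) != charToRaw(m))
  expect_lt(abs(mm - 1000), 3 * sqrt(1e5 * 0.01 * 0.99))
  expect_identical(mutateSeq(s, 0.01, seed = 5), m)
  expect_false(identical(mutateSeq(s, 0.01, seed = 6), m))
})

test_that("simulateDiploid plants exact identity inside ROH on a diverged background", {
  roh <- data.frame(chrom = "c1", start = 1e5, end = 4e5)
  sim <- simulateDiploid(c(c1 = 1e6), backgroundDivergence = 0.01,
                         rohSegments = roh, seed = 11)
  a <- charToRaw(sim$hap1[["c1"]]); b <- charToRaw(sim$hap2[["c1"]])
  inside <- (1e5 + 1):4e5
  expect_equal(sum(a[inside] != b[inside]), 0L)
  outMm <- sum(a[-inside] != b[-inside])
  nOut <- 1e6 - 3e5
  expect_lt(abs(outMm - nOut * 0.01), 3 * sqrt(nOut * 0.01 * 0.99))
  # truth alignment mirrors the segment structure with realized divergence
  expect_equal(nrow(sim$alignment), 3L)
  expect_equal(sim$alignment$de[2], 0)
  expect_equal(sum(sim$alignment$alen - sim$alignment$nmatch), outMm)
})

test_that("simulateDiploid zero divergence gives identical haplotypes", {
  sim <- simulateDiploid(c(c1 = 5e4), backgroundDivergence = 0, seed = 1)
  expect_identical(sim$hap1, sim$hap2)
  expect_equal(sim$alignment$de, 0)
})

test_that("simulateDiploid rejects overlapping or out-of-range ROH", {
  bad <- data.frame(chrom = c("c1", "c1"), start = c(0, 5e3), end = c(1e4, 2e4))
  expect_error(simulateDiploid(c(c1 = 1e5), 0.01, bad), "overlap")
  expect_error(simulateDiploid(c(c1 = 1e5), 0.01,
                               data.frame(chrom = "c1", start = 9e4, end = 2e5)),
               "outside")
  expect_error(simulateDiploid(c(c1 = 1e5), 0.5), "backgroundDivergence")
})

test_that("simulateDiploid is bit-reproducible per seed", {
  a <- simulateDiploid(c(c1 = 2e4), 0.02, seed = 42)
  b <- simulateDiploid(c(c1 = 2e4), 0.02, seed = 42)
  expect_identical(a, b)
})

test_that("simulatePanel extremes: single shared pool and all-private", {
  same <- simulatePanel(3, 400, poolSize = 1, privateRate = 0, seed = 1)
  expect_equal(length(unique(same$genomes)), 1L)
  idx <- buildKmerIndex(same$genomes, k = 7)
  expect_true(all(jaccardMatrix(idx) == 1))
  allPriv <- simulatePanel(3, 400, poolSize = 0, privateRate = 1,
                           nBlocks = 2, seed = 2)
  sets <- lapply(allPriv$genomes, oracleKmerSet, k = 15)
  for (a in 1:2) for (b in (a + 1):3)
    expect_length(intersect(sets[[a]], sets[[b]]), 0)
  expect_error(simulatePanel(3, 400, poolSize = 0, privateRate = 0.5,
                             nBlocks = 2), "privateRate")
  expect_identical(simulatePanel(3, 100, 2, 0.5, seed = 9),
                   simulatePanel(3, 100, 2, 0.5, seed = 9))
})

test_that("simulateF2 genotype frequencies are Mendelian without distortion", {
  f2 <- simulateF2(c(chr1 = 100), nMarkers = 60, nIndividuals = 500, seed = 31)
  cnt <- countGenotypes(f2$geno)
  sc <- segregationChi2(cnt$n_AA, cnt$n_AB, cnt$n_BB)
  expect_gte(mean(sc$p >= 1e-5), 0.99)
  # allele A frequency converges to 0.5
  f2b <- simulateF2(c(chr1 = 100), nMarkers = 30, nIndividuals = 2000,
                    seed = 32)
  cnt <- countGenotypes(f2b$geno)
  pA <- (2 * cnt$n_AA + cnt$n_AB) / (2 * rowSums(cnt[, 1:3]))
  expect_lt(max(abs(pA - 0.5)), 0.03)
})

test_that("simulateF2 zero map length gives crossover-free chromosomes", {
  f2 <- simulateF2(c(chr1 = 0), nMarkers = 40, nIndividuals = 20, seed = 33)
  for (j in seq_len(20))
    expect_length(unique(f2$geno[, j]), 1L)
})

test_that("simulateF2 lethal distortion empties the selected homozygote class", {
  f2 <- simulateF2(c(chr1 = 0), nMarkers = 20, nIndividuals = 100,
                   distortionLocus = list(chrom = "chr1", pos = 0.5, s = 1,
                                          against = "AA"),
                   seed = 34)
  expect_equal(sum(f2$geno == "AA"), 0L)
  expect_gt(sum(f2$geno == "BB"), 0L)
})

test_that("simulateF2 missingness and monomorphic regions are honored", {
  f2 <- simulateF2(c(chr1 = 50), nMarkers = 100, nIndividuals = 200,
                   monomorphicRegion = list(chrom = "chr1", start = 0.4,
                                            end = 0.6),
                   missingRate = 0.2, seed = 35)
  fracNA <- mean(is.na(f2$geno))
  expect_lt(abs(fracNA - 0.2), 0.02)
  x <- f2$markers$pos_bp / 1e8
  inreg <- x >= 0.4 & x <= 0.6
  mono <- apply(f2$geno[inreg, , drop = FALSE], 1,
                function(r) length(unique(stats::na.omit(r))) <= 1)
  expect_true(all(mono))
})

test_that("crossover positions follow the requested density", {
  # ~1e4 gametes; chi-square GOF on the CDF-transformed positions
  for (dens in c("uniform", "periphery")) {
    f2 <- simulateF2(c(chr1 = 200), nMarkers = 10, nIndividuals = 5000,
                     crossoverDensity = dens, seed = 36)
    cx <- f2$truth$crossovers$chr1
    expect_gt(length(cx), 5000)
    u <- if (dens == "uniform") cx else (1 + (2 * cx - 1)^3) / 2
    ct <- table(cut(u, seq(0, 1, length.out = 21)))
    gof <- stats::chisq.test(ct)
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("custom density tables are honored and bad tables rejected", {
  tab <- data.frame(x = c(0, 0.5, 1), density = c(2, 0, 2))
  f2 <- simulateF2(c(chr1 = 300), nMarkers = 10, nIndividuals = 2000,
                   crossoverDensity = tab, seed = 37)
  cx <- f2$truth$crossovers$chr1
  # central trough: far fewer crossovers near 0.5 than near the ends
  expect_lt(mean(cx > 0.4 & cx < 0.6), 0.5 * mean(cx < 0.2 | cx > 0.8))
  expect_error(simulateF2(c(chr1 = 100), 10, 10,
                          crossoverDensity = data.frame(x = c(0, 1),
                                                        density = c(0, 0))),
               "normalizable")
})

test_that("simulateBulks closed-form allele frequencies at and away from the locus", {
  b <- simulateBulks(2e7, 4000, causalPos = 5e6, nPlants = 200,
                     meanDepth = 2000, recombRate = 1, seed = 41)
  f1 <- b$snps$bulk1_alt / (b$snps$bulk1_ref + b$snps$bulk1_alt)
  f2 <- b$snps$bulk2_alt / (b$snps$bulk2_ref + b$snps$bulk2_alt)
  d <- abs(b$snps$pos - 5e6)
  near <- d < 1e5          # r < 0.001: selected bulk at ~1.0
  at10 <- abs(d - 1e7) < 2e5  # r = 0.10: selected bulk at ~0.90
  expect_gt(mean(f1[near]), 0.99)
  expect_lt(abs(mean(f1[at10]) - 0.90), 0.01)
  expect_lt(abs(mean(f2) - 0.5), 0.01)   # unselected bulk Mendelian everywhere
  expect_error(simulateBulks(1e6, 10, 5e5, nPlants = 0), "nPlants")
  expect_error(simulateBulks(1e6, 10, 2e6), "causalPos")
})

test_that("null bulks show no G-statistic signal downstream", {
  b <- simulateBulks(2e7, 300, causalPos = NULL, nPlants = 50,
                     meanDepth = 40, seed = 42)
  pr <- smoothG(addG(b$snps), windowWidth = 5e5)
  pr <- nullThreshold(b$snps, pr, nSim = 500, nPlants = 50, seed = 43)
  expect_lt(mean(smoothedG(pr) > gThreshold(pr), na.rm = TRUE), 0.05)
})

test_that("truth sets serialize to BED/TSV/YAML sidecars", {
  dir <- withr::local_tempdir()
  sim <- simulateDiploid(c(c1 = 1e4), 0.01,
                         data.frame(chrom = "c1", start = 2e3, end = 5e3),
                         seed = 2)
  paths <- writeTruthSet(sim$truth, dir)
  expect_true(file.exists(file.path(dir, "roh.bed")))
  expect_true(file.exists(file.path(dir, "truth.yaml")))
  y <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(y$background_divergence, 0.01)
  bed <- read.delim(file.path(dir, "roh.bed"), header = FALSE)
  expect_equal(bed$V2, 2000)
  expect_equal(bed$V3, 5000)
})
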