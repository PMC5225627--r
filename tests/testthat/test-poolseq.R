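syncFromLines <- function(lines) readSync(writeSyncFixture(lines))

test_that("SNP calling applies the coverage and minor-count rules exactly", {
  ## joint minor count 2 < 4: rejected even though both pools are covered
  s1 <- syncFromLines(c("c\t1\tA\t30:0:0:0:0:0\t28:2:0:0:0:0"))
  r1 <- callBiallelicSnps(s1)
  expect_equal(nrow(r1), 0L)
  expect_equal(unname(metadata(r1)$report["low_joint_minor_count"]), 1L)

  ## joint minor 15 >= 4, coverage 30 in [20, 400]: retained with the
  ## per-population frequencies of the global minor allele
  s2 <- syncFromLines(c("c\t1\tA\t25:5:0:0:0:0\t20:10:0:0:0:0"))
  r2 <- callBiallelicSnps(s2)
  expect_equal(nrow(r2), 1L)
  expect_equal(rowData(r2)$major, "A")
  expect_equal(rowData(r2)$minor, "T")
  expect_equal(unname(snpFreq(r2)[1, ]), c(5 / 30, 10 / 30))
})

test_that("a hand-built fixture is filtered exactly as designed", {
  ok <- function(pos, a = "28:6:0:0:0:0", b = "30:4:0:0:0:0")
    sprintf("c\t%d\tA\t%s\t%s", pos, a, b)
  lines <- c(
    ok(1),                                        # retained
    ok(2, a = "10:6:0:0:0:0"),                    # coverage 16 < 20
    ok(3, b = "500:4:0:0:0:0"),                   # coverage 504 > 400
    ok(4, a = "30:1:0:0:0:0", b = "30:2:0:0:0:0"),# joint minor 3 < 4
    ok(5, a = "28:6:4:0:0:0"),                    # third allele >= 4
    ok(6),                                        # retained
    ok(7, a = "34:0:0:0:0:0", b = "36:0:0:0:0:0"),# monomorphic
    ok(8, a = "28:6:2:0:0:0"),                    # stray base < 4: kept
    ok(9, a = "28:6:0:0:12:0"),                   # N reads ignored: kept
    ok(10, a = "0:28:6:0:0:0", b = "0:30:4:0:0:0"),# T/C site: kept
    ok(11, a = "19:1:0:0:0:0", b = "20:0:0:0:0:0"),# coverage 20 ok, minor 1
    ok(12))                                       # retained
  snps <- callBiallelicSnps(syncFromLines(lines))
  expect_equal(GenomicRanges::start(snps), c(1L, 6L, 8L, 9L, 10L, 12L))
  rep <- metadata(snps)$report
  expect_equal(unname(rep["input"]), 12L)
  expect_equal(unname(rep["coverage_low"]), 1L)
  expect_equal(unname(rep["coverage_high"]), 1L)
  expect_equal(unname(rep["low_joint_minor_count"]), 3L)
  expect_equal(unname(rep["multiallelic"]), 1L)
  expect_equal(unname(rep["retained"]), 6L)
  ## site 9: N reads excluded from coverage and from alleles
  expect_equal(unname(snpCoverage(snps)[4, 1]), 34L)
})

test_that("SNP-He evaluates its definition and stays within [0, 1/2]", {
  one <- SNPFrequencies(matrix(0.5, 1, 1))
  expect_equal(unname(snpHe(one)$mean), 0.5)
  two <- SNPFrequencies(matrix(c(0.1, 0.2), 2, 1))
  expect_equal(unname(snpHe(two)$mean), (0.18 + 0.32) / 2)
  ## a site fixed in one population but polymorphic jointly adds zero
  mix <- SNPFrequencies(cbind(p1 = c(0.1, 0), p2 = c(0.1, 0.3)))
  expect_equal(unname(snpHe(mix)$mean["p1"]), 0.09)
  expect_error(snpHe(SNPFrequencies(matrix(numeric(), 0, 2))), "empty")
  rnd <- SNPFrequencies(matrix(runif(300), 100, 3))
  expect_true(all(snpHe(rnd)$perSnp >= 0 & snpHe(rnd)$perSnp <= 0.5))
})

test_that("detection weights hit exact small cases and the classical limit", {
  ## perfect-detection limit recovers the Watterson harmonic denominator
  expect_equal(detectionWeight(4, 1e5, 1), 1 + 1 / 2 + 1 / 3,
               tolerance = 1e-3)
  ## exact enumeration of Binomial(2, i/4) masses
  expect_equal(detectionWeight(4, 2, 1),
               1 * 0.375 + 0.5 * 0.5 + (1 / 3) * 0.375,
               tolerance = 1e-12)
  expect_error(detectionWeight(4, 3, 2), "b > C/2")
  ## pi weight approaches 1 at perfect detection
  expect_equal(piDetectionWeight(4, 1e4, 1), 1, tolerance = 2e-3)
})

test_that("detection weight matches a Monte-Carlo count of detected sites", {
  ## draw the neutral count spectrum directly (Poisson numbers of sites
  ## in class i with weight theta*L/i), push each site through binomial
  ## read sampling, and compare detected density to theta * D(n, C, b)
  set.seed(99)
  n <- 40L; C <- 60L; b <- 2L; theta <- 0.01; L <- 1e6
  Ni <- stats::rpois(n - 1L, theta * L / seq_len(n - 1L))
  det <- 0
  for (i in seq_len(n - 1L)) {
    if (Ni[i] == 0) next
    x <- stats::rbinom(Ni[i], C, i / n)
    det <- det + sum(x >= b & x <= C - b)
  }
  D <- detectionWeight(n, C, b)
  expect_equal(det / (theta * L), D, tolerance = 0.01)
})

test_that("gene-wise theta responds only to segregating sites and not to coverage", {
  ## one gene, ten positions: no segregating site means theta 0
  ann <- tiledGeneAnnotation(1, 10)
  mono <- syncFromLines(sprintf("chr1\t%d\tA\t30:0:0:0:0:0", 1:10))
  t0 <- wattersonThetaPool(mono, ann, filterParams(poolSize = 40))
  expect_equal(unname(t0$genomeMean), 0)
  expect_equal(t0$genes$nValid, 10)

  ## adding segregating sites is monotone non-decreasing in theta
  seg1 <- syncFromLines(c(sprintf("chr1\t%d\tA\t30:0:0:0:0:0", 1:9),
                          "chr1\t10\tA\t27:3:0:0:0:0"))
  seg2 <- syncFromLines(c(sprintf("chr1\t%d\tA\t30:0:0:0:0:0", 1:8),
                          "chr1\t9\tA\t27:3:0:0:0:0",
                          "chr1\t10\tA\t27:3:0:0:0:0"))
  th1 <- wattersonThetaPool(seg1, ann, filterParams(poolSize = 40))
  th2 <- wattersonThetaPool(seg2, ann, filterParams(poolSize = 40))
  expect_gt(th1$genomeMean, t0$genomeMean)
  expect_gt(th2$genomeMean, th1$genomeMean)

  ## genes below the valid-fraction rule in any population drop out
  half <- syncFromLines(sprintf("chr1\t%d\tA\t30:0:0:0:0:0", 1:4))
  expect_equal(length(wattersonThetaPool(
    half, ann, filterParams(poolSize = 40))$retainedGenes), 0L)

  ## doubling coverage on the same underlying pools moves theta < 2%.
  ## Error-free read sampling isolates the coverage correction itself
  ## (min-count error false positives would scale with coverage), and a
  ## small pMin gives a near-complete singleton class so the neutral-law
  ## normalization applies across coverages
  base <- list(nPopulations = 2, Fst = 0.005, nGenes = 600,
               geneLength = 250, seqError = 0, pMin = 1e-4, seed = 23)
  s60 <- simulateSnpPools(do.call(simConfig, c(base, meanCoverage = 60)))
  s120 <- simulateSnpPools(do.call(simConfig, c(base, meanCoverage = 120)))
  expect_identical(s60$truth$popFreq, s120$truth$popFreq)
  p <- filterParams(poolSize = 40)
  g60 <- wattersonThetaPool(s60$sync, s60$annotation, p)$genomeMean
  g120 <- wattersonThetaPool(s120$sync, s120$annotation, p)$genomeMean
  expect_lt(max(abs(g120 / g60 - 1)), 0.02)
})

test_that("population order never leaks into pool estimates", {
  cfg <- simConfig(nPopulations = 3, nGenes = 50, geneLength = 100,
                   meanCoverage = 40, seed = 6)
  sim <- simulateSnpPools(cfg)
  perm <- c(3L, 1L, 2L)
  p <- filterParams(poolSize = 40)
  th <- wattersonThetaPool(sim$sync, sim$annotation, p)$genomeMean
  thP <- wattersonThetaPool(sim$sync[, perm], sim$annotation, p)$genomeMean
  expect_equal(unname(thP), unname(th[perm]))
  snps <- callBiallelicSnps(sim$sync, p)
  snpsP <- callBiallelicSnps(sim$sync[, perm], p)
  expect_equal(unname(snpHe(snpsP)$mean), unname(snpHe(snps)$mean[perm]))
  f <- fstPoolPairwise(snps)$fst
  fP <- fstPoolPairwise(snpsP)$fst
  expect_equal(unname(fP), unname(f[perm, perm]), ignore_attr = TRUE)
})

test_that("pooled Tajima's D tracks its numerator and the spectrum skew", {
  p <- filterParams(poolSize = 40)
  ## neutral-ish small run: sign of D matches sign of pi - theta per gene
  cfg <- simConfig(nPopulations = 2, Fst = 0.01, nGenes = 100,
                   geneLength = 300, meanCoverage = 60, seed = 14)
  sim <- simulateSnpPools(cfg)
  taj <- tajimasDPool(sim$sync, sim$annotation, p)
  g <- taj$genes[is.finite(taj$genes$D), ]
  expect_gt(nrow(g), 50)
  expect_true(all(sign(g$D) == sign(g$piTotal - g$thetaTotal)))

  ## a spectrum skewed toward detectable rare variants (Beta mean ~0.07)
  ## pushes mean D negative
  skew <- simulateSnpPools(simConfig(
    nPopulations = 2, Fst = 0.01, nGenes = 150, geneLength = 300,
    meanCoverage = 60, sfs = "beta", sfsShape1 = 0.8, sfsShape2 = 10,
    seed = 15))
  tajSkew <- tajimasDPool(skew$sync, skew$annotation, p)
  expect_true(all(tajSkew$summary$meanD < 0))
})

test_that("pooled FST boundary cases and the rare-variant depression", {
  cov <- matrix(60L, 2, 2)
  eq <- SNPFrequencies(cbind(a = c(0.2, 0.4), b = c(0.2, 0.4)), cov)
  ## identical observed frequencies: the heterozygosity partition is
  ## exactly zero; the Hudson form discounts sampling noise that these
  ## noiseless inputs lack and so sits at or just below zero
  expect_equal(fstPoolPairwise(eq, estimator = "nei")$fst["a", "b"], 0)
  expect_lte(fstPoolPairwise(eq, poolSize = 40)$fst["a", "b"], 0)
  expect_gt(fstPoolPairwise(eq, poolSize = 40)$fst["a", "b"], -0.06)

  fix <- SNPFrequencies(cbind(a = 0, b = 1),
                        matrix(60L, 1, 2))
  expect_equal(fstPoolPairwise(fix, poolSize = 40)$fst["a", "b"], 1)
  expect_equal(fstPoolPairwise(fix, estimator = "nei")$fst["a", "b"], 1)

  ## hand evaluation of the heterozygosity partition at p = 0.2 vs 0.4
  hand <- SNPFrequencies(cbind(a = 0.2, b = 0.4), matrix(60L, 1, 2))
  expect_equal(fstPoolPairwise(hand, estimator = "nei")$fst["a", "b"],
               0.02 / 0.42, tolerance = 1e-12)

  ## low-frequency SNPs depress the per-SNP mean FST: dropping them
  ## raises it (both estimators)
  cfg <- simConfig(nPopulations = 4, Fst = 0.05, nGenes = 400,
                   geneLength = 500, meanCoverage = 60, seed = 41)
  sim <- simulateSnpPools(cfg, emit = "snps")
  snps <- callBiallelicSnps(sim$sync, filterParams(poolSize = 40))
  common <- snps[rowMeans(snpFreq(snps)) > 0.1, ]
  for (est in c("hudson", "nei")) {
    full <- fstPoolPairwise(snps, est, "meanOfRatios")$fst
    sub <- fstPoolPairwise(common, est, "meanOfRatios")$fst
    expect_lt(mean(full[lower.tri(full)]), mean(sub[lower.tri(sub)]))
  }
})
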