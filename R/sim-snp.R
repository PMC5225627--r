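#' Simulate pooled-sequencing read counts with known truth
#'
#' Generates a [SyncCounts-class] object (plus the matching single-exon
#' gene annotation) under the sampling chain pool sequencing implies, so
#' that every downstream estimator can be checked against recorded ground
#' truth:
#'
#' 1. SNP count: the neutral law places `theta * L * log((1-pMin)/pMin)`
#'    segregating sites on the `L = nGenes * geneLength` simulated
#'    positions, with ancestral allele frequency drawn from the
#'    configured spectrum.
#' 2. Population frequency: Balding-Nichols,
#'    `p_j ~ Beta(p0 (1-F_j)/F_j, (1-p0)(1-F_j)/F_j)`.
#' 3. Pool composition: allele count `a_j ~ Binomial(n, p_j)` among the
#'    `n` haploid genomes in the pool.
#' 4. Reads: coverage `C_j ~ Poisson(meanCoverage_j)`, alternate-allele
#'    reads `~ Binomial(C_j, a_j / n)`, then every read is flipped to a
#'    uniformly chosen different base with probability `seqError` (also
#'    at monomorphic positions, so error rejection is exercised).
#'
#' Sites are independent: no linkage or recombination model (appropriate
#' for genome-wide SNP panels where linked-site effects average out), and
#' no demographic trajectories -- a rare-variant-skewed spectrum is
#' produced directly via `sfs = "beta"`.
#'
#' @param config a [simConfig()] object.
#' @param emit `"all"` emits every simulated position (needed for
#'   gene-wise theta, which counts covered monomorphic positions);
#'   `"snps"` emits only the segregating sites (cheaper, sufficient for
#'   SNP-frequency work).
#' @return A list with components `sync` ([SyncCounts-class]),
#'   `annotation` (single-exon gene [GenomicRanges::GRanges]) and
#'   `truth`, a list holding per-SNP ancestral (`p0`) and per-population
#'   (`popFreq`) frequencies, the drift parameters (`Fst`), the nominal
#'   `theta`, the realized per-population perfect-detection Watterson
#'   expectation `thetaPop` (mean over positions of
#'   `(1 - p^n - (1-p)^n) / a_n`), and the realized per-population mean
#'   SNP heterozygosity over emitted SNPs (`heSnp`).
#' @examples
#' cfg <- simConfig(nPopulations = 2, nGenes = 10, geneLength = 100,
#'                  meanCoverage = 30, seed = 42)
#' sim <- simulateSnpPools(cfg, emit = "snps")
#' sim$truth$heSnp
#' @export
simulateSnpPools <- function(config, emit = c("all", "snps")) {
  stopifnot(inherits(config, "SimConfig"))
  emit <- match.arg(emit)
  set.seed(deriveSeed(config$seed, "snp-pools"))
  npop <- config$nPopulations
  n <- config$poolSize
  L <- config$nGenes * config$geneLength
  pMin <- config$pMin
  Z <- log((1 - pMin) / pMin)
  nSnp <- max(1L, round(config$theta * L * Z))
  if (nSnp > L) stop("theta too large: more SNPs than positions")
  snpPos <- sort(sample.int(L, nSnp))

  p0 <- switch(config$sfs,
    neutral = pMin * exp(stats::runif(nSnp) * Z),
    beta = stats::rbeta(nSnp, config$sfsShape1, config$sfsShape2),
    point = rep(config$sfsPoint, nSnp))

  popFreq <- matrix(0, nSnp, npop, dimnames = list(NULL, config$popNames))
  for (j in seq_len(npop)) {
    k <- (1 - config$Fst[j]) / config$Fst[j]
    popFreq[, j] <- stats::rbeta(nSnp, p0 * k, (1 - p0) * k)
  }

  refIdx <- sample.int(4L, L, replace = TRUE)
  altIdx <- (refIdx[snpPos] + sample.int(3L, nSnp, replace = TRUE) - 1L) %% 4L + 1L
  others <- t(vapply(1:4, function(i) setdiff(1:4, i), integer(3L)))

  keepRows <- if (emit == "all") seq_len(L) else snpPos
  nr <- length(keepRows)
  snpRow <- if (emit == "all") snpPos else seq_len(nSnp)
  assaysOut <- lapply(1:4, function(i) matrix(0L, nr, npop))
  eps <- config$seqError

  for (j in seq_len(npop)) {
    cnt <- matrix(0L, nr, 4L)
    ## pool composition is drawn before coverage so that runs differing
    ## only in sequencing depth share identical underlying pools
    a <- stats::rbinom(nSnp, n, popFreq[, j])
    C <- stats::rpois(nr, config$meanCoverage[j])
    alt <- stats::rbinom(nSnp, C[snpRow], a / n)
    refReads <- C
    refReads[snpRow] <- refReads[snpRow] - alt
    if (eps > 0) {
      eR <- stats::rbinom(nr, refReads, eps)
      refReads <- refReads - eR
      e1 <- stats::rbinom(nr, eR, 1 / 3)
      e2 <- stats::rbinom(nr, eR - e1, 1 / 2)
      e3 <- eR - e1 - e2
      oRef <- others[refIdx[keepRows], , drop = FALSE]
      rows <- seq_len(nr)
      cnt[cbind(rows, oRef[, 1L])] <- cnt[cbind(rows, oRef[, 1L])] + e1
      cnt[cbind(rows, oRef[, 2L])] <- cnt[cbind(rows, oRef[, 2L])] + e2
      cnt[cbind(rows, oRef[, 3L])] <- cnt[cbind(rows, oRef[, 3L])] + e3
      eA <- stats::rbinom(nSnp, alt, eps)
      alt <- alt - eA
      f1 <- stats::rbinom(nSnp, eA, 1 / 3)
      f2 <- stats::rbinom(nSnp, eA - f1, 1 / 2)
      f3 <- eA - f1 - f2
      oAlt <- others[altIdx, , drop = FALSE]
      cnt[cbind(snpRow, oAlt[, 1L])] <- cnt[cbind(snpRow, oAlt[, 1L])] + f1
      cnt[cbind(snpRow, oAlt[, 2L])] <- cnt[cbind(snpRow, oAlt[, 2L])] + f2
      cnt[cbind(snpRow, oAlt[, 3L])] <- cnt[cbind(snpRow, oAlt[, 3L])] + f3
    }
    cnt[cbind(seq_len(nr), refIdx[keepRows])] <-
      cnt[cbind(seq_len(nr), refIdx[keepRows])] + refReads
    cnt[cbind(snpRow, altIdx)] <- cnt[cbind(snpRow, altIdx)] + alt
    for (b in 1:4) assaysOut[[b]][, j] <- cnt[, b]
  }

  zero <- matrix(0L, nr, npop)
  counts <- list(A = assaysOut[[1L]], T = assaysOut[[2L]],
                 C = assaysOut[[3L]], G = assaysOut[[4L]],
                 N = zero, del = zero)
  sync <- SyncCounts(rep("chr1", nr), keepRows, BASES[refIdx[keepRows]],
                     counts, popNames = config$popNames)

  an <- sum(1 / seq_len(n - 1L))
  thetaPop <- colSums(1 - popFreq^n - (1 - popFreq)^n) / (L * an)
  truth <- list(
    snpPos = snpPos, p0 = p0, popFreq = popFreq,
    Fst = stats::setNames(config$Fst, config$popNames),
    thetaNominal = config$theta,
    thetaPop = stats::setNames(thetaPop, config$popNames),
    heSnp = colMeans(2 * popFreq * (1 - popFreq)),
    nPositions = L, seed = config$seed)

  list(sync = sync,
       annotation = tiledGeneAnnotation(config$nGenes, config$geneLength),
       truth = truth)
}
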