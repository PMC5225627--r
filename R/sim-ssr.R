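#' Simulate diploid microsatellite genotypes with known truth
#'
#' Generates an [SSRGenotypes-class] table under a per-locus
#' Balding-Nichols/Dirichlet model.  Each locus draws an ancestral allele
#' count from its class range (wider for species-specific loci,
#' emulating ascertainment toward polymorphic markers) and ancestral
#' frequencies from a symmetric Dirichlet; population frequencies follow
#' `Dirichlet(p0 * (1-F_j)/F_j)`.  Genotypes are drawn in Hardy-Weinberg
#' proportions except that with probability `inbreeding` the two alleles
#' are forced identical by state, and each transmitted allele is a
#' non-amplifying null with probability `nullRate`: a null/visible
#' genotype renders as an apparent homozygote for the visible allele and
#' null/null renders as missing.
#'
#' @param config a [simConfig()] object.
#' @return A list with components `genotypes` ([SSRGenotypes-class]) and
#'   `truth`: per-locus ancestral (`ancestralFreq`) and per-population
#'   (`popFreq`) visible-allele frequencies, per-locus `nullRate`,
#'   per-population expected heterozygosity averaged over loci
#'   (`hePop`, computed from the true frequencies), and the per-locus
#'   allele counts.
#' @examples
#' cfg <- simConfig(nPopulations = 3, nIndividuals = 10, seed = 7)
#' sim <- simulateSsrGenotypes(cfg)
#' sim$truth$hePop
#' @export
simulateSsrGenotypes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(deriveSeed(config$seed, "ssr-genotypes"))
  npop <- config$nPopulations
  nInd <- config$nIndividuals
  nLoci <- config$nLociCross + config$nLociSpecific
  cls <- rep(c("cross-species", "species-specific"),
             c(config$nLociCross, config$nLociSpecific))
  lociNames <- sprintf("%s%02d", ifelse(cls == "cross-species", "cx", "sp"),
                       seq_len(nLoci))
  nAlleles <- integer(nLoci)
  rng <- list(`cross-species` = config$alleleRangeCross,
              `species-specific` = config$alleleRangeSpecific)
  for (l in seq_len(nLoci)) {
    r <- rng[[cls[l]]]
    nAlleles[l] <- if (r[1L] == r[2L]) r[1L] else
      sample(seq(r[1L], r[2L]), 1L)
  }

  rdirichlet <- function(alpha) {
    g <- stats::rgamma(length(alpha), alpha)
    if (all(g == 0)) g[which.max(alpha)] <- 1
    g / sum(g)
  }

  a1 <- matrix(NA_integer_, nLoci, npop * nInd)
  a2 <- matrix(NA_integer_, nLoci, npop * nInd)
  ancestralFreq <- vector("list", nLoci)
  popFreqs <- vector("list", nLoci)
  heLocusPop <- matrix(0, nLoci, npop)
  f <- config$inbreeding

  for (l in seq_len(nLoci)) {
    A <- nAlleles[l]
    labels <- 100L + 2L * (seq_len(A) - 1L)
    p0 <- rdirichlet(rep(config$dirichletAlpha, A))
    ancestralFreq[[l]] <- stats::setNames(p0, labels)
    r <- config$nullRate[l]
    pf <- matrix(0, A, npop)
    for (j in seq_len(npop)) {
      kj <- (1 - config$ssrFst[j]) / config$ssrFst[j]
      pj <- rdirichlet(p0 * kj)
      pf[, j] <- pj
      heLocusPop[l, j] <- 1 - sum(pj^2)
      ## allele states 1..A visible, A+1 = null
      prob <- c(pj * (1 - r), r)
      cols <- (j - 1L) * nInd + seq_len(nInd)
      ib <- stats::runif(nInd) < f
      g1 <- sample.int(A + 1L, nInd, replace = TRUE, prob = prob)
      g2 <- sample.int(A + 1L, nInd, replace = TRUE, prob = prob)
      g2[ib] <- g1[ib]
      null1 <- g1 == A + 1L; null2 <- g2 == A + 1L
      v1 <- ifelse(null1, NA_integer_, labels[g1])
      v2 <- ifelse(null2, NA_integer_, labels[g2])
      ## null/visible renders as apparent homozygote for the visible allele
      v1[null1 & !null2] <- v2[null1 & !null2]
      v2[null2 & !null1] <- v1[null2 & !null1]
      a1[l, cols] <- v1
      a2[l, cols] <- v2
    }
    dimnames(pf) <- list(labels, config$popNames)
    popFreqs[[l]] <- pf
  }

  pop <- factor(rep(config$popNames, each = nInd), levels = config$popNames)
  ind <- paste0(rep(config$popNames, each = nInd), "_",
                sprintf("%02d", rep(seq_len(nInd), npop)))
  genotypes <- SSRGenotypes(a1, a2, pop, cls,
                            lociNames = lociNames, indNames = ind)
  names(ancestralFreq) <- names(popFreqs) <- lociNames
  truth <- list(
    ancestralFreq = ancestralFreq, popFreq = popFreqs,
    nAlleles = stats::setNames(nAlleles, lociNames),
    nullRate = stats::setNames(config$nullRate, lociNames),
    ssrFst = stats::setNames(config$ssrFst, config$popNames),
    hePop = stats::setNames(colMeans(heLocusPop), config$popNames),
    heLocusPop = heLocusPop, seed = config$seed)
  list(genotypes = genotypes, truth = truth)
}
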