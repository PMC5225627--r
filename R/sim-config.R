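#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' The defaults emulate the structure of a nine-population Pool-Seq +
#' microsatellite study of an outcrossing plant at desk scale:
#' 9 pools of 20 diploids (pool size n = 40 haploid genomes), per-pool
#' coverage around 60x, per-site mutation parameter theta = 0.009 over
#' 2000 single-exon genes of 500 bp (about 5e4 emitted SNPs),
#' population differentiation in the 0.02-0.09 pairwise-FST range, and
#' 19 microsatellite loci in two ascertainment classes (12 cross-species
#' loci with few alleles, 7 species-specific loci with more).
#'
#' Population allele frequencies follow the Balding-Nichols model: for a
#' site with ancestral frequency p and drift parameter F, the frequency
#' in population j is Beta(p(1-F_j)/F_j, (1-p)(1-F_j)/F_j).  `Fst` may be
#' a scalar or one value per population; the expected pairwise FST of
#' populations i and j is approximately (F_i + F_j)/2.
#'
#' The ancestral minor-allele frequency law `sfs = "neutral"` is the
#' folded neutral spectrum: density proportional to 1/p on
#' (pMin, 1 - pMin) for the frequency of a randomly labelled allele,
#' folded onto minor frequencies.  `sfs = "beta"` substitutes a
#' Beta(`sfsShape1`, `sfsShape2`) law (e.g. to skew the spectrum toward
#' rare variants); `sfs = "point"` fixes every ancestral frequency at
#' `sfsPoint`.
#'
#' @param nPopulations number of population pools.
#' @param poolSize haploid genomes per pool (must be even: diploids).
#' @param theta per-site mutation parameter driving SNP density.
#' @param Fst Balding-Nichols drift parameter, scalar or per population;
#'   all values in (0, 1).
#' @param meanCoverage mean Poisson sequencing coverage per pool, scalar
#'   or per population.
#' @param seqError per-base sequencing error rate in `[0, 0.01)`; an
#'   erroneous read is assigned a uniformly chosen different base, so
#'   tri-allelic artifacts occur and the biallelic filter has real work.
#' @param nGenes,geneLength number and exon length (bp) of the simulated
#'   single-exon genes.
#' @param sfs ancestral frequency law: `"neutral"`, `"beta"` or `"point"`.
#' @param sfsShape1,sfsShape2 Beta law parameters (used when
#'   `sfs = "beta"`).
#' @param sfsPoint fixed ancestral frequency (used when `sfs = "point"`).
#' @param pMin lower truncation of the neutral law; default
#'   `1/(nPopulations * poolSize)`, one copy in the total sample.
#' @param nIndividuals diploid individuals genotyped per population for
#'   the SSR table.
#' @param nLociCross,nLociSpecific number of cross-species and
#'   species-specific SSR loci.
#' @param alleleRangeCross,alleleRangeSpecific inclusive ranges of the
#'   per-locus ancestral allele counts for the two classes (the larger
#'   species-specific range emulates ascertainment toward polymorphic
#'   markers).
#' @param dirichletAlpha symmetric Dirichlet concentration for ancestral
#'   SSR allele frequencies.
#' @param ssrFst per-population drift parameter for the SSR loci, scalar
#'   or per population.  The default range (0.12-0.22) gives the higher
#'   differentiation of multi-allelic markers (mean pairwise FST ~0.17)
#'   with a modest true diversity spread -- the observed per-population
#'   He spread of a 19-locus panel is then dominated by marker sampling
#'   noise, as in real microsatellite panels.
#' @param nullRate per-locus null-allele rate, scalar or per locus, in
#'   `[0, 0.5)`.
#' @param inbreeding within-population inbreeding f in `[0, 1)`: with
#'   probability f a genotype's two alleles are forced identical by state.
#' @param seed global seed; per-stage child seeds are derived from it by
#'   stage name, so stages can be re-run in isolation and reproduce.
#' @return A validated `SimConfig` object (a classed list).
#' @export
simConfig <- function(nPopulations = 9L,
                      poolSize = 40L,
                      theta = 0.009,
                      Fst = seq(0.02, 0.09, length.out = nPopulations),
                      meanCoverage = 60,
                      seqError = 0.001,
                      nGenes = 2000L,
                      geneLength = 500L,
                      sfs = c("neutral", "beta", "point"),
                      sfsShape1 = 0.5, sfsShape2 = 0.5,
                      sfsPoint = 0.5,
                      pMin = NULL,
                      nIndividuals = 20L,
                      nLociCross = 12L,
                      nLociSpecific = 7L,
                      alleleRangeCross = c(2L, 5L),
                      alleleRangeSpecific = c(5L, 10L),
                      dirichletAlpha = 0.5,
                      ssrFst = seq(0.12, 0.22, length.out = nPopulations),
                      nullRate = 0,
                      inbreeding = 0,
                      seed = 1L) {
  sfs <- match.arg(sfs)
  if (is.null(pMin)) pMin <- 1 / (nPopulations * poolSize)
  cfg <- list(
    nPopulations = as.integer(nPopulations), poolSize = as.integer(poolSize),
    theta = theta, Fst = rep_len(Fst, nPopulations),
    meanCoverage = rep_len(meanCoverage, nPopulations),
    seqError = seqError, nGenes = as.integer(nGenes),
    geneLength = as.integer(geneLength),
    sfs = sfs, sfsShape1 = sfsShape1, sfsShape2 = sfsShape2,
    sfsPoint = sfsPoint, pMin = pMin,
    nIndividuals = as.integer(nIndividuals),
    nLociCross = as.integer(nLociCross),
    nLociSpecific = as.integer(nLociSpecific),
    alleleRangeCross = as.integer(alleleRangeCross),
    alleleRangeSpecific = as.integer(alleleRangeSpecific),
    dirichletAlpha = dirichletAlpha,
    ssrFst = rep_len(ssrFst, nPopulations),
    nullRate = rep_len(nullRate, nLociCross + nLociSpecific),
    inbreeding = inbreeding, seed = as.integer(seed),
    popNames = sprintf("pop%d", seq_len(nPopulations)))
  validateSimConfig(cfg)
  structure(cfg, class = "SimConfig")
}

validateSimConfig <- function(cfg) {
  with(cfg, {
    stopifnot(
      nPopulations >= 1L,
      poolSize >= 2L, poolSize %% 2L == 0L,
      theta > 0,
      all(Fst > 0), all(Fst < 1),
      all(ssrFst > 0), all(ssrFst < 1),
      all(meanCoverage > 0),
      seqError >= 0, seqError < 0.01,
      nGenes >= 1L, geneLength >= 1L,
      pMin > 0, pMin < 0.5,
      nIndividuals >= 2L,
      all(nullRate >= 0), all(nullRate < 0.5),
      inbreeding >= 0, inbreeding < 1)
  })
  invisible(cfg)
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$nPopulations, "populations, pool size", x$poolSize,
      "\n  SNPs: theta =", x$theta, "over", x$nGenes, "genes x",
      x$geneLength, "bp; coverage ~", paste(unique(x$meanCoverage),
      collapse = "/"), "; F in [", min(x$Fst), ",", max(x$Fst), "]\n",
      " SSR:", x$nLociCross, "cross-species +", x$nLociSpecific,
      "species-specific loci,", x$nIndividuals, "diploids/pop\n",
      " seed:", x$seed, "\n")
  invisible(x)
}

## Deterministic per-stage child seed; keeps stages independently
## re-runnable from one global seed.  Kept below 2^31 - 1.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 9973) %% 2147483629)
}
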