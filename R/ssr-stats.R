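## Microsatellite estimators: expected heterozygosity, allelic richness,
## permutation G_IS, EM null-allele frequencies, Weir-Cockerham FST.

selectMarkers <- function(x, markerSet) {
  markerSet <- match.arg(markerSet,
                         c("all", "cross-species", "species-specific"))
  if (markerSet == "all") x else x[rowData(x)$markerClass == markerSet, ]
}

## per-locus, per-population complete-case summaries
locusPopTable <- function(x) {
  a1 <- assay(x, "allele1"); a2 <- assay(x, "allele2")
  pop <- colData(x)$population
  out <- vector("list", nrow(x) * nlevels(pop))
  k <- 0L
  for (l in seq_len(nrow(x))) {
    for (p in levels(pop)) {
      idx <- which(pop == p)
      g1 <- a1[l, idx]; g2 <- a2[l, idx]
      typed <- !is.na(g1)
      k <- k + 1L
      if (!any(typed)) {
        out[[k]] <- list(locus = rownames(x)[l], population = p,
                         nTyped = 0L, Ho = NA_real_, freq = numeric())
        next
      }
      alleles <- c(g1[typed], g2[typed])
      freq <- table(alleles) / length(alleles)
      out[[k]] <- list(locus = rownames(x)[l], population = p,
                       nTyped = sum(typed),
                       Ho = mean(g1[typed] != g2[typed]),
                       freq = stats::setNames(as.numeric(freq),
                                              names(freq)))
    }
  }
  out
}

unbiasedHe <- function(freq, n, correction = "nei1978") {
  raw <- 1 - sum(freq^2)
  if (correction == "nei1978") 2 * n / (2 * n - 1) * raw else raw
}

#' Microsatellite diversity per locus and population
#'
#' Computes, for each locus x population (complete-case within locus:
#' an individual missing at a locus is dropped at that locus only),
#' allele frequencies, observed heterozygosity, expected heterozygosity
#' and the observed allele count, plus per-population summaries: allelic
#' richness `Ar` (mean allele count over loci -- no rarefaction by
#' default, appropriate when all populations are typed for the same
#' number of individuals), mean expected heterozygosity, and the
#' median/quartiles of the per-locus heterozygosities.
#'
#' Expected heterozygosity uses the Nei (1978) small-sample correction
#' `2n/(2n-1) * (1 - sum p^2)` by default (`heBiasCorrection = "raw"`
#' gives the uncorrected gene diversity).
#'
#' @param x an [SSRGenotypes-class] object.
#' @param markerSet `"all"`, `"cross-species"` or `"species-specific"`.
#' @param heBiasCorrection `"nei1978"` (default) or `"raw"`.
#' @param rarefy if `TRUE`, `Ar` is the hypergeometric expectation of
#'   the allele count standardized to the smallest 2n across populations
#'   (for unequal sample sizes); default off.
#' @return A list with `locusStats` (data frame: locus, population,
#'   nTyped, Ho, He, nAlleles) and `popSummary` (data frame: population,
#'   Ar, meanHe, medianHe, q25He, q75He, nLoci).  Locus x population
#'   cells with zero typed individuals are excluded with a warning.
#' @examples
#' cfg <- simConfig(nPopulations = 2, nIndividuals = 8, seed = 3)
#' tab <- simulateSsrGenotypes(cfg)$genotypes
#' ssrDiversity(tab)$popSummary
#' @export
ssrDiversity <- function(x, markerSet = "all",
                         heBiasCorrection = c("nei1978", "raw"),
                         rarefy = FALSE) {
  stopifnot(is(x, "SSRGenotypes"))
  heBiasCorrection <- match.arg(heBiasCorrection)
  x <- selectMarkers(x, markerSet)
  cells <- locusPopTable(x)
  empty <- vapply(cells, function(z) z$nTyped == 0L, logical(1L))
  if (any(empty)) {
    warning(sum(empty), " locus x population cell(s) with zero typed ",
            "individuals were excluded")
    cells <- cells[!empty]
  }
  rarefyN <- NULL
  if (rarefy) {
    nt <- vapply(cells, `[[`, integer(1L), "nTyped")
    rarefyN <- 2L * min(nt)
  }
  locusStats <- do.call(rbind, lapply(cells, function(z) {
    nA <- length(z$freq)
    ar <- if (is.null(rarefyN)) nA else {
      cnt <- round(z$freq * 2 * z$nTyped)
      tot <- sum(cnt)
      sum(1 - exp(lchoose(tot - cnt, rarefyN) - lchoose(tot, rarefyN)))
    }
    data.frame(locus = z$locus, population = z$population,
               nTyped = z$nTyped, Ho = z$Ho,
               He = unbiasedHe(z$freq, z$nTyped, heBiasCorrection),
               nAlleles = ar)
  }))
  popSummary <- do.call(rbind, lapply(split(locusStats,
                                            locusStats$population),
    function(d) data.frame(
      population = d$population[1L],
      Ar = mean(d$nAlleles),
      meanHe = mean(d$He),
      medianHe = stats::median(d$He),
      q25He = unname(stats::quantile(d$He, 0.25)),
      q75He = unname(stats::quantile(d$He, 0.75)),
      nLoci = nrow(d))))
  rownames(popSummary) <- NULL
  list(locusStats = locusStats, popSummary = popSummary)
}

#' Heterozygosity-based inbreeding test (G_IS) with permutations
#'
#' Estimates the within-population inbreeding coefficient as
#' `G_IS = 1 - Ho / Hs`, with `Ho` the observed heterozygosity and `Hs`
#' the unbiased within-population gene diversity, both averaged over
#' loci, and tests heterozygote deficiency by permutation: alleles are
#' re-paired at random among individuals within the population (which
#' preserves allele frequencies and hence `Hs`, and destroys genotypic
#' association), and the one-sided p-value is the proportion of permuted
#' statistics at least as large as the observed one, with the (1+b)/(1+m)
#' correction so p is never zero.
#'
#' @param x an [SSRGenotypes-class] object.
#' @param population population label.
#' @param nPermutations number of permutations (default 999).
#' @param seed seed for the permutation stream.
#' @param markerSet locus subset, as in [ssrDiversity()].
#' @return A data frame row: population, Gis, pValue (one-sided,
#'   heterozygote deficiency), nPermutations, flagged (TRUE when all
#'   loci are monomorphic and G_IS is undefined).
#' @export
gisFis <- function(x, population, nPermutations = 999L, seed = 1L,
                   markerSet = "all") {
  stopifnot(is(x, "SSRGenotypes"), population %in% popNames(x))
  x <- selectMarkers(x, markerSet)
  idx <- which(colData(x)$population == population)
  a1 <- assay(x, "allele1")[, idx, drop = FALSE]
  a2 <- assay(x, "allele2")[, idx, drop = FALSE]
  lociAlleles <- list(); HsL <- numeric(); HoL <- numeric()
  for (l in seq_len(nrow(a1))) {
    typed <- !is.na(a1[l, ])
    if (sum(typed) < 2L) next
    al <- c(a1[l, typed], a2[l, typed])
    n <- sum(typed)
    HsL <- c(HsL, unbiasedHe(table(al) / (2 * n), n))
    HoL <- c(HoL, mean(a1[l, typed] != a2[l, typed]))
    lociAlleles[[length(lociAlleles) + 1L]] <- al
  }
  if (!length(HsL) || mean(HsL) == 0)
    return(data.frame(population = population, Gis = NA_real_,
                      pValue = NA_real_, nPermutations = nPermutations,
                      flagged = TRUE))
  gis <- 1 - mean(HoL) / mean(HsL)
  set.seed(deriveSeed(seed, paste0("gis-", population)))
  exceed <- 0L
  for (b in seq_len(nPermutations)) {
    hoPerm <- vapply(lociAlleles, function(al) {
      perm <- sample(al)
      half <- length(al) / 2L
      mean(perm[seq_len(half)] != perm[half + seq_len(half)])
    }, numeric(1L))
    if (1 - mean(hoPerm) / mean(HsL) >= gis) exceed <- exceed + 1L
  }
  data.frame(population = population, Gis = gis,
             pValue = (1 + exceed) / (1 + nPermutations),
             nPermutations = nPermutations, flagged = FALSE)
}

#' EM estimate of the null-allele frequency at one locus
#'
#' Maximum-likelihood estimation under the classical null-allele model:
#' the true allele set is the visible alleles plus one non-amplifying
#' null, Hardy-Weinberg proportions hold, and the observable classes are
#' heterozygote (i, j), apparent homozygote i (true (i, i) or (i, null)),
#' and blank (null, null) -- missing genotypes are treated as candidate
#' blanks.  The EM iterates expected class memberships until the
#' log-likelihood improves by less than `tol`.
#'
#' @param a1,a2 integer vectors, the two alleles per individual at one
#'   locus in one population (`NA`/`NA` = blank).
#' @param tol log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations; non-convergence raises an error
#'   of class `emNonConvergence` carrying the last iterate.
#' @return A list: `rHat` (null frequency), `freq` (named visible-allele
#'   frequencies), `logLik`, `iterations`, `converged`.
#' @examples
#' set.seed(1)
#' al <- sample(3, 40, TRUE)
#' nullAlleleEM(al[1:20], al[21:40])$rHat   # HWE data, no nulls
#' @export
nullAlleleEM <- function(a1, a2, tol = 1e-8, maxIter = 10000L) {
  stopifnot(length(a1) == length(a2))
  blank <- is.na(a1) & is.na(a2)
  typed <- !is.na(a1) & !is.na(a2)
  N <- sum(blank) + sum(typed)
  if (sum(typed) < 10L)
    warning("fewer than 10 typed individuals; EM estimate is unstable")
  B <- sum(blank)
  g1 <- a1[typed]; g2 <- a2[typed]
  alleles <- sort(unique(c(g1, g2)))
  K <- length(alleles)
  i1 <- match(g1, alleles); i2 <- match(g2, alleles)
  het <- i1 != i2
  ## per-allele copies in heterozygotes, and apparent-homozygote counts
  hcop <- tabulate(c(i1[het], i2[het]), K)
  m <- tabulate(i1[!het], K)
  r <- 0.05
  cnt <- tabulate(c(i1, i2), K)
  p <- cnt / sum(cnt) * (1 - r)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    denom <- p + 2 * r
    t_i <- ifelse(denom > 0, m * p / denom, 0)       # true homozygotes
    u_i <- m - t_i                                   # (i, null) carriers
    p <- (hcop + 2 * t_i + u_i) / (2 * N)
    r <- (sum(u_i) + 2 * B) / (2 * N)
    llNew <- sum(m * log(p^2 + 2 * p * r)) +
      sum(hcop * log(p)) + sum(het) * log(2) +
      (if (B > 0) 2 * B * log(r) else 0)
    if (is.finite(ll) && abs(llNew - ll) < tol) {
      return(list(rHat = r, freq = stats::setNames(p, alleles),
                  logLik = llNew, iterations = it, converged = TRUE))
    }
    ll <- llNew
  }
  stop(structure(class = c("emNonConvergence", "error", "condition"),
                 list(message = sprintf(
                   "null-allele EM did not converge in %d iterations (last r = %.6f)",
                   maxIter, r),
                   call = sys.call(-1L),
                   iterate = list(rHat = r, logLik = ll))))
}

#' Null-allele frequencies for every locus and population
#'
#' Applies [nullAlleleEM()] to each locus x population cell.
#'
#' @param x an [SSRGenotypes-class] object.
#' @return Data frame: locus, population, rHat, converged.
#' @export
nullAlleleTable <- function(x) {
  stopifnot(is(x, "SSRGenotypes"))
  a1 <- assay(x, "allele1"); a2 <- assay(x, "allele2")
  pop <- colData(x)$population
  rows <- list()
  for (l in seq_len(nrow(x))) for (p in levels(pop)) {
    idx <- which(pop == p)
    fit <- tryCatch(
      suppressWarnings(nullAlleleEM(a1[l, idx], a2[l, idx])),
      error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      locus = rownames(x)[l], population = p,
      rHat = if (is.null(fit)) NA_real_ else fit$rHat,
      converged = !is.null(fit))
  }
  do.call(rbind, rows)
}

## Weir & Cockerham (1984) variance components for one allele in a pair
## of populations; n = typed individuals, p = allele frequency, h =
## proportion of individuals heterozygous for this allele.
wcComponents <- function(n1, n2, p1, p2, h1, h2) {
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

#' Pairwise Weir-Cockerham (1984) FST from genotypes
#'
#' Allele-identity-based pairwise differentiation: for every population
#' pair, per locus and allele the Weir-Cockerham variance components
#' a (among populations), b (among individuals within populations) and
#' c (within individuals) are computed, and the multilocus estimate is
#' the ratio of sums `theta = sum(a) / sum(a + b + c)` over alleles and
#' loci (the combination Weir & Cockerham recommend).  Loci with typed
#' individuals in only one of the two populations are skipped for that
#' pair; negative estimates are reported as computed, not truncated.
#'
#' @param x an [SSRGenotypes-class] object.
#' @param markerSet locus subset, as in [ssrDiversity()].
#' @return A list: `fst` (symmetric matrix with zero diagonal, estimator
#'   tag `"WC84"` in `attr(, "estimator")`; `NA` and a `flagged` entry
#'   for pairs with no co-typed polymorphic locus) and `perLocus` (data
#'   frame: pop1, pop2, locus, theta).
#' @export
fstWc84Pairwise <- function(x, markerSet = "all") {
  stopifnot(is(x, "SSRGenotypes"), nPopulations(x) >= 2L)
  x <- selectMarkers(x, markerSet)
  a1 <- assay(x, "allele1"); a2 <- assay(x, "allele2")
  pop <- colData(x)$population
  pops <- levels(pop)
  K <- length(pops)
  fst <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  diag(fst) <- 0
  perLocus <- list(); flagged <- character()
  for (i in seq_len(K - 1L)) for (j in seq((i + 1L), K)) {
    iIdx <- which(pop == pops[i]); jIdx <- which(pop == pops[j])
    sumA <- 0; sumAll <- 0; anyPoly <- FALSE
    for (l in seq_len(nrow(x))) {
      g1i <- a1[l, iIdx]; g2i <- a2[l, iIdx]
      g1j <- a1[l, jIdx]; g2j <- a2[l, jIdx]
      ti <- !is.na(g1i); tj <- !is.na(g1j)
      n1 <- sum(ti); n2 <- sum(tj)
      if (n1 < 1L || n2 < 1L) next
      alleles <- sort(unique(c(g1i[ti], g2i[ti], g1j[tj], g2j[tj])))
      if (length(alleles) < 2L) next
      anyPoly <- TRUE
      locA <- 0; locAll <- 0
      for (al in alleles) {
        p1 <- (sum(g1i[ti] == al) + sum(g2i[ti] == al)) / (2 * n1)
        p2 <- (sum(g1j[tj] == al) + sum(g2j[tj] == al)) / (2 * n2)
        h1 <- mean((g1i[ti] == al) != (g2i[ti] == al))
        h2 <- mean((g1j[tj] == al) != (g2j[tj] == al))
        comp <- wcComponents(n1, n2, p1, p2, h1, h2)
        locA <- locA + comp["a"]; locAll <- locAll + sum(comp)
      }
      perLocus[[length(perLocus) + 1L]] <- data.frame(
        pop1 = pops[i], pop2 = pops[j], locus = rownames(x)[l],
        theta = unname(if (locAll != 0) locA / locAll else NA_real_))
      sumA <- sumA + locA; sumAll <- sumAll + locAll
    }
    if (!anyPoly || sumAll == 0) {
      flagged <- c(flagged, paste(pops[i], pops[j], sep = ":"))
    } else {
      fst[i, j] <- fst[j, i] <- sumA / sumAll
    }
  }
  attr(fst, "estimator") <- "WC84"
  attr(fst, "flagged") <- flagged
  list(fst = fst, perLocus = do.call(rbind, perLocus))
}

#' Flag loci for review (HWE deviation plus high null frequency)
#'
#' Generic screening filter: a locus is flagged when it shows a
#' significant heterozygote deficiency (Bonferroni-adjusted one-sided
#' permutation p below `alpha` in at least one population, locus-wise
#' G_IS test) and its mean EM null-allele frequency is at least
#' `nullThreshold`.  The decision to drop a flagged locus stays with the
#' user.
#'
#' @param x an [SSRGenotypes-class] object.
#' @param alpha significance level after Bonferroni correction.
#' @param nullThreshold null-frequency threshold (default 0.10).
#' @param nPermutations,seed permutation settings per locus/population.
#' @return Data frame: locus, minAdjP, meanNullFreq, flagged.
#' @export
flagLociForReview <- function(x, alpha = 0.05, nullThreshold = 0.10,
                              nPermutations = 999L, seed = 1L) {
  stopifnot(is(x, "SSRGenotypes"))
  nulls <- nullAlleleTable(x)
  rows <- lapply(seq_len(nrow(x)), function(l) {
    xl <- x[l, ]
    ps <- vapply(popNames(x), function(p)
      gisFis(xl, p, nPermutations, seed)$pValue, numeric(1L))
    ps <- ps[!is.na(ps)]
    minAdj <- if (length(ps)) min(pmin(1, ps * nPopulations(x))) else NA_real_
    mn <- mean(nulls$rHat[nulls$locus == rownames(x)[l]], na.rm = TRUE)
    data.frame(locus = rownames(x)[l], minAdjP = minAdj,
               meanNullFreq = mn,
               flagged = isTRUE(minAdj < alpha && mn >= nullThreshold))
  })
  do.call(rbind, rows)
}
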