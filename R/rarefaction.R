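## SNP down-sampling: how many random SNPs are needed for accurate
## expected-heterozygosity estimates and for resolving population rank.

#' Default down-sampling grid
#'
#' Subsample sizes from 100 to 10,000 in steps of 100 and from 10,000
#' to 400,000 in steps of 1000, truncated to the available SNP count.
#'
#' @param total total number of SNPs available.
#' @return Strictly increasing integer vector of grid values.
#' @export
defaultDownsampleGrid <- function(total) {
  g <- unique(c(seq(100L, 10000L, 100L), seq(10000L, 400000L, 1000L)))
  g[g <= total]
}

#' Down-sampling curves of SNP expected heterozygosity
#'
#' For each replicate, `k` SNPs are sampled uniformly without
#' replacement -- the same SNP indices for every population within a
#' replicate -- and the per-population mean `2p(1-p)` is recorded; per
#' grid value the replicate mean and the percentile 95% confidence
#' interval (2.5th/97.5th percentiles of replicate means) are reported.
#' Internally each replicate draws one random permutation of the SNP
#' index and reads every grid value off its prefix cumulative mean,
#' which leaves the marginal distribution at each `k` identical to an
#' independent uniform subsample while costing one pass per replicate.
#'
#' @param snps a [SNPFrequencies-class] object.
#' @param grid subsample sizes; defaults to [defaultDownsampleGrid()].
#'   Values above the SNP count are dropped with a warning.
#' @param nReplicates replicates per grid value (default 1000).
#' @param seed seed for the sampling stream.
#' @return Data frame (class `RarefactionCurve`): population, k, meanHe,
#'   loCI, hiCI; attributes `nReplicates`, `seed`, `grid`.
#' @export
downsampleHe <- function(snps, grid = NULL, nReplicates = 1000L,
                         seed = 1L) {
  stopifnot(is(snps, "SNPFrequencies"), nrow(snps) >= 1L)
  he <- snpHe(snps)$perSnp
  total <- nrow(he)
  if (is.null(grid)) grid <- defaultDownsampleGrid(total)
  grid <- as.integer(grid)
  if (any(grid > total)) {
    warning("grid values above the SNP count (", total, ") were dropped")
    grid <- grid[grid <= total]
  }
  stopifnot(length(grid) >= 1L, all(grid >= 1L), !is.unsorted(grid,
            strictly = TRUE))
  pops <- colnames(he)
  set.seed(deriveSeed(seed, "downsample"))
  means <- array(NA_real_,
                 c(length(grid), nReplicates, length(pops)),
                 dimnames = list(NULL, NULL, pops))
  for (r in seq_len(nReplicates)) {
    perm <- sample.int(total)
    for (j in seq_along(pops)) {
      cs <- cumsum(he[perm, j])
      means[, r, j] <- cs[grid] / grid
    }
  }
  rows <- lapply(seq_along(pops), function(j) {
    m <- means[, , j, drop = FALSE]
    dim(m) <- c(length(grid), nReplicates)
    qs <- apply(m, 1L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    data.frame(population = pops[j], k = grid,
               meanHe = rowMeans(m), loCI = qs[1L, ], hiCI = qs[2L, ])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "nReplicates") <- as.integer(nReplicates)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "grid") <- grid
  class(out) <- c("RarefactionCurve", class(out))
  out
}

#' Smallest subsample sizes meeting CI half-width thresholds
#'
#' For each half-width threshold `h`, the smallest grid `k` at which
#' `(hiCI - loCI)/2 <= h` holds simultaneously for every population
#' (the headline criterion); per-population values are also reported.
#'
#' @param curves output of [downsampleHe()].
#' @param thresholds CI half-width thresholds (default
#'   `c(0.01, 0.005, 0.001)`).
#' @return A list: `k` (named by threshold; `NA` when never satisfied on
#'   the grid) and `perPopulation` (matrix threshold x population).
#' @export
kForCiThresholds <- function(curves, thresholds = c(0.01, 0.005, 0.001)) {
  stopifnot(inherits(curves, "RarefactionCurve"))
  curves$half <- (curves$hiCI - curves$loCI) / 2
  grid <- sort(unique(curves$k))
  pops <- unique(curves$population)
  hw <- matrix(NA_real_, length(grid), length(pops),
               dimnames = list(NULL, pops))
  for (p in pops)
    hw[, p] <- curves$half[curves$population == p][
      order(curves$k[curves$population == p])]
  worst <- apply(hw, 1L, max)
  kAll <- vapply(thresholds, function(h) {
    i <- which(worst <= h)
    if (length(i)) grid[min(i)] else NA_integer_
  }, numeric(1L))
  perPop <- vapply(pops, function(p) vapply(thresholds, function(h) {
    i <- which(hw[, p] <= h)
    if (length(i)) grid[min(i)] else NA_integer_
  }, numeric(1L)), numeric(length(thresholds)))
  perPop <- matrix(perPop, length(thresholds), length(pops),
                   dimnames = list(paste0("h=", thresholds), pops))
  list(k = stats::setNames(kAll, paste0("h=", thresholds)),
       perPopulation = perPop)
}

#' Smallest subsample size resolving the population ranking
#'
#' Populations whose full-data mean heterozygosities differ by at most
#' `tieTolerance` are declared indistinguishable and exempted; the
#' reported `k` is the smallest grid value at which every non-exempt
#' population pair has non-overlapping 95% confidence intervals.
#'
#' @param curves output of [downsampleHe()].
#' @param fullHe named per-population full-data mean SNP-He (e.g.
#'   `snpHe(snps)$mean`).
#' @param tieTolerance full-data He difference at or below which a pair
#'   counts as a tie (default 0.0005, i.e. equality at the third
#'   decimal).
#' @return A list: `k` (`NA` if never resolved on the grid),
#'   `exemptPairs` (data frame pop1/pop2), `vacuous` (TRUE when no pair
#'   is testable).
#' @export
kForRanking <- function(curves, fullHe, tieTolerance = 0.0005) {
  stopifnot(inherits(curves, "RarefactionCurve"))
  pops <- unique(curves$population)
  stopifnot(all(pops %in% names(fullHe)))
  pr <- utils::combn(length(pops), 2L)
  exempt <- abs(fullHe[pops[pr[1L, ]]] - fullHe[pops[pr[2L, ]]]) <=
    tieTolerance
  exemptPairs <- data.frame(pop1 = pops[pr[1L, exempt]],
                            pop2 = pops[pr[2L, exempt]])
  grid <- sort(unique(curves$k))
  if (all(exempt))
    return(list(k = grid[1L], exemptPairs = exemptPairs, vacuous = TRUE))
  lo <- hi <- matrix(NA_real_, length(grid), length(pops),
                     dimnames = list(NULL, pops))
  for (p in pops) {
    sel <- curves$population == p
    o <- order(curves$k[sel])
    lo[, p] <- curves$loCI[sel][o]
    hi[, p] <- curves$hiCI[sel][o]
  }
  resolved <- vapply(seq_along(grid), function(g) {
    all(vapply(which(!exempt), function(k) {
      i <- pops[pr[1L, k]]; j <- pops[pr[2L, k]]
      hi[g, i] < lo[g, j] || hi[g, j] < lo[g, i]
    }, logical(1L)))
  }, logical(1L))
  k <- if (any(resolved)) grid[min(which(resolved))] else NA_integer_
  list(k = k, exemptPairs = exemptPairs, vacuous = FALSE)
}
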