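## Independent oracles used by the test suite.  These deliberately take
## different computational routes than the package implementation.

## Weir-Cockerham theta via the gametic-indicator ANOVA route:
## genotypes is a list of two n_i x 2 allele matrices (one per
## population).  Mean squares among populations / among individuals /
## within individuals are combined by method of moments.
wcAnovaOracle <- function(genotypes) {
  stopifnot(length(genotypes) == 2L)
  alleles <- sort(unique(unlist(genotypes)))
  ni <- vapply(genotypes, nrow, integer(1L))
  N <- sum(ni)
  r <- 2L
  nc <- (N - sum(ni^2) / N) / (r - 1)
  sumA <- 0; sumAll <- 0
  for (al in alleles) {
    x <- lapply(genotypes, function(g) (g == al) + 0)
    indMean <- lapply(x, rowMeans)
    pi <- vapply(indMean, mean, numeric(1L))
    pbar <- sum(ni * pi) / N
    SSG <- sum(vapply(seq_len(2L), function(i)
      sum((x[[i]] - indMean[[i]])^2), numeric(1L)))
    SSI <- 2 * sum(vapply(seq_len(2L), function(i)
      sum((indMean[[i]] - pi[i])^2), numeric(1L)))
    SSP <- 2 * sum(ni * (pi - pbar)^2)
    MSG <- SSG / N
    MSI <- SSI / (N - r)
    MSP <- SSP / (r - 1)
    a <- (MSP - MSI) / (2 * nc)
    b <- (MSI - MSG) / 2
    sumA <- sumA + a
    sumAll <- sumAll + a + b + MSG
  }
  sumA / sumAll
}

## All perfect pairings (matchings) of an even-length allele vector,
## as a list of n x 2 matrices.  Used for the exhaustive G_IS null.
allPairings <- function(alleles) {
  n <- length(alleles)
  if (n == 2L) return(list(matrix(alleles, 1L, 2L)))
  out <- list()
  for (j in 2:n) {
    rest <- allPairings(alleles[-c(1L, j)])
    for (m in rest)
      out[[length(out) + 1L]] <- rbind(c(alleles[1L], alleles[j]), m)
  }
  out
}

## Exhaustive one-sided G_IS p-value on a single-locus population:
## distribution of G_IS over all equally likely allele pairings.
gisExhaustive <- function(a1, a2) {
  alleles <- c(a1, a2)
  n <- length(a1)
  hs <- (2 * n / (2 * n - 1)) * (1 - sum((table(alleles) / (2 * n))^2))
  gObs <- 1 - mean(a1 != a2) / hs
  gAll <- vapply(allPairings(alleles), function(m)
    1 - mean(m[, 1L] != m[, 2L]) / hs, numeric(1L))
  mean(gAll >= gObs - 1e-12)
}

## Exhaustive one-sided Mantel p-value over all label permutations of B.
mantelExhaustive <- function(A, B) {
  lt <- lower.tri(A)
  rObs <- cor(A[lt], B[lt])
  perms <- listPermutations(nrow(A))
  rAll <- vapply(perms, function(p) cor(A[lt], B[p, p][lt]), numeric(1L))
  mean(rAll >= rObs - 1e-12)
}

listPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in listPermutations(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

## Profile-likelihood grid search for the null-allele rate: for each r
## on the grid the visible-allele frequencies are optimized numerically
## (softmax parameterization, optim), independently of the EM updates.
nullAlleleGridOracle <- function(a1, a2, grid = seq(0, 0.5, 0.001)) {
  blank <- sum(is.na(a1) & is.na(a2))
  typed <- !is.na(a1) & !is.na(a2)
  g1 <- a1[typed]; g2 <- a2[typed]
  alleles <- sort(unique(c(g1, g2)))
  K <- length(alleles)
  i1 <- match(g1, alleles); i2 <- match(g2, alleles)
  het <- i1 != i2
  hcop <- tabulate(c(i1[het], i2[het]), K)
  m <- tabulate(i1[!het], K)
  loglik <- function(p, r) {
    sum(m * log(p^2 + 2 * p * r)) + sum(hcop * log(p)) +
      (if (blank > 0) 2 * blank * log(r) else 0)
  }
  profile <- vapply(grid, function(r) {
    if (r == 0 && blank > 0) return(-Inf)
    obj <- function(z) {
      p <- exp(z) / sum(exp(z)) * (1 - r)
      -loglik(p, r)
    }
    cnt <- tabulate(c(i1, i2), K)
    fit <- optim(log(cnt / sum(cnt) + 1e-6), obj, method = "BFGS",
                 control = list(maxit = 500))
    -fit$value
  }, numeric(1L))
  grid[which.max(profile)]
}

## Small deterministic sync text builder for parser tests.
writeSyncFixture <- function(lines, path = tempfile(fileext = ".sync")) {
  writeLines(lines, path)
  path
}
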