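## Statistical comparison battery between marker types and estimators.

testResult <- function(test, statistic, pValue, n, sided,
                       pAdjusted = NA_real_, adjustMethod = NA_character_,
                       seed = NA_integer_, flagged = FALSE) {
  data.frame(test = test, statistic = statistic, pValue = pValue,
             pAdjusted = pAdjusted, adjustMethod = adjustMethod,
             n = n, sided = sided, seed = seed, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Correlation test between per-population estimates
#'
#' Pearson's r or Spearman's rho (midranks for ties) with a two-sided
#' p-value from the t-approximation on `n - 2` degrees of freedom.
#' Zero variance in either variable yields a flagged, undefined result
#' instead of an error.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite.
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row data frame (test, statistic, pValue, n, sided,
#'   flagged, ...).
#' @examples
#' correlationTest(1:9, 2 * (1:9) + 1)
#' @export
correlationTest <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(testResult(paste0("correlation_", method), NA_real_, NA_real_,
                      length(x), "two-sided", flagged = TRUE))
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  testResult(paste0("correlation_", method), unname(ct$estimate),
             ct$p.value, length(x), "two-sided")
}

#' Paired t-test between two per-unit estimate vectors
#'
#' Student's t on the paired differences with `n - 1` degrees of
#' freedom, two-sided.  Zero-variance differences (including identical
#' inputs) give a flagged degenerate result, never a silent `p = 0`.
#'
#' @param a,b numeric vectors paired by shared unit (population or
#'   population pair), equal length >= 2.
#' @return A one-row data frame as in [correlationTest()].
#' @export
pairedTTest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) == 0)
    return(testResult("paired_t", NA_real_, NA_real_, length(a),
                      "two-sided", flagged = TRUE))
  tt <- stats::t.test(a, b, paired = TRUE)
  testResult("paired_t", unname(tt$statistic), tt$p.value, length(a),
             "two-sided")
}

#' Pairwise Wilcoxon signed-rank tests across populations
#'
#' For every pair of populations, a Wilcoxon signed-rank test on the
#' paired per-locus values (zero differences dropped; exact p-value for
#' up to 25 informative pairs and no ties, otherwise the normal
#' approximation with continuity correction), Bonferroni-adjusted over
#' all population pairs.  A pair whose differences are all zero gets
#' `p = 1`.
#'
#' @param valuesMatrix numeric matrix, loci x populations (paired by
#'   locus), at least 6 loci.
#' @param adjust p-adjustment method (default `"bonferroni"`).
#' @return Data frame with one row per population pair (pop1, pop2
#'   prepended to the [correlationTest()] columns).
#' @export
pairwiseWilcoxon <- function(valuesMatrix, adjust = "bonferroni") {
  stopifnot(is.matrix(valuesMatrix), nrow(valuesMatrix) >= 6L,
            ncol(valuesMatrix) >= 2L)
  pops <- colnames(valuesMatrix)
  if (is.null(pops)) pops <- paste0("pop", seq_len(ncol(valuesMatrix)))
  pr <- utils::combn(ncol(valuesMatrix), 2L)
  rows <- lapply(seq_len(ncol(pr)), function(k) {
    i <- pr[1L, k]; j <- pr[2L, k]
    d <- valuesMatrix[, i] - valuesMatrix[, j]
    d <- d[d != 0]
    if (!length(d)) {
      res <- testResult("wilcoxon_signed_rank", NA_real_, 1, 0L,
                        "two-sided")
    } else if (length(d) <= 25L && length(unique(sign(d))) == 1L) {
      ## all informative differences share one sign: the statistic is at
      ## its extreme and the exact two-sided p is 2/2^n whether or not
      ## the absolute values are tied
      v <- if (d[1L] > 0) length(d) * (length(d) + 1) / 2 else 0
      res <- testResult("wilcoxon_signed_rank", v,
                        min(1, 2 / 2^length(d)), length(d), "two-sided")
    } else {
      wt <- suppressWarnings(stats::wilcox.test(
        d, exact = length(d) <= 25L && !anyDuplicated(abs(d)),
        correct = TRUE))
      res <- testResult("wilcoxon_signed_rank", unname(wt$statistic),
                        wt$p.value, length(d), "two-sided")
    }
    cbind(data.frame(pop1 = pops[i], pop2 = pops[j]), res)
  })
  out <- do.call(rbind, rows)
  out$pAdjusted <- stats::p.adjust(out$pValue, method = adjust)
  out$adjustMethod <- adjust
  out
}

#' Mantel test between two distance/differentiation matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance
#' from jointly permuting the row/column labels of `B`.  One-sided for
#' positive association by default (the usual direction when comparing
#' FST matrices); the permutation p-value uses the `(1 + b)/(1 + m)`
#' estimator and so never reaches zero.
#'
#' @param A,B symmetric hollow matrices with identical dimnames in
#'   identical order.
#' @param nPermutations number of permutations (default 1001).
#' @param seed seed for the permutation stream.
#' @param alternative `"greater"` (one-sided positive, default) or
#'   `"two-sided"`.
#' @return A one-row data frame as in [correlationTest()].
#' @export
mantelTest <- function(A, B, nPermutations = 1001L, seed = 1L,
                       alternative = c("greater", "two-sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(A), is.matrix(B), identical(dim(A), dim(B)))
  if (!identical(rownames(A), rownames(B)) ||
      !identical(colnames(A), colnames(B)))
    stop("matrix labels differ or are ordered differently")
  lt <- lower.tri(A)
  r <- stats::cor(A[lt], B[lt])
  set.seed(deriveSeed(seed, "mantel"))
  K <- nrow(A)
  exceed <- 0L
  for (p in seq_len(nPermutations)) {
    perm <- sample.int(K)
    rp <- stats::cor(A[lt], B[perm, perm][lt])
    hit <- if (alternative == "greater") rp >= r else abs(rp) >= abs(r)
    if (hit) exceed <- exceed + 1L
  }
  testResult("mantel", r, (1 + exceed) / (1 + nPermutations),
             sum(lt), alternative, seed = as.integer(seed))
}

#' Test per-gene Tajima's D against zero
#'
#' Welch two-sample t-test between the observed per-gene D values and a
#' same-size pseudo-sample drawn from `Normal(0, sd(observed))` with the
#' given seed -- a deliberately simulation-based reference (the result
#' records the seed since the procedure is stochastic by design).
#' `oneSample = TRUE` gives the conventional one-sample t-test against
#' zero instead.
#'
#' @param d numeric vector of per-gene Tajima's D values (>= 10).
#' @param seed seed for the pseudo-sample.
#' @param oneSample use the standard one-sample test instead.
#' @return A one-row data frame as in [correlationTest()].
#' @export
tajimaZeroTest <- function(d, seed = 1L, oneSample = FALSE) {
  stopifnot(length(d) >= 10L)
  if (stats::sd(d) == 0)
    return(testResult("tajima_d_vs_zero", NA_real_, NA_real_, length(d),
                      "two-sided", seed = as.integer(seed),
                      flagged = TRUE))
  if (oneSample) {
    tt <- stats::t.test(d, mu = 0)
    return(testResult("tajima_d_vs_zero_onesample", unname(tt$statistic),
                      tt$p.value, length(d), "two-sided"))
  }
  set.seed(deriveSeed(seed, "tajima-zero"))
  ref <- stats::rnorm(length(d), 0, stats::sd(d))
  tt <- stats::t.test(d, ref)
  testResult("tajima_d_vs_zero", unname(tt$statistic), tt$p.value,
             length(d), "two-sided", seed = as.integer(seed))
}
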