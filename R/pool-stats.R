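## Pool-Seq estimators from per-site read counts.

#' Pool-Seq filter parameters
#'
#' Bundles the coverage and minor-allele-count thresholds applied to
#' per-site pooled read counts.  Defaults are the standard settings for
#' pools of 20 diploids: per-population coverage in `[20, 400]` (the
#' lower bound mimics the number of individuals, the upper bound guards
#' against collapsed repeats), within-population minor count 2 (a
#' minor-allele frequency floor of 2/40 = 0.05 against sequencing
#' errors), joint minor count 4 across all populations (frequency floor
#' 4/(9*40) = 0.011 when nine populations are pooled jointly), pool size
#' 40 haploid genomes, Tajima's-D coverage floor `floor(poolSize/3)` =
#' 13, and gene inclusion when at least 50% of a gene's exonic positions
#' are validly covered in all populations.
#'
#' @param minCoverage,maxCoverage per-population nucleotide coverage
#'   bounds (N and deletion reads never count toward coverage).
#' @param minMinorCountWithin within-population minor-allele count floor
#'   used for segregating-site calls (theta, Tajima's D).
#' @param minMinorCountJoint joint (summed over populations) minor count
#'   floor used by [callBiallelicSnps()].
#' @param poolSize haploid genomes per pool.
#' @param tajimaMinCoverage coverage floor for Tajima's D.
#' @param geneValidFraction minimum fraction of a gene's exonic
#'   positions with valid coverage, required in every population.
#' @return A validated classed list.
#' @export
filterParams <- function(minCoverage = 20L, maxCoverage = 400L,
                         minMinorCountWithin = 2L,
                         minMinorCountJoint = 4L,
                         poolSize = 40L,
                         tajimaMinCoverage = floor(poolSize / 3),
                         geneValidFraction = 0.5) {
  p <- list(minCoverage = as.integer(minCoverage),
            maxCoverage = as.integer(maxCoverage),
            minMinorCountWithin = as.integer(minMinorCountWithin),
            minMinorCountJoint = as.integer(minMinorCountJoint),
            poolSize = as.integer(poolSize),
            tajimaMinCoverage = as.integer(tajimaMinCoverage),
            geneValidFraction = geneValidFraction)
  stopifnot(p$minCoverage > 0L, p$minCoverage <= p$maxCoverage,
            p$minMinorCountWithin >= 1L, p$minMinorCountJoint >= 1L,
            p$poolSize >= 2L, p$tajimaMinCoverage >= 1L,
            p$geneValidFraction > 0, p$geneValidFraction <= 1)
  structure(p, class = "FilterParams")
}

## second-largest of the four nucleotide count matrices
secondLargest <- function(A, T, C, G) {
  m12 <- pmax(A, T); n12 <- pmin(A, T)
  m34 <- pmax(C, G); n34 <- pmin(C, G)
  pmax(pmin(m12, m34), ifelse(m12 >= m34, n12, n34))
}

#' Call biallelic SNPs from pooled read counts
#'
#' A site is retained iff (i) every population's nucleotide coverage
#' lies in `[minCoverage, maxCoverage]`; (ii) the second-largest summed
#' (across populations) allele count is at least `minMinorCountJoint`
#' (defining the global minor allele); and (iii) no third allele reaches
#' that count -- genuinely multi-allelic sites are dropped entirely, not
#' reduced to their top two alleles, while sub-threshold stray bases
#' (sequencing error) are ignored.  Per-population minor-allele
#' frequencies are computed from the retained (major + minor) read
#' counts.  Rejected sites are tallied by the first failing rule in
#' `metadata()$report`.
#'
#' @param sync a [SyncCounts-class] object.
#' @param params a [filterParams()] object.
#' @return A [SNPFrequencies-class] object.
#' @export
callBiallelicSnps <- function(sync, params = filterParams()) {
  stopifnot(is(sync, "SyncCounts"), inherits(params, "FilterParams"))
  A <- assay(sync, "A"); T <- assay(sync, "T")
  C <- assay(sync, "C"); G <- assay(sync, "G")
  cov <- A + T + C + G
  tooLow <- rowSums(cov < params$minCoverage) > 0L
  tooHigh <- !tooLow & rowSums(cov > params$maxCoverage) > 0L
  joint <- cbind(A = rowSums(A), T = rowSums(T),
                 C = rowSums(C), G = rowSums(G))
  n <- nrow(joint)
  rows <- seq_len(n)
  tmp <- joint
  majorIdx <- max.col(tmp, ties.method = "first")
  tmp[cbind(rows, majorIdx)] <- -1
  minorIdx <- max.col(tmp, ties.method = "first")
  minorCnt <- joint[cbind(rows, minorIdx)]
  tmp[cbind(rows, minorIdx)] <- -1
  thirdCnt <- joint[cbind(rows, max.col(tmp, ties.method = "first"))]
  covOK <- !tooLow & !tooHigh
  lowMinor <- covOK & minorCnt < params$minMinorCountJoint
  multi <- covOK & !lowMinor & thirdCnt >= params$minMinorCountJoint
  keep <- covOK & !lowMinor & !multi
  report <- c(input = n, coverage_low = sum(tooLow),
              coverage_high = sum(tooHigh),
              low_joint_minor_count = sum(lowMinor),
              multiallelic = sum(multi), retained = sum(keep))
  counts <- list(A, T, C, G)
  idx <- which(keep)
  majorReads <- matrix(0L, length(idx), ncol(A))
  minorReads <- matrix(0L, length(idx), ncol(A))
  for (b in 1:4) {
    sel <- majorIdx[idx] == b
    if (any(sel)) majorReads[sel, ] <- counts[[b]][idx[sel], , drop = FALSE]
    sel <- minorIdx[idx] == b
    if (any(sel)) minorReads[sel, ] <- counts[[b]][idx[sel], , drop = FALSE]
  }
  denom <- majorReads + minorReads
  freq <- ifelse(denom > 0L, minorReads / denom, 0)
  dimnames(freq) <- list(NULL, popNames(sync))
  covOut <- cov[idx, , drop = FALSE]
  dimnames(covOut) <- dimnames(freq)
  gr <- rowRanges(sync)[idx]
  mcols(gr) <- NULL
  mcols(gr)$major <- colnames(joint)[majorIdx[idx]]
  mcols(gr)$minor <- colnames(joint)[minorIdx[idx]]
  se <- SummarizedExperiment(
    assays = list(freq = freq, coverage = covOut), rowRanges = gr,
    colData = DataFrame(population = popNames(sync),
                        row.names = popNames(sync)))
  out <- new("SNPFrequencies", se)
  metadata(out)$params <- params
  metadata(out)$report <- report
  out
}

#' Mean SNP expected heterozygosity
#'
#' `SNP-He = (1/n) * sum 2 p_i (1 - p_i)` over the retained SNPs, with
#' `p_i` the population's frequency of the globally-defined minor
#' allele.  Assumes Hardy-Weinberg equilibrium within populations.
#'
#' @param snps a [SNPFrequencies-class] object (must be non-empty).
#' @param population optional label(s); default all populations.
#' @return A list: `mean` (named per-population means) and `perSnp`
#'   (sites x populations matrix of `2p(1-p)`).
#' @export
snpHe <- function(snps, population = NULL) {
  stopifnot(is(snps, "SNPFrequencies"))
  if (nrow(snps) == 0L) stop("empty SNP table: SNP-He is undefined")
  q <- snpFreq(snps)
  if (!is.null(population)) {
    stopifnot(all(population %in% colnames(q)))
    q <- q[, population, drop = FALSE]
  }
  perSnp <- 2 * q * (1 - q)
  list(mean = colMeans(perSnp), perSnp = perSnp)
}

#' Expected detected segregating sites per unit theta
#'
#' The detection weight `D(n, C, b)` is the expected number of detected
#' segregating sites per site and per unit theta, under the neutral
#' frequency spectrum (class `i` of `n - 1` carrying weight `1/i`) with
#' binomial read sampling at coverage `C` and a two-sided minor-read
#' floor `b`:
#' `D = sum_{i=1}^{n-1} (1/i) P(b <= X <= C - b)`, `X ~ Binomial(C, i/n)`.
#' Dividing the observed count of detected segregating sites by the sum
#' of site-specific weights corrects Watterson's theta for both pool
#' size and coverage-dependent detection; as `C -> Inf` with `b = 1` the
#' weight recovers the classical harmonic denominator
#' `a_n = sum 1/i`.
#'
#' @param n pool size (haploid genomes), `n >= 2`.
#' @param C coverage (vectorized).
#' @param b minor-allele read-count floor, `1 <= b <= C/2`.
#' @return Numeric vector of weights, one per coverage value.
#' @examples
#' detectionWeight(4, 1e5, 1)   # ~ 1 + 1/2 + 1/3
#' detectionWeight(4, 2, 1)     # exact small-case value 0.75
#' @export
detectionWeight <- function(n, C, b) {
  stopifnot(n >= 2L, all(C >= 1L), b >= 1L)
  if (any(b > C / 2))
    stop("b > C/2: no detectable allele configuration at this coverage")
  i <- seq_len(n - 1L)
  vapply(C, function(cc)
    sum((pbinom(cc - b, cc, i / n) - pbinom(b - 1L, cc, i / n)) / i),
    numeric(1L))
}

#' Expected detected pairwise diversity per unit theta
#'
#' Companion weight for the pooled pairwise-diversity (pi) estimator:
#' the expected value, per site and unit theta under the neutral
#' spectrum, of the per-site pi statistic
#' `(C/(C-1)) (n/(n-1)) 2 (X/C)(1 - X/C)` restricted to the detection
#' window `b <= X <= C - b` (outside it the minor allele is discarded
#' and the site contributes zero).  Normalizing summed per-site pi by
#' the summed weights yields a pi-based theta estimate on the same scale
#' as the Watterson one, which is what pooled Tajima's D requires.
#'
#' @inheritParams detectionWeight
#' @return Numeric vector of weights, one per coverage value.
#' @export
piDetectionWeight <- function(n, C, b) {
  stopifnot(n >= 2L, all(C >= 2L), b >= 1L)
  if (any(b > C / 2))
    stop("b > C/2: no detectable allele configuration at this coverage")
  i <- seq_len(n - 1L)
  vapply(C, function(cc) {
    x <- seq(b, cc - b)
    contrib <- vapply(i, function(ii)
      sum(dbinom(x, cc, ii / n) * 2 * x * (cc - x) / cc^2), numeric(1L))
    (cc / (cc - 1)) * (n / (n - 1)) * sum(contrib / i)
  }, numeric(1L))
}

## map sync rows to annotation gene ids; NA for intergenic rows
geneIndexOf <- function(sync, annotation) {
  hits <- GenomicRanges::findOverlaps(rowRanges(sync), annotation,
                                      select = "first")
  annotation$gene_id[hits]
}

#' Detection-corrected Watterson's theta per gene from pooled counts
#'
#' For each gene and population: valid positions are the gene's exonic
#' positions with nucleotide coverage in `[minCoverage, maxCoverage]`;
#' segregating positions are valid positions whose within-population
#' minor (second-largest nucleotide) count is at least
#' `minMinorCountWithin`; and the per-site estimate is
#' `theta = S / sum(D(n, C_site, b))`, the detected segregating-site
#' count over the summed site-specific detection weights
#' ([detectionWeight()]).  A gene enters the genome-wide (unweighted
#' over genes) mean only when its valid-position fraction reaches
#' `geneValidFraction` in every population -- the fraction is taken over
#' covered positions, not over called SNPs, because SNP status itself
#' depends on the same thresholds.
#'
#' @param sync a [SyncCounts-class] object.
#' @param annotation merged exon [GenomicRanges::GRanges] with a
#'   `gene_id` column ([readExonAnnotation()]).
#' @param params a [filterParams()] object.
#' @return A list: `genes` (data frame: gene, population, theta, nValid,
#'   nSeg, validFrac), `genomeMean` (named per-population mean theta
#'   over retained genes), `retainedGenes`, `nGenesExcluded`.
#' @export
wattersonThetaPool <- function(sync, annotation, params = filterParams()) {
  thetaEngine(sync, annotation, params, tajima = FALSE)
}

tajimaConstants <- function(m) {
  i <- seq_len(m - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (m + 1) / (3 * (m - 1))
  b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Pooled Tajima's D per gene
#'
#' Contrasts two detection-corrected per-site diversity estimates per
#' gene and population: the pairwise estimate (per-site pi computed from
#' alleles passing the minor-count floor, corrected for read sampling by
#' `C/(C-1)` and for pool size by `n/(n-1)`, normalized by the summed
#' [piDetectionWeight()]s) and the Watterson estimate (as in
#' [wattersonThetaPool()]), both accumulated over the gene's valid
#' positions (coverage floor `tajimaMinCoverage`, by the usual
#' pool-size/3 rule).  The difference of the two gene totals is
#' standardized by the classical variance approximation evaluated at an
#' effective sample size `min(poolSize, mean valid coverage)`; values
#' are approximate by construction and labelled so in pipeline output.
#'
#' @inheritParams wattersonThetaPool
#' @return A list: `genes` (data frame: gene, population, D, piTotal,
#'   thetaTotal, nValid, nSeg), `summary` (data frame per population:
#'   meanD, sdD, nGenes), `retainedGenes`.
#' @export
tajimasDPool <- function(sync, annotation, params = filterParams()) {
  thetaEngine(sync, annotation, params, tajima = TRUE)
}

thetaEngine <- function(sync, annotation, params, tajima) {
  stopifnot(is(sync, "SyncCounts"))
  n <- params$poolSize
  b <- params$minMinorCountWithin
  minCov <- if (tajima) params$tajimaMinCoverage else params$minCoverage
  gene <- geneIndexOf(sync, annotation)
  inGene <- !is.na(gene)
  if (!any(inGene)) stop("no sync positions overlap the annotation")
  sub <- sync[inGene, ]
  gene <- gene[inGene]
  geneLen <- tapply(GenomicRanges::width(annotation),
                    annotation$gene_id, sum)
  A <- assay(sub, "A"); T <- assay(sub, "T")
  C <- assay(sub, "C"); G <- assay(sub, "G")
  cov <- A + T + C + G
  valid <- cov >= minCov & cov <= params$maxCoverage
  M2 <- secondLargest(A, T, C, G)
  seg <- valid & M2 >= b
  uc <- sort(unique(cov[valid & cov > 0]))
  Dtab <- numeric(max(uc))
  Dtab[uc] <- detectionWeight(n, uc, b)
  Dsite <- matrix(0, nrow(cov), ncol(cov))
  Dsite[valid] <- Dtab[cov[valid]]
  gf <- factor(gene, levels = unique(gene))
  nValid <- rowsum(valid + 0, gf)
  nSeg <- rowsum(seg + 0, gf)
  Dsum <- rowsum(Dsite, gf)
  pops <- popNames(sync)
  genes <- rownames(nValid)
  validFrac <- sweep(nValid, 1L, as.numeric(geneLen[genes]), "/")
  ## genes absent from the sync entirely have validFrac 0 everywhere and
  ## are excluded below together with under-covered ones
  retained <- genes[apply(validFrac >= params$geneValidFraction, 1L, all)]

  if (!tajima) {
    theta <- ifelse(Dsum > 0, nSeg / Dsum, NA_real_)
    df <- data.frame(
      gene = rep(genes, times = length(pops)),
      population = rep(pops, each = length(genes)),
      theta = as.vector(theta), nValid = as.vector(nValid),
      nSeg = as.vector(nSeg), validFrac = as.vector(validFrac))
    keep <- df$gene %in% retained
    gm <- vapply(pops, function(p)
      mean(df$theta[keep & df$population == p], na.rm = TRUE),
      numeric(1L))
    return(list(genes = df, genomeMean = gm, retainedGenes = retained,
                nGenesExcluded = length(genes) - length(retained)))
  }

  ## pi per site from alleles passing the count floor
  Ak <- A * (A >= b); Tk <- T * (T >= b)
  Ck <- C * (C >= b); Gk <- G * (G >= b)
  Cr <- Ak + Tk + Ck + Gk
  ss <- Ak^2 + Tk^2 + Ck^2 + Gk^2
  pi <- matrix(0, nrow(cov), ncol(cov))
  ok <- valid & Cr > 1L
  pi[ok] <- (Cr[ok] / (Cr[ok] - 1)) * (n / (n - 1)) *
    (1 - ss[ok] / Cr[ok]^2)
  Dpitab <- numeric(max(uc))
  Dpitab[uc] <- piDetectionWeight(n, uc, b)
  DpiSite <- matrix(0, nrow(cov), ncol(cov))
  DpiSite[valid] <- Dpitab[cov[valid]]
  piSum <- rowsum(pi, gf)
  DpiSum <- rowsum(DpiSite, gf)
  covSum <- rowsum(cov * valid, gf)
  thetaPi <- ifelse(DpiSum > 0, piSum / DpiSum, NA_real_)
  thetaW <- ifelse(Dsum > 0, nSeg / Dsum, NA_real_)
  piTot <- thetaPi * nValid
  thTot <- thetaW * nValid
  cbar <- ifelse(nValid > 0, covSum / nValid, NA_real_)
  meff <- pmin(round(cbar), n)   # pmin keeps the matrix shape this way
  D <- matrix(NA_real_, nrow(nValid), ncol(nValid))
  for (r in seq_len(nrow(nValid))) for (j in seq_len(ncol(nValid))) {
    S <- nSeg[r, j]
    if (is.na(meff[r, j]) || meff[r, j] < 4L || S < 1L ||
        nValid[r, j] < 2L) next
    k <- tajimaConstants(meff[r, j])
    V <- k$e1 * S + k$e2 * S * (S - 1)
    if (V > 0) D[r, j] <- (piTot[r, j] - thTot[r, j]) / sqrt(V)
  }
  df <- data.frame(
    gene = rep(genes, times = length(pops)),
    population = rep(pops, each = length(genes)),
    D = as.vector(D), piTotal = as.vector(piTot),
    thetaTotal = as.vector(thTot), nValid = as.vector(nValid),
    nSeg = as.vector(nSeg))
  keep <- df$gene %in% retained & is.finite(df$D)
  summary <- do.call(rbind, lapply(pops, function(p) {
    v <- df$D[keep & df$population == p]
    data.frame(population = p, meanD = mean(v), sdD = stats::sd(v),
               nGenes = length(v))
  }))
  list(genes = df, summary = summary, retainedGenes = retained)
}

#' Pooled pairwise FST from SNP frequencies
#'
#' Two per-SNP statistics are offered for a population pair with
#' minor-allele frequencies `q1`, `q2`:
#'
#' * `"hudson"` (default): `1 - Hw / Hb` with the within-pair
#'   heterozygosity `Hw = (hS1 + hS2)/2`,
#'   `hS_j = 2 q_j (1 - q_j) * C_j/(C_j - 1) * n/(n - 1)` (unbiased for
#'   the population heterozygosity under binomial read and pool
#'   sampling; the correction is skipped where coverage is unknown), and
#'   the between-pair heterozygosity `Hb = q1(1 - q2) + q2(1 - q1)`
#'   (already unbiased).  Its expectation equals the Balding-Nichols
#'   drift parameter F, making it the estimator of choice when absolute
#'   differentiation matters.
#' * `"nei"`: the plain heterozygosity partition
#'   `(H_T - mean(H_S)) / H_T` computed from the observed read
#'   frequencies, `H_S = 2 q_j (1 - q_j)`,
#'   `H_T = 2 qbar (1 - qbar)`.  It carries both the two-deme deflation
#'   and a read/pool sampling-noise floor and is retained for
#'   comparability with window-averaging Pool-Seq pipelines.
#'
#' SNPs with zero between/total heterozygosity in a pair are
#' uninformative for it.  SNPs are combined by ratio of sums by default
#' (the combination recommended for Hudson-style estimators); the
#' unweighted mean of per-SNP ratios is available but is depressed by
#' low-frequency SNPs, whose individual ratios are systematically small
#' -- the reason high-coverage Pool-Seq FST scans sit below
#' microsatellite FST.
#'
#' @param snps a [SNPFrequencies-class] object with at least two
#'   populations.
#' @param estimator `"hudson"` (default) or `"nei"`.
#' @param combination `"ratioOfSums"` (default) or `"meanOfRatios"`.
#' @param poolSize haploid pool size for the Hudson correction; default
#'   from the filter parameters recorded by [callBiallelicSnps()].
#' @return A list: `fst` (symmetric matrix, zero diagonal, estimator
#'   tag `"pool"` with the per-SNP statistic in
#'   `attr(, "perSnpStatistic")`; `NA` for pairs with no informative
#'   SNP) and `nInformative` (matrix of informative SNP counts).
#' @export
fstPoolPairwise <- function(snps, estimator = c("hudson", "nei"),
                            combination = c("ratioOfSums",
                                            "meanOfRatios"),
                            poolSize = NULL) {
  stopifnot(is(snps, "SNPFrequencies"), nPopulations(snps) >= 2L)
  estimator <- match.arg(estimator)
  combination <- match.arg(combination)
  if (is.null(poolSize))
    poolSize <- metadata(snps)$params$poolSize
  q <- snpFreq(snps)
  cv <- snpCoverage(snps)
  pops <- colnames(q)
  K <- length(pops)
  fst <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  diag(fst) <- 0
  nInf <- matrix(0L, K, K, dimnames = list(pops, pops))
  poolFac <- if (!is.null(poolSize) && poolSize >= 2L)
    poolSize / (poolSize - 1) else 1
  for (i in seq_len(K - 1L)) for (j in seq((i + 1L), K)) {
    q1 <- q[, i]; q2 <- q[, j]
    if (estimator == "hudson") {
      c1 <- cv[, i]; c2 <- cv[, j]
      f1 <- ifelse(c1 > 1L, c1 / (c1 - 1), 1)
      f2 <- ifelse(c2 > 1L, c2 / (c2 - 1), 1)
      num <- (2 * q1 * (1 - q1) * f1 + 2 * q2 * (1 - q2) * f2) *
        poolFac / 2
      den <- q1 * (1 - q2) + q2 * (1 - q1)
    } else {
      m <- (q1 + q2) / 2
      den <- 2 * m * (1 - m)
      num <- den - (q1 * (1 - q1) + q2 * (1 - q2))
    }
    ok <- den > 0
    nInf[i, j] <- nInf[j, i] <- sum(ok)
    if (!any(ok)) next
    val <- switch(combination,
      ratioOfSums = sum(num[ok]) / sum(den[ok]),
      meanOfRatios = mean(num[ok] / den[ok]))
    fst[i, j] <- fst[j, i] <-
      if (estimator == "hudson") 1 - val else val
  }
  attr(fst, "estimator") <- "pool"
  attr(fst, "perSnpStatistic") <- estimator
  list(fst = fst, nInformative = nInf)
}
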