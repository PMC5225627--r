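#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start strand
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData rowRanges
NULL

BASES <- c("A", "T", "C", "G")
SYNC_COLS <- c("A", "T", "C", "G", "N", "del")

#' Per-site pooled read counts (sync data)
#'
#' `SyncCounts` holds per-site, per-population nucleotide read counts as
#' parsed from a PoPoolation2 "sync" file: one integer matrix
#' (sites x populations) per count column `A`, `T`, `C`, `G`, `N` and
#' `del`.  Rows are genomic positions (1-based, width-1 ranges), columns
#' are population pools.  The reference base of every site is kept in
#' `rowData(x)$ref`.
#'
#' Coverage, wherever this package applies coverage thresholds, counts
#' nucleotide reads only (`A+T+C+G`); the `N` and deletion columns are
#' carried through file round-trips but never enter allele-frequency or
#' diversity computations.
#'
#' @seealso [readSync()], [writeSync()], [callBiallelicSnps()]
#' @export
setClass("SyncCounts", contains = "RangedSummarizedExperiment")

setValidity("SyncCounts", function(object) {
  msg <- character()
  if (!identical(assayNames(object), SYNC_COLS))
    msg <- c(msg, sprintf("assays must be named %s", paste(SYNC_COLS, collapse = ", ")))
  for (nm in assayNames(object)) {
    a <- assay(object, nm)
    if (!is.integer(a))
      msg <- c(msg, sprintf("assay '%s' must be integer", nm))
    else if (nrow(a) && anyNA(a))
      msg <- c(msg, sprintf("assay '%s' contains NA counts", nm))
    else if (nrow(a) && min(a) < 0L)
      msg <- c(msg, sprintf("assay '%s' contains negative counts", nm))
  }
  if (is.null(rowData(object)$ref))
    msg <- c(msg, "rowData must carry a 'ref' column")
  else if (nrow(object) && !all(rowData(object)$ref %in% c(BASES, "N")))
    msg <- c(msg, "reference bases must be one of A, T, C, G, N")
  if (nrow(object) && any(start(object) < 1L))
    msg <- c(msg, "positions must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SyncCounts object
#'
#' @param chrom character vector of sequence names.
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference bases (`A`, `T`, `C`, `G` or `N`).
#' @param counts named list of six integer matrices (`A`, `T`, `C`, `G`,
#'   `N`, `del`), each sites x populations.
#' @param popNames optional population labels; defaults to `pool1..poolK`.
#' @return A [SyncCounts-class] object.
#' @export
SyncCounts <- function(chrom, pos, ref, counts, popNames = NULL) {
  stopifnot(is.list(counts), identical(names(counts), SYNC_COLS))
  npop <- ncol(counts[[1L]])
  if (is.null(popNames)) popNames <- paste0("pool", seq_len(npop))
  counts <- lapply(counts, function(m) {
    if (!is.integer(m)) storage.mode(m) <- "integer"
    dimnames(m) <- list(NULL, popNames)
    m
  })
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
  mcols(gr)$ref <- as.character(ref)
  se <- SummarizedExperiment(
    assays = counts, rowRanges = gr,
    colData = DataFrame(population = popNames, row.names = popNames))
  new("SyncCounts", se)
}

#' Biallelic SNP frequency table
#'
#' `SNPFrequencies` stores the sites retained by [callBiallelicSnps()]:
#' the globally-defined major and minor allele of each site
#' (`rowData(x)$major`, `rowData(x)$minor`) together with two assays,
#' `freq` (per-population frequency of the global minor allele, computed
#' from the retained major + minor read counts) and `coverage`
#' (per-population nucleotide coverage `A+T+C+G`).  The filter parameters
#' and a rejection report are kept in `metadata(x)`.
#'
#' @seealso [callBiallelicSnps()], [snpHe()], [fstPoolPairwise()],
#'   [downsampleHe()]
#' @export
setClass("SNPFrequencies", contains = "RangedSummarizedExperiment")

setValidity("SNPFrequencies", function(object) {
  msg <- character()
  if (!all(c("freq", "coverage") %in% assayNames(object)))
    msg <- c(msg, "assays 'freq' and 'coverage' are required")
  else {
    f <- assay(object, "freq")
    if (nrow(object) && (anyNA(f) || min(f) < 0 || max(f) > 1))
      msg <- c(msg, "minor-allele frequencies must lie in [0, 1]")
  }
  rd <- rowData(object)
  if (!all(c("major", "minor") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry 'major' and 'minor' alleles")
  if (length(msg)) msg else TRUE
})

#' Construct an SNPFrequencies object
#'
#' Programmatic constructor, mainly for simulations and tests;
#' [callBiallelicSnps()] is the usual producer.
#'
#' @param freq numeric matrix of minor-allele frequencies, sites x
#'   populations (column names = population labels).
#' @param coverage integer matrix of per-population nucleotide coverage,
#'   same shape; defaults to zero (unknown).
#' @param chrom,pos site coordinates; default `chr1`, 1..n.
#' @param major,minor allele bases per site; default `"A"`/`"T"`.
#' @return A [SNPFrequencies-class] object.
#' @export
SNPFrequencies <- function(freq, coverage = NULL, chrom = "chr1",
                           pos = seq_len(nrow(freq)),
                           major = "A", minor = "T") {
  if (is.null(colnames(freq)))
    colnames(freq) <- paste0("pool", seq_len(ncol(freq)))
  if (is.null(coverage))
    coverage <- matrix(0L, nrow(freq), ncol(freq),
                       dimnames = dimnames(freq))
  gr <- GRanges(rep_len(chrom, nrow(freq)),
                IRanges(as.integer(pos), width = 1L))
  mcols(gr)$major <- rep_len(major, nrow(freq))
  mcols(gr)$minor <- rep_len(minor, nrow(freq))
  se <- SummarizedExperiment(
    assays = list(freq = freq, coverage = coverage), rowRanges = gr,
    colData = DataFrame(population = colnames(freq),
                        row.names = colnames(freq)))
  new("SNPFrequencies", se)
}

#' Diploid microsatellite genotype table
#'
#' `SSRGenotypes` stores diploid allele-length calls for a set of
#' microsatellite (SSR) loci: rows are loci, columns are individuals, and
#' the two assays `allele1`/`allele2` hold the integer fragment lengths of
#' the unordered allele pair (both `NA` for a missing genotype).
#' `colData(x)$population` assigns individuals to populations and
#' `rowData(x)$markerClass` tags each locus as `cross-species` or
#' `species-specific`.
#'
#' @seealso [readGenepop()], [ssrDiversity()], [gisFis()],
#'   [fstWc84Pairwise()]
#' @export
setClass("SSRGenotypes", contains = "SummarizedExperiment")

setValidity("SSRGenotypes", function(object) {
  msg <- character()
  if (!all(c("allele1", "allele2") %in% assayNames(object)))
    msg <- c(msg, "assays 'allele1' and 'allele2' are required")
  else {
    a1 <- assay(object, "allele1"); a2 <- assay(object, "allele2")
    if (!identical(is.na(a1), is.na(a2)))
      msg <- c(msg, "half-missing genotypes are not allowed")
  }
  if (is.null(colData(object)$population))
    msg <- c(msg, "colData must carry a 'population' column")
  mc <- rowData(object)$markerClass
  if (is.null(mc))
    msg <- c(msg, "rowData must carry a 'markerClass' column")
  else if (nrow(object) && !all(mc %in% c("cross-species", "species-specific")))
    msg <- c(msg, "markerClass must be 'cross-species' or 'species-specific'")
  if (length(msg)) msg else TRUE
})

#' Construct an SSRGenotypes object
#'
#' @param allele1,allele2 integer matrices, loci x individuals; `NA` in
#'   both marks a missing genotype.  Allele order within a genotype is not
#'   meaningful.
#' @param population factor or character vector assigning individuals to
#'   populations (length = number of individuals).
#' @param markerClass character vector per locus, `"cross-species"` or
#'   `"species-specific"`.
#' @param lociNames,indNames optional dimension names.
#' @return An [SSRGenotypes-class] object.
#' @export
SSRGenotypes <- function(allele1, allele2, population, markerClass,
                         lociNames = NULL, indNames = NULL) {
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"
  if (is.null(lociNames)) lociNames <- rownames(allele1)
  if (is.null(lociNames)) lociNames <- paste0("locus", seq_len(nrow(allele1)))
  if (is.null(indNames)) indNames <- colnames(allele1)
  if (is.null(indNames)) indNames <- paste0("ind", seq_len(ncol(allele1)))
  dimnames(allele1) <- dimnames(allele2) <- list(lociNames, indNames)
  ## store the pair in canonical (sorted) order
  lo <- pmin(allele1, allele2)
  hi <- pmax(allele1, allele2)
  se <- SummarizedExperiment(
    assays = list(allele1 = lo, allele2 = hi),
    rowData = DataFrame(markerClass = as.character(markerClass),
                        row.names = lociNames),
    colData = DataFrame(population = factor(population),
                        row.names = indNames))
  new("SSRGenotypes", se)
}
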