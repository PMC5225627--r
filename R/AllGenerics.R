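#' Population labels of a marker data object
#'
#' @param x a [SyncCounts-class], [SNPFrequencies-class] or
#'   [SSRGenotypes-class] object.
#' @return Character vector of population labels, in storage order.
#' @export
setGeneric("popNames", function(x) standardGeneric("popNames"))

#' @rdname popNames
#' @export
setGeneric("nPopulations", function(x) standardGeneric("nPopulations"))

#' @rdname popNames
#' @export
setMethod("popNames", "SyncCounts", function(x) colnames(assay(x, "A")))

#' @rdname popNames
#' @export
setMethod("popNames", "SNPFrequencies", function(x) colnames(assay(x, "freq")))

#' @rdname popNames
#' @export
setMethod("popNames", "SSRGenotypes",
          function(x) levels(colData(x)$population))

#' @rdname popNames
#' @export
setMethod("nPopulations", "SyncCounts", function(x) ncol(x))

#' @rdname popNames
#' @export
setMethod("nPopulations", "SNPFrequencies", function(x) ncol(x))

#' @rdname popNames
#' @export
setMethod("nPopulations", "SSRGenotypes", function(x) length(popNames(x)))

#' Marker class tags of SSR loci
#'
#' @param x an [SSRGenotypes-class] object.
#' @return Named character vector (`cross-species` / `species-specific`),
#'   one entry per locus.
#' @export
markerClass <- function(x) {
  stopifnot(is(x, "SSRGenotypes"))
  stats::setNames(rowData(x)$markerClass, rownames(x))
}

#' Minor-allele frequency and coverage assays
#'
#' Accessors for the two assays of a [SNPFrequencies-class] object.
#'
#' @param x a [SNPFrequencies-class] object.
#' @return A numeric (`snpFreq`) or integer (`snpCoverage`) matrix,
#'   sites x populations.
#' @export
snpFreq <- function(x) {
  stopifnot(is(x, "SNPFrequencies"))
  assay(x, "freq")
}

#' @rdname snpFreq
#' @export
snpCoverage <- function(x) {
  stopifnot(is(x, "SNPFrequencies"))
  assay(x, "coverage")
}

#' Per-base read counts of a SyncCounts object
#'
#' @param x a [SyncCounts-class] object.
#' @param base one of `"A"`, `"T"`, `"C"`, `"G"`, `"N"`, `"del"`.
#' @return Integer matrix, sites x populations.
#' @export
baseCounts <- function(x, base) {
  stopifnot(is(x, "SyncCounts"), base %in% SYNC_COLS)
  assay(x, base)
}

#' Nucleotide coverage of a SyncCounts object
#'
#' Coverage counts nucleotide reads only (`A+T+C+G`); `N` and deletion
#' reads are excluded, matching how all filters in this package count
#' coverage.
#'
#' @param x a [SyncCounts-class] object.
#' @return Integer matrix, sites x populations.
#' @export
nucleotideCoverage <- function(x) {
  stopifnot(is(x, "SyncCounts"))
  assay(x, "A") + assay(x, "T") + assay(x, "C") + assay(x, "G")
}
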