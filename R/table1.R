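#' Reference nine-population diversity summary
#'
#' Loads the packaged reference table of per-population diversity
#' estimates for nine *Arabidopsis halleri* populations: microsatellite
#' allelic richness (`Ar`), expected heterozygosity (`ssrHe`) and
#' inbreeding coefficient (`Fis`, with its one-sided heterozygote-
#' deficiency p-value), and Pool-Seq estimates of exonic Watterson's
#' theta (`thetaW`), genome-wide SNP heterozygosity (`snpHe`) and
#' Tajima's D (`tajimaD`, with its against-zero p-value).  Values carry
#' their published precision; the table anchors this package's output
#' schema and is used by [summarizeTable1()].
#'
#' @return Data frame with nine population rows.
#' @examples
#' head(table1())
#' @export
table1 <- function() {
  path <- system.file("extdata", "table1.tsv", package = "poolDiv",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Column means and cross-estimator correlations of a diversity summary
#'
#' Computes the arithmetic mean of every numeric estimator column
#' (rounded to each column's conventional printed precision for the
#' fixture check) and all pairwise Pearson and Spearman correlations
#' between estimator columns via [correlationTest()].
#'
#' Note on `snpHe`: the mean of the nine rounded per-population values
#' is 0.147, while reference tables of this kind typically print a mean
#' computed on unrounded values (0.148 here); the rounded-column mean is
#' therefore reported descriptively but is not a reproduction target at
#' printed precision.
#'
#' @param rows a nine-row data frame as returned by [table1()].
#' @return A list: `means` (named, at printed precision),
#'   `meansUnrounded`, and `correlations` (data frame: var1, var2,
#'   method, statistic, pValue).
#' @export
summarizeTable1 <- function(rows = table1()) {
  cols <- c(Ar = 1L, ssrHe = 3L, Fis = 3L, thetaW = 4L, snpHe = 3L,
            tajimaD = 3L)
  missingCols <- setdiff(names(cols), names(rows))
  if (length(missingCols))
    stop("summary table is missing column(s): ",
         paste(missingCols, collapse = ", "))
  if (anyNA(rows[names(cols)])) stop("summary table has missing fields")
  meansUnrounded <- vapply(names(cols), function(cn) mean(rows[[cn]]),
                           numeric(1L))
  means <- round(meansUnrounded, cols)
  pr <- utils::combn(names(cols), 2L)
  correlations <- do.call(rbind, lapply(seq_len(ncol(pr)), function(k) {
    v1 <- pr[1L, k]; v2 <- pr[2L, k]
    do.call(rbind, lapply(c("pearson", "spearman"), function(m) {
      res <- correlationTest(rows[[v1]], rows[[v2]], method = m)
      cbind(data.frame(var1 = v1, var2 = v2, method = m),
            res[, c("statistic", "pValue")])
    }))
  }))
  rownames(correlations) <- NULL
  list(means = means, meansUnrounded = meansUnrounded,
       correlations = correlations)
}
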