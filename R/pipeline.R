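## End-to-end orchestration: simulate or read inputs, run both marker
## pipelines, the comparison battery and the down-sampling stage, and
## write all result tables as TSV with a '#' metadata preamble.

#' Write a result table with a metadata preamble
#'
#' Emits a TSV with a `#`-prefixed preamble recording the package
#' version, seed and any stage parameters, followed by a header line
#' and the data.  [readResultTable()] reads it back.
#'
#' @param df data frame.
#' @param path output path.
#' @param meta named list of metadata values.
#' @return Invisibly, `path`.
#' @export
writeResultTable <- function(df, path, meta = list()) {
  meta <- c(list(tool = paste0("poolDiv ",
                               as.character(utils::packageVersion("poolDiv"))),
                 written = "deterministic-output"), meta)
  hdr <- sprintf("#%s: %s", names(meta),
                 vapply(meta, function(v) paste(format(v), collapse = ","),
                        character(1L)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

fstMatrixToDf <- function(m) {
  data.frame(population = rownames(m), as.data.frame(m),
             check.names = FALSE)
}

#' Run the full marker-comparison pipeline
#'
#' Executes the stages in order: data acquisition (synthetic generation
#' from `config`, or reading the supplied sync/GFF3/GenePop files --
#' exactly one of the two modes), microsatellite statistics, Pool-Seq
#' statistics, the marker-comparison battery, and SNP down-sampling.
#' Every output table lands in `outDir` with a metadata preamble
#' recording the seed and stage parameters.  Stages whose inputs are
#' absent are skipped with a message (e.g. SSR-only runs skip the pool
#' and comparison stages).
#'
#' @param outDir output directory (created if needed).
#' @param config a [simConfig()]; used when no input files are given.
#' @param syncFile,gffFile,genepopFile,classFile optional real inputs.
#' @param params a [filterParams()] object.
#' @param nPermutations permutations for the G_IS test (default 999).
#' @param mantelPermutations permutations for Mantel tests (default
#'   1001).
#' @param downsampleReplicates replicates per down-sampling grid value
#'   (default 1000).
#' @param grid down-sampling grid; default [defaultDownsampleGrid()].
#' @param seed global seed; defaults to `config$seed`.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
runPipeline <- function(outDir, config = simConfig(),
                        syncFile = NULL, gffFile = NULL,
                        genepopFile = NULL, classFile = NULL,
                        params = NULL, nPermutations = 999L,
                        mantelPermutations = 1001L,
                        downsampleReplicates = 1000L, grid = NULL,
                        seed = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  realInput <- !is.null(syncFile) || !is.null(genepopFile)
  if (is.null(seed)) seed <- config$seed
  if (is.null(params))
    params <- filterParams(poolSize = config$poolSize)
  results <- list(seed = seed)

  if (realInput) {
    sync <- if (!is.null(syncFile)) readSync(syncFile) else NULL
    annotation <- if (!is.null(gffFile)) readExonAnnotation(gffFile)
                  else NULL
    ssr <- if (!is.null(genepopFile))
      readGenepop(genepopFile, classFile) else NULL
  } else {
    message("simulating synthetic inputs (seed ", seed, ")")
    snpSim <- simulateSnpPools(config)
    ssrSim <- simulateSsrGenotypes(config)
    sync <- snpSim$sync
    annotation <- snpSim$annotation
    ssr <- ssrSim$genotypes
    results$truth <- list(snp = snpSim$truth, ssr = ssrSim$truth)
  }
  meta0 <- list(seed = seed, mode = if (realInput) "real" else "synthetic")

  if (!is.null(ssr)) {
    div <- ssrDiversity(ssr)
    fis <- do.call(rbind, lapply(popNames(ssr), function(p)
      gisFis(ssr, p, nPermutations, seed)))
    nulls <- nullAlleleTable(ssr)
    ssrFst <- fstWc84Pairwise(ssr)
    writeResultTable(div$locusStats, file.path(outDir, "ssr_locus_stats.tsv"), meta0)
    writeResultTable(div$popSummary, file.path(outDir, "ssr_pop_summary.tsv"), meta0)
    writeResultTable(fis, file.path(outDir, "ssr_fis.tsv"),
                     c(meta0, nPermutations = nPermutations))
    writeResultTable(nulls, file.path(outDir, "null_alleles.tsv"), meta0)
    writeResultTable(fstMatrixToDf(ssrFst$fst),
                     file.path(outDir, "ssr_fst_matrix.tsv"),
                     c(meta0, estimator = "WC84"))
    results$ssr <- list(diversity = div, fis = fis, nulls = nulls,
                        fst = ssrFst)
  } else message("no SSR input: microsatellite stage skipped")

  if (!is.null(sync)) {
    snps <- callBiallelicSnps(sync, params)
    heOut <- snpHe(snps)
    poolFst <- fstPoolPairwise(snps)
    snpDf <- data.frame(
      chrom = as.character(seqnames(snps)), pos = start(snps),
      major = rowData(snps)$major, minor = rowData(snps)$minor,
      freq = snpFreq(snps), coverage = snpCoverage(snps),
      check.names = FALSE)
    writeResultTable(snpDf, file.path(outDir, "snp_table.tsv"),
                     c(meta0, unclass(params)))
    writeResultTable(
      data.frame(reason = names(metadata(snps)$report),
                 sites = as.integer(metadata(snps)$report)),
      file.path(outDir, "filter_report.tsv"), meta0)
    writeResultTable(fstMatrixToDf(poolFst$fst),
                     file.path(outDir, "pool_fst_matrix.tsv"),
                     c(meta0, estimator = "pool"))
    results$pool <- list(snps = snps, he = heOut$mean, fst = poolFst)
    if (!is.null(annotation)) {
      theta <- wattersonThetaPool(sync, annotation, params)
      taj <- tajimasDPool(sync, annotation, params)
      writeResultTable(theta$genes, file.path(outDir, "gene_theta.tsv"),
                       c(meta0, unclass(params)))
      writeResultTable(taj$genes, file.path(outDir, "gene_tajima_d.tsv"),
                       c(meta0, note = "approximate pooled Tajima's D"))
      results$pool$theta <- theta
      results$pool$tajima <- taj
    } else message("no annotation: gene-wise theta/Tajima stage skipped")
  } else message("no sync input: pool stage skipped")

  if (!is.null(ssr) && !is.null(sync)) {
    cmp <- comparisonBattery(results, mantelPermutations, seed)
    writeResultTable(cmp, file.path(outDir, "comparison_report.tsv"),
                     c(meta0, mantelPermutations = mantelPermutations))
    results$comparison <- cmp
  } else message("only one marker type present: comparison stage skipped")

  if (!is.null(sync)) {
    snps <- results$pool$snps
    curves <- downsampleHe(snps, grid = grid,
                           nReplicates = downsampleReplicates,
                           seed = seed)
    thr <- kForCiThresholds(curves)
    rank <- kForRanking(curves, snpHe(snps)$mean)
    writeResultTable(curves, file.path(outDir, "rarefaction_curves.tsv"),
                     c(meta0, nReplicates = downsampleReplicates))
    writeResultTable(
      data.frame(criterion = c(names(thr$k), "ranking"),
                 k = c(unname(thr$k), rank$k)),
      file.path(outDir, "rarefaction_thresholds.tsv"), meta0)
    results$downsample <- list(curves = curves, thresholds = thr,
                               ranking = rank)
  }
  invisible(results)
}

## assemble the comparison report from in-memory stage results
comparisonBattery <- function(results, mantelPermutations, seed) {
  popSum <- results$ssr$diversity$popSummary
  pools <- popNames(results$pool$snps)
  ## align populations by order (synthetic runs share pop order; real
  ## runs must supply matching label sets)
  stopifnot(nrow(popSum) == length(pools))
  theta <- if (!is.null(results$pool$theta))
    results$pool$theta$genomeMean else NULL
  he <- results$pool$he
  rows <- list()
  add <- function(label, res) {
    res$comparison <- label
    rows[[length(rows) + 1L]] <<- res
  }
  add("Ar_vs_snpHe", correlationTest(popSum$Ar, he))
  add("ssrHe_vs_snpHe", correlationTest(popSum$meanHe, he))
  if (!is.null(theta)) {
    add("Ar_vs_thetaW", correlationTest(popSum$Ar, theta))
    add("Ar_vs_thetaW_spearman",
        correlationTest(popSum$Ar, theta, method = "spearman"))
    add("ssrHe_vs_thetaW", correlationTest(popSum$meanHe, theta))
    add("thetaW_vs_snpHe", correlationTest(theta, he))
  }
  add("ssrHe_vs_snpHe_paired_t", pairedTTest(popSum$meanHe, he))
  ssrM <- results$ssr$fst$fst
  poolM <- results$pool$fst$fst
  if (!anyNA(poolM) && !anyNA(ssrM)) {
    dimnames(poolM) <- dimnames(ssrM)   # positional population pairing
    add("fst_mantel_ssr_vs_pool",
        mantelTest(ssrM, poolM, mantelPermutations, seed))
    lt <- lower.tri(ssrM)
    add("fst_paired_t_ssr_vs_pool", pairedTTest(ssrM[lt], poolM[lt]))
  }
  if (!is.null(results$pool$tajima)) {
    g <- results$pool$tajima$genes
    for (p in unique(g$population)) {
      d <- g$D[g$population == p & is.finite(g$D)]
      if (length(d) >= 10L)
        add(paste0("tajimaD_vs_zero_", p), tajimaZeroTest(d, seed))
    }
  }
  out <- do.call(rbind, rows)
  out[, c("comparison", setdiff(names(out), "comparison"))]
}
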