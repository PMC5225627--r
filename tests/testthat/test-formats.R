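test_that("sync records map fields directly and round-trip byte-identically", {
  path <- writeSyncFixture(c(
    "scaf1\t5\tT\t0:12:0:0:0:0\t3:9:0:0:0:0",
    "scaf1\t6\tA\t20:0:1:0:0:0\t18:0:0:0:1:0"))
  x <- readSync(path, nPopulations = 2)
  expect_s4_class(x, "SyncCounts")
  expect_equal(nrow(x), 2L)
  expect_equal(as.character(GenomicRanges::seqnames(x)),
               c("scaf1", "scaf1"))
  expect_equal(GenomicRanges::start(x), c(5L, 6L))
  expect_equal(SummarizedExperiment::rowData(x)$ref, c("T", "A"))
  expect_equal(baseCounts(x, "A")[1, ], c(pool1 = 0L, pool2 = 3L))
  expect_equal(baseCounts(x, "T")[1, ], c(pool1 = 12L, pool2 = 9L))
  expect_equal(baseCounts(x, "N")[2, ], c(pool1 = 0L, pool2 = 1L))

  out <- tempfile(fileext = ".sync")
  writeSync(x, out)
  expect_identical(readLines(out), readLines(path))
})

test_that("malformed sync input produces parse errors naming the line", {
  twoOK <- "s\t1\tA\t1:0:0:0:0:0\t0:1:0:0:0:0"
  expect_error(readSync(writeSyncFixture(c(
    twoOK, "s\t2\tA\t1:0:0:0:0\t0:1:0:0:0:0"))),
    "count block.*line 2")
  expect_error(readSync(writeSyncFixture(twoOK), nPopulations = 3),
               "expected 3 count blocks")
  expect_error(readSync(writeSyncFixture(
    "s\t0\tA\t1:0:0:0:0:0")), "position < 1")
  expect_error(readSync(writeSyncFixture(
    "s\t1\tA\t1:x:0:0:0:0")), "non-integer count")
  expect_error(readSync(writeSyncFixture(
    "s\t1\tZ\t1:0:0:0:0:0")), "reference base")
})

test_that("sync reading streams in chunks with identical results", {
  lines <- sprintf("c1\t%d\tA\t%d:2:0:0:0:0\t0:%d:0:0:0:0",
                   1:10, 1:10, 10:1)
  path <- writeSyncFixture(lines)
  whole <- readSync(path)
  parts <- readSyncChunked(path, function(chunk) chunk, chunkSize = 3L)
  expect_length(parts, 4L)
  expect_equal(sum(vapply(parts, nrow, integer(1L))), 10L)
  recA <- do.call(rbind, lapply(parts, baseCounts, "A"))
  expect_equal(recA, baseCounts(whole, "A"))
})

test_that("empty sync input yields an empty object, not an error", {
  path <- writeSyncFixture(character())
  x <- readSync(path, nPopulations = 2)
  expect_equal(nrow(x), 0L)
  expect_equal(nPopulations(x), 2L)
})

test_that("GenePop genotypes decode, round-trip, and flag inconsistencies", {
  ## 3-digit coding decodes into allele pairs; 0-codes mark missing
  gp <- c("title", "locA", "locB", "POP",
          "north_01 , 102104 095095",
          "north_02 , 104102 000000",
          "POP",
          "south_01 , 102102 095097")
  path <- tempfile(); writeLines(gp, path)
  x <- readGenepop(path)
  expect_s4_class(x, "SSRGenotypes")
  expect_equal(popNames(x), c("north", "south"))
  expect_equal(unname(SummarizedExperiment::assay(x, "allele1")[, 1]),
               c(102L, 95L))
  ## unordered pair: 104102 stores as (102, 104)
  expect_equal(unname(SummarizedExperiment::assay(x, "allele1")["locA", 2]), 102L)
  expect_equal(unname(SummarizedExperiment::assay(x, "allele2")["locA", 2]), 104L)
  expect_true(is.na(SummarizedExperiment::assay(x, "allele1")["locB", 2]))

  out <- tempfile(); side <- tempfile()
  writeGenepop(x, out, side)
  y <- readGenepop(out, side)
  expect_equal(SummarizedExperiment::assay(y, "allele1"),
               SummarizedExperiment::assay(x, "allele1"))
  expect_equal(popNames(y), popNames(x))
  expect_equal(unname(markerClass(y)), unname(markerClass(x)))

  ## 2-digit coding and its missing sentinel
  gp2 <- c("t", "l1", "POP", "a_1 , 0104", "a_2 , 0000")
  path2 <- tempfile(); writeLines(gp2, path2)
  y2 <- readGenepop(path2)
  expect_equal(unname(SummarizedExperiment::assay(y2, "allele1")[1, ]),
               c(1L, NA))

  ## inconsistent code width within a locus, wrong locus count
  bad1 <- c("t", "l1", "POP", "a_1 , 0104", "a_2 , 000000")
  p <- tempfile(); writeLines(bad1, p)
  expect_error(readGenepop(p), "inconsistent allele code width")
  bad2 <- c("t", "l1", "l2", "POP", "a_1 , 102102")
  p <- tempfile(); writeLines(bad2, p)
  expect_error(readGenepop(p), "has 1 genotypes for 2 loci")
})

test_that("a simulated nine-population table round-trips through GenePop", {
  cfg <- simConfig(seed = 21)
  sim <- simulateSsrGenotypes(cfg)
  expect_equal(nPopulations(sim$genotypes), 9L)
  expect_equal(as.vector(table(SummarizedExperiment::colData(
    sim$genotypes)$population)), rep(20L, 9L))
  gp <- tempfile(); side <- tempfile()
  writeGenepop(sim$genotypes, gp, side)
  y <- readGenepop(gp, side)
  expect_equal(SummarizedExperiment::assay(y, "allele1"),
               SummarizedExperiment::assay(sim$genotypes, "allele1"))
  expect_equal(SummarizedExperiment::assay(y, "allele2"),
               SummarizedExperiment::assay(sim$genotypes, "allele2"))
  expect_equal(unname(markerClass(y)), unname(markerClass(sim$genotypes)))
})

test_that("GFF3 exons merge per gene; degenerate inputs behave", {
  gff <- c("##gff-version 3",
           "c1\tsrc\tgene\t10\t40\t.\t+\t.\tID=g1",
           "c1\tsrc\tmRNA\t10\t40\t.\t+\t.\tID=m1;Parent=g1",
           "c1\tsrc\texon\t10\t20\t.\t+\t.\tParent=m1",
           "c1\tsrc\texon\t15\t30\t.\t+\t.\tParent=m1")
  path <- tempfile(fileext = ".gff3"); writeLines(gff, path)
  ann <- readExonAnnotation(path)
  expect_equal(length(ann), 1L)
  expect_equal(ann$gene_id, "g1")
  expect_equal(GenomicRanges::start(ann), 10L)
  expect_equal(GenomicRanges::end(ann), 30L)
  expect_equal(GenomicRanges::width(ann), 21L)

  ## exon attached directly to a gene resolves too
  gff2 <- c("##gff-version 3",
            "c1\tsrc\tgene\t1\t50\t.\t-\t.\tID=g2",
            "c1\tsrc\texon\t5\t15\t.\t-\t.\tParent=g2")
  path2 <- tempfile(fileext = ".gff3"); writeLines(gff2, path2)
  ann2 <- readExonAnnotation(path2)
  expect_equal(ann2$gene_id, "g2")

  ## an exon with start > end violates the coordinate invariant
  bad <- c("##gff-version 3",
           "c1\tsrc\texon\t30\t10\t.\t+\t.\tParent=g1")
  pb <- tempfile(fileext = ".gff3"); writeLines(bad, pb)
  expect_error(suppressWarnings(readExonAnnotation(pb)))

  ## empty annotation is an empty collection, not an error
  pe <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", pe)
  empty <- readExonAnnotation(pe)
  expect_equal(length(empty), 0L)

  ## orphan exons are skipped with a warning and counted
  orphan <- c("##gff-version 3",
              "c1\tsrc\tgene\t1\t50\t.\t+\t.\tID=g3",
              "c1\tsrc\texon\t1\t10\t.\t+\t.\tParent=g3",
              "c1\tsrc\texon\t20\t30\t.\t+\t.\tNote=noParent")
  po <- tempfile(fileext = ".gff3"); writeLines(orphan, po)
  expect_warning(res <- readExonAnnotation(po), "skipped")
  expect_equal(length(res), 1L)
  expect_equal(S4Vectors::metadata(res)$skippedExons, 1L)
})
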