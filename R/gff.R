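#' Read exon annotation from a GFF3 file
#'
#' Imports a GFF3 annotation, resolves every `exon` feature to its gene
#' through the `Parent`/`ID` attribute chain (exons attached directly to
#' a gene, or via an mRNA/transcript), merges overlapping exons of the
#' same gene, and returns the merged exon intervals.  Coordinates stay
#' 1-based inclusive throughout.  Exons whose parent chain does not reach
#' a feature with an `ID` are skipped with a warning; the skip count is
#' stored in `metadata()$skippedExons`.
#'
#' Strand is retained but ignored by all diversity computations in this
#' package (site-level statistics are strand-symmetric).
#'
#' @param path path to the GFF3 file.
#' @return A [GenomicRanges::GRanges] of merged exon intervals with a
#'   `gene_id` metadata column.
#' @export
readExonAnnotation <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  exons <- gff[tolower(as.character(gff$type)) == "exon"]
  if (!length(exons)) {
    out <- GRanges()
    mcols(out)$gene_id <- character()
    metadata(out)$skippedExons <- 0L
    return(out)
  }
  ids <- as.character(gff$ID)
  parentOf <- function(feat) {
    p <- feat$Parent
    vapply(as.list(p), function(v)
      if (length(v)) as.character(v)[1L] else NA_character_, character(1L))
  }
  ## climb one level: exon -> parent; if that parent is itself a child
  ## (mRNA), climb to its parent (the gene)
  par1 <- parentOf(exons)
  idx <- match(par1, ids, incomparables = NA)
  grand <- rep(NA_character_, length(exons))
  hit <- !is.na(idx)
  if (any(hit)) {
    gp <- gff$Parent[idx[hit]]
    grand[hit] <- vapply(as.list(gp), function(v)
      if (length(v)) as.character(v)[1L] else NA_character_, character(1L))
  }
  geneId <- ifelse(is.na(grand), par1, grand)
  bad <- is.na(geneId)
  if (any(bad)) {
    warning(sum(bad), " exon(s) without a resolvable gene parent were skipped")
    exons <- exons[!bad]
    geneId <- geneId[!bad]
  }
  byGene <- GenomicRanges::reduce(
    GenomicRanges::split(exons, factor(geneId, levels = unique(geneId))))
  merged <- unlist(byGene, use.names = TRUE)
  mcols(merged) <- NULL
  mcols(merged)$gene_id <- names(merged)
  names(merged) <- NULL
  metadata(merged)$skippedExons <- sum(bad)
  merged
}

#' Build a single-exon gene annotation
#'
#' Convenience constructor used by the simulator and by tests: `nGenes`
#' genes laid head-to-tail on one chromosome, each a single exon of
#' `geneLength` bp.
#'
#' @param nGenes number of genes.
#' @param geneLength exon length in bp.
#' @param chrom chromosome name.
#' @return A [GenomicRanges::GRanges] with a `gene_id` column.
#' @export
tiledGeneAnnotation <- function(nGenes, geneLength, chrom = "chr1") {
  starts <- seq(1L, by = geneLength, length.out = nGenes)
  gr <- GRanges(chrom, IRanges(starts, width = geneLength))
  mcols(gr)$gene_id <- sprintf("gene%05d", seq_len(nGenes))
  gr
}
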