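#' Read a GenePop genotype file
#'
#' Parses the GenePop dialect used for diploid microsatellite tables:
#' a title line, locus names (one per line, or comma-separated on one
#' line), `POP` separators, and per-individual lines
#' `id , 102104 095095 ...` with 2- or 3-digit-per-allele coding
#' (auto-detected per file).  Allele code `000`/`00` marks a missing
#' allele; a genotype with any missing allele is treated as missing.
#'
#' GenePop has no slot for marker metadata, so the cross-species /
#' species-specific class of each locus is read from a sidecar
#' tab-separated file with columns `locus` and `class`.  Loci not listed
#' there (or all loci, when `classFile` is `NULL`) default to
#' `"cross-species"`.
#'
#' Population labels are taken from the shared `<label>_` prefix of the
#' individual identifiers in each `POP` block when one exists, otherwise
#' blocks are labelled `pop1`, `pop2`, ...
#'
#' @param path path to the GenePop file.
#' @param classFile optional path to the locus-class sidecar TSV.
#' @return An [SSRGenotypes-class] object.
#' @export
readGenepop <- function(path, classFile = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("GenePop parse error: file too short")
  isPop <- toupper(trimws(lines)) == "POP"
  firstPop <- which(isPop)[1L]
  if (is.na(firstPop)) stop("GenePop parse error: no POP separator found")
  if (firstPop < 3L) stop("GenePop parse error: no locus names before first POP")
  lociLines <- lines[2:(firstPop - 1L)]
  loci <- trimws(unlist(strsplit(lociLines, ",", fixed = TRUE)))
  loci <- loci[nzchar(loci)]
  nLoci <- length(loci)

  popStarts <- which(isPop)
  blocks <- mapply(function(from, to) lines[seq(from + 1L, to)],
                   popStarts, c(popStarts[-1L] - 1L, length(lines)),
                   SIMPLIFY = FALSE)
  ids <- character(); popIdx <- integer(); geno <- character()
  for (b in seq_along(blocks)) {
    for (ln in blocks[[b]]) {
      parts <- strsplit(ln, ",", fixed = TRUE)[[1L]]
      if (length(parts) < 2L)
        stop("GenePop parse error: individual line without ',': ", ln)
      id <- trimws(parts[1L])
      fields <- strsplit(trimws(paste(parts[-1L], collapse = " ")),
                         "[ \t]+")[[1L]]
      if (length(fields) != nLoci)
        stop("GenePop parse error: individual '", id, "' has ",
             length(fields), " genotypes for ", nLoci, " loci")
      ids <- c(ids, id)
      popIdx <- c(popIdx, b)
      geno <- c(geno, fields)
    }
  }
  widths <- nchar(geno)
  if (!all(widths %in% c(4L, 6L)))
    stop("GenePop parse error: genotype fields must be 4 or 6 digits wide")
  gm <- matrix(geno, nrow = nLoci)          # loci x individuals
  wm <- matrix(widths, nrow = nLoci)
  perLocus <- apply(wm, 1L, function(w) length(unique(w)))
  if (any(perLocus > 1L))
    stop("GenePop parse error: inconsistent allele code width within locus '",
         loci[which(perLocus > 1L)[1L]], "'")
  digits <- wm[, 1L] / 2L
  a1 <- matrix(NA_integer_, nLoci, length(ids))
  a2 <- matrix(NA_integer_, nLoci, length(ids))
  for (l in seq_len(nLoci)) {
    d <- digits[l]
    x1 <- as.integer(substr(gm[l, ], 1L, d))
    x2 <- as.integer(substr(gm[l, ], d + 1L, 2L * d))
    miss <- x1 == 0L | x2 == 0L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[l, ] <- x1; a2[l, ] <- x2
  }
  popLabels <- vapply(split(ids, popIdx), function(v) {
    pre <- unique(sub("_[^_]*$", "", v))
    if (length(pre) == 1L && all(grepl("_", v))) pre else NA_character_
  }, character(1L))
  if (anyNA(popLabels) || anyDuplicated(popLabels))
    popLabels <- paste0("pop", seq_along(blocks))
  cls <- rep("cross-species", nLoci)
  if (!is.null(classFile)) {
    sidecar <- utils::read.delim(classFile, stringsAsFactors = FALSE,
                                 comment.char = "#")
    if (!all(c("locus", "class") %in% names(sidecar)))
      stop("marker-class sidecar needs columns 'locus' and 'class'")
    m <- match(loci, sidecar$locus)
    cls[!is.na(m)] <- sidecar$class[m[!is.na(m)]]
  }
  pop <- factor(popLabels[popIdx], levels = popLabels)
  SSRGenotypes(a1, a2, pop, cls, lociNames = loci, indNames = ids)
}

#' Write an SSRGenotypes object as GenePop plus class sidecar
#'
#' Writes the genotype table in the 3-digit GenePop dialect (individuals
#' named `<population>_<i>` so that population labels survive a
#' round-trip) and the locus-class sidecar TSV.  [readGenepop()] on the
#' output reproduces the object.
#'
#' @param x an [SSRGenotypes-class] object.
#' @param path output GenePop path.
#' @param classFile output sidecar path; `NULL` suppresses it.
#' @param title title line content.
#' @return Invisibly, `path`.
#' @export
writeGenepop <- function(x, path, classFile = NULL,
                         title = "poolDiv SSR genotypes") {
  stopifnot(is(x, "SSRGenotypes"))
  a1 <- assay(x, "allele1"); a2 <- assay(x, "allele2")
  if (nrow(x) && max(c(a1, a2), na.rm = TRUE) > 999L)
    stop("allele labels exceed 3-digit GenePop coding")
  enc <- function(v) {
    v[is.na(v)] <- 0L
    sprintf("%03d", v)
  }
  pop <- colData(x)$population
  out <- c(title, rownames(x))
  for (p in levels(pop)) {
    out <- c(out, "POP")
    idx <- which(pop == p)
    for (k in seq_along(idx)) {
      i <- idx[k]
      g <- paste0(enc(a1[, i]), enc(a2[, i]))
      out <- c(out, paste0(p, "_", sprintf("%02d", k), " , ",
                           paste(g, collapse = " ")))
    }
  }
  writeLines(out, path)
  if (!is.null(classFile))
    utils::write.table(
      data.frame(locus = rownames(x), class = rowData(x)$markerClass),
      classFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
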