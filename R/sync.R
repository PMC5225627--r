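#' Read a PoPoolation2 sync file
#'
#' Parses a tab-separated sync file (columns: chromosome, 1-based
#' position, reference base, then one `A:T:C:G:N:del` count block per
#' population pool) into a [SyncCounts-class] object with strict
#' validation.  Record order is preserved.
#'
#' @param path path to the sync file (plain text).
#' @param nPopulations expected number of count blocks; if supplied, a
#'   mismatch is a parse error.
#' @param popNames optional population labels.
#' @return A [SyncCounts-class] object.
#' @examples
#' f <- tempfile(fileext = ".sync")
#' writeLines("scaf1\t5\tT\t0:12:0:0:0:0\t3:9:0:0:0:0", f)
#' readSync(f, nPopulations = 2)
#' @export
readSync <- function(path, nPopulations = NULL, popNames = NULL) {
  lines <- readLines(path)
  parseSyncLines(lines, nPopulations, popNames, offset = 0L)
}

#' Process a sync file in chunks
#'
#' Streams a sync file record-by-record in fixed-size chunks so that
#' files larger than memory can be processed; each chunk is parsed into a
#' [SyncCounts-class] object and handed to `callback`.
#'
#' @inheritParams readSync
#' @param callback function of one argument (the chunk, a
#'   [SyncCounts-class]); its return values are collected in a list.
#' @param chunkSize number of records per chunk.
#' @return Invisibly, the list of callback return values.
#' @export
readSyncChunked <- function(path, callback, nPopulations = NULL,
                            popNames = NULL, chunkSize = 50000L) {
  con <- file(path, "r")
  on.exit(close(con))
  out <- list()
  offset <- 0L
  repeat {
    lines <- readLines(con, n = chunkSize)
    if (!length(lines)) break
    chunk <- parseSyncLines(lines, nPopulations, popNames, offset = offset)
    if (is.null(nPopulations)) nPopulations <- nPopulations(chunk)
    out[[length(out) + 1L]] <- callback(chunk)
    offset <- offset + length(lines)
  }
  invisible(out)
}

parseSyncLines <- function(lines, nPopulations, popNames, offset = 0L) {
  lineNo <- function(i) offset + i
  if (!length(lines)) {
    npop <- if (is.null(nPopulations)) 0L else nPopulations
    empty <- matrix(integer(), 0L, npop)
    counts <- stats::setNames(rep(list(empty), 6L), SYNC_COLS)
    return(SyncCounts(character(), integer(), character(), counts, popNames))
  }
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  nf <- length(fields)
  if (nf < 4L)
    stop("sync parse error: fewer than 4 tab-separated columns (line ",
         lineNo(1L), ")")
  bad <- is.na(fields[[nf]])
  if (any(bad))
    stop("sync parse error: inconsistent column count at line ",
         lineNo(which(bad)[1L]))
  npop <- nf - 3L
  if (!is.null(nPopulations) && npop != nPopulations)
    stop("sync parse error: expected ", nPopulations,
         " count blocks but found ", npop, " (line ", lineNo(1L), ")")
  pos <- suppressWarnings(as.integer(fields[[2L]]))
  if (anyNA(pos))
    stop("sync parse error: non-integer position at line ",
         lineNo(which(is.na(pos))[1L]))
  if (any(pos < 1L))
    stop("sync parse error: position < 1 at line ",
         lineNo(which(pos < 1L)[1L]))
  ref <- toupper(fields[[3L]])
  badRef <- !ref %in% c(BASES, "N")
  if (any(badRef))
    stop("sync parse error: invalid reference base at line ",
         lineNo(which(badRef)[1L]))
  n <- length(lines)
  counts <- lapply(SYNC_COLS, function(x) matrix(NA_integer_, n, npop))
  names(counts) <- SYNC_COLS
  for (j in seq_len(npop)) {
    block <- data.table::tstrsplit(fields[[3L + j]], ":", fixed = TRUE)
    if (length(block) != 6L || anyNA(block[[length(block)]])) {
      arity <- vapply(strsplit(fields[[3L + j]], ":", fixed = TRUE),
                      length, integer(1L))
      stop("sync parse error: count block with ", arity[arity != 6L][1L],
           " fields (expected 6) at line ", lineNo(which(arity != 6L)[1L]))
    }
    for (k in seq_len(6L)) {
      v <- suppressWarnings(as.integer(block[[k]]))
      if (anyNA(v))
        stop("sync parse error: non-integer count at line ",
             lineNo(which(is.na(v))[1L]))
      counts[[k]][, j] <- v
    }
  }
  SyncCounts(fields[[1L]], pos, ref, counts, popNames)
}

#' Write a SyncCounts object to a sync file
#'
#' Emits the canonical tab-separated sync representation; `writeSync()`
#' and [readSync()] are exact inverses on canonical files.
#'
#' @param x a [SyncCounts-class] object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeSync <- function(x, path) {
  stopifnot(is(x, "SyncCounts"))
  npop <- nPopulations(x)
  blocks <- lapply(seq_len(npop), function(j) {
    do.call(paste, c(lapply(SYNC_COLS, function(nm) assay(x, nm)[, j]),
                     sep = ":"))
  })
  lines <- do.call(paste, c(list(as.character(seqnames(x)), start(x),
                                 rowData(x)$ref), blocks, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
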