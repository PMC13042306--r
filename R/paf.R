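#' Read a PAF alignment file
#'
#' Parses the tab-separated pairwise mapping format: the first 12
#' columns (query name/length/start/end, strand, target name/length/
#' start/end, residue matches, block length, mapping quality) are kept;
#' optional SAM-style tags are ignored. Coordinates are 0-based
#' half-open. Malformed lines (fewer than 12 columns, non-numeric
#' coordinates, out-of-range intervals) raise an error naming the line
#' number.
#'
#' @param source Path to a PAF file, or a character vector of PAF
#'   lines.
#' @return data.frame with columns `queryId`, `queryLen`, `queryStart`,
#'   `queryEnd`, `strand`, `targetId`, `targetLen`, `targetStart`,
#'   `targetEnd`, `nMatches`, `blockLen`, `mapq`.
#' @export
readPaf <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else source
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(emptyPaf())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 12L)
  if (length(short))
    stop("PAF line ", short[1], ": fewer than 12 columns")
  num <- function(i, col) {
    v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", i)))
    if (anyNA(v))
      stop("PAF line ", which(is.na(v))[1], ": non-numeric ", col)
    v
  }
  df <- data.frame(
    queryId = vapply(parts, `[[`, "", 1L),
    queryLen = num(2L, "query length"),
    queryStart = num(3L, "query start"),
    queryEnd = num(4L, "query end"),
    strand = vapply(parts, `[[`, "", 5L),
    targetId = vapply(parts, `[[`, "", 6L),
    targetLen = num(7L, "target length"),
    targetStart = num(8L, "target start"),
    targetEnd = num(9L, "target end"),
    nMatches = num(10L, "residue matches"),
    blockLen = num(11L, "block length"),
    mapq = num(12L, "mapping quality"),
    stringsAsFactors = FALSE)
  bad <- which(!(df$queryStart >= 0 & df$queryStart < df$queryEnd &
                   df$queryEnd <= df$queryLen))
  if (length(bad))
    stop("PAF line ", bad[1], ": query coordinates out of range")
  bad <- which(df$nMatches > df$blockLen)
  if (length(bad))
    stop("PAF line ", bad[1], ": residue matches exceed block length")
  df
}

emptyPaf <- function() {
  data.frame(queryId = character(), queryLen = numeric(),
             queryStart = numeric(), queryEnd = numeric(),
             strand = character(), targetId = character(),
             targetLen = numeric(), targetStart = numeric(),
             targetEnd = numeric(), nMatches = numeric(),
             blockLen = numeric(), mapq = numeric(),
             stringsAsFactors = FALSE)
}

#' Write PAF records
#'
#' @param paf data.frame in [readPaf()] layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePaf <- function(paf, path) {
  write.table(paf, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Exact-match test for a PAF record
#'
#' A record is an exact match when the alignment is full-length and
#' mismatch-free: `nMatches == blockLen == queryEnd - queryStart ==
#' queryLen`.
#'
#' @param record One-or-more-row PAF data.frame.
#' @return Logical vector, one value per record.
#' @export
isExactMatch <- function(record) {
  record$nMatches == record$blockLen &
    record$blockLen == (record$queryEnd - record$queryStart) &
    (record$queryEnd - record$queryStart) == record$queryLen
}

#' Coverage of one query by one reference
#'
#' Fraction of query bases covered by the union of the record
#' intervals. Overlapping alignments are union-merged, never summed,
#' so coverage cannot exceed 1.
#'
#' @param records PAF records sharing one (`queryId`, `targetId`) pair.
#' @return One-row data.frame: `queryId`, `refId`, `coverage`,
#'   `nAlignments`, `exact`.
#' @export
queryCoverage <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(queryId = NA_character_, refId = NA_character_,
                      coverage = 0, nAlignments = 0L, exact = FALSE,
                      stringsAsFactors = FALSE))
  if (length(unique(records$queryId)) != 1L ||
      length(unique(records$targetId)) != 1L)
    stop("queryCoverage expects records for a single (query, reference)")
  if (length(unique(records$queryLen)) != 1L)
    stop("inconsistent query length across records for ",
         records$queryId[1])
  ir <- IRanges::reduce(IRanges::IRanges(start = records$queryStart + 1,
                                         end = records$queryEnd))
  data.frame(queryId = records$queryId[1], refId = records$targetId[1],
             coverage = sum(IRanges::width(ir)) / records$queryLen[1],
             nAlignments = nrow(records),
             exact = any(isExactMatch(records)),
             stringsAsFactors = FALSE)
}

#' Per-(query, reference) coverage table for a whole PAF
#'
#' @param paf data.frame from [readPaf()].
#' @return data.frame with one row per (query, reference) pair.
#' @export
coverageTable <- function(paf) {
  if (nrow(paf) == 0L)
    return(data.frame(queryId = character(), refId = character(),
                      coverage = numeric(), nAlignments = integer(),
                      exact = logical(), stringsAsFactors = FALSE))
  key <- paste(paf$queryId, paf$targetId, sep = "\r")
  out <- do.call(rbind, lapply(split(paf, key), queryCoverage))
  rownames(out) <- NULL
  out[order(out$queryId, out$refId), , drop = FALSE]
}

#' External aligner hook configuration
#'
#' The tested classification path consumes PAF; this hook describes how
#' to produce one with minimap2 when it is available. Presets follow
#' the pipeline's two input modes: `asm10` for contigs (genome-to-
#' genome, ~10% divergence) and `sr` for short reads.
#'
#' @param preset `"asm10"` or `"sr"`.
#' @param threads Integer thread count.
#' @param extraFlags Extra command-line flags (character vector).
#' @return Named list with class `AlignerHook`.
#' @export
alignerHook <- function(preset = c("asm10", "sr"), threads = 1L,
                        extraFlags = character()) {
  preset <- match.arg(preset)
  structure(list(preset = preset, threads = as.integer(threads),
                 extraFlags = extraFlags), class = "AlignerHook")
}

#' Align queries to references with minimap2
#'
#' Thin wrapper over the external `minimap2` binary; writes and reads
#' plain PAF. Requires minimap2 on the PATH.
#'
#' @param queryFasta,refFasta FASTA file paths.
#' @param hook An [alignerHook()].
#' @param pafOut Optional output path; a temporary file by default.
#' @return data.frame of PAF records ([readPaf()] layout).
#' @export
alignWithMinimap2 <- function(queryFasta, refFasta,
                              hook = alignerHook(), pafOut = NULL) {
  bin <- Sys.which("minimap2")
  if (!nzchar(bin)) stop("minimap2 not found on PATH")
  if (is.null(pafOut)) pafOut <- tempfile(fileext = ".paf")
  args <- c("-x", hook$preset, "-t", hook$threads, hook$extraFlags,
            refFasta, queryFasta)
  status <- system2(bin, args, stdout = pafOut, stderr = FALSE)
  if (status != 0) stop("minimap2 failed with status ", status)
  readPaf(pafOut)
}
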