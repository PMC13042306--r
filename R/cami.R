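#' Write a profile in CAMI profiling format
#'
#' Emits the standard CAMI header (`@SampleID`, `@Version`, `@Ranks`)
#' followed by `@@TAXID RANK TAXPATH TAXPATHSN PERCENTAGE` rows, one
#' per taxon per rank, with percentages on the 0-100 scale.
#'
#' @param profile A [TaxProfile-class].
#' @param taxonomy A [Taxonomy-class] used for taxpaths and names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCamiProfile <- function(profile, taxonomy, path) {
  ranks <- names(Filter(length, profile@abundances))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("@SampleID:", profile@sampleId),
    "@Version:0.9.1",
    paste0("@Ranks:", paste(ranks, collapse = "|")),
    "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE"), con)
  for (rank in ranks) {
    v <- profile@abundances[[rank]]
    for (tid in names(v)) {
      lin <- lineageOf(taxonomy, as.integer(tid))
      lin <- lin[match(lin$rank, taxRanks()) <= match(rank, taxRanks()),
                 , drop = FALSE]
      writeLines(sprintf("%s\t%s\t%s\t%s\t%.6f", tid, rank,
                         paste(lin$taxid, collapse = "|"),
                         paste(lin$name, collapse = "|"),
                         100 * v[[tid]]), con)
    }
  }
  invisible(path)
}

#' Read a CAMI profiling file
#'
#' @param path CAMI-format file path.
#' @param sampleId Override the sample id (default: from the header).
#' @return A [TaxProfile-class] with abundances as fractions.
#' @export
readCamiProfile <- function(path, sampleId = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^@", lines, value = TRUE)
  sid <- sub("^@SampleID:", "", grep("^@SampleID:", hdr, value = TRUE))
  if (is.null(sampleId)) sampleId <- if (length(sid)) sid[1] else "sample"
  rows <- lines[!grepl("^@", lines)]
  ab <- stats::setNames(vector("list", length(taxRanks())), taxRanks())
  for (r in taxRanks()) ab[[r]] <- numeric(0)
  if (length(rows)) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    for (p in parts) {
      rank <- p[[2]]
      if (!rank %in% taxRanks()) next
      ab[[rank]][p[[1]]] <- as.numeric(p[[5]]) / 100
    }
  }
  TaxProfile(ab, sampleId = sampleId, basis = "count")
}

#' Write / read a contig-truth map TSV
#'
#' Two columns: `contig`, `taxid`.
#'
#' @param truth Named vector contig id -> taxid.
#' @param path File path.
#' @return `path` / the named integer vector.
#' @export
writeContigTruth <- function(truth, path) {
  write.table(data.frame(contig = names(truth),
                         taxid = as.integer(truth)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContigTruth
#' @export
readContigTruth <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(contig = "character"))
  setNames(as.integer(df$taxid), df$contig)
}

#' Build a profile directly from a rank -> abundance table
#'
#' Convenience constructor for truth profiles given externally, e.g. a
#' table of genus percentages: values may be on the percent scale
#' (`percent = TRUE`) or fractions.
#'
#' @param taxids Vector of taxids (or arbitrary taxon labels).
#' @param values Abundances, parallel to `taxids`.
#' @param rank Canonical rank the values live at.
#' @param percent Divide by 100 when TRUE.
#' @param sampleId Sample identifier.
#' @return A [TaxProfile-class] with the single rank filled.
#' @export
profileFromTable <- function(taxids, values, rank, percent = FALSE,
                             sampleId = "sample") {
  v <- as.numeric(values)
  if (percent) v <- v / 100
  ab <- setNames(list(setNames(v, as.character(taxids))), rank)
  TaxProfile(ab, sampleId = sampleId, basis = "count")
}
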