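#' Build a taxonomy from a node table
#'
#' Validates and wraps a node table (columns `taxid`, `parent`, `rank`,
#' `name`). The rank "kingdom" is normalized to "superkingdom"
#' (CAMI convention) and "no rank" to "no-rank". Validation rejects
#' duplicate taxids, multiple/missing roots, orphans and cycles.
#'
#' @param nodes data.frame with columns `taxid`, `parent`, `rank`,
#'   `name`.
#' @return A [Taxonomy-class].
#' @export
taxonomyFromFrame <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent <- as.integer(nodes$parent)
  nodes$rank <- tolower(as.character(nodes$rank))
  nodes$rank[nodes$rank == "kingdom"] <- "superkingdom"
  nodes$rank[nodes$rank %in% c("no rank", "norank", "")] <- "no-rank"
  nodes$name <- as.character(nodes$name)
  missing_parent <- !(nodes$parent %in% nodes$taxid)
  if (any(missing_parent))
    stop("taxonomy: parent taxid absent for node(s): ",
         paste(head(nodes$taxid[missing_parent], 5), collapse = ", "))
  root <- nodes$taxid[nodes$taxid == nodes$parent]
  if (length(root) != 1L)
    stop(sprintf("taxonomy: expected exactly one root, found %d",
                 length(root)))
  obj <- new("Taxonomy", nodes = nodes, root = as.integer(root))
  validObject(obj)
  obj
}

#' Load a taxonomy from a 4-column TSV
#'
#' The TSV dialect has a header and columns `taxid`, `parent`, `rank`,
#' `name`.
#'
#' @param path TSV file path.
#' @return A [Taxonomy-class].
#' @export
loadTaxonomyTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxid", "parent", "rank", "name")
  if (!all(need %in% names(df)))
    stop("taxonomy TSV needs columns: ", paste(need, collapse = ", "))
  taxonomyFromFrame(df[, need])
}

#' Load a taxonomy from NCBI-style dump files
#'
#' Parses the `nodes.dmp` / `names.dmp` dialect: fields separated by
#' `\t|\t` with a trailing `\t|`. Only "scientific name" entries are
#' taken from the names dump; nodes without one get their taxid as
#' name.
#'
#' @param nodesPath Path to a `nodes.dmp`-dialect file.
#' @param namesPath Path to a `names.dmp`-dialect file.
#' @return A [Taxonomy-class].
#' @export
loadTaxonomyDump <- function(nodesPath, namesPath) {
  parse_dmp <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  nd <- parse_dmp(nodesPath)
  nodes <- data.frame(
    taxid = as.integer(vapply(nd, `[[`, "", 1L)),
    parent = as.integer(vapply(nd, `[[`, "", 2L)),
    rank = vapply(nd, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  nm <- parse_dmp(namesPath)
  cls <- vapply(nm, function(x) if (length(x) >= 4) x[[4]] else "", "")
  sci <- nm[trimws(cls) == "scientific name"]
  nmap <- setNames(vapply(sci, `[[`, "", 2L),
                   vapply(sci, `[[`, "", 1L))
  nodes$name <- nmap[as.character(nodes$taxid)]
  nodes$name[is.na(nodes$name)] <- as.character(nodes$taxid[is.na(nodes$name)])
  taxonomyFromFrame(nodes)
}

#' Lineage of a taxid
#'
#' Walks the parent chain from `taxid` to the root and returns the
#' named-rank entries in descending rank order (superkingdom first).
#' Nodes with non-canonical ranks ("no-rank" etc.) are traversed but
#' not reported.
#'
#' @param taxonomy A [Taxonomy-class].
#' @param taxid Taxid present in the taxonomy.
#' @return data.frame with columns `rank`, `taxid`, `name`; zero rows
#'   for the root or for lineages with no named ranks.
#' @export
lineageOf <- function(taxonomy, taxid) {
  nd <- taxonomy@nodes
  idx <- match(as.integer(taxid), nd$taxid)
  if (is.na(idx)) stop("unknown taxid: ", taxid)
  chain <- integer(0)
  guard <- nrow(nd) + 1L
  while (guard > 0L) {
    chain <- c(idx, chain)
    if (nd$taxid[idx] == nd$parent[idx]) break
    idx <- match(nd$parent[idx], nd$taxid)
    guard <- guard - 1L
  }
  out <- data.frame(rank = nd$rank[chain], taxid = nd$taxid[chain],
                    name = nd$name[chain], stringsAsFactors = FALSE)
  out <- out[out$rank %in% taxRanks(), , drop = FALSE]
  out <- out[order(match(out$rank, taxRanks())), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Project a lineage to one rank
#'
#' @param lineage A lineage data.frame from [lineageOf()].
#' @param rank A canonical rank name (see [taxRanks()]).
#' @return The taxid at that rank, or `NA_integer_` when the lineage
#'   does not reach it.
#' @export
projectToRank <- function(lineage, rank) {
  stopifnot(rank %in% taxRanks())
  i <- match(rank, lineage$rank)
  if (is.na(i)) NA_integer_ else lineage$taxid[i]
}

#' Base accession of an assembly accession
#'
#' Strips the `GCF_`/`GCA_` prefix and the version suffix, returning
#' the 9-digit core so different assembly versions (`GCF_000169215.1`,
#' `GCF_000169215.2`) compare equal.
#'
#' @param accession Accession string(s) matching
#'   `GC[AF]_<digits>(.<version>)?`.
#' @return Character vector of digit cores.
#' @export
#' @examples
#' accessionBase("GCF_000169215.1")  # "000169215"
accessionBase <- function(accession) {
  ok <- grepl("^GC[AF]_[0-9]+(\\.[0-9]+)?$", accession)
  if (!all(ok))
    stop("malformed accession(s): ",
         paste(head(accession[!ok], 5), collapse = ", "))
  sub("^GC[AF]_([0-9]+)(\\.[0-9]+)?$", "\\1", accession)
}

#' Map candidate accessions to taxids via an assembly summary
#'
#' Matches candidate reference ids against an assembly-summary-style
#' TSV (columns `accession`, `taxid`, `species_taxid`) using the base
#' accession, so version drift between candidate lists and summaries
#' does not break the mapping. Unresolved candidates are reported in
#' the result, not fatal. When several summary rows share a base
#' accession with differing taxids, the first by full-accession sort
#' wins and a warning is raised.
#'
#' @param refIds Character vector of candidate accessions.
#' @param summarySource Path to the TSV, or a data.frame.
#' @return List with `map` (data.frame `refId`, `base`, `accession`,
#'   `taxid`, `speciesTaxid`) and `unresolved` (character vector).
#' @export
mapCandidates <- function(refIds, summarySource) {
  summ <- if (is.character(summarySource)) {
    if (!file.exists(summarySource))
      stop("cannot read assembly summary: ", summarySource)
    read.delim(summarySource, stringsAsFactors = FALSE, comment.char = "#")
  } else as.data.frame(summarySource, stringsAsFactors = FALSE)
  need <- c("accession", "taxid", "species_taxid")
  if (!all(need %in% names(summ)))
    stop("assembly summary needs columns: ", paste(need, collapse = ", "))
  summ$base <- accessionBase(summ$accession)
  summ <- summ[order(summ$accession), , drop = FALSE]
  dup <- duplicated(summ$base)
  if (any(dup)) {
    clash <- unique(summ$base[dup])
    diff_tax <- vapply(clash, function(b)
      length(unique(summ$taxid[summ$base == b])) > 1L, logical(1))
    if (any(diff_tax))
      warning("assembly summary: duplicate base accession(s) with ",
              "differing taxids; keeping first by accession sort: ",
              paste(head(clash[diff_tax], 5), collapse = ", "))
    summ <- summ[!dup, , drop = FALSE]
  }
  bases <- accessionBase(refIds)
  i <- match(bases, summ$base)
  map <- data.frame(refId = refIds, base = bases,
                    accession = summ$accession[i],
                    taxid = as.integer(summ$taxid[i]),
                    speciesTaxid = as.integer(summ$species_taxid[i]),
                    stringsAsFactors = FALSE)
  list(map = map[!is.na(map$taxid), , drop = FALSE],
       unresolved = refIds[is.na(i)])
}
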