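#' Reference abundance in an alignment set
#'
#' The frequency of each reference among all alignment records in the
#' dataset (record basis, the default) or among distinct queries
#' aligned to it (query basis). Fractions sum to 1 on the record basis.
#'
#' @param paf PAF data.frame for the whole dataset; must be non-empty.
#' @param basis `"records"` (default) or `"queries"`.
#' @return Named numeric vector refId -> fraction.
#' @export
referenceAbundance <- function(paf, basis = c("records", "queries")) {
  basis <- match.arg(basis)
  if (nrow(paf) == 0L) stop("referenceAbundance: empty alignment set")
  if (basis == "records") {
    tb <- table(paf$targetId)
    setNames(as.numeric(tb) / nrow(paf), names(tb))
  } else {
    pairs <- unique(paf[, c("queryId", "targetId")])
    tb <- table(pairs$targetId)
    setNames(as.numeric(tb) / length(unique(paf$queryId)), names(tb))
  }
}

#' Classify one query from its per-reference coverages
#'
#' Implements the coverage-weighted consensus classifier:
#'
#' 1. If any supporting reference has an exact (full-length,
#'    mismatch-free) alignment, that reference's full lineage is
#'    assigned directly with confidence 1.0. Ties among exact hits are
#'    broken by higher coverage, then lexicographic refId.
#' 2. Otherwise each reference is weighted by
#'    `coverage x abundance`. Descending the rank ladder, the weights
#'    are accumulated onto the references' lineage taxids at each
#'    rank; the maximum-weight taxid consistent with the parent chosen
#'    at the previous rank wins, and its consensus fraction (winning
#'    weight over total weight at that rank) is recorded. Descent
#'    stops at the deepest rank whose fraction is `>= minSupport`;
#'    the confidence is the product of the recorded fractions and the
#'    representative taxid is the winner at the stopping rank.
#'
#' Ties in the max-weight taxid are broken by the smaller taxid, so
#' output is deterministic and independent of record order.
#'
#' @param coverages data.frame from [coverageTable()] restricted to one
#'   query (columns `refId`, `coverage`, `exact`); zero rows mean the
#'   query is unclassified.
#' @param abundances Named numeric refId -> dataset frequency.
#' @param refTaxids Named vector refId -> taxid.
#' @param taxonomy A [Taxonomy-class].
#' @param minSupport Minimum consensus fraction to keep descending
#'   (default 0.5).
#' @return One-row data.frame: `queryId`, `lineage` (rank-prefixed,
#'   semicolon-joined), `taxonomicLevel`, `taxid`, `confidence`.
#'   Unclassified queries get level "unclassified", `NA` taxid and
#'   confidence 0.
#' @export
classifyQuery <- function(coverages, abundances, refTaxids, taxonomy,
                          minSupport = 0.5) {
  qid <- if (nrow(coverages)) coverages$queryId[1] else NA_character_
  unclassified <- data.frame(
    queryId = qid, lineage = "", taxonomicLevel = "unclassified",
    taxid = NA_integer_, confidence = 0, stringsAsFactors = FALSE)
  if (nrow(coverages) == 0L) return(unclassified)
  missing_tax <- setdiff(coverages$refId, names(refTaxids))
  if (length(missing_tax))
    stop("no taxid for reference(s): ",
         paste(head(missing_tax, 5), collapse = ", "))

  lineages <- lapply(coverages$refId, function(r)
    lineageOf(taxonomy, refTaxids[[r]]))

  # exact-hit fast path: directly assign that reference's lineage
  ex <- which(coverages$exact)
  if (length(ex)) {
    pick <- ex[order(-coverages$coverage[ex], coverages$refId[ex])][1]
    lin <- lineages[[pick]]
    return(data.frame(
      queryId = qid, lineage = renderLineage(lin),
      taxonomicLevel = if (nrow(lin)) lin$rank[nrow(lin)] else "unclassified",
      taxid = as.integer(refTaxids[[coverages$refId[pick]]]),
      confidence = 1, stringsAsFactors = FALSE))
  }

  w <- coverages$coverage *
    vapply(coverages$refId, function(r) {
      a <- abundances[[r]]
      if (is.null(a) || is.na(a)) 0 else a
    }, numeric(1))
  if (all(w <= 0)) return(unclassified)

  active <- rep(TRUE, length(w))   # refs consistent with the chosen path
  fractions <- numeric(0)
  chosen <- data.frame(rank = character(), taxid = integer(),
                       name = character(), stringsAsFactors = FALSE)
  for (rank in taxRanks()) {
    at_rank <- vapply(lineages, projectToRank, integer(1), rank = rank)
    defined <- !is.na(at_rank) & w > 0
    if (!any(defined & active)) break
    total <- sum(w[defined])       # all refs defining the rank
    tw <- tapply(w[defined & active], at_rank[defined & active], sum)
    winner <- as.integer(names(tw)[order(-tw, as.integer(names(tw)))][1])
    frac <- unname(tw[as.character(winner)]) / total
    if (frac < minSupport) break
    fractions <- c(fractions, frac)
    i <- which(defined & active & at_rank == winner)[1]
    lin_i <- lineages[[i]]
    chosen <- rbind(chosen, lin_i[lin_i$rank == rank, , drop = FALSE])
    active <- active & defined & at_rank == winner
  }
  if (nrow(chosen) == 0L) return(unclassified)
  data.frame(
    queryId = qid, lineage = renderLineage(chosen),
    taxonomicLevel = chosen$rank[nrow(chosen)],
    taxid = chosen$taxid[nrow(chosen)],
    confidence = prod(fractions), stringsAsFactors = FALSE)
}

# rank-prefixed, semicolon-joined lineage string
renderLineage <- function(lineage) {
  if (nrow(lineage) == 0L) return("")
  prefix <- c(superkingdom = "k", phylum = "p", class = "c",
              order = "o", family = "f", genus = "g", species = "s",
              strain = "t")
  paste(sprintf("%s__%s", prefix[lineage$rank], lineage$name),
        collapse = ";")
}

#' Classify every query in an alignment set
#'
#' Convenience wrapper: computes per-pair coverages, dataset reference
#' abundances, and runs [classifyQuery()] per query. Queries listed in
#' `allQueries` but absent from the PAF are reported unclassified.
#'
#' @param paf PAF data.frame for the dataset.
#' @param refTaxids Named vector refId -> taxid.
#' @param taxonomy A [Taxonomy-class].
#' @param minSupport Passed to [classifyQuery()].
#' @param abundanceBasis Passed to [referenceAbundance()].
#' @param allQueries Optional character vector of all query ids.
#' @return data.frame of classifications, one row per query.
#' @export
classifyAll <- function(paf, refTaxids, taxonomy, minSupport = 0.5,
                        abundanceBasis = "records", allQueries = NULL) {
  covs <- coverageTable(paf)
  ab <- if (nrow(paf)) referenceAbundance(paf, abundanceBasis) else numeric()
  res <- lapply(split(covs, covs$queryId), classifyQuery,
                abundances = ab, refTaxids = refTaxids,
                taxonomy = taxonomy, minSupport = minSupport)
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(queryId = character(), lineage = character(),
               taxonomicLevel = character(), taxid = integer(),
               confidence = numeric(), stringsAsFactors = FALSE)
  if (!is.null(allQueries)) {
    miss <- setdiff(allQueries, out$queryId)
    if (length(miss))
      out <- rbind(out, data.frame(
        queryId = miss, lineage = "", taxonomicLevel = "unclassified",
        taxid = NA_integer_, confidence = 0, stringsAsFactors = FALSE))
    out <- out[match(allQueries, out$queryId), , drop = FALSE]
  } else {
    out <- out[order(out$queryId), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write classifications TSV
#'
#' Writes the five-column tab-delimited classification table with
#' header `Query`, `Lineage`, `Taxonomic Level`, `TaxID`, `Confidence`;
#' confidence is rendered with 4 decimals.
#'
#' @param classifications data.frame from [classifyAll()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeClassifications <- function(classifications, path) {
  df <- data.frame(
    Query = classifications$queryId,
    Lineage = classifications$lineage,
    `Taxonomic Level` = classifications$taxonomicLevel,
    TaxID = classifications$taxid,
    Confidence = sprintf("%.4f", classifications$confidence),
    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClassifications
#' @return `readClassifications` returns the classification data.frame
#'   in [classifyAll()] layout.
#' @export
readClassifications <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = c(Query = "character"))
  data.frame(queryId = as.character(df$Query), lineage = df$Lineage,
             taxonomicLevel = df$`Taxonomic Level`,
             taxid = as.integer(df$TaxID),
             confidence = as.numeric(df$Confidence),
             stringsAsFactors = FALSE)
}
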