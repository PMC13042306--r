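#' Build an abundance profile from classifications
#'
#' For every canonical rank, each classified query's mass (1/N on the
#' count basis, length/total-length on the length basis) is assigned to
#' its lineage's taxid at that rank. Queries whose classification does
#' not reach a rank leave their mass unassigned there, so per-rank sums
#' may be below 1.
#'
#' @param classifications data.frame from [classifyAll()].
#' @param taxonomy A [Taxonomy-class].
#' @param basis `"count"` or `"length"`.
#' @param lengths Named numeric query lengths (required for the length
#'   basis).
#' @param sampleId Sample identifier recorded in the profile.
#' @return A [TaxProfile-class].
#' @export
profileFromClassifications <- function(classifications, taxonomy,
                                       basis = c("count", "length"),
                                       lengths = NULL,
                                       sampleId = "sample") {
  basis <- match.arg(basis)
  n <- nrow(classifications)
  mass <- if (basis == "count") rep(1 / n, n) else {
    stopifnot(!is.null(lengths))
    l <- as.numeric(lengths[classifications$queryId])
    l / sum(l)
  }
  lin <- lapply(classifications$taxid, function(t)
    if (is.na(t)) NULL else lineageOf(taxonomy, t))
  ab <- lapply(taxRanks(), function(rank) {
    at <- vapply(lin, function(L)
      if (is.null(L)) NA_integer_ else projectToRank(L, rank), integer(1))
    ok <- !is.na(at)
    if (!any(ok)) return(numeric(0))
    v <- tapply(mass[ok], at[ok], sum)
    setNames(as.numeric(v), names(v))
  })
  names(ab) <- taxRanks()
  TaxProfile(ab, sampleId = sampleId, basis = basis)
}

# union-aligned abundance vectors of two profiles at a rank
unionVectors <- function(pred, truth, rank) {
  p <- rankAbundance(pred, rank)
  t <- rankAbundance(truth, rank)
  taxa <- union(names(p), names(t))
  list(pred = setNames(ifelse(taxa %in% names(p), p[taxa], 0), taxa),
       truth = setNames(ifelse(taxa %in% names(t), t[taxa], 0), taxa))
}

#' Presence/absence metrics at a rank
#'
#' Taxa with abundance at or above `threshold` in a profile count as
#' present. Precision is the fraction of predicted-present taxa that
#' are truly present; recall the fraction of truly present taxa that
#' were predicted; F1 their harmonic mean. All are percentages. An
#' empty predicted-positive set yields precision 0 with
#' `emptyPrediction = TRUE` (declared convention); an empty truth set
#' is an error since recall is undefined.
#'
#' @param pred,truth [TaxProfile-class] objects.
#' @param rank Canonical rank.
#' @param threshold Minimum abundance fraction (default 0.001 = 0.1%).
#' @return List: `precision`, `recall`, `f1` (percent),
#'   `emptyPrediction` flag.
#' @export
presenceMetrics <- function(pred, truth, rank, threshold = 0.001) {
  v <- unionVectors(pred, truth, rank)
  P <- names(v$pred)[v$pred >= threshold]
  Tr <- names(v$truth)[v$truth >= threshold]
  if (length(Tr) == 0L)
    stop("presenceMetrics: no truth taxa at or above threshold; ",
         "recall is undefined")
  tp <- length(intersect(P, Tr))
  prec <- if (length(P)) 100 * tp / length(P) else 0
  rec <- 100 * tp / length(Tr)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1,
       emptyPrediction = length(P) == 0L)
}

#' L1 total-variation distance at a rank
#'
#' Sum over the union of taxa of `|pred - truth|`. Reported without the
#' 1/2 total-variation factor, so for normalized profiles it equals
#' twice the Bray-Curtis dissimilarity. `scale = "pp"` multiplies by
#' 100 to report percentage points.
#'
#' @param pred,truth [TaxProfile-class] objects.
#' @param rank Canonical rank.
#' @param scale `"fraction"` (default) or `"pp"`.
#' @return Non-negative numeric distance.
#' @export
l1Distance <- function(pred, truth, rank, scale = c("fraction", "pp")) {
  scale <- match.arg(scale)
  v <- unionVectors(pred, truth, rank)
  d <- sum(abs(v$pred - v$truth))
  if (scale == "pp") 100 * d else d
}

#' Bray-Curtis dissimilarity at a rank
#'
#' `sum|pred - truth| / sum(pred + truth)` over the union of taxa;
#' 0 for identical profiles, 1 for disjoint ones.
#'
#' @inheritParams l1Distance
#' @return Value in `[0, 1]`.
#' @export
brayCurtis <- function(pred, truth, rank) {
  v <- unionVectors(pred, truth, rank)
  denom <- sum(v$pred + v$truth)
  if (denom == 0) stop("brayCurtis: both profiles empty at rank ", rank)
  sum(abs(v$pred - v$truth)) / denom
}

#' Pearson correlation of abundances at a rank
#'
#' Correlation over the union vector of abundances (absent taxa as 0).
#' Requires at least two taxa in the union and nonzero variance in
#' both vectors.
#'
#' @inheritParams l1Distance
#' @return Correlation in `[-1, 1]`.
#' @export
pearsonAbundance <- function(pred, truth, rank) {
  v <- unionVectors(pred, truth, rank)
  if (length(v$pred) < 2L)
    stop("pearsonAbundance: need >= 2 taxa in the union")
  if (stats::sd(v$pred) == 0 || stats::sd(v$truth) == 0)
    stop("pearsonAbundance: zero variance; correlation undefined")
  cor(v$pred, v$truth)
}

#' Contig-level accuracy at a rank
#'
#' Fraction (percent) of truth contigs whose predicted lineage,
#' projected to `rank`, equals the truth lineage projected to the same
#' rank. Contigs unclassified at the rank — or missing from the
#' predictions — count as incorrect.
#'
#' @param classifications data.frame from [classifyAll()].
#' @param truth Named vector contig id -> truth taxid.
#' @param taxonomy A [Taxonomy-class].
#' @param rank Canonical rank.
#' @return Percent accuracy.
#' @export
contigAccuracy <- function(classifications, truth, taxonomy, rank) {
  stopifnot(length(truth) > 0)
  pred_at <- function(qid) {
    i <- match(qid, classifications$queryId)
    if (is.na(i) || is.na(classifications$taxid[i])) return(NA_integer_)
    projectToRank(lineageOf(taxonomy, classifications$taxid[i]), rank)
  }
  truth_at <- vapply(truth, function(t)
    projectToRank(lineageOf(taxonomy, t), rank), integer(1))
  pred <- vapply(names(truth), pred_at, integer(1))
  scored <- !is.na(truth_at)   # contigs whose truth reaches the rank
  if (!any(scored)) return(NA_real_)
  100 * sum(!is.na(pred[scored]) &
              pred[scored] == truth_at[scored]) / sum(scored)
}

#' Rank-group shares of classified queries
#'
#' Shares (percent of classified queries) of the most specific reported
#' level grouped as species/strain, genus, family, and higher/unknown
#' (order and above, plus unclassified-at-named-rank outputs).
#'
#' @param classifications data.frame from [classifyAll()].
#' @return Named numeric: `species_strain`, `genus`, `family`,
#'   `higher_unknown` percentages plus `n_classified`.
#' @export
rankShareSummary <- function(classifications) {
  cls <- classifications[classifications$taxonomicLevel != "unclassified",
                         , drop = FALSE]
  n <- nrow(cls)
  if (n == 0L) stop("rankShareSummary: no classified queries")
  lvl <- cls$taxonomicLevel
  grp <- ifelse(lvl %in% c("species", "strain"), "species_strain",
         ifelse(lvl == "genus", "genus",
         ifelse(lvl == "family", "family", "higher_unknown")))
  out <- c(species_strain = 0, genus = 0, family = 0, higher_unknown = 0)
  tb <- table(grp)
  out[names(tb)] <- 100 * as.numeric(tb) / n
  c(out, n_classified = n)
}

#' Per-taxon difference table at a rank
#'
#' One row per taxon in the union of the two profiles: truth and
#' predicted abundances in percent and their signed difference
#' (predicted minus truth) in percentage points, sorted by truth
#' abundance descending.
#'
#' @inheritParams l1Distance
#' @param taxonomy Optional [Taxonomy-class] used to attach names.
#' @return data.frame with columns `taxid`, `name`, `truthPct`,
#'   `predPct`, `diffPp`.
#' @export
diffTable <- function(pred, truth, rank, taxonomy = NULL) {
  v <- unionVectors(pred, truth, rank)
  nm <- names(v$truth)
  label <- if (!is.null(taxonomy)) {
    i <- match(as.integer(nm), taxonomy@nodes$taxid)
    ifelse(is.na(i), nm, taxonomy@nodes$name[i])
  } else nm
  out <- data.frame(taxid = nm, name = label,
                    truthPct = 100 * as.numeric(v$truth),
                    predPct = 100 * as.numeric(v$pred),
                    stringsAsFactors = FALSE)
  out$diffPp <- out$predPct - out$truthPct
  out <- out[order(-out$truthPct, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank-wise metrics report
#'
#' Computes the presence metrics, L1, Bray-Curtis and (where defined)
#' Pearson correlation per rank, plus means across ranks.
#'
#' @param pred,truth [TaxProfile-class] objects.
#' @param ranks Ranks to evaluate (default all shared ranks with truth
#'   taxa).
#' @param threshold Presence threshold (fraction).
#' @return data.frame, one row per rank plus a `mean` row.
#' @export
metricsReport <- function(pred, truth, ranks = NULL, threshold = 0.001) {
  if (is.null(ranks))
    ranks <- names(Filter(length, truth@abundances))
  rows <- lapply(ranks, function(r) {
    pm <- presenceMetrics(pred, truth, r, threshold)
    pr <- tryCatch(pearsonAbundance(pred, truth, r),
                   error = function(e) NA_real_)
    data.frame(rank = r, precision = pm$precision, recall = pm$recall,
               f1 = pm$f1, l1 = l1Distance(pred, truth, r),
               brayCurtis = brayCurtis(pred, truth, r), pearson = pr,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  mean_row <- data.frame(rank = "mean",
                         t(colMeans(df[, -1], na.rm = TRUE)))
  names(mean_row) <- names(df)
  rbind(df, mean_row)
}
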