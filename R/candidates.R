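#' Candidate-selection budget
#'
#' Parameters of the sample-adaptive candidate selection: the loop
#' starts at `startThreshold`, lowers the threshold in `step`
#' decrements, and stops as soon as the number of qualifying candidates
#' reaches the target (`perSequence` candidates per query, rounded half
#' up, with an absolute `minimum`) or the `floorThreshold` has been
#' tried. Candidates below the floor are never returned. When
#' `dedupSpecies` is TRUE and a species map is supplied, candidates are
#' deduplicated to one reference per species before counting.
#'
#' @param perSequence Target candidates per input sequence (default 3.25).
#' @param minimum Floor on the target count (default 5).
#' @param startThreshold Initial score threshold (default 0.90).
#' @param step Threshold decrement (default 0.02).
#' @param floorThreshold Lowest threshold tried (default 0.70).
#' @param dedupSpecies Deduplicate candidates per species (default TRUE).
#' @return A named list with class `CandidateBudget`.
#' @export
#' @examples
#' candidateBudget()
candidateBudget <- function(perSequence = 3.25, minimum = 5L,
                            startThreshold = 0.90, step = 0.02,
                            floorThreshold = 0.70, dedupSpecies = TRUE) {
  stopifnot(perSequence > 0, minimum >= 0, step > 0,
            floorThreshold > 0, floorThreshold <= startThreshold,
            startThreshold <= 1)
  structure(list(perSequence = perSequence, minimum = as.integer(minimum),
                 startThreshold = startThreshold, step = step,
                 floorThreshold = floorThreshold,
                 dedupSpecies = isTRUE(dedupSpecies)),
            class = "CandidateBudget")
}

#' Candidate-count target for a sample
#'
#' `max(round_half_up(perSequence * nQueries), minimum)`. With the
#' defaults a single query targets 5 candidates and 100 queries target
#' 325.
#'
#' @param nQueries Number of input query sequences (>= 1).
#' @param budget A [candidateBudget()].
#' @return Integer target count.
#' @export
#' @examples
#' candidateTarget(1, candidateBudget())    # 5
#' candidateTarget(100, candidateBudget())  # 325
candidateTarget <- function(nQueries, budget = candidateBudget()) {
  if (length(nQueries) != 1L || is.na(nQueries) || nQueries < 1)
    stop("candidateTarget: nQueries must be >= 1 (no queries to screen)")
  as.integer(max(round_half_up(budget$perSequence * nQueries),
                 budget$minimum))
}

#' Species-level candidate deduplication
#'
#' Keeps one candidate per species taxid: the one with the highest
#' containment (ties broken by lexicographically smallest `refId`).
#' References absent from the species map pass through untouched.
#'
#' @param candidates data.frame with columns `refId`, `containment`
#'   (and optionally `speciesTaxid`).
#' @param speciesMap Named vector/list mapping refId to species taxid.
#' @return Deduplicated data.frame, containment-descending order.
#' @export
dedupSpecies <- function(candidates, speciesMap) {
  if (nrow(candidates) == 0L) return(candidates)
  sp <- speciesMap[candidates$refId]
  sp <- vapply(seq_along(sp), function(i) {
    v <- sp[[i]]
    if (is.null(v) || is.na(v)) NA_character_ else as.character(v)
  }, character(1))
  candidates$speciesTaxid <- sp
  ord <- order(-candidates$containment, candidates$refId)
  candidates <- candidates[ord, , drop = FALSE]
  keep <- is.na(sp[ord]) | !duplicated(sp[ord], incomparables = NA)
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Adaptive candidate selection with a dynamic threshold
#'
#' Starting at the budget's start threshold, counts screen hits whose
#' score (`containment` column) meets the threshold — after per-species
#' deduplication when enabled and a species map is given. If the count
#' reaches the target the loop stops; otherwise the threshold is
#' lowered by `step`. The loop terminates at the floor threshold,
#' returning whatever qualifies there (possibly nothing). Thresholds
#' are stepped with integer arithmetic on hundredths so `0.90, 0.88,
#' ..., 0.70` are hit exactly.
#'
#' @param hits data.frame of screen hits ([screenSketches()] output or
#'   compatible); may be empty.
#' @param nQueries Number of query sequences the sample contains.
#' @param budget A [candidateBudget()].
#' @param speciesMap Optional named map refId -> species taxid.
#' @return List with `candidates` (data.frame sorted by containment
#'   descending, refId ascending), `finalThreshold`, `targetCount`,
#'   `nQueries`.
#' @export
adaptiveSelect <- function(hits, nQueries, budget = candidateBudget(),
                           speciesMap = NULL) {
  target <- candidateTarget(nQueries, budget)
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- data.frame(refId = character(), containment = numeric(),
                       stringsAsFactors = FALSE)
  }
  # integer hundredths avoid float drift in the threshold ladder
  to_h <- function(x) as.integer(round(x * 100))
  thresholds <- seq(to_h(budget$startThreshold), to_h(budget$floorThreshold),
                    by = -to_h(budget$step))
  if (length(thresholds) == 0L) thresholds <- to_h(budget$startThreshold)
  qualify <- function(th) {
    sub <- hits[hits$containment >= th / 100 - 1e-12, , drop = FALSE]
    if (budget$dedupSpecies && !is.null(speciesMap))
      sub <- dedupSpecies(sub, speciesMap)
    sub
  }
  final <- thresholds[length(thresholds)]
  sel <- NULL
  for (th in thresholds) {
    sel <- qualify(th)
    if (nrow(sel) >= target) { final <- th; break }
    final <- th
  }
  sel <- sel[order(-sel$containment, sel$refId), , drop = FALSE]
  rownames(sel) <- NULL
  list(candidates = sel, finalThreshold = final / 100,
       targetCount = target, nQueries = as.integer(nQueries))
}

#' Write a candidate manifest TSV
#'
#' Columns: `refId`, `containment`, `speciesTaxid` (NA when unmapped),
#' `finalThreshold`.
#'
#' @param selection Result of [adaptiveSelect()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCandidateManifest <- function(selection, path) {
  df <- selection$candidates
  if (is.null(df$speciesTaxid)) df$speciesTaxid <- NA_character_
  df$finalThreshold <- selection$finalThreshold
  write.table(df[, c("refId", "containment", "speciesTaxid",
                     "finalThreshold")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
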