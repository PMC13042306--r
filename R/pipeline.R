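# pool query k-mers: join with an N so no chimeric k-mer spans two queries
pooledQueryHashes <- function(queries, params) {
  kmerHashes(paste(as.character(queries), collapse = "N"), params)
}

#' Run the full classification pipeline
#'
#' Sketch the references, screen the pooled query k-mer set against
#' them, select candidate references with the adaptive threshold,
#' align the queries to the selected candidates, and classify each
#' query with the coverage-weighted consensus classifier. Returns the
#' classifications, the derived abundance profile and the intermediate
#' artifacts.
#'
#' Screening scores: `screenScore = "identity"` (default) thresholds a
#' Mash-style identity estimate (`containment^(1/k)`), which keeps the
#' 0.90/0.70 ladder meaningful for diverged queries;
#' `"containment"` thresholds the raw containment index.
#'
#' @param queries Named character vector or `Biostrings::DNAStringSet`
#'   of query contigs/reads.
#' @param references Named character vector or `DNAStringSet` of
#'   reference genomes.
#' @param refTaxids Named vector refId -> taxid.
#' @param taxonomy A [Taxonomy-class].
#' @param params [SketchParams-class] for screening (default k = 15,
#'   s = 1000, the small-genome setting).
#' @param budget A [candidateBudget()].
#' @param minSupport Consensus threshold for [classifyQuery()].
#' @param mode `"contigs"` (asm10 alignment preset) or `"reads"` (sr).
#' @param screenScore `"identity"` or `"containment"`.
#' @param paf Optional pre-computed PAF data.frame; when supplied the
#'   aligner is not invoked and candidate selection only restricts the
#'   PAF to selected references.
#' @param speciesMap Optional refId -> species taxid map for candidate
#'   deduplication; by default derived from `refTaxids` lineages.
#' @param outDir Optional output directory; when given, the
#'   classifications TSV, candidate manifest, profile and a run log
#'   are written there.
#' @param threads Threads for the aligner.
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return List: `classifications`, `profile`, `selection`, `hits`,
#'   `paf`.
#' @export
runPipeline <- function(queries, references, refTaxids, taxonomy,
                        params = SketchParams(k = 15, s = 1000, seed = 42),
                        budget = candidateBudget(), minSupport = 0.5,
                        mode = c("contigs", "reads"),
                        screenScore = c("identity", "containment"),
                        paf = NULL, speciesMap = NULL, outDir = NULL,
                        threads = 1L, seed = 1L) {
  mode <- match.arg(mode)
  screenScore <- match.arg(screenScore)
  queries <- as_named_chr(queries)
  references <- as_named_chr(references)
  stopifnot(!is.null(names(queries)), !is.null(names(references)),
            all(names(references) %in% names(refTaxids)))

  if (is.null(speciesMap)) {
    speciesMap <- vapply(names(references), function(r)
      projectToRank(lineageOf(taxonomy, refTaxids[[r]]), "species"),
      integer(1))
  }

  sketches <- sketchReferences(references, params)
  qh <- pooledQueryHashes(queries, params)
  hits <- screenSketches(qh, sketches)
  scored <- hits
  if (screenScore == "identity")
    scored$containment <- containmentToIdentity(hits$containment,
                                                params@k)
  selection <- adaptiveSelect(scored, nQueries = length(queries),
                              budget = budget, speciesMap = speciesMap)
  cand <- selection$candidates$refId

  if (is.null(paf)) {
    if (length(cand) == 0L) {
      paf <- emptyPaf()
    } else {
      qf <- tempfile(fileext = ".fa"); rf <- tempfile(fileext = ".fa")
      on.exit(unlink(c(qf, rf)), add = TRUE)
      writeFasta(queries, qf)
      writeFasta(references[cand], rf)
      hook <- alignerHook(if (mode == "contigs") "asm10" else "sr",
                          threads = threads)
      paf <- alignWithMinimap2(qf, rf, hook)
    }
  } else {
    paf <- paf[paf$targetId %in% cand, , drop = FALSE]
  }

  cls <- classifyAll(paf, refTaxids, taxonomy, minSupport = minSupport,
                     allQueries = names(queries))
  prof <- profileFromClassifications(cls, taxonomy, basis = "count",
                                     sampleId = "run")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeClassifications(cls, file.path(outDir,
                                        "classified_sequences.tsv"))
    writeCandidateManifest(selection,
                           file.path(outDir, "candidates.tsv"))
    writeCamiProfile(prof, taxonomy, file.path(outDir, "profile.tsv"))
    log <- list(params = list(k = params@k, s = params@s,
                              seed = params@seed),
                budget = unclass(budget), minSupport = minSupport,
                mode = mode, screenScore = screenScore,
                nQueries = length(queries),
                nReferences = length(references),
                nCandidates = length(cand), seed = seed,
                finalThreshold = selection$finalThreshold,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    log$configHash <- hash_string_cpp(jsonlite::toJSON(
      log[setdiff(names(log), "timestamp")], auto_unbox = TRUE))
    jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(classifications = cls, profile = prof, selection = selection,
       hits = hits, paf = paf)
}
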