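#' Sketching parameters
#'
#' Parameters governing bottom-s MinHash sketch construction: the k-mer
#' length `k`, the sketch size `s` (number of retained hashes), the
#' integer hash `seed`, and the `alphabetSize` (4 for nucleotides).
#' Sketches are comparable only when `k` and `seed` match.
#'
#' @slot k Integer k-mer length in bases.
#' @slot s Integer sketch size.
#' @slot seed Integer hash seed.
#' @slot alphabetSize Integer alphabet size.
#' @export
setClass("SketchParams",
  representation(k = "integer", s = "integer", seed = "integer",
                 alphabetSize = "integer"),
  prototype(k = 21L, s = 1000L, seed = 42L, alphabetSize = 4L))

setValidity("SketchParams", function(object) {
  msg <- character()
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "k must be a single integer >= 1")
  if (length(object@k) == 1L && !is.na(object@k) && object@k > 31L)
    msg <- c(msg, "k must be <= 31 (2-bit packed 64-bit codes)")
  if (length(object@s) != 1L || is.na(object@s) || object@s < 1L)
    msg <- c(msg, "s must be a single integer >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(object@alphabetSize) != 1L || is.na(object@alphabetSize) ||
      object@alphabetSize < 2L)
    msg <- c(msg, "alphabetSize must be >= 2")
  if (length(msg)) msg else TRUE
})

#' @describeIn SketchParams-class Constructor.
#' @param k,s,seed,alphabetSize See slots.
#' @return A `SketchParams` object.
#' @export
#' @examples
#' SketchParams(k = 15, s = 5000, seed = 42)
SketchParams <- function(k = 21, s = 1000, seed = 42, alphabetSize = 4) {
  new("SketchParams", k = as.integer(k), s = as.integer(s),
      seed = as.integer(seed), alphabetSize = as.integer(alphabetSize))
}

setMethod("show", "SketchParams", function(object) {
  cat(sprintf("SketchParams: k=%d s=%d seed=%d |Sigma|=%d\n",
              object@k, object@s, object@seed, object@alphabetSize))
})

#' Bottom-s MinHash sketch of a reference sequence
#'
#' The `s` smallest distinct 53-bit canonical k-mer hash values of one
#' reference sequence, with provenance (`SketchParams`) and the count of
#' distinct canonical k-mers observed. Deterministic for a fixed
#' (sequence, params) pair; identical for a sequence and its reverse
#' complement.
#'
#' @slot refId Character reference identifier.
#' @slot params The `SketchParams` used.
#' @slot hashes Strictly increasing numeric vector of retained hashes
#'   (length `min(s, nKmers)`).
#' @slot nKmers Number of distinct canonical k-mers in the sequence.
#' @export
setClass("KmerSketch",
  representation(refId = "character", params = "SketchParams",
                 hashes = "numeric", nKmers = "numeric"))

setValidity("KmerSketch", function(object) {
  msg <- character()
  if (length(object@refId) != 1L) msg <- c(msg, "refId must be length 1")
  if (length(object@hashes) != min(object@params@s, object@nKmers))
    msg <- c(msg, "|hashes| must equal min(s, nKmers)")
  if (length(object@hashes) > 1L && any(diff(object@hashes) <= 0))
    msg <- c(msg, "hashes must be strictly increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "KmerSketch", function(object) {
  cat(sprintf("KmerSketch '%s': %d/%d hashes (k=%d, seed=%d)\n",
              object@refId, length(object@hashes), object@params@s,
              object@params@k, object@params@seed))
})

#' @describeIn KmerSketch-class Number of retained hashes.
#' @param x A `KmerSketch`.
#' @export
setMethod("length", "KmerSketch", function(x) length(x@hashes))

#' Accessors for sketch objects
#'
#' @param x A [KmerSketch-class] object.
#' @return `sketchHashes` returns the numeric hash vector, `sketchParams`
#'   the [SketchParams-class], `refId` the reference identifier and
#'   `nKmers` the distinct canonical k-mer count.
#' @export
sketchHashes <- function(x) x@hashes
#' @rdname sketchHashes
#' @export
sketchParams <- function(x) x@params
#' @rdname sketchHashes
#' @export
refId <- function(x) x@refId
#' @rdname sketchHashes
#' @export
nKmers <- function(x) x@nKmers

#' Taxonomy with lineage resolution
#'
#' A validated rooted taxonomy. Nodes carry a `taxid`, `parent`, `rank`
#' and scientific `name`; exactly one root (parent == self) must exist
#' and every node must be reachable from it (this rejects both orphans
#' and cycles). Ranks outside the canonical ladder (see [taxRanks()])
#' are traversed but skipped when lineages are projected to named ranks.
#'
#' @slot nodes A data.frame with columns `taxid`, `parent`, `rank`,
#'   `name`.
#' @slot root Integer taxid of the root node.
#' @export
setClass("Taxonomy",
  representation(nodes = "data.frame", root = "integer"))

setValidity("Taxonomy", function(object) {
  nd <- object@nodes
  msg <- character()
  need <- c("taxid", "parent", "rank", "name")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$taxid)) msg <- c(msg, "duplicate taxid")
  roots <- nd$taxid[nd$taxid == nd$parent]
  if (length(roots) != 1L)
    msg <- c(msg, sprintf("expected exactly one root, found %d", length(roots)))
  if (length(msg)) return(msg)
  # reachability from root catches orphans and cycles in one pass
  kids <- split(nd$taxid, factor(nd$parent, levels = nd$taxid))
  seen <- logical(nrow(nd))
  names(seen) <- as.character(nd$taxid)
  queue <- roots
  seen[as.character(roots)] <- TRUE
  while (length(queue)) {
    nxt <- unlist(kids[as.character(queue)], use.names = FALSE)
    nxt <- setdiff(nxt, queue)
    nxt <- nxt[!seen[as.character(nxt)]]
    seen[as.character(nxt)] <- TRUE
    queue <- nxt
  }
  if (!all(seen))
    msg <- c(msg, sprintf(
      "node(s) not reachable from root (orphan or cycle): %s",
      paste(head(nd$taxid[!seen], 5), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "Taxonomy", function(object) {
  cat(sprintf("Taxonomy: %d nodes, root taxid %d\n",
              nrow(object@nodes), object@root))
  tb <- table(object@nodes$rank)
  cat("  ranks:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
})

#' @describeIn Taxonomy-class Node table accessor.
#' @param x A `Taxonomy`.
#' @export
taxNodes <- function(x) x@nodes

#' Rank-indexed relative-abundance profile
#'
#' Per taxonomic rank, a named numeric vector mapping taxid to relative
#' abundance (fractions). Per-rank sums may be below 1: mass of queries
#' not classified to that depth stays unassigned.
#'
#' @slot abundances Named list (by rank) of named numeric vectors
#'   (names are taxids, values are fractions).
#' @slot sampleId Character sample identifier.
#' @slot basis Either "count" (each query contributes 1/N) or "length"
#'   (contribution proportional to query length).
#' @export
setClass("TaxProfile",
  representation(abundances = "list", sampleId = "character",
                 basis = "character"))

setValidity("TaxProfile", function(object) {
  msg <- character()
  if (!object@basis %in% c("count", "length"))
    msg <- c(msg, "basis must be 'count' or 'length'")
  for (r in names(object@abundances)) {
    v <- object@abundances[[r]]
    if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
      msg <- c(msg, sprintf("rank '%s': abundances must be named by taxid", r))
    if (any(v < 0)) msg <- c(msg, sprintf("rank '%s': negative abundance", r))
    if (length(v) && sum(v) > 1 + 1e-8)
      msg <- c(msg, sprintf("rank '%s': abundances sum to > 1", r))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TaxProfile-class Constructor.
#' @param abundances,sampleId,basis See slots.
#' @export
TaxProfile <- function(abundances, sampleId = "sample", basis = "count") {
  new("TaxProfile", abundances = abundances, sampleId = sampleId,
      basis = basis)
}

setMethod("show", "TaxProfile", function(object) {
  cat(sprintf("TaxProfile '%s' (basis=%s):\n", object@sampleId, object@basis))
  for (r in names(object@abundances))
    cat(sprintf("  %-13s %d taxa, mass %.3f\n", r,
                length(object@abundances[[r]]),
                sum(object@abundances[[r]])))
})

#' @describeIn TaxProfile-class Abundance vector at one rank (taxid-named
#'   fractions); empty numeric if the rank is absent.
#' @param x A `TaxProfile`.
#' @param rank Canonical rank name.
#' @export
rankAbundance <- function(x, rank) {
  v <- x@abundances[[rank]]
  if (is.null(v)) numeric(0) else v
}

#' @describeIn TaxProfile-class Ranks present in the profile.
#' @export
profileRanks <- function(x) names(x@abundances)

#' Synthetic community with ground truth
#'
#' A seeded synthetic metagenome: reference genomes with lineages, the
#' taxonomy they live in, contigs sampled from the genomes, the
#' contig-to-taxid truth map, and the truth abundance profile derived
#' from the contigs under the declared basis.
#'
#' @slot genomes `DNAStringSet` of reference genomes (names are ref ids).
#' @slot genomeTaxids Integer vector, parallel to `genomes`.
#' @slot taxonomy The [Taxonomy-class] the taxids live in.
#' @slot contigs `DNAStringSet` of query contigs.
#' @slot contigTruth Named integer vector: contig id -> truth taxid.
#' @slot truthProfile [TaxProfile-class] implied by the contigs.
#' @slot abundances Named numeric: genome-level relative abundances.
#' @slot seed Integer seed the community was generated from.
#' @export
setClass("SyntheticCommunity",
  representation(genomes = "ANY", genomeTaxids = "integer",
                 taxonomy = "Taxonomy", contigs = "ANY",
                 contigTruth = "integer", truthProfile = "TaxProfile",
                 abundances = "numeric", seed = "integer"))

setValidity("SyntheticCommunity", function(object) {
  msg <- character()
  if (length(object@genomes) != length(object@genomeTaxids))
    msg <- c(msg, "genomes and genomeTaxids lengths differ")
  if (!all(object@genomeTaxids %in% object@taxonomy@nodes$taxid))
    msg <- c(msg, "genome taxid missing from taxonomy")
  if (!all(object@contigTruth %in% object@taxonomy@nodes$taxid))
    msg <- c(msg, "contig truth taxid missing from taxonomy")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticCommunity", function(object) {
  cat(sprintf(
    "SyntheticCommunity: %d genomes, %d contigs, seed %d\n",
    length(object@genomes), length(object@contigs), object@seed))
})

#' Accessors for synthetic communities
#'
#' @param x A [SyntheticCommunity-class].
#' @return The corresponding component.
#' @export
communityGenomes <- function(x) x@genomes
#' @rdname communityGenomes
#' @export
communityContigs <- function(x) x@contigs
#' @rdname communityGenomes
#' @export
communityTaxonomy <- function(x) x@taxonomy
#' @rdname communityGenomes
#' @export
contigTruth <- function(x) x@contigTruth
#' @rdname communityGenomes
#' @export
truthProfile <- function(x) x@truthProfile
#' @rdname communityGenomes
#' @export
genomeTaxids <- function(x) setNames(x@genomeTaxids, names(x@genomes))
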