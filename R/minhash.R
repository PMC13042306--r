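#' k-mer hash set of a sequence
#'
#' Computes the distinct canonical k-mer hash set of a nucleotide
#' sequence: each k-mer is replaced by the lexicographic minimum of
#' itself and its reverse complement before hashing, so the result is
#' identical for a sequence and its reverse complement. k-mers
#' containing non-ACGT bases are skipped.
#'
#' @param sequence A character string or a `Biostrings::DNAString`.
#' @param params A [SketchParams-class]; only `k` and `seed` are used.
#' @return Sorted numeric vector of distinct hash values (possibly
#'   empty when the sequence is shorter than `k`).
#' @export
#' @examples
#' p <- SketchParams(k = 5, s = 10, seed = 42)
#' h <- kmerHashes("ACGTACGTACGT", p)
kmerHashes <- function(sequence, params) {
  stopifnot(is(params, "SketchParams"))
  kmer_hashes_cpp(as.character(sequence), params@k, as.double(params@seed))
}

#' Build a bottom-s MinHash sketch
#'
#' Retains the `s` smallest distinct canonical k-mer hashes of a
#' reference sequence. A sequence shorter than `k` yields an empty
#' sketch (`nKmers = 0`), which is a valid object but cannot be
#' screened against.
#'
#' @param sequence Character string or `Biostrings::DNAString`.
#' @param params A [SketchParams-class].
#' @param refId Reference identifier stored in the sketch.
#' @return A [KmerSketch-class].
#' @export
#' @examples
#' sk <- buildSketch(paste(rep("ACGT", 30), collapse = ""),
#'                   SketchParams(k = 5, s = 10), refId = "toy")
buildSketch <- function(sequence, params, refId = "ref") {
  stopifnot(is(params, "SketchParams"))
  res <- sketch_cpp(as.character(sequence), params@k, params@s,
                    as.double(params@seed))
  new("KmerSketch", refId = as.character(refId), params = params,
      hashes = res$hashes, nKmers = res$n_kmers)
}

#' Sketch a set of reference sequences
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet`.
#' @param params A [SketchParams-class].
#' @return Named list of [KmerSketch-class] objects.
#' @export
sketchReferences <- function(sequences, params) {
  seqs <- as_named_chr(sequences)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("ref", seq_along(seqs))
  out <- lapply(seq_along(seqs), function(i)
    buildSketch(seqs[[i]], params, refId = ids[[i]]))
  names(out) <- ids
  out
}

#' Containment of a reference sketch in a query k-mer set
#'
#' Estimates the containment index: the fraction of the reference
#' sketch's hashes found in the query's full distinct k-mer hash set.
#' The estimate carries a standard error of about `sqrt(1/s)` (see
#' [sketchError()]). A binomial-tail p-value for observing at least the
#' shared count by chance is attached.
#'
#' @param queryHashes Numeric hash set from [kmerHashes()], computed
#'   with the same `k` and `seed` as the sketch.
#' @param sketch A [KmerSketch-class]; must be non-empty.
#' @return One-row data.frame with columns `refId`, `containment`,
#'   `shared`, `sketchSizeUsed`, `pValue`.
#' @export
screenContainment <- function(queryHashes, sketch) {
  stopifnot(is(sketch, "KmerSketch"))
  if (length(sketch@hashes) == 0L)
    stop("empty reference sketch: containment is undefined")
  shared <- sum(sketch@hashes %in% queryHashes)
  m <- length(sketch@hashes)
  data.frame(
    refId = sketch@refId,
    containment = shared / m,
    shared = shared,
    sketchSizeUsed = m,
    pValue = containmentPvalue(shared, m, length(queryHashes),
                               sketch@params),
    stringsAsFactors = FALSE)
}

#' Screen a query against many reference sketches
#'
#' @param queryHashes Numeric hash set of the (pooled) query sequences.
#' @param sketches List of [KmerSketch-class] objects sharing one
#'   (`k`, `seed`); mixing seeds or k is an error, since hashes are not
#'   comparable across them.
#' @return data.frame of screen hits, one row per reference, sorted by
#'   containment descending.
#' @export
screenSketches <- function(queryHashes, sketches) {
  stopifnot(length(sketches) > 0)
  ks <- vapply(sketches, function(s) s@params@k, integer(1))
  seeds <- vapply(sketches, function(s) s@params@seed, integer(1))
  if (length(unique(ks)) != 1L || length(unique(seeds)) != 1L)
    stop("sketches mix k or hash seed; they are not comparable")
  hits <- do.call(rbind, lapply(sketches, function(s)
    screenContainment(queryHashes, s)))
  rownames(hits) <- NULL
  hits[order(-hits$containment, hits$refId), , drop = FALSE]
}

#' Binomial-tail significance of a shared-hash count
#'
#' Upper-tail probability of observing at least `shared` of the
#' `sketchSize` reference hashes in a random query of
#' `queryDistinctKmers` distinct k-mers: `P(X >= shared)` with
#' `X ~ Binomial(sketchSize, r)` and
#' `r = 1 - (1 - alphabetSize^-k)^queryDistinctKmers`, the chance that
#' one specific k-mer occurs in the query by chance.
#'
#' @param shared Observed shared-hash count (0..sketchSize).
#' @param sketchSize Number of reference hashes screened.
#' @param queryDistinctKmers Distinct k-mer count of the query.
#' @param params A [SketchParams-class] (uses `k` and `alphabetSize`).
#' @return Probability in `[0, 1]`, non-increasing in `shared`.
#' @export
#' @examples
#' containmentPvalue(0, 100, 1e6, SketchParams(k = 15))  # 1
containmentPvalue <- function(shared, sketchSize, queryDistinctKmers,
                              params) {
  stopifnot(shared >= 0, shared <= sketchSize, queryDistinctKmers >= 0)
  # r via log1p/expm1: alphabetSize^-k underflows naive arithmetic
  log_miss <- queryDistinctKmers *
    log1p(-as.numeric(params@alphabetSize)^(-as.numeric(params@k)))
  r <- -expm1(log_miss)
  if (shared == 0) return(1)
  pbinom(shared - 1, sketchSize, r, lower.tail = FALSE)
}

#' Optimal k-mer size for a genome
#'
#' `k = ceil( log_alphabet( n (1 - q) / q ) )`, where `n` is the genome
#' size and `q` the acceptable probability of observing a random k-mer.
#' Smaller genomes (e.g. viruses) give smaller k; a 3 Gb genome at
#' `q = 0.01` gives `k = 20`.
#'
#' @param n Genome size in bases (>= 1).
#' @param q Desired random-k-mer probability, in (0, 1).
#' @param alphabetSize Alphabet size (default 4).
#' @return Integer k-mer size (at least 1).
#' @export
#' @examples
#' optimalKmerSize(5e6, 0.01)  # 15
optimalKmerSize <- function(n, q, alphabetSize = 4) {
  stopifnot(n >= 1, q > 0, q < 1, alphabetSize >= 2)
  k <- ceiling(log(n * (1 - q) / q) / log(alphabetSize))
  as.integer(max(1L, k))
}

#' Sketch-size error bound
#'
#' The standard error of the containment estimate for a sketch of size
#' `s` is proportional to `sqrt(1/s)`; larger sketches give tighter
#' estimates at higher cost.
#'
#' @param s Sketch size (>= 1).
#' @return `sqrt(1/s)`.
#' @export
#' @examples
#' sketchError(1000)
sketchError <- function(s) {
  stopifnot(s >= 1)
  sqrt(1 / s)
}

#' Mash-style identity estimate from containment
#'
#' Converts a containment index to an approximate sequence identity,
#' `identity = containment^(1/k)`: under a simple independent-mutation
#' model a query diverged at rate `d` retains a fraction `(1-d)^k` of
#' its k-mers, so the k-th root recovers `1 - d`. This is the scale on
#' which screening thresholds such as 0.90/0.70 are meaningful for
#' diverged queries.
#'
#' @param containment Containment index in `[0, 1]`.
#' @param k k-mer size.
#' @return Identity estimate in `[0, 1]`.
#' @export
containmentToIdentity <- function(containment, k) {
  stopifnot(all(containment >= 0), all(containment <= 1), k >= 1)
  containment^(1 / k)
}

#' Serialize sketches to JSON
#'
#' Writes a list of sketches as a documented JSON container recording
#' params, reference ids, distinct-k-mer counts and hash values. This
#' container is this package's own format (it is not Mash-compatible).
#'
#' @param sketches Named list of [KmerSketch-class] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSketchSet <- function(sketches, path) {
  stopifnot(length(sketches) > 0)
  p <- sketches[[1]]@params
  obj <- list(
    format = "taxsift-sketch-set",
    version = 1L,
    params = list(k = p@k, s = p@s, seed = p@seed,
                  alphabetSize = p@alphabetSize),
    sketches = unname(lapply(sketches, function(s) list(
      ref_id = s@refId, n_kmers = s@nKmers, hashes = s@hashes))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSketchSet
#' @return `readSketchSet` returns the named list of sketches.
#' @export
readSketchSet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "taxsift-sketch-set"))
    stop("not a taxsift sketch-set file: ", path)
  params <- SketchParams(obj$params$k, obj$params$s, obj$params$seed,
                         obj$params$alphabetSize)
  sk <- obj$sketches
  out <- lapply(seq_along(sk$ref_id), function(i)
    new("KmerSketch", refId = sk$ref_id[[i]], params = params,
        hashes = as.numeric(sk$hashes[[i]]), nKmers = sk$n_kmers[[i]]))
  names(out) <- sk$ref_id
  out
}
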