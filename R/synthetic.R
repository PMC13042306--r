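random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

#' Point-mutate a sequence with substitutions and short indels
#'
#' Each base independently seeds a mutation event with probability
#' `rate`. An event is a substitution (to a uniformly chosen different
#' base) with probability `subFraction`, otherwise an indel: insertion
#' or deletion with equal probability, with geometric length of mean
#' `indelMeanLen`. `rate` counts events per base before indel
#' expansion. Deterministic under a fixed seed.
#'
#' @param sequence Character string or `Biostrings::DNAString`.
#' @param rate Total divergence rate in `[0, 0.5]`.
#' @param subFraction Share of events that are substitutions
#'   (default 0.9).
#' @param indelMeanLen Mean indel length in bases (default 3).
#' @param seed Integer seed.
#' @return Mutated character string.
#' @export
mutateSequence <- function(sequence, rate, subFraction = 0.9,
                           indelMeanLen = 3, seed = 1) {
  stopifnot(rate >= 0, rate <= 0.5, subFraction >= 0, subFraction <= 1)
  s <- as.character(sequence)
  if (rate == 0) return(s)
  with_seed(seed, {
    bases <- strsplit(s, "")[[1]]
    n <- length(bases)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0L) return(s)  # unwinds mutateSequence; RNG restored
    alphabet <- c("A", "C", "G", "T")
    out <- vector("list", length(hit) * 2 + 1)
    prev <- 1L
    oi <- 1L
    skip_until <- 0L
    for (p in hit) {
      if (p <= skip_until) next   # inside an earlier deletion
      out[[oi]] <- if (prev <= p - 1L) bases[prev:(p - 1L)] else character(0)
      oi <- oi + 1L
      if (runif(1) < subFraction) {
        out[[oi]] <- sample(setdiff(alphabet, bases[p]), 1)
        prev <- p + 1L
      } else {
        len <- rgeom(1, 1 / indelMeanLen) + 1L
        if (runif(1) < 0.5) {  # insertion (original base kept)
          out[[oi]] <- c(bases[p], sample(alphabet, len, replace = TRUE))
          prev <- p + 1L
        } else {               # deletion of `len` bases starting at p
          out[[oi]] <- character(0)
          prev <- min(p + len, n + 1L)
          skip_until <- prev - 1L
        }
      }
      oi <- oi + 1L
    }
    if (prev <= n) { out[[oi]] <- bases[prev:n]; oi <- oi + 1L }
    paste(unlist(out[seq_len(oi - 1L)]), collapse = "")
  })
}

#' Fragment a genome into contigs
#'
#' Either tiles the genome with non-overlapping fragments
#' (`tile = TRUE`) or samples `nFragments` random substrings of length
#' `fragmentLen`. Every contig is an exact substring of the genome and
#' is mapped to the genome's taxid in the returned truth.
#'
#' @param genome Character string or `Biostrings::DNAString`.
#' @param taxid Truth taxid of the genome.
#' @param nFragments Number of fragments (random mode).
#' @param fragmentLen Fragment length in bases (default 2500); must not
#'   exceed the genome length.
#' @param tile Tile without overlap instead of random sampling.
#' @param seed Integer seed (random mode).
#' @param prefix Contig-name prefix.
#' @return List: `contigs` (named character vector), `truth` (named
#'   integer vector contig -> taxid).
#' @export
fragmentContigs <- function(genome, taxid, nFragments = 10,
                            fragmentLen = 2500, tile = FALSE, seed = 1,
                            prefix = "contig") {
  g <- as.character(genome)
  n <- nchar(g)
  if (n == 0L) stop("fragmentContigs: empty genome")
  if (fragmentLen > n)
    stop("fragmentContigs: fragment length exceeds genome length")
  if (tile) {
    starts <- seq(1L, n, by = fragmentLen)
    contigs <- substring(g, starts, pmin(starts + fragmentLen - 1L, n))
  } else {
    starts <- with_seed(seed,
      sample.int(n - fragmentLen + 1L, nFragments, replace = TRUE))
    contigs <- substring(g, starts, starts + fragmentLen - 1L)
  }
  names(contigs) <- sprintf("%s_%03d", prefix, seq_along(contigs))
  list(contigs = contigs,
       truth = setNames(rep(as.integer(taxid), length(contigs)),
                        names(contigs)))
}

#' Window contigs into fixed-size reads
#'
#' Deterministically slices each contig into consecutive
#' non-overlapping windows of `window` bases; a final partial window is
#' kept iff its length is at least `minTail`. Read names are
#' `<contig>.r<i>`.
#'
#' @param contigs Named character vector or `Biostrings::DNAStringSet`.
#' @param window Window size in bases (default 250).
#' @param minTail Minimum length of the kept tail window (default 125).
#' @return Named character vector of reads.
#' @export
#' @examples
#' windowReads(c(c1 = strrep("ACGT", 150)))  # 600 bp -> two 250 bp reads
windowReads <- function(contigs, window = 250, minTail = 125) {
  stopifnot(window > 0, minTail > 0, minTail <= window)
  seqs <- as_named_chr(contigs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("contig", seq_along(seqs))
  out <- character(0)
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[[i]])
    starts <- seq(1L, n, by = window)
    ends <- pmin(starts + window - 1L, n)
    keep <- (ends - starts + 1L) >= minTail  # tail kept iff >= minTail
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts) == 0L) next
    reads <- substring(seqs[[i]], starts, ends)
    names(reads) <- sprintf("%s.r%d", ids[[i]], seq_along(reads))
    out <- c(out, reads)
  }
  out
}

#' Source contig of a windowed read
#'
#' @param readIds Read names produced by [windowReads()].
#' @return The originating contig ids.
#' @export
readSourceContig <- function(readIds) sub("\\.r[0-9]+$", "", readIds)

# taxonomy for a set of genera: each genus gets its own
# phylum/class/order/family chain under one of `nSuperkingdoms` domains
build_community_taxonomy <- function(genusSizes, nSuperkingdoms = 2) {
  rows <- list(list(1L, 1L, "no-rank", "root"))
  nid <- 1L
  nxt <- function() { nid <<- nid + 1L; nid }
  sk_ids <- integer(nSuperkingdoms)
  for (i in seq_len(nSuperkingdoms)) {
    sk_ids[i] <- nxt()
    rows[[length(rows) + 1L]] <-
      list(sk_ids[i], 1L, "superkingdom", paste0("Domain", i))
  }
  species <- data.frame(taxid = integer(), genus = integer(),
                        name = character(), stringsAsFactors = FALSE)
  genus_ids <- integer(length(genusSizes))
  for (gi in seq_along(genusSizes)) {
    parent <- sk_ids[((gi - 1L) %% nSuperkingdoms) + 1L]
    for (rk in c("phylum", "class", "order", "family", "genus")) {
      id <- nxt()
      rows[[length(rows) + 1L]] <-
        list(id, parent, rk, sprintf("%s%d", tools::toTitleCase(rk), gi))
      parent <- id
    }
    genus_ids[gi] <- parent
    for (si in seq_len(genusSizes[gi])) {
      id <- nxt()
      nm <- sprintf("Genus%d species%d", gi, si)
      rows[[length(rows) + 1L]] <- list(id, parent, "species", nm)
      species <- rbind(species, data.frame(
        taxid = id, genus = parent, name = nm, stringsAsFactors = FALSE))
    }
  }
  nodes <- data.frame(
    taxid = vapply(rows, function(r) r[[1]], integer(1)),
    parent = vapply(rows, function(r) r[[2]], integer(1)),
    rank = vapply(rows, function(r) r[[3]], character(1)),
    name = vapply(rows, function(r) r[[4]], character(1)),
    stringsAsFactors = FALSE)
  list(taxonomy = taxonomyFromFrame(nodes), species = species,
       genusIds = genus_ids)
}

#' Generate a seeded synthetic community
#'
#' Builds a rank-complete taxonomy, one random genome per species,
#' log-normal species abundances, and contigs sampled from the genomes
#' in proportion to abundance, together with the contig truth map and
#' the truth profile the contigs imply (count basis).
#'
#' Genera may hold several congeneric species; within such a genus each
#' species genome is an independently mutated copy (divergence
#' `genusDivergence` per species) of a shared genus ancestor, so
#' congeners share most of their sequence, as sister species in real
#' mock communities do. Singleton genera get independent random
#' genomes.
#'
#' @param nTaxa Number of species (default 10).
#' @param genomeLenRange Genome length range in bases
#'   (default 30000-60000).
#' @param genusSizes Integer vector of species counts per genus summing
#'   to `nTaxa`; default places 4 congeners in the first genus, 2 in
#'   the second, singletons elsewhere (degrading gracefully for small
#'   `nTaxa`).
#' @param genusDivergence Per-species divergence from the genus
#'   ancestor (default 0.03).
#' @param contigsTotal Approximate total contig count (default 150).
#' @param contigLen Contig length in bases (default 2500).
#' @param abundanceSdlog sdlog of the log-normal abundance distribution
#'   (default 1).
#' @param seed Integer seed; the whole community is a deterministic
#'   function of it.
#' @return A [SyntheticCommunity-class].
#' @export
generateCommunity <- function(nTaxa = 10,
                              genomeLenRange = c(30000, 60000),
                              genusSizes = NULL,
                              genusDivergence = 0.03,
                              contigsTotal = 150, contigLen = 2500,
                              abundanceSdlog = 1, seed = 1) {
  stopifnot(nTaxa >= 1)
  if (is.null(genusSizes)) {
    genusSizes <- integer(0)
    left <- nTaxa
    for (sz in c(4L, 2L)) if (left > sz) {
      genusSizes <- c(genusSizes, sz); left <- left - sz
    }
    genusSizes <- c(genusSizes, rep(1L, left))
  }
  stopifnot(sum(genusSizes) == nTaxa)
  shape <- build_community_taxonomy(genusSizes)
  sp <- shape$species

  genomes <- with_seed(seed, {
    out <- character(nTaxa)
    k <- 0L
    for (gi in seq_along(genusSizes)) {
      len <- sample(genomeLenRange[1]:genomeLenRange[2], 1)
      ancestor <- random_dna(len)
      for (si in seq_len(genusSizes[gi])) {
        k <- k + 1L
        out[k] <- if (genusSizes[gi] > 1L)
          mutateSequence(ancestor, genusDivergence,
                         seed = seed * 1000L + k) else ancestor
      }
    }
    out
  })
  names(genomes) <- sprintf("ref_%d", sp$taxid)

  ab <- with_seed(seed + 1L, rlnorm(nTaxa, 0, abundanceSdlog))
  ab <- ab / sum(ab)
  names(ab) <- names(genomes)

  contigs <- character(0)
  truth <- integer(0)
  for (i in seq_len(nTaxa)) {
    nfrag <- max(1L, round_half_up(ab[i] * contigsTotal))
    fl <- min(contigLen, nchar(genomes[i]))
    fr <- fragmentContigs(genomes[i], sp$taxid[i], nFragments = nfrag,
                          fragmentLen = fl, seed = seed + 100L + i,
                          prefix = sprintf("ctg_t%d", sp$taxid[i]))
    contigs <- c(contigs, fr$contigs)
    truth <- c(truth, fr$truth)
  }

  fake_cls <- data.frame(queryId = names(truth), taxid = truth,
                         stringsAsFactors = FALSE)
  prof <- profileFromClassifications(fake_cls, shape$taxonomy,
                                     basis = "count",
                                     sampleId = "synthetic")
  new("SyntheticCommunity",
      genomes = Biostrings::DNAStringSet(genomes),
      genomeTaxids = sp$taxid, taxonomy = shape$taxonomy,
      contigs = Biostrings::DNAStringSet(contigs),
      contigTruth = truth, truthProfile = prof, abundances = ab,
      seed = as.integer(seed))
}

#' Synthesize PAF alignments from contig truth
#'
#' Emits alignment records that follow a declared noise model, letting
#' the classifier be tested without an aligner. Models: `"perfect"`
#' (one full-length mismatch-free record per contig against a
#' reference of its truth taxid), `"partial"` (coverage uniform in
#' `[0.5, 1]` with ~95% identity), `"bleed"` (partial, plus an
#' off-target record against a random other reference with probability
#' `bleedProb`).
#'
#' @param contigLens Named numeric contig lengths.
#' @param truth Named vector contig -> taxid.
#' @param refTaxids Named vector refId -> taxid.
#' @param refLens Named numeric reference lengths.
#' @param noiseModel `"perfect"`, `"partial"`, or `"bleed"`.
#' @param bleedProb Off-target probability for the bleed model.
#' @param seed Integer seed.
#' @return PAF data.frame ([readPaf()] layout).
#' @export
synthPaf <- function(contigLens, truth, refTaxids, refLens,
                     noiseModel = c("perfect", "partial", "bleed"),
                     bleedProb = 0.1, seed = 1) {
  noiseModel <- match.arg(noiseModel)
  stopifnot(all(truth %in% refTaxids))
  by_taxid <- split(names(refTaxids), refTaxids)
  with_seed(seed, {
    rows <- list()
    for (q in names(truth)) {
      qlen <- contigLens[[q]]
      ref <- sort(by_taxid[[as.character(truth[[q]])]])[1]
      if (noiseModel == "perfect") {
        qs <- 0; qe <- qlen; nm <- qlen; bl <- qlen
      } else {
        cov <- runif(1, 0.5, 1)
        qs <- 0; qe <- round(cov * qlen)
        bl <- qe - qs; nm <- round(0.95 * bl)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        queryId = q, queryLen = qlen, queryStart = qs, queryEnd = qe,
        strand = "+", targetId = ref, targetLen = refLens[[ref]],
        targetStart = 0, targetEnd = qe - qs, nMatches = nm,
        blockLen = bl, mapq = 60, stringsAsFactors = FALSE)
      if (noiseModel == "bleed" && runif(1) < bleedProb) {
        other <- setdiff(names(refTaxids), ref)
        if (length(other)) {
          oref <- sample(other, 1)
          qe2 <- round(runif(1, 0.3, 0.6) * qlen)
          rows[[length(rows) + 1L]] <- data.frame(
            queryId = q, queryLen = qlen, queryStart = 0, queryEnd = qe2,
            strand = "+", targetId = oref,
            targetLen = refLens[[oref]], targetStart = 0,
            targetEnd = qe2, nMatches = round(0.9 * qe2),
            blockLen = qe2, mapq = 10, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Ablate reference sequences of selected taxa
#'
#' For each listed taxid, removes `floor(level * n_sequences)` of its
#' reference sequences, chosen reproducibly under the seed. Taxids not
#' listed are untouched; an unknown taxid is an error.
#'
#' @param references Named character vector or
#'   `Biostrings::DNAStringSet`.
#' @param refTaxids Named vector refId -> taxid.
#' @param taxidsToRemove Taxids whose references are ablated.
#' @param level Removal fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return List: `references` (same class as input, reduced),
#'   `refTaxids` (reduced).
#' @export
ablateReferences <- function(references, refTaxids, taxidsToRemove,
                             level, seed = 1) {
  stopifnot(level >= 0, level <= 1)
  unknown <- setdiff(taxidsToRemove, refTaxids)
  if (length(unknown))
    stop("ablateReferences: unknown taxid(s): ",
         paste(unknown, collapse = ", "))
  drop <- character(0)
  with_seed(seed, {
    for (t in taxidsToRemove) {
      ids <- sort(names(refTaxids)[refTaxids == t])
      k <- floor(level * length(ids))
      if (k > 0) drop <- c(drop, sample(ids, k))
    }
  })
  keep <- setdiff(names(refTaxids), drop)
  list(references = references[keep], refTaxids = refTaxids[keep])
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector or `Biostrings::DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a taxonomy as the 4-column TSV dialect
#'
#' @param taxonomy A [Taxonomy-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTaxonomyTSV <- function(taxonomy, path) {
  write.table(taxonomy@nodes, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
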