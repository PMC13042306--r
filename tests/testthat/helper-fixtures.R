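# shared fixtures, built in code

# small fixed taxonomy: two domains; GenusA holds two sister species,
# the rest are singletons
toy_taxonomy <- function() {
  taxonomyFromFrame(data.frame(
    taxid  = c(1L, 2L, 3L, 10L, 11L, 12L, 13L, 14L, 15L, 16L,
               20L, 21L, 22L, 23L, 24L, 25L),
    parent = c(1L, 1L, 1L, 2L, 10L, 11L, 12L, 13L, 14L, 14L,
               3L, 20L, 21L, 22L, 23L, 24L),
    rank   = c("no-rank", "superkingdom", "superkingdom",
               "phylum", "class", "order", "family", "genus",
               "species", "species",
               "phylum", "class", "order", "family", "genus",
               "species"),
    name   = c("root", "DomA", "DomB",
               "PhyA", "ClaA", "OrdA", "FamA", "GenusA",
               "A. one", "A. two",
               "PhyB", "ClaB", "OrdB", "FamB", "GenusB",
               "B. one"),
    stringsAsFactors = FALSE))
}

random_seq <- function(n, seed) {
  taxsift:::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
          collapse = ""))
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# independent scalar-path oracle for the full canonical k-mer hash set
oracle_kmer_hashes <- function(seq, k, seed) {
  n <- nchar(seq)
  if (n < k) return(numeric(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  keep <- !grepl("[^ACGT]", kmers)
  kmers <- kmers[keep]
  canon <- vapply(kmers, function(km) min(km, revcomp(km)), "")
  sort(unique(vapply(canon, taxsift:::hash_kmer_cpp, 0, seed = seed)))
}

# minimal PAF row constructor
paf_row <- function(q, qlen, qs, qe, t, tlen = 10000, nm = NULL,
                    bl = NULL, mapq = 60) {
  if (is.null(bl)) bl <- qe - qs
  if (is.null(nm)) nm <- bl
  data.frame(queryId = q, queryLen = qlen, queryStart = qs,
             queryEnd = qe, strand = "+", targetId = t,
             targetLen = tlen, targetStart = 0, targetEnd = qe - qs,
             nMatches = nm, blockLen = bl, mapq = mapq,
             stringsAsFactors = FALSE)
}

# independent re-derivation of the weighted consensus classifier, used
# as the brute-force oracle: plain loops, no shared code path with
# classifyQuery beyond lineageOf/projectToRank
oracle_classify <- function(coverages, abundances, refTaxids, taxonomy,
                            minSupport = 0.5) {
  if (any(coverages$exact)) {
    ex <- coverages[coverages$exact, , drop = FALSE]
    ex <- ex[order(-ex$coverage, ex$refId), , drop = FALSE]
    lin <- lineageOf(taxonomy, refTaxids[[ex$refId[1]]])
    return(list(taxid = refTaxids[[ex$refId[1]]],
                level = lin$rank[nrow(lin)], confidence = 1))
  }
  w <- numeric(nrow(coverages))
  for (i in seq_len(nrow(coverages)))
    w[i] <- coverages$coverage[i] * abundances[[coverages$refId[i]]]
  lins <- lapply(coverages$refId,
                 function(r) lineageOf(taxonomy, refTaxids[[r]]))
  keep <- rep(TRUE, length(w))
  conf <- 1
  last <- NULL
  for (rank in taxRanks()) {
    ids <- vapply(lins, function(L) {
      i <- which(L$rank == rank)
      if (length(i)) L$taxid[i] else NA_integer_
    }, integer(1))
    total <- sum(w[!is.na(ids) & w > 0])
    cand <- which(!is.na(ids) & keep & w > 0)
    if (length(cand) == 0L || total <= 0) break
    agg <- sort(tapply(w[cand], ids[cand], sum), decreasing = TRUE)
    best_w <- max(agg)
    best <- min(as.integer(names(agg)[agg == best_w]))
    frac <- best_w / total
    if (frac < minSupport) break
    conf <- conf * frac
    last <- list(taxid = best, level = rank)
    keep <- keep & !is.na(ids) & ids == best
  }
  if (is.null(last))
    return(list(taxid = NA_integer_, level = "unclassified",
                confidence = 0))
  list(taxid = last$taxid, level = last$level, confidence = conf)
}

# one shared 10-taxon community + clean pipeline run, computed once
shared_env <- new.env()
shared_community <- function() {
  if (is.null(shared_env$com))
    shared_env$com <- generateCommunity(seed = 3)
  shared_env$com
}
shared_clean_run <- function() {
  if (is.null(shared_env$run)) {
    com <- shared_community()
    shared_env$run <- runPipeline(
      communityContigs(com), communityGenomes(com),
      genomeTaxids(com), communityTaxonomy(com))
  }
  shared_env$run
}
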