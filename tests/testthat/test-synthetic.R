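test_that("community generation is byte-identical under a fixed seed", {
  a <- generateCommunity(nTaxa = 4, contigsTotal = 30, seed = 17)
  b <- generateCommunity(nTaxa = 4, contigsTotal = 30, seed = 17)
  expect_identical(as.character(communityGenomes(a)),
                   as.character(communityGenomes(b)))
  expect_identical(as.character(communityContigs(a)),
                   as.character(communityContigs(b)))
  expect_identical(contigTruth(a), contigTruth(b))
  c2 <- generateCommunity(nTaxa = 4, contigsTotal = 30, seed = 18)
  expect_false(identical(as.character(communityGenomes(a)),
                         as.character(communityGenomes(c2))))
})

test_that("a one-taxon community has unit truth abundance at every rank", {
  com <- generateCommunity(nTaxa = 1, contigsTotal = 10, seed = 5)
  prof <- truthProfile(com)
  for (r in setdiff(taxRanks(), "strain"))
    expect_equal(sum(rankAbundance(prof, r)), 1)
})

test_that("truth profiles of a 10-taxon community sum to one per rank", {
  com <- shared_community()
  prof <- truthProfile(com)
  for (r in setdiff(taxRanks(), "strain"))
    expect_equal(sum(rankAbundance(prof, r)), 1, tolerance = 1e-12)
  # every genome taxid is a species in the taxonomy
  nd <- taxNodes(communityTaxonomy(com))
  expect_true(all(nd$rank[match(genomeTaxids(com), nd$taxid)] == "species"))
})

test_that("congeneric genomes share sequence; unrelated genomes do not", {
  com <- shared_community()
  g <- taxsift:::as_named_chr(communityGenomes(com))
  p <- SketchParams(k = 15, s = 500, seed = 42)
  tax <- communityTaxonomy(com)
  gid <- vapply(genomeTaxids(com), function(t)
    projectToRank(lineageOf(tax, t), "genus"), integer(1))
  sisters <- names(gid)[gid == gid[1]]
  expect_gte(length(sisters), 2)
  c_sis <- screenContainment(kmerHashes(g[[sisters[1]]], p),
                             buildSketch(g[[sisters[2]]], p))$containment
  other <- names(gid)[gid != gid[1]][1]
  c_oth <- screenContainment(kmerHashes(g[[sisters[1]]], p),
                             buildSketch(g[[other]], p))$containment
  expect_gt(c_sis, 0.3)   # ~3% divergence each from the ancestor
  expect_lt(c_oth, 0.01)  # unrelated random genomes
})

test_that("fragmentation produces exact substrings with truth labels", {
  g <- random_seq(5000, seed = 61)
  fr <- fragmentContigs(g, taxid = 15L, nFragments = 8,
                        fragmentLen = 500, seed = 3)
  expect_length(fr$contigs, 8)
  expect_true(all(nchar(fr$contigs) == 500))
  expect_true(all(vapply(fr$contigs, grepl, TRUE, x = g, fixed = TRUE)))
  expect_equal(unname(fr$truth), rep(15L, 8))
  # deterministic under the seed
  fr2 <- fragmentContigs(g, 15L, nFragments = 8, fragmentLen = 500,
                         seed = 3)
  expect_identical(fr$contigs, fr2$contigs)
  # whole-genome fragment
  whole <- fragmentContigs(g, 15L, tile = TRUE, fragmentLen = 5000)
  expect_identical(unname(whole$contigs), g)
  expect_error(fragmentContigs(g, 15L, fragmentLen = 6000), "exceeds")
})

test_that("tiled fragments reassemble the genome without overlap", {
  g <- random_seq(3210, seed = 62)
  fr <- fragmentContigs(g, 15L, tile = TRUE, fragmentLen = 1000)
  expect_identical(paste(fr$contigs, collapse = ""), g)
  expect_equal(unname(nchar(fr$contigs)), c(1000, 1000, 1000, 210))
})

test_that("read windowing keeps tails only at or above the minimum", {
  r1 <- windowReads(c(c1 = random_seq(250, 63)))
  expect_equal(unname(nchar(r1)), 250)
  r2 <- windowReads(c(c1 = random_seq(600, 64)))
  expect_equal(unname(nchar(r2)), c(250, 250))  # 100 bp tail dropped
  r3 <- windowReads(c(c1 = random_seq(375, 65)))
  expect_equal(unname(nchar(r3)), c(250, 125))  # 125 bp tail kept
  expect_equal(readSourceContig(names(r3)), c("c1", "c1"))
  # reads are substrings in order
  expect_equal(paste(r3, collapse = ""), random_seq(375, 65))
})

test_that("mutation respects the rate, mix, and seed", {
  g <- random_seq(20000, seed = 66)
  expect_identical(mutateSequence(g, 0), g)
  expect_identical(mutateSequence(g, 0.1, seed = 9),
                   mutateSequence(g, 0.1, seed = 9))
  expect_false(identical(mutateSequence(g, 0.1, seed = 9),
                         mutateSequence(g, 0.1, seed = 10)))
  # substitutions only: same length, mismatch count within 4 sigma
  m <- mutateSequence(g, 0.1, subFraction = 1, seed = 11)
  expect_equal(nchar(m), nchar(g))
  diffs <- sum(strsplit(g, "")[[1]] != strsplit(m, "")[[1]])
  expected <- 20000 * 0.1
  sigma <- sqrt(20000 * 0.1 * 0.9)
  expect_lt(abs(diffs - expected), 4 * sigma)
  # with indels the length changes but stays in the same ballpark
  mi <- mutateSequence(g, 0.1, subFraction = 0.5, seed = 12)
  expect_false(nchar(mi) == nchar(g))
  expect_lt(abs(nchar(mi) - nchar(g)), 0.1 * nchar(g))
})

test_that("synthetic PAF obeys its declared noise model", {
  com <- generateCommunity(nTaxa = 4, contigsTotal = 40, seed = 19)
  contigs <- taxsift:::as_named_chr(communityContigs(com))
  lens <- setNames(nchar(contigs), names(contigs))
  rt <- genomeTaxids(com)
  rlens <- setNames(nchar(taxsift:::as_named_chr(communityGenomes(com))),
                    names(rt))
  perfect <- synthPaf(lens, contigTruth(com), rt, rlens, "perfect")
  expect_true(all(isExactMatch(perfect)))
  expect_equal(nrow(perfect), length(contigs))
  # bleed: off-target fraction within 4 sigma of the declared rate
  bled <- synthPaf(lens, contigTruth(com), rt, rlens, "bleed",
                   bleedProb = 0.3, seed = 2)
  n <- length(contigs)
  off <- nrow(bled) - n
  expect_lt(abs(off - 0.3 * n), 4 * sqrt(n * 0.3 * 0.7))
  expect_identical(bled, synthPaf(lens, contigTruth(com), rt, rlens,
                                  "bleed", bleedProb = 0.3, seed = 2))
})

test_that("ablation removes the requested share reproducibly", {
  refs <- setNames(vapply(1:4, function(i) random_seq(400, 70 + i), ""),
                   paste0("r", 1:4))
  rt <- setNames(c(15L, 15L, 15L, 15L), names(refs))
  none <- ablateReferences(refs, rt, 15L, level = 0)
  expect_identical(none$refTaxids, rt)
  all_gone <- ablateReferences(refs, rt, 15L, level = 1)
  expect_length(all_gone$refTaxids, 0)
  half <- ablateReferences(refs, rt, 15L, level = 0.5, seed = 4)
  expect_length(half$refTaxids, 2)
  expect_identical(half$refTaxids,
                   ablateReferences(refs, rt, 15L, 0.5, seed = 4)$refTaxids)
  expect_error(ablateReferences(refs, rt, 999L, 0.5), "unknown taxid")
})
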