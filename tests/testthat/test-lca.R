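cov_row <- function(ref, coverage, exact = FALSE, q = "q1") {
  data.frame(queryId = q, refId = ref, coverage = coverage,
             nAlignments = 1L, exact = exact, stringsAsFactors = FALSE)
}

test_that("reference abundance is the record frequency in the dataset", {
  paf <- rbind(paf_row("q1", 100, 0, 50, "tA"),
               paf_row("q2", 100, 0, 50, "tA"),
               paf_row("q3", 100, 0, 50, "tA"),
               paf_row("q4", 100, 0, 50, "tB"))
  ab <- referenceAbundance(paf)
  expect_equal(unname(ab[c("tA", "tB")]), c(0.75, 0.25))
  expect_equal(sum(ab), 1)
  expect_error(referenceAbundance(readPaf(character(0))), "empty")
  # query basis counts distinct (query, ref) pairs
  ab2 <- referenceAbundance(rbind(paf, paf), basis = "queries")
  expect_equal(unname(ab2["tA"]), 0.75)
})

test_that("an exact hit assigns the reference lineage at confidence 1", {
  tax <- toy_taxonomy()
  rt <- c(rA = 15L, rB = 16L)
  cov <- rbind(cov_row("rA", 1, exact = TRUE),
               cov_row("rB", 0.99))
  cls <- classifyQuery(cov, c(rA = 0.5, rB = 0.5), rt, tax)
  expect_equal(cls$taxid, 15L)
  expect_equal(cls$confidence, 1)
  expect_equal(cls$taxonomicLevel, "species")
  expect_match(cls$lineage, "s__A. one$")
  # ties among exact hits: higher coverage wins, then refId
  cov2 <- rbind(cov_row("rB", 1, exact = TRUE),
                cov_row("rA", 1, exact = TRUE))
  expect_equal(classifyQuery(cov2, c(rA = .5, rB = .5), rt, tax)$taxid, 15L)
})

test_that("unanimous alignments give the full lineage at confidence 1", {
  tax <- toy_taxonomy()
  cov <- rbind(cov_row("r1", 0.8), cov_row("r2", 0.6))
  cls <- classifyQuery(cov, c(r1 = 0.5, r2 = 0.5),
                       c(r1 = 15L, r2 = 15L), tax)
  expect_equal(cls$taxid, 15L)
  expect_equal(cls$confidence, 1)
})

test_that("equal-weight sister species sit exactly at the 0.5 support boundary", {
  tax <- toy_taxonomy()
  rt <- c(rA = 15L, rB = 16L)
  ab <- c(rA = 0.5, rB = 0.5)
  cov <- rbind(cov_row("rA", 0.8), cov_row("rB", 0.8))
  # fraction 0.5 >= minSupport 0.5: descends to species (smaller taxid)
  at_half <- classifyQuery(cov, ab, rt, tax, minSupport = 0.5)
  expect_equal(at_half$taxonomicLevel, "species")
  expect_equal(at_half$taxid, 15L)
  expect_equal(at_half$confidence, 0.5)
  # minSupport 0.6: stops at the genus, all fractions above it are 1
  at_06 <- classifyQuery(cov, ab, rt, tax, minSupport = 0.6)
  expect_equal(at_06$taxonomicLevel, "genus")
  expect_equal(at_06$taxid, 14L)
  expect_equal(at_06$confidence, 1)
})

test_that("weights multiply coverage by abundance and set the consensus fraction", {
  tax <- toy_taxonomy()
  rt <- c(rA = 15L, rB = 16L)
  # weight A = 0.9 x 0.8 = 0.72, weight B = 0.08: species fraction 0.9
  cov <- rbind(cov_row("rA", 0.9), cov_row("rB", 0.4))
  cls <- classifyQuery(cov, c(rA = 0.8, rB = 0.2), rt, tax)
  expect_equal(cls$taxonomicLevel, "species")
  expect_equal(cls$taxid, 15L)
  expect_equal(cls$confidence, 0.9, tolerance = 1e-12)
})

test_that("classification matches brute-force enumeration on random toy cases", {
  tax <- toy_taxonomy()
  ref_pool <- c(r1 = 15L, r2 = 16L, r3 = 25L, r4 = 15L, r5 = 16L,
                r6 = 25L)
  for (i in 1:25) {
    taxsift:::with_seed(2000 + i, {
      n <- sample(1:6, 1)
      refs <- sample(names(ref_pool), n)
      cov <- do.call(rbind, lapply(refs, function(r)
        cov_row(r, runif(1, 0.1, 1))))
      ab <- setNames(runif(n), refs)
      ab <- ab / sum(ab)
      ms <- sample(c(0.4, 0.5, 0.6), 1)
      got <- classifyQuery(cov, ab, ref_pool, tax, minSupport = ms)
      want <- oracle_classify(cov, ab, ref_pool, tax, minSupport = ms)
      expect_equal(got$taxid, want$taxid)
      expect_equal(got$taxonomicLevel, want$level)
      expect_equal(got$confidence, want$confidence, tolerance = 1e-12)
    })
  }
})

test_that("record order never changes a classification", {
  tax <- toy_taxonomy()
  paf <- rbind(paf_row("q1", 200, 0, 180, "r1"),
               paf_row("q1", 200, 0, 150, "r2", nm = 140),
               paf_row("q2", 300, 0, 300, "r3"),
               paf_row("q2", 300, 10, 200, "r1", nm = 180))
  rt <- c(r1 = 15L, r2 = 16L, r3 = 25L)
  a <- classifyAll(paf, rt, tax)
  b <- classifyAll(paf[sample(nrow(paf)), ], rt, tax)
  expect_identical(a, b)
})

test_that("queries without alignments are reported unclassified", {
  tax <- toy_taxonomy()
  paf <- paf_row("q1", 200, 0, 200, "r1")
  cls <- classifyAll(paf, c(r1 = 15L), tax, allQueries = c("q1", "q2"))
  expect_equal(cls$taxonomicLevel, c("species", "unclassified"))
  expect_true(is.na(cls$taxid[2]))
  expect_equal(cls$confidence[2], 0)
})

test_that("confidence shrinks exactly with sub-unanimous ranks", {
  tax <- toy_taxonomy()
  rt <- c(rA = 15L, rB = 16L, rC = 25L)
  # rC (other domain) takes 20% of weight; GenusA species split 60/20
  cov <- rbind(cov_row("rA", 0.6), cov_row("rB", 0.2), cov_row("rC", 0.2))
  ab <- c(rA = 1, rB = 1, rC = 1); ab <- ab / 3
  cls <- classifyQuery(cov, ab, rt, tax, minSupport = 0.5)
  # superkingdom..genus fractions = 0.8; species fraction = 0.6 (the
  # off-genus reference still counts in the rank's total weight)
  expect_equal(cls$confidence, 0.8^6 * 0.6, tolerance = 1e-12)
  expect_equal(cls$taxid, 15L)
})

test_that("the classification TSV has the declared five columns and round-trips", {
  tax <- toy_taxonomy()
  cls <- classifyAll(paf_row("q1", 200, 0, 200, "r1"), c(r1 = 15L), tax)
  f <- tempfile(fileext = ".tsv")
  writeClassifications(cls, f)
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(hdr, c("Query", "Lineage", "Taxonomic Level",
                          "TaxID", "Confidence"))
  back <- readClassifications(f)
  expect_equal(back$taxid, cls$taxid)
  expect_equal(back$confidence, round(cls$confidence, 4))
  # empty input: header-only file
  writeClassifications(cls[0, ], f)
  expect_equal(length(readLines(f)), 1L)
  unlink(f)
})
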