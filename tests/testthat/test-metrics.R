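cls_frame <- function(queryIds, taxids) {
  data.frame(queryId = queryIds, taxid = as.integer(taxids),
             taxonomicLevel = "species", lineage = "",
             confidence = 1, stringsAsFactors = FALSE)
}

test_that("profiles distribute query mass over lineage ranks", {
  tax <- toy_taxonomy()
  p1 <- profileFromClassifications(cls_frame(paste0("q", 1:4),
                                             rep(15L, 4)), tax)
  expect_equal(unname(rankAbundance(p1, "species")["15"]), 1)
  p2 <- profileFromClassifications(cls_frame(paste0("q", 1:4),
                                             c(15L, 15L, 15L, 25L)), tax)
  expect_equal(unname(rankAbundance(p2, "species")[c("15", "25")]),
               c(0.75, 0.25))
  # a genus-level classification leaves species-rank mass unassigned
  mixed <- cls_frame(paste0("q", 1:4), c(15L, 15L, 15L, 14L))
  p3 <- profileFromClassifications(mixed, tax)
  expect_lt(sum(rankAbundance(p3, "species")), 1)
  expect_equal(sum(rankAbundance(p3, "genus")), 1)
})

test_that("length-weighted profiles use base counts as mass", {
  tax <- toy_taxonomy()
  cls <- cls_frame(c("a", "b"), c(15L, 25L))
  p <- profileFromClassifications(cls, tax, basis = "length",
                                  lengths = c(a = 300, b = 100))
  expect_equal(unname(rankAbundance(p, "species")[c("15", "25")]),
               c(0.75, 0.25))
})

test_that("presence metrics follow set overlap at the 0.1% threshold", {
  # 14 truth genera; prediction holds 11 of them plus 3 extras
  truth <- profileFromTable(1:14, rep(1 / 14, 14), "genus")
  pred <- profileFromTable(c(1:11, 101:103), rep(1 / 14, 14), "genus")
  pm <- presenceMetrics(pred, truth, "genus")
  expect_equal(pm$recall, 100 * 11 / 14, tolerance = 1e-9)
  expect_equal(round(pm$recall, 1), 78.6)
  expect_equal(pm$precision, 100 * 11 / 14, tolerance = 1e-9)
  ident <- presenceMetrics(truth, truth, "genus")
  expect_equal(c(ident$precision, ident$recall, ident$f1),
               c(100, 100, 100))
  # all predicted mass below threshold: precision 0 with a flag
  tiny <- profileFromTable(21:24, rep(5e-4, 4), "genus")
  pm2 <- presenceMetrics(tiny, truth, "genus")
  expect_equal(pm2$precision, 0)
  expect_equal(pm2$recall, 0)
  expect_true(pm2$emptyPrediction)
  expect_error(presenceMetrics(pred, tiny, "genus"), "undefined")
})

test_that("F1 is bounded by the larger of precision and recall", {
  taxsift:::with_seed(7, {
    for (i in 1:20) {
      x <- runif(8); y <- runif(8)
      truth <- profileFromTable(1:8, x / sum(x), "genus")
      pred <- profileFromTable(sample(1:12, 8), y / sum(y), "genus")
      pm <- presenceMetrics(pred, truth, "genus")
      expect_lte(pm$f1, max(pm$precision, pm$recall) + 1e-9)
      if (pm$f1 == 100)
        expect_true(pm$precision == 100 && pm$recall == 100)
    }
  })
})

test_that("L1 and Bray-Curtis hit their analytic endpoints", {
  a <- profileFromTable(1:3, c(0.5, 0.3, 0.2), "genus")
  b <- profileFromTable(4:6, c(0.5, 0.3, 0.2), "genus")
  expect_equal(l1Distance(a, a, "genus"), 0)
  expect_equal(l1Distance(a, b, "genus"), 2)     # disjoint, normalized
  expect_equal(brayCurtis(a, a, "genus"), 0)
  expect_equal(brayCurtis(a, b, "genus"), 1)
  expect_equal(l1Distance(a, b, "genus", scale = "pp"), 200)
})

test_that("Bray-Curtis is symmetric and equals L1/2 for normalized profiles", {
  taxsift:::with_seed(8, {
    for (i in 1:10) {
      x <- runif(5); y <- runif(5)
      a <- profileFromTable(1:5, x / sum(x), "genus")
      b <- profileFromTable(3:7, y / sum(y), "genus")
      expect_equal(brayCurtis(a, b, "genus"), brayCurtis(b, a, "genus"))
      expect_equal(brayCurtis(a, b, "genus"),
                   l1Distance(a, b, "genus") / 2, tolerance = 1e-12)
      expect_gte(brayCurtis(a, b, "genus"), 0)
      expect_lte(brayCurtis(a, b, "genus"), 1)
    }
  })
})

test_that("Bray-Curtis agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  taxsift:::with_seed(9, {
    x <- runif(6); y <- runif(6)
    a <- profileFromTable(1:6, x / sum(x), "genus")
    b <- profileFromTable(4:9, y / sum(y), "genus")
    taxa <- as.character(1:9)
    va <- setNames(rep(0, 9), taxa); vb <- va
    va[names(rankAbundance(a, "genus"))] <- rankAbundance(a, "genus")
    vb[names(rankAbundance(b, "genus"))] <- rankAbundance(b, "genus")
    expect_equal(brayCurtis(a, b, "genus"),
                 as.numeric(vegan::vegdist(rbind(va, vb), "bray")),
                 tolerance = 1e-12)
  })
})

test_that("Pearson abundance correlation matches the closed form", {
  a <- profileFromTable(1:4, c(0.4, 0.3, 0.2, 0.1), "genus")
  expect_equal(pearsonAbundance(a, a, "genus"), 1)
  half <- profileFromTable(1:4, c(0.2, 0.15, 0.1, 0.05), "genus")
  expect_equal(pearsonAbundance(half, a, "genus"), 1)  # scale invariant
  b <- profileFromTable(1:4, c(0.1, 0.2, 0.4, 0.3), "genus")
  va <- c(0.4, 0.3, 0.2, 0.1); vb <- c(0.1, 0.2, 0.4, 0.3)
  closed <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(pearsonAbundance(a, b, "genus"), closed, tolerance = 1e-12)
  flat <- profileFromTable(1:4, rep(0.25, 4), "genus")
  expect_error(pearsonAbundance(flat, a, "genus"), "zero variance")
})

test_that("contig accuracy coarsens monotonically with rank", {
  tax <- toy_taxonomy()
  truth <- setNames(rep(15L, 4), paste0("q", 1:4))
  right <- cls_frame(paste0("q", 1:4), rep(15L, 4))
  for (r in c("superkingdom", "genus", "species"))
    expect_equal(contigAccuracy(right, truth, tax, r), 100)
  # sister-species confusion: wrong at species, right at genus
  sis <- cls_frame(paste0("q", 1:4), rep(16L, 4))
  expect_equal(contigAccuracy(sis, truth, tax, "species"), 0)
  expect_equal(contigAccuracy(sis, truth, tax, "genus"), 100)
  # half unclassified bounds accuracy at 50%
  half <- cls_frame(paste0("q", 1:4), c(15L, 15L, NA, NA))
  expect_lte(contigAccuracy(half, truth, tax, "species"), 50)
})

test_that("rank-group shares reproduce count percentages", {
  lv <- c(rep("species", 54), rep(c("genus", "family", "order"), 6))
  cls <- data.frame(queryId = seq_along(lv), taxonomicLevel = lv,
                    taxid = 1L, confidence = 1, lineage = "")
  sh <- rankShareSummary(cls)
  expect_equal(unname(sh["species_strain"]), 100 * 54 / 72)
  expect_equal(unname(sh["n_classified"]), 72)
  expect_equal(round(percentOf(54, 72), 2), 75.00)
  expect_equal(round(percentOf(27, 61), 2), 44.26)
  expect_error(percentOf(1, 0), "zero")
})

test_that("diff tables report signed percentage-point differences", {
  truth <- profileFromTable(c(101, 102), c(34.39, 65.61), "genus",
                            percent = TRUE)
  pred <- profileFromTable(c(101, 102), c(32.96, 67.04), "genus",
                           percent = TRUE)
  dt <- diffTable(pred, truth, "genus")
  expect_equal(dt$diffPp[dt$taxid == "101"], -1.43, tolerance = 1e-9)
  self <- diffTable(truth, truth, "genus")
  expect_true(all(self$diffPp == 0))
  extra <- profileFromTable(c(101, 999), c(0.5, 0.5), "genus")
  dt2 <- diffTable(extra, truth, "genus")
  expect_equal(dt2$truthPct[dt2$taxid == "999"], 0)
  expect_equal(dt2$diffPp[dt2$taxid == "999"], 50)
  # sorted by truth abundance descending
  expect_equal(dt$taxid, c("102", "101"))
})

test_that("CAMI profiles round-trip through the text format", {
  tax <- toy_taxonomy()
  prof <- profileFromClassifications(
    cls_frame(paste0("q", 1:4), c(15L, 15L, 16L, 25L)), tax,
    sampleId = "s1")
  f <- tempfile(fileext = ".profile")
  writeCamiProfile(prof, tax, f)
  expect_match(readLines(f, n = 1), "^@SampleID:s1")
  back <- readCamiProfile(f)
  for (r in c("superkingdom", "genus", "species")) {
    a <- rankAbundance(prof, r); b <- rankAbundance(back, r)
    expect_equal(b[order(names(b))], a[order(names(a))],
                 tolerance = 1e-6)
  }
  unlink(f)
})
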