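test_that("readGenotype parses a headerless matrix with its marker key", {
  d <- withr::local_tempfile(); k <- withr::local_tempfile()
  writeLines(c("0 1 2", "1 1 0"), d)
  writeLines(c("chr1 100", "chr1 200 rs7", "chr2 50"), k)
  g <- readGenotype(d, k)
  expect_s4_class(g, "GenotypeMatrix")
  expect_equal(nSamples(g), 2L)
  expect_equal(nMarkers(g), 3L)
  expect_equal(values(g), matrix(c(0, 1, 1, 1, 2, 0), 2, 3))
  expect_equal(markerIds(g), c("snp_1", "rs7", "snp_3"))
  expect_equal(as.character(GenomicRanges::seqnames(loci(g))),
               c("chr1", "chr1", "chr2"))
  expect_equal(GenomicRanges::start(loci(g)), c(100L, 200L, 50L))
})

test_that("readGenotype reports a marker count mismatch with both counts", {
  d <- withr::local_tempfile(); k <- withr::local_tempfile()
  writeLines(c("0 1 2", "1 1 0"), d)
  writeLines(c("chr1 100", "chr1 200"), k)
  err <- expect_error(readGenotype(d, k), class = "gfmap_import_error")
  expect_match(conditionMessage(err), "marker count mismatch (3 vs 2)",
               fixed = TRUE)
})

test_that("missing-value and non-numeric tokens are rejected, never imputed", {
  k <- withr::local_tempfile()
  writeLines(c("chr1 1", "chr1 2", "chr1 3"), k)
  for (bad in c("NA", ".", "abc", "NaN", "Inf")) {
    d <- tempfile()
    writeLines(c("0 1 2", paste("1", bad, "0")), d)
    expect_error(readGenotype(d, k), class = "gfmap_import_error")
    unlink(d)
  }
})

test_that("ragged rows are a structured import error", {
  d <- withr::local_tempfile(); k <- withr::local_tempfile()
  writeLines(c("0 1 2", "1 1"), d)
  writeLines(c("chr1 1", "chr1 2", "chr1 3"), k)
  expect_error(readGenotype(d, k), class = "gfmap_import_error")
})

test_that("readTraits supports the four header modes and label files", {
  base <- matrix(c(1.5, 2.5, 3.5, 4.5), 2, 2)
  lab <- withr::local_tempfile(); writeLines(c("gA", "gB"), lab)

  f0 <- withr::local_tempfile()
  writeLines(c("1.5 3.5", "2.5 4.5"), f0)
  t0 <- readTraits(f0, lab, headerMode = "none")
  expect_equal(values(t0), base)
  expect_equal(traitIds(t0), c("gA", "gB"))

  f1 <- withr::local_tempfile()
  writeLines(c("gA gB", "1.5 3.5", "2.5 4.5"), f1)
  t1 <- readTraits(f1, headerMode = "column_headers")
  expect_equal(values(t1), base)
  expect_equal(traitIds(t1), c("gA", "gB"))

  f2 <- withr::local_tempfile()
  writeLines(c("s1 1.5 3.5", "s2 2.5 4.5"), f2)
  t2 <- readTraits(f2, lab, headerMode = "row_headers")
  expect_equal(values(t2), base)
  expect_equal(sampleIds(t2), c("s1", "s2"))

  f3 <- withr::local_tempfile()
  writeLines(c("id gA gB", "s1 1.5 3.5", "s2 2.5 4.5"), f3)
  t3 <- readTraits(f3, headerMode = "both")
  expect_equal(values(t3), base)
  expect_equal(traitIds(t3), c("gA", "gB"))
  expect_equal(sampleIds(t3), c("s1", "s2"))
})

test_that("trait label count mismatch is an import error", {
  f <- withr::local_tempfile(); lab <- withr::local_tempfile()
  writeLines(c("1 2", "3 4"), f)
  writeLines(c("a", "b", "c"), lab)
  expect_error(readTraits(f, lab), class = "gfmap_import_error")
})

test_that("delimiter 'w' and an explicit tab agree when tokens agree", {
  fw <- withr::local_tempfile(); ft <- withr::local_tempfile()
  lab <- withr::local_tempfile(); writeLines(c("a", "b", "c"), lab)
  writeLines(c("1 2 3", "4 5 6"), fw)
  writeLines(c("1\t2\t3", "4\t5\t6"), ft)
  expect_identical(values(readTraits(fw, lab, delimiter = "w")),
                   values(readTraits(ft, lab, delimiter = "\t")))
})

test_that("pairDatasets requires equal sample counts and is symmetric", {
  g <- GenotypeMatrix(matrix(0:5, 3, 2))
  t2 <- TraitMatrix(matrix(rnorm(6), 3, 2))
  pd <- pairDatasets(g, t2)
  expect_s4_class(pd, "PairedDataset")
  expect_equal(nSamples(pd), 3L)
  tBad <- TraitMatrix(matrix(rnorm(8), 4, 2))
  expect_error(pairDatasets(g, tBad), class = "gfmap_pairing_error")
})

test_that("pairDatasets aligns rows by sample label", {
  set.seed(1)
  X <- matrix(rbinom(12, 2, 0.4), 4, 3)
  Y <- matrix(rnorm(8), 4, 2)
  ids <- c("s3", "s1", "s4", "s2")
  g <- GenotypeMatrix(X, sampleIds = ids)
  t1 <- TraitMatrix(Y, sampleIds = ids)                     # same order
  perm <- c(2, 4, 1, 3)
  t2 <- TraitMatrix(Y[perm, ], sampleIds = ids[perm])        # shuffled rows
  pd1 <- pairDatasets(g, t1)
  pd2 <- pairDatasets(g, t2)
  expect_identical(values(pd1@genotype), values(pd2@genotype))
  expect_identical(values(pd1@traits), values(pd2@traits))
  expect_error(pairDatasets(g, TraitMatrix(Y, sampleIds = c("s1", "s2", "s3", "zz"))),
               class = "gfmap_pairing_error")
})

test_that("association results round-trip losslessly through TSV", {
  res <- AssociationResult(paste0("m", 1:4), paste0("t", 1:3),
                           marker = c(1L, 2L, 4L), trait = c(2L, 1L, 3L),
                           weight = c(0.123456789, -2.5, 1e-4),
                           p_value = c(0.01, 0.5, 1), methodTag = "wald")
  f <- withr::local_tempfile()
  writeAssociation(res, f)
  back <- readAssociation(f)
  expect_equal(markerIds(back), markerIds(res))
  expect_equal(traitIds(back), traitIds(res))
  expect_equal(entries(back)$weight, signif(entries(res)$weight, 6))
  expect_equal(entries(back)[c("marker", "trait")],
               entries(res)[c("marker", "trait")])
  expect_equal(methodTag(back), "wald")
  # write-read-write is byte-identical (printed precision is a fixed point)
  f2 <- withr::local_tempfile()
  writeAssociation(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("empty association result survives the round trip", {
  res <- AssociationResult(c("m1", "m2"), c("t1"), methodTag = "gflasso")
  f <- withr::local_tempfile()
  writeAssociation(res, f)
  back <- readAssociation(f)
  expect_equal(nrow(entries(back)), 0L)
  expect_equal(markerIds(back), c("m1", "m2"))
  expect_equal(methodTag(back), "gflasso")
})

test_that("AssociationResult stores only nonzero weights", {
  res <- AssociationResult(paste0("m", 1:3), paste0("t", 1:2),
                           marker = 1:3, trait = c(1L, 2L, 1L),
                           weight = c(1, 0, -2))
  expect_equal(nrow(entries(res)), 2L)
  expect_true(all(entries(res)$weight != 0))
})

test_that("trait networks round-trip including isolated traits", {
  set.seed(2)
  Y <- matrix(rnorm(40), 10, 4)
  Y[, 2] <- Y[, 1] + rnorm(10, sd = 0.01)
  net <- correlationNetwork(TraitMatrix(Y), threshold = 0.8)
  f <- withr::local_tempfile()
  writeNetwork(net, f)
  back <- readNetwork(f)
  expect_equal(traitIds(back), traitIds(net))
  expect_equal(back@threshold, net@threshold)
  expect_equal(edges(back)$from, edges(net)$from)
  expect_equal(edges(back)$to, edges(net)$to)
  expect_equal(edges(back)$weight, signif(edges(net)$weight, 6))
})

test_that("reals are written with 6 significant digits and re-read exactly", {
  x <- c(1/3, pi, 123456.789, 1.000000499e-7)
  expect_identical(as.numeric(gfmap:::fmtReal(x)), signif(x, 6))
})
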