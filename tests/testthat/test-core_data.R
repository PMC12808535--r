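test_that("Matrix Market read attaches labels and computes library sizes", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 3 3", "1 1 4", "2 2 1", "1 3 2"),
             file.path(d, "m.mtx"))
  writeLines(c("gA", "gB"), file.path(d, "genes.txt"))
  writeLines(c("c1", "c2", "c3"), file.path(d, "cells.txt"))
  x <- readCounts(file.path(d, "m.mtx"), file.path(d, "genes.txt"),
                  file.path(d, "cells.txt"))
  expect_identical(dim(x), c(2L, 3L))
  expect_identical(colData(x)$library_size, c(4L, 1L, 2L))
  expect_identical(rownames(x), c("gA", "gB"))
  expect_identical(colnames(x), c("c1", "c2", "c3"))
})

test_that("label/dimension mismatches and bad entries are fatal", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 3 2", "1 1 4", "2 2 1"), file.path(d, "m.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(d, "genes3.txt"))
  writeLines(c("c1", "c2", "c3"), file.path(d, "cells.txt"))
  expect_error(
    readCounts(file.path(d, "m.mtx"), file.path(d, "genes3.txt"),
               file.path(d, "cells.txt")),
    "3 labels vs 2")
  bad <- matrix(c(1.5, 0, 2, 1), 2, 2,
                dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_error(makeCohort(bad), "non-integer")
  bad2 <- matrix(c(-1L, 0L, 2L, 1L), 2, 2,
                 dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_error(makeCohort(bad2), "negative")
  expect_error(makeCohort(matrix(1L, 2, 2)), "rownames")
})

test_that("counts round-trip through write and read exactly", {
  withr::local_seed(7)
  cnt <- matrix(rpois(20 * 50, 2), 20, 50,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:50)))
  cnt[, 1] <- pmax(cnt[, 1], 1L)  # no zero-count cells in this fixture
  x <- makeCohort(cnt)
  d <- withr::local_tempdir()
  writeCounts(x, d)
  x2 <- readCounts(file.path(d, "matrix.mtx"), file.path(d, "genes.txt"),
                   file.path(d, "cells.txt"))
  expect_identical(dim(x2), dim(x))
  expect_identical(dimnames(x2), dimnames(x))
  expect_equal(as.matrix(counts(x2)), as.matrix(counts(x)),
               ignore_attr = TRUE)
})

test_that("dense delimited input honors the orientation flag", {
  d <- withr::local_tempdir()
  # on disk as cells x genes: header row = genes, first column = cells
  writeLines(c("\tgA\tgB", "c1\t4\t0", "c2\t0\t1", "c3\t2\t0"),
             file.path(d, "dense.tsv"))
  x <- readCounts(file.path(d, "dense.tsv"),
                  orientation = "cells_by_genes")
  expect_identical(dim(x), c(2L, 3L))
  expect_identical(rownames(x), c("gA", "gB"))
  expect_identical(colData(x)$library_size, c(4L, 1L, 2L))
  # same file taken as genes x cells transposes the interpretation
  y <- readCounts(file.path(d, "dense.tsv"))
  expect_identical(rownames(y), c("c1", "c2", "c3"))
})

test_that("cell metadata aligns, recomputes library sizes, drops extras", {
  cnt <- matrix(c(1L, 0L, 3L, 2L, 2L, 0L), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  x <- makeCohort(cnt)
  d <- withr::local_tempdir()
  writeLines(c("cell_id\tpatient_id", "c3\tP2", "c1\tP1", "c2\tP1"),
             file.path(d, "meta.tsv"))
  x2 <- attachCellMeta(x, file.path(d, "meta.tsv"))
  expect_identical(table(colData(x2)$patient_id)[["P1"]], 2L)
  expect_identical(table(colData(x2)$patient_id)[["P2"]], 1L)
  # library size is the column sum of counts, not whatever the file says
  expect_identical(colData(x2)$library_size,
                   as.integer(colSums(cnt)))
  writeLines(c("cell_id\tpatient_id", "c1\tP1", "c2\tP1", "c3\tP2",
               "cX\tP9"), file.path(d, "meta_extra.tsv"))
  expect_warning(attachCellMeta(x, file.path(d, "meta_extra.tsv")),
                 "1 metadata row")
  writeLines(c("cell_id\tpatient_id", "c1\tP1"), file.path(d, "meta_miss.tsv"))
  expect_error(attachCellMeta(x, file.path(d, "meta_miss.tsv")),
               "missing from metadata")
})

test_that("GMT parsing handles duplicates, empty lists, name clashes", {
  d <- withr::local_tempdir()
  writeLines(c("S1\tdesc\tA\tB\tC", "S2\tdesc\tD\tE"), file.path(d, "ok.gmt"))
  ss <- readGMT(file.path(d, "ok.gmt"))
  expect_identical(names(ss), c("S1", "S2"))
  expect_identical(ss[["S1"]], c("A", "B", "C"))

  writeLines("S1\tdesc\tA\tA\tB", file.path(d, "dup.gmt"))
  expect_warning(ss2 <- readGMT(file.path(d, "dup.gmt")), "duplicate gene")
  expect_identical(ss2[["S1"]], c("A", "B"))

  writeLines("S1\tdesc", file.path(d, "empty.gmt"))
  expect_error(readGMT(file.path(d, "empty.gmt")), "empty gene list")

  writeLines(c("S1\td\tA", "S1\td\tB"), file.path(d, "clash.gmt"))
  expect_error(readGMT(file.path(d, "clash.gmt")), "duplicate signature name")

  ss3 <- readGMT(system.file("extdata", "example_signatures.gmt",
                             package = "scContrastMeta"))
  expect_true(all(c("G1S", "G2M") %in% names(ss3)))
})

test_that("normalization matches the closed form and is scale invariant", {
  cnt <- matrix(c(1L, 3L, 0L, 5L), 2, 2,
                dimnames = list(c("g1", "g2"), c("c1", "c2")))
  x <- normalizeCohort(makeCohort(cnt), scaleFactor = 1e4)
  # count 1 in a library of 4 at scale 10,000 -> ln(1 + 2500)
  expect_equal(as.numeric(logcounts(x)["g1", "c1"]), log(1 + 2500),
               tolerance = 1e-12)
  expect_identical(as.numeric(logcounts(x)["g1", "c2"]), 0)

  # doubling one cell's counts doubles its library size: no change
  cnt2 <- cnt; cnt2[, 1] <- cnt2[, 1] * 2L
  x2 <- normalizeCohort(makeCohort(cnt2), scaleFactor = 1e4)
  expect_equal(as.numeric(logcounts(x2)[, "c1"]),
               as.numeric(logcounts(x)[, "c1"]), tolerance = 1e-12)
})

test_that("zero-count cells are removed at load and fatal in normalize", {
  cnt <- matrix(c(1L, 2L, 0L, 0L, 3L, 1L), 2, 3,
                dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  expect_message(x <- makeCohort(cnt), "zero total counts removed")
  expect_identical(colnames(x), c("c1", "c3"))
  xraw <- makeCohort(cnt, dropEmptyCells = FALSE)
  expect_error(normalizeCohort(xraw), "zero library size.*c2")
})

test_that("SignatureSet enforces uniqueness and non-emptiness", {
  expect_error(new("SignatureSet",
                   signatures = list(a = "G1", a = "G2")), "unique")
  expect_error(new("SignatureSet", signatures = list(a = character(0))),
               "empty")
  expect_warning(ss <- SignatureSet(list(s = c("A", "A", "B"))), "duplicate")
  expect_identical(ss[["s"]], c("A", "B"))
  expect_identical(length(ss), 1L)
})
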