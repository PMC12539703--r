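test_that("identical config and seed give a bit-identical section", {
  sc <- smallConfig(seed = 3)
  a <- generateSection(sc)
  b <- generateSection(sc)
  expect_identical(SummarizedExperiment::assay(a, "counts"),
                   SummarizedExperiment::assay(b, "counts"))
  expect_identical(S4Vectors::metadata(a)$truth_signals,
                   S4Vectors::metadata(b)$truth_signals)
  expect_identical(SummarizedExperiment::colData(a),
                   SummarizedExperiment::colData(b))
})

test_that("a zero multiplier silences a program in that region", {
  # neuron-like program: zero mean in the tumor core
  se <- generateSection(smallConfig(seed = 5))
  tc <- SummarizedExperiment::colData(se)$truth_region == "TC"
  neu <- grep("^Neu", rownames(se))
  expect_equal(sum(SummarizedExperiment::assay(se, "counts")[neu, tc]), 0)
  # and the uniform program is not silenced anywhere
  uni <- grep("^Uni", rownames(se))
  expect_gt(sum(SummarizedExperiment::assay(se, "counts")[uni, tc]), 0)
})

test_that("planted label geometry is concentric on the hex lattice", {
  sc <- smallConfig(seed = 9)
  se <- generateSection(sc)
  cd <- SummarizedExperiment::colData(se)
  coords <- cbind(cd$array_row, cd$array_col)
  truth <- as.character(cd$truth_region)
  # BFS oracle: every TP spot within tpWidth steps of a TC spot
  dTC <- hexBFS(coords, truth == "TC")
  expect_true(all(dTC[truth == "TP"] <= sc@tpWidth))
  # every BO spot within boWidth steps of the tumor mass (TC or TP)
  dMass <- hexBFS(coords, truth %in% c("TC", "TP"))
  expect_true(all(dMass[truth == "BO"] <= sc@boWidth))
  expect_true(all(dMass[truth == "BR"] > sc@boWidth))
})

test_that("mean total count per spot tracks the library size", {
  se <- generateSection(smallConfig(seed = 2))
  totals <- Matrix::colSums(SummarizedExperiment::assay(se, "counts"))
  lib <- SummarizedExperiment::colData(se)$library_size
  expect_gt(cor(totals, lib), 0.9)
  # unbiased on average: the ratio centers on 1
  expect_equal(mean(totals / lib), 1, tolerance = 0.05)
})

test_that("planted signal covariances are recovered empirically", {
  # correlation 0.6 between astro and tumor planted in TP, 0.0 in TC:
  # Monte-Carlo recovery over 20 seeds (means converge; individual seeds
  # stay within the +/-0.1 band up to the expected sampling-tail rate)
  skipMisses <- 0L
  rTPs <- rTCs <- numeric(0)
  for (seed in 1:20) {
    sc <- SectionConfig(gridRows = 60L, gridCols = 90L,
                        coreCenter = c(30L, 44L), coreRadius = 12L,
                        tpWidth = 7L, boWidth = 1L,
                        nBackgroundGenes = 10L, seed = seed)
    se <- generateSection(sc)
    sig <- S4Vectors::metadata(se)$truth_signals
    truth <- SummarizedExperiment::colData(se)$truth_region
    stopifnot(sum(truth == "TP") >= 400, sum(truth == "TC") >= 400)
    rTP <- cor(sig[truth == "TP", "astro"], sig[truth == "TP", "tumor"])
    rTC <- cor(sig[truth == "TC", "astro"], sig[truth == "TC", "tumor"])
    rTPs <- c(rTPs, rTP); rTCs <- c(rTCs, rTC)
    if (abs(rTP - 0.6) > 0.1 || abs(rTC - 0.0) > 0.1) {
      skipMisses <- skipMisses + 1L
    }
  }
  expect_equal(mean(rTPs), 0.6, tolerance = 0.05)
  expect_equal(mean(rTCs), 0.0, tolerance = 0.05)
  expect_lte(skipMisses, 3L)
})

test_that("invalid configurations are rejected", {
  expect_error(SectionConfig(gridRows = 10L, gridCols = 10L,
                             coreCenter = c(5L, 5L), coreRadius = 6L),
               "exceed")
  mk <- function(r) {
    m <- diag(2); m[1, 2] <- m[2, 1] <- r
    dimnames(m) <- list(c("a", "b"), c("a", "b")); m
  }
  badCov <- list(TC = mk(2), TP = mk(0), BO = mk(0), BR = mk(0))
  expect_error(SectionConfig(signalCovariance = badCov,
                             signalMeans = list(TC = c(a = 0, b = 0),
                                                TP = c(a = 0, b = 0),
                                                BO = c(a = 0, b = 0),
                                                BR = c(a = 0, b = 0))),
               "positive semidefinite")
  dupProgs <- list(
    geneProgram("a", c("G1", "G2"), c(TC = 1, TP = 1, BO = 1, BR = 1)),
    geneProgram("b", c("G2", "G3"), c(TC = 1, TP = 1, BO = 1, BR = 1)))
  expect_error(SectionConfig(programs = dupProgs), "unique")
  expect_error(geneProgram("z", "G1", c(TC = 0, TP = 0, BO = 0, BR = 0)),
               "at least one")
})

test_that("write / read round-trips a section through the text formats", {
  se <- generateSection(smallConfig(seed = 4))
  dir <- withr::local_tempdir()
  writeSection(se, dir)
  back <- readSection(dir)
  expect_equal(as.matrix(SummarizedExperiment::assay(back, "counts")),
               as.matrix(SummarizedExperiment::assay(se, "counts")))
  expect_identical(colnames(back), colnames(se))
  expect_identical(as.character(SummarizedExperiment::colData(back)$truth_region),
                   as.character(SummarizedExperiment::colData(se)$truth_region))
  # truth labels cover exactly the in-tissue spots
  tl <- read.delim(file.path(dir, "truth_labels.tsv"))
  expect_equal(nrow(tl),
               sum(SummarizedExperiment::colData(se)$in_tissue == 1L))
  # rewriting is byte-identical
  dir2 <- withr::local_tempdir()
  writeSection(se, dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})
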