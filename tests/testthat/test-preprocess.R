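test_that("log-normalization follows the closed form and its invariances", {
  cts <- matrix(c(10, 9990, 0, 5000, 5000, 0), nrow = 3,
                dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  se <- matrixSE(cts, "counts")
  se <- logNormalize(se, scaleFactor = 10000)
  ln <- as.matrix(SummarizedExperiment::assay(se, "lognorm"))
  # count 10 in a spot totalling 10,000 at scale 10,000 -> ln(11)
  expect_equal(ln["gA", "s1"], log(11), tolerance = 1e-12)
  # zeros stay zero for any total
  expect_equal(ln["gC", ], c(s1 = 0, s2 = 0))
  # doubling all counts of a spot leaves its normalized vector unchanged
  se2 <- matrixSE(cts * 2, "counts")
  se2 <- logNormalize(se2, scaleFactor = 10000)
  expect_equal(as.matrix(SummarizedExperiment::assay(se2, "lognorm")), ln)
})

test_that("zero-total spots are excluded instead of divided by zero", {
  cts <- matrix(c(5, 1, 0, 0), nrow = 2,
                dimnames = list(c("g1", "g2"), c("ok", "empty")))
  se <- matrixSE(cts, "counts")
  expect_warning(out <- logNormalize(se), "zero total")
  expect_equal(colnames(out), "ok")
})

test_that("gene scaling standardizes, zeroes constants, and clips", {
  set.seed(1)
  m <- rbind(var1 = rnorm(200, 5, 2), flat = rep(3, 200),
             spike = c(rnorm(199), 1000))
  se <- matrixSE(m, "lognorm")
  se <- scaleGenes(se, clip = 10)
  sc <- SummarizedExperiment::assay(se, "scaled")
  expect_equal(mean(sc["var1", ]), 0, tolerance = 1e-12)
  expect_equal(sd(sc["var1", ]), 1, tolerance = 1e-12)
  expect_equal(unname(sc["flat", ]), rep(0, 200))
  expect_equal(max(sc["spike", ]), 10)   # 1000 is far beyond 10 sd
})

test_that("cv2 baseline fit recovers Poisson behavior and planted variability", {
  set.seed(42)
  nG <- 2000; nS <- 300
  means <- runif(nG, 0.2, 8)
  cts <- matrix(rpois(nG * nS, rep(means, nS)), nrow = nG)
  rownames(cts) <- sprintf("p%04d", seq_len(nG))
  # Poisson: cv2 = 1/mean, so a1 ~ 1 and a0 ~ 0
  hv <- selectHVG(cts, minMean = 0.1, nTop = 100)
  fitmeta <- S4Vectors::metadata(hv)
  expect_equal(fitmeta$a1, 1, tolerance = 0.1)
  expect_equal(fitmeta$a0, 0, tolerance = 0.05)

  # plant 20 genes with ~5x inflated variance (NB with theta = mean/4)
  idx <- seq(1, 1000, by = 50)
  for (i in idx) {
    cts[i, ] <- rnbinom(nS, mu = means[i], size = means[i] / 4)
  }
  hv2 <- selectHVG(cts, minMean = 0.1, nTop = 100)
  expect_gte(sum(hv2$selected[idx]), 18)
})

test_that("degenerate cv2 inputs are rejected or excluded", {
  set.seed(7)
  cts <- matrix(rpois(100 * 100, 2), nrow = 100,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
  cts[1, ] <- 5L  # constant gene: cv2 = 0
  hv <- selectHVG(cts, minMean = 0.1, nTop = 99)
  expect_equal(hv$cv2[1], 0)
  expect_false(hv$selected[1])
  flat <- matrix(3L, nrow = 60, ncol = 10)
  expect_error(selectHVG(flat, minMean = 0.1, nTop = 5), "degenerate")
})

test_that("a single scaled gene can never pass the MP edge", {
  set.seed(3)
  X <- matrix(scale(rnorm(100)), ncol = 1)
  pc <- pcaMP(X, twCorrection = FALSE)
  expect_equal(pc@kRetained, 0L)
  expect_gt(pc@mpUpperEdge, 1)
})

test_that("a planted factor is retained while pure noise is not", {
  set.seed(5)
  X <- scale(matrix(rnorm(800 * 60), 800, 60))
  pc0 <- pcaMP(X)
  expect_equal(pc0@kRetained, 0L)
  f <- rnorm(800, sd = sqrt(10))
  Xs <- matrix(rnorm(800 * 60), 800, 60)
  Xs[, 1:30] <- Xs[, 1:30] + f
  pc1 <- pcaMP(scale(Xs))
  expect_equal(pc1@kRetained, 1L)
  # eigenvalues nonincreasing; reported edge is the operative threshold
  expect_false(is.unsorted(rev(pc1@eigenvalues)))
  expect_equal(pc1@kRetained, sum(pc1@eigenvalues > pc1@mpUpperEdge))
})

test_that("clustering separates well-separated blobs and is seeded", {
  set.seed(8)
  S <- rbind(cbind(rnorm(60), rnorm(60)),
             cbind(rnorm(60) + 12, rnorm(60) + 12))
  rownames(S) <- sprintf("s%03d", 1:120)
  cl <- clusterSpots(S, kNeighbors = 10, resolution = 0.25, seed = 2)
  expect_equal(length(unique(cl$cluster)), 2L)
  # perfect agreement up to label permutation
  blob <- rep(1:2, each = 60)
  tab <- table(cl$cluster, blob)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_equal(sort(rowSums(tab)), c(60, 60), ignore_attr = TRUE)
  # determinism
  cl2 <- clusterSpots(S, kNeighbors = 10, resolution = 0.25, seed = 2)
  expect_identical(cl, cl2)
  # tiny resolution on a connected graph collapses to one cluster
  set.seed(9)
  S1 <- cbind(rnorm(50), rnorm(50))
  cl3 <- clusterSpots(S1, kNeighbors = 10, resolution = 1e-4, seed = 1)
  expect_equal(length(unique(cl3$cluster)), 1L)
  expect_error(clusterSpots(S1, kNeighbors = 50), "must be <")
})
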