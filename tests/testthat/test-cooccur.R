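test_that("perfectly correlated signals are flagged with a degenerate CI", {
  set.seed(40)
  v <- rnorm(60)
  res <- bootstrapCooccurrence(cbind(a = v, b = v), B = 200, seed = 1)
  expect_equal(res@mean["a", "b"], 1)
  expect_equal(res@ciLow["a", "b"], 1)
  expect_equal(res@ciHigh["a", "b"], 1)
  expect_equal(res@significant["a", "b"], 1)
})

test_that("the significance flag equals the CI-excludes-zero predicate", {
  set.seed(41)
  X <- cbind(a = rnorm(80), b = rnorm(80), c = rnorm(80) + 0.1)
  X[, "c"] <- X[, "c"] + 0.8 * X[, "a"]
  res <- bootstrapCooccurrence(X, B = 300, seed = 2)
  off <- upper.tri(res@mean)
  expect_equal(res@significant[off],
               ifelse(res@ciLow[off] > 0 | res@ciHigh[off] < 0, 1, 0))
  # and the planted a-c association is detected
  expect_equal(res@significant["a", "c"], 1)
})

test_that("bootstrap means converge to the plug-in Pearson correlation", {
  set.seed(42)
  X <- rbinorm(500, 0.45)
  colnames(X) <- c("a", "b")
  res <- bootstrapCooccurrence(X, B = 3000, seed = 3)
  expect_lt(abs(res@mean["a", "b"] - cor(X)[1, 2]), 0.02)
})

test_that("bootstrap results are reproducible and seed-sensitive", {
  set.seed(43)
  X <- cbind(a = rnorm(50), b = rnorm(50))
  r1 <- bootstrapCooccurrence(X, B = 200, seed = 9)
  r2 <- bootstrapCooccurrence(X, B = 200, seed = 9)
  r3 <- bootstrapCooccurrence(X, B = 200, seed = 10)
  expect_identical(r1@replicates, r2@replicates)
  expect_false(identical(r1@replicates, r3@replicates))
})

test_that("constant signals yield NA pairs; excess skipping is an error", {
  set.seed(44)
  X <- cbind(a = rnorm(30), flat = rep(2, 30), b = rnorm(30))
  res <- bootstrapCooccurrence(X, B = 200, seed = 1)
  expect_true(all(is.na(res@mean["flat", ])))
  expect_false(is.na(res@mean["a", "b"]))
  # three one-hot signals: most resamples drop at least one nonzero entry
  Y <- diag(3)[rep(1:3, c(1, 1, 1)), ]
  Y <- rbind(Y, matrix(0, 9, 3))
  colnames(Y) <- c("a", "b", "c")
  expect_error(bootstrapCooccurrence(Y, B = 200, seed = 5),
               "50% valid")
})

test_that("differential co-occurrence has exact identity and antisymmetry", {
  set.seed(45)
  X <- cbind(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  rA <- bootstrapCooccurrence(X, B = 200, seed = 7, region = "TC")
  rB <- bootstrapCooccurrence(X, B = 200, seed = 7, region = "TP")
  d0 <- differentialCooccurrence(rA, rB)
  expect_equal(d0$delta, rep(0, 3))
  expect_equal(d0$ciLow, rep(0, 3))
  rC <- bootstrapCooccurrence(X[1:40, ], B = 200, seed = 8, region = "TP")
  ab <- differentialCooccurrence(rA, rC)
  ba <- differentialCooccurrence(rC, rA)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$ciLow, -ba$ciHigh)
})

test_that("a planted opposite correlation is recovered as delta ~ 1.2", {
  hits <- 0
  for (seed in 1:3) {
    set.seed(seed)
    A <- rbinorm(500, 0.6); colnames(A) <- c("x", "y")
    B <- rbinorm(500, -0.6); colnames(B) <- c("x", "y")
    rA <- bootstrapCooccurrence(A, B = 400, seed = seed, region = "A")
    rB <- bootstrapCooccurrence(B, B = 400, seed = seed + 50, region = "B")
    d <- differentialCooccurrence(rA, rB)
    hits <- hits + (abs(d$delta - 1.2) < 0.15 && d$excludesZero)
  }
  expect_equal(hits, 3)
})

test_that("per-region streams are derived from the root seed", {
  set.seed(46)
  X <- cbind(a = rnorm(200), b = rnorm(200))
  labels <- rep(c("TC", "TP"), each = 100)
  res <- cooccurrenceByRegion(X, labels, regions = c("TC", "TP"),
                              B = 150, seed = 100)
  direct <- bootstrapCooccurrence(X[1:100, ], B = 150, seed = 101,
                                  region = "TC")
  expect_identical(res$TC@replicates, direct@replicates)
})

test_that("marker signals are mean z-scores with generator consistency", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1))
  se <- matrixSE(m, "lognorm")
  sig <- markerSignalMatrix(se, list(s1 = "g1", dup = "g1",
                                     both = c("g1", "g2")))
  expect_equal(unname(sig[, "s1"]), as.numeric(scale(m["g1", ])))
  expect_identical(sig[, "s1"], sig[, "dup"])
  expect_equal(unname(sig[, "both"]), rep(0, 4))
  expect_error(markerSignalMatrix(se, list(bad = "nope")), "bad")
  # marker-score signals track the generator's latent signals
  sec <- generateSection(smallConfig(seed = 11))
  sec <- logNormalize(sec)
  ms <- markerSignalMatrix(sec, list(
    tumor = grep("^Tum", rownames(sec), value = TRUE),
    astro = grep("^Scar", rownames(sec), value = TRUE)))
  truth <- S4Vectors::metadata(sec)$truth_signals[colnames(sec), ]
  expect_gte(cor(ms[, "tumor"], truth[, "tumor"]), 0.7)
  expect_gte(cor(ms[, "astro"], truth[, "astro"]), 0.7)
})
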