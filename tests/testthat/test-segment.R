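test_that("marker scores are mean z-scores with degenerate-input policies", {
  set.seed(2)
  m <- rbind(mk1 = rnorm(50, 2), mk2 = rnorm(50, 5), flat = rep(1, 50))
  se <- matrixSE(m, "lognorm")
  # single marker: exactly that gene's z-score
  s1 <- markerScore(se, "mk1")
  expect_equal(unname(s1), as.numeric(scale(m["mk1", ])), tolerance = 1e-12)
  # constant expression scores zero everywhere
  expect_equal(unname(markerScore(se, "flat")), rep(0, 50))
  # two markers average their z-scores: opposite z's cancel
  s12 <- markerScore(se, c("mk1", "mk2"))
  z <- (scale(m["mk1", ]) + scale(m["mk2", ])) / 2
  expect_equal(unname(s12), as.numeric(z), tolerance = 1e-12)
  expect_warning(markerScore(se, c("mk1", "nope")), "nope")
  expect_error(markerScore(se, c("nope1", "nope2")), "nope1")
})

test_that("segmentation recovers planted concentric regions", {
  hits <- 0; total <- 0
  for (seed in 1:3) {
    se <- generateSection(smallConfig(seed = seed))
    se <- logNormalize(se)
    se <- scaleGenes(se)
    hvg <- selectHVG(se, nTop = 60)
    pca <- pcaMP(se, genes = rownames(hvg)[hvg$selected], kMax = 20)
    cl <- clusterSpots(pca, kNeighbors = 15, resolution = 1, seed = seed)
    score <- markerScore(se, grep("^Tum", rownames(se), value = TRUE))
    se <- segmentRegions(se, cl, score, tpRings = 2, boRings = 2)
    truth <- as.character(SummarizedExperiment::colData(se)$truth_region)
    pred <- as.character(regionLabels(se))
    hits <- hits + sum(truth == pred); total <- total + length(pred)
  }
  expect_gte(hits / total, 0.9)
})

test_that("a single-spot tumor mass is all periphery, never core", {
  # 8 x 8 lattice block, one tumor-cluster spot in the middle
  rows <- rep(0:7, each = 8); cols <- rep(0:7, times = 8)
  keep <- (rows + cols) %% 2L == 0L
  n <- sum(keep)
  m <- matrix(rnorm(2 * n), nrow = 2,
              dimnames = list(c("g1", "g2"), sprintf("BC%02d", 1:n)))
  pos <- data.frame(barcode = colnames(m), in_tissue = 1L,
                    array_row = rows[keep], array_col = cols[keep],
                    pxl_row = 0, pxl_col = 0)
  se <- SpotExperiment(Matrix::Matrix(m, sparse = TRUE), pos)
  SummarizedExperiment::assay(se, "lognorm") <- m
  mid <- which(pos$array_row == 4L & pos$array_col == 4L)
  cl <- rep(1L, n); cl[mid] <- 2L
  score <- rep(0, n); score[mid] <- 5
  se <- segmentRegions(se, cl, score, scoreThreshold = 0.5,
                       tpRings = 2, boRings = 2)
  lab <- as.character(regionLabels(se))
  expect_equal(lab[mid], "TP")
  expect_false(any(lab == "TC"))
  expect_true(all(lab[-mid] %in% c("BO", "BR")))
  # topology: every BO spot within boRings of the mass
  coords <- cbind(pos$array_row, pos$array_col)
  d <- hexBFS(coords, mid)
  expect_true(all(d[lab == "BO"] <= 2))
  expect_true(all(d[lab == "BR"] > 2))
})

test_that("no passing cluster labels everything BR with a warning", {
  se <- generateSection(smallConfig(seed = 6))
  se <- logNormalize(se)
  cl <- rep(1L, ncol(se))
  score <- rep(0, ncol(se))
  expect_warning(out <- segmentRegions(se, cl, score), "no cluster")
  expect_true(all(regionLabels(out) == "BR"))
})

test_that("labels partition the spots and BO grows with its ring width", {
  se <- generateSection(smallConfig(seed = 7))
  se <- logNormalize(se)
  truth <- SummarizedExperiment::colData(se)$truth_region
  cl <- as.integer(truth %in% c("TC", "TP")) + 1L
  score <- ifelse(truth %in% c("TC", "TP"), 1, 0)
  out2 <- segmentRegions(se, cl, score, boRings = 2)
  out4 <- segmentRegions(se, cl, score, boRings = 4)
  lab2 <- regionLabels(out2); lab4 <- regionLabels(out4)
  expect_false(anyNA(lab2))           # partition covers every spot
  expect_true(all(which(lab2 == "BO") %in% which(lab4 == "BO")))
  expect_gt(sum(lab4 == "BO"), sum(lab2 == "BO"))
})

test_that("region profiles equal brute-force summaries and rank the ring program", {
  se <- generateSection(smallConfig(seed = 8))
  se <- logNormalize(se)
  se <- setRegionLabels(
    se, stats::setNames(as.character(SummarizedExperiment::colData(se)$truth_region),
                        colnames(se)))
  prof <- regionProfile(se, c("Scar01", "Uni01"))
  ln <- as.matrix(SummarizedExperiment::assay(se, "lognorm"))
  lab <- as.character(regionLabels(se))
  for (i in seq_len(nrow(prof))) {
    v <- ln[prof$gene[i], lab == prof$region[i]]
    expect_equal(prof$n[i], length(v))
    expect_equal(prof$mean[i], mean(v))
    expect_equal(prof$median[i], median(v))
    expect_equal(prof$q25[i], unname(quantile(v, 0.25)))
  }
  # the scar (Gfap-like) program peaks in the border ring
  sc <- prof[prof$gene == "Scar01", ]
  expect_equal(sc$region[which.max(sc$mean)], "BO")
})
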