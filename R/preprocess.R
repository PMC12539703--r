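#' Log-normalize spot counts
#'
#' Per spot, counts are divided by the spot total, multiplied by
#' `scaleFactor`, and transformed by `log1p` (natural log): the Seurat
#' `NormalizeData` convention. Spots with zero total counts are dropped with
#' a warning rather than divided by zero.
#'
#' @param x A [SpotExperiment-class] (or SingleCellExperiment) with a
#'   `counts` assay.
#' @param scaleFactor Positive scale factor, default `10000`.
#' @return `x` (possibly with zero-total spots removed) with an added
#'   `lognorm` assay; the zero pattern of `counts` is preserved.
#' @export
logNormalize <- function(x, scaleFactor = 10000) {
  stopifnot(scaleFactor > 0)
  cts <- assay(x, "counts")
  totals <- Matrix::colSums(cts)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " spot(s) with zero total counts excluded")
    x <- x[, totals > 0]
    cts <- assay(x, "counts")
    totals <- Matrix::colSums(cts)
  }
  ln <- cts
  if (methods::is(ln, "sparseMatrix")) {
    ln <- methods::as(ln, "CsparseMatrix")
    # column-scale the nonzeros in place, then log1p
    ln@x <- log1p(ln@x / rep.int(totals, diff(ln@p)) * scaleFactor)
  } else {
    ln <- log1p(sweep(ln, 2L, totals, "/") * scaleFactor)
  }
  assay(x, "lognorm") <- ln
  x
}

#' Center, scale and clip genes
#'
#' Per gene (row), subtracts the mean and divides by the standard deviation
#' across spots; zero-variance genes map to 0; absolute values are clipped
#' at `clip`. The Seurat `ScaleData` convention.
#'
#' @param x Object with a `lognorm` assay.
#' @param clip Clip threshold for absolute scaled values, default 10.
#' @return `x` with an added dense `scaled` assay.
#' @export
scaleGenes <- function(x, clip = 10) {
  ln <- as.matrix(assay(x, "lognorm"))
  mu <- rowMeans(ln)
  sdv <- sqrt(rowSums((ln - mu)^2) / (ncol(ln) - 1L))
  sc <- (ln - mu) / ifelse(sdv > 0, sdv, 1)
  sc[sdv == 0, ] <- 0
  sc[sc > clip] <- clip
  sc[sc < -clip] <- -clip
  assay(x, "scaled") <- sc
  x
}

#' Select highly variable genes by cv-squared modeling
#'
#' For each gene, computes the squared coefficient of variation
#' `cv2 = var/mean^2` and fits the mean-dependent baseline
#' `cv2(m) = a1/m + a0` by ordinary least squares over genes with
#' `mean >= minMean`. Genes are ranked by the ratio of observed to fitted
#' cv2 and the top `nTop` are flagged.
#'
#' @param x Object with the assay named by `assay`, or a plain matrix
#'   (genes x spots).
#' @param minMean Minimum gene mean entering the fit and the selection.
#' @param nTop Number of genes to select.
#' @param assay Assay name when `x` is a SummarizedExperiment
#'   (default `"lognorm"`).
#' @return A [S4Vectors::DataFrame] with per-gene `mean`, `cv2`, `fit`,
#'   `ratio`, `selected`, plus the fit coefficients in `metadata()`.
#' @export
selectHVG <- function(x, minMean = 0.05, nTop = 2000, assay = "lognorm") {
  m <- if (methods::is(x, "SummarizedExperiment")) {
    as.matrix(SummarizedExperiment::assay(x, assay))
  } else as.matrix(x)
  gm <- rowMeans(m)
  gv <- rowSums((m - gm)^2) / (ncol(m) - 1L)
  cv2 <- ifelse(gm > 0, gv / gm^2, 0)
  use <- gm >= minMean
  if (sum(use) < 50L) stop("need >= 50 genes with mean >= minMean, have ",
                           sum(use))
  if (stats::sd(gm[use]) == 0) stop("degenerate cv2 fit: all gene means equal")
  fit <- stats::lm.fit(cbind(a1 = 1 / gm[use], a0 = 1), cv2[use])
  a1 <- fit$coefficients[["a1"]]; a0 <- fit$coefficients[["a0"]]
  fitted <- a1 / gm + a0
  ratio <- ifelse(use & fitted > 0, cv2 / fitted, NA_real_)
  ord <- order(ratio, decreasing = TRUE, na.last = TRUE)
  selected <- logical(length(gm))
  selected[ord[seq_len(min(nTop, sum(!is.na(ratio))))]] <- TRUE
  selected[is.na(ratio)] <- FALSE
  out <- DataFrame(mean = unname(gm), cv2 = unname(cv2),
                   fit = unname(fitted), ratio = unname(ratio),
                   selected = selected, row.names = rownames(m))
  metadata(out) <- list(a1 = a1, a0 = a0, minMean = minMean, nTop = nTop)
  out
}

# TW1 95% point, Johnstone finite-sample scaling for the largest eigenvalue.
.TW1_Q95 <- 0.9793

#' PCA with Marchenko-Pastur component selection
#'
#' Computes the eigenvalues of the sample covariance of the scaled data by
#' economy SVD (genes standardized, so the noise variance is 1) and retains
#' components whose eigenvalue lies strictly above the upper
#' Marchenko-Pastur edge `(1 + sqrt(p/n))^2` with `gamma = p/n`
#' (`p` genes, `n` spots). By default a finite-sample Tracy-Widom allowance
#' (Johnstone scaling, 95% point) is added to the asymptotic edge, since at
#' realistic sizes the largest pure-noise eigenvalue exceeds the asymptotic
#' edge in a non-negligible fraction of datasets; set
#' `twCorrection = FALSE` for the plain asymptotic edge.
#'
#' @param x Object with a `scaled` assay, or a spots x genes matrix of
#'   standardized values.
#' @param genes Optional gene subset (e.g. the HVGs) when `x` is a
#'   SummarizedExperiment.
#' @param kMax Maximum number of component scores returned.
#' @param twCorrection Add the Tracy-Widom finite-sample allowance
#'   (default `TRUE`).
#' @return A [SpotPCA-class]. `kRetained = 0` is a legal result.
#' @export
pcaMP <- function(x, genes = NULL, kMax = 50, twCorrection = TRUE) {
  X <- if (methods::is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, "scaled")
    if (!is.null(genes)) m <- m[genes, , drop = FALSE]
    t(as.matrix(m))
  } else as.matrix(x)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L || p < 1L) stop("need >= 2 spots and >= 1 gene")
  sv <- svd(X, nu = min(kMax, n, p), nv = min(kMax, n, p))
  ev <- sv$d^2 / (n - 1L)
  edge <- (1 + sqrt(p / n))^2
  if (twCorrection) {
    sigma <- (sqrt(n - 1) + sqrt(p)) *
      (1 / sqrt(n - 1) + 1 / sqrt(p))^(1 / 3) / n
    edge <- edge + .TW1_Q95 * sigma
  }
  k <- sum(ev > edge)
  kScores <- min(k, kMax)
  scores <- sv$u[, seq_len(kScores), drop = FALSE] %*%
    diag(sv$d[seq_len(kScores)], nrow = kScores)
  rownames(scores) <- rownames(X)
  loadings <- sv$v[, seq_len(kScores), drop = FALSE]
  rownames(loadings) <- colnames(X)
  new("SpotPCA", scores = scores, loadings = loadings,
      eigenvalues = ev, mpUpperEdge = edge, kRetained = as.integer(k),
      nSpots = as.integer(n), nGenes = as.integer(p))
}

#' Cluster spots on a shared-nearest-neighbor graph
#'
#' Builds a k-nearest-neighbor graph on the retained component scores,
#' reweights edges by the Jaccard overlap of neighbor sets (shared /
#' (2k - shared), pruned below 1/15), and partitions it with the Leiden
#' algorithm (modularity objective) at the given resolution. Deterministic
#' given `seed`.
#'
#' @param pca A [SpotPCA-class] (or a spots x k score matrix).
#' @param kNeighbors Neighbors per spot; must be `< n` spots.
#' @param resolution Leiden resolution parameter.
#' @param seed Integer seed.
#' @return A `data.frame` with `barcode` and 1-based `cluster`, with
#'   `resolution`, `kNeighbors` and `seed` as attributes.
#' @export
clusterSpots <- function(pca, kNeighbors = 20, resolution = 1, seed = 1) {
  S <- if (methods::is(pca, "SpotPCA")) {
    if (pca@kRetained < 1L) {
      stop("no components retained; pass a score matrix to override")
    }
    pca@scores
  } else as.matrix(pca)
  n <- nrow(S)
  if (kNeighbors >= n) stop("kNeighbors (", kNeighbors,
                            ") must be < number of spots (", n, ")")
  d2 <- as.matrix(stats::dist(S))
  nn <- t(apply(d2, 1L, function(r) order(r)[2:(kNeighbors + 1L)]))
  # indicator of "i's neighbor set" including self, then shared counts
  ind <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = kNeighbors + 1L),
    j = as.integer(t(cbind(seq_len(n), nn))),
    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(ind)
  jac <- shared / (2 * (kNeighbors + 1L) - shared)
  jac <- as.matrix(jac)
  jac[jac < 1 / 15] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10L)
  out <- data.frame(barcode = if (!is.null(rownames(S))) rownames(S) else
                      as.character(seq_len(n)),
                    cluster = as.integer(igraph::membership(cl)))
  attr(out, "resolution") <- resolution
  attr(out, "kNeighbors") <- kNeighbors
  attr(out, "seed") <- seed
  out
}
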