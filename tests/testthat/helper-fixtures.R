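# Shared fixtures, built in code at test time.

# A small section config that still has all four regions populated.
smallConfig <- function(seed = 1, ...) {
  SectionConfig(gridRows = 40L, gridCols = 48L, coreCenter = c(20L, 24L),
                coreRadius = 4L, tpWidth = 2L, boWidth = 2L,
                nBackgroundGenes = 40L, libSizeLogMean = log(2000),
                seed = seed, ...)
}

# Wrap a plain genes x spots matrix as a SpotExperiment on a hex strip,
# with the given assay name.
matrixSE <- function(m, assayName = "lognorm", region = NULL) {
  n <- ncol(m)
  if (is.null(colnames(m))) colnames(m) <- sprintf("BC%04d", seq_len(n))
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  pos <- data.frame(barcode = colnames(m), in_tissue = 1L,
                    array_row = rep(0:1, length.out = n),
                    array_col = 2L * seq_len(n) - rep(0:1, length.out = n) * 1L,
                    pxl_row = 0, pxl_col = 0)
  # ensure even parity: row 0 -> even col, row 1 -> odd col
  pos$array_col <- ifelse(pos$array_row == 0L, 2L * seq_len(n),
                          2L * seq_len(n) + 1L)
  se <- SpotExperiment(Matrix::Matrix(m, sparse = TRUE), pos)
  SummarizedExperiment::assay(se, assayName) <- m
  if (!is.null(region)) regionLabels(se) <- region
  se
}

# Bivariate-normal draws with a given correlation.
rbinorm <- function(n, rho) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
}

# A SpotExperiment whose "lognorm" values for two genes carry a planted
# per-region correlation structure.
plantedCorrelationSE <- function(nPerRegion, rhoByRegion, seed) {
  set.seed(seed)
  regions <- names(rhoByRegion)
  vals <- lapply(regions, function(r) rbinorm(nPerRegion, rhoByRegion[[r]]))
  m <- t(do.call(rbind, vals))
  rownames(m) <- c("anchorG", "partnerG")
  labels <- rep(regions, each = nPerRegion)
  matrixSE(m, "lognorm", region = labels)
}
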