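#' Gene programs for the synthetic section
#'
#' A gene program is a set of genes sharing one spatial expression profile: a
#' nonnegative mean multiplier per region (TC, TP, BO, BR). The bundled
#' defaults emulate the marker classes seen in glioma-bearing sections: a
#' core-enriched tumor program, a border-enriched reactive-astrocyte ("glial
#' scar") program, a uniformly expressed program, and a core-depleted
#' neuronal program (zero in the tumor core).
#'
#' @param name Program label.
#' @param genes Character vector of gene symbols.
#' @param profile Named numeric vector with entries `TC`, `TP`, `BO`, `BR`;
#'   all `>= 0`, at least one `> 0`.
#' @return A validated `list` with elements `name`, `genes`, `profile`.
#' @export
geneProgram <- function(name, genes, profile) {
  if (!all(.REGIONS %in% names(profile))) {
    stop("program '", name, "': profile must name all of ",
         paste(.REGIONS, collapse = ", "))
  }
  profile <- profile[.REGIONS]
  if (any(profile < 0) || !any(profile > 0)) {
    stop("program '", name,
         "': multipliers must be >= 0 with at least one > 0")
  }
  list(name = name, genes = as.character(genes), profile = profile)
}

.defaultPrograms <- function() {
  list(
    geneProgram("tumor", sprintf("Tum%02d", 1:10),
                c(TC = 6, TP = 4, BO = 0.5, BR = 0.1)),
    geneProgram("scar", sprintf("Scar%02d", 1:10),
                c(TC = 0.2, TP = 1.5, BO = 8, BR = 0.8)),
    geneProgram("uniform", sprintf("Uni%02d", 1:10),
                c(TC = 1, TP = 1, BO = 1, BR = 1)),
    geneProgram("neuron", sprintf("Neu%02d", 1:10),
                c(TC = 0, TP = 0.2, BO = 1.5, BR = 2))
  )
}

.defaultSignalCovariance <- function() {
  sig <- c("astro", "micro", "tumor")
  # within-region sd 1/sqrt(2): regional mean shifts dominate local noise
  mk <- function(r12 = 0, r13 = 0, r23 = 0) {
    m <- diag(3)
    m[1, 2] <- m[2, 1] <- r12   # astro-micro
    m[1, 3] <- m[3, 1] <- r13   # astro-tumor
    m[2, 3] <- m[3, 2] <- r23   # micro-tumor
    dimnames(m) <- list(sig, sig)
    m * 0.5
  }
  # astrocyte and tumor signals co-occur in the periphery but not the core;
  # microglia track tumor signal in core and periphery.
  list(TC = mk(0, 0, 0.4), TP = mk(0.2, 0.6, 0.4),
       BO = mk(0.3, 0, 0), BR = mk(0, 0, 0))
}

.defaultSignalMeans <- function() {
  # Region-level mean shifts couple the latent signals to the matching gene
  # programs (tumor high in core, astro high at the border ring).
  # z-scale abundance proxies: astrocyte signal depleted in the core
  # (counts there are dominated by the tumor program) and peaking in the
  # reactive border ring, mirroring the planted expression programs
  list(TC = c(astro = -4, micro = 2, tumor = 6),
       TP = c(astro = 1, micro = 3, tumor = 4),
       BO = c(astro = 5, micro = 1, tumor = 0.5),
       BR = c(astro = 0, micro = 0.5, tumor = 0))
}

#' Configuration of a synthetic glioma-bearing section
#'
#' Defines the geometry (a contiguous tumor core, an inner periphery rim, a
#' reactive border ring, and surrounding brain on a Visium hex lattice), the
#' count model (negative binomial with spot-specific log-normal library
#' sizes), the planted gene programs, and the per-region Gaussian model for
#' cell-type signals.
#'
#' @param gridRows,gridCols Lattice extent; spots occupy every `(row, col)`
#'   with even `row + col`.
#' @param coreCenter Integer `(row, col)` of the tumor center (even parity).
#' @param coreRadius Hex-step radius of the tumor core (TC), `>= 1`.
#' @param tpWidth,boWidth Ring widths (hex steps) of the tumor periphery
#'   (inside the tumor mass) and border (outside it), `>= 1`.
#' @param libSizeLogMean,libSizeLogSd Log-normal library size parameters.
#' @param nbDispersion Negative binomial dispersion `theta`
#'   (variance `= mu + mu^2/theta`), `> 0`.
#' @param nBackgroundGenes Number of spatially uniform background genes.
#' @param programs List of [geneProgram()] objects.
#' @param signalCovariance Named list (one PSD matrix per region) over the
#'   cell-type signals.
#' @param signalMeans Named list (one mean vector per region).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A validated `SectionConfig` object (S4).
#' @export
SectionConfig <- function(gridRows = 60L, gridCols = 60L,
                          coreCenter = c(30L, 30L), coreRadius = 6L,
                          tpWidth = 2L, boWidth = 2L,
                          libSizeLogMean = log(5000), libSizeLogSd = 0.35,
                          nbDispersion = 2, nBackgroundGenes = 100L,
                          programs = .defaultPrograms(),
                          signalCovariance = .defaultSignalCovariance(),
                          signalMeans = .defaultSignalMeans(),
                          seed = 1L) {
  new("SectionConfig",
      gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
      coreCenter = as.integer(coreCenter), coreRadius = as.integer(coreRadius),
      tpWidth = as.integer(tpWidth), boWidth = as.integer(boWidth),
      libSizeLogMean = libSizeLogMean, libSizeLogSd = libSizeLogSd,
      nbDispersion = nbDispersion,
      nBackgroundGenes = as.integer(nBackgroundGenes),
      programs = programs, signalCovariance = signalCovariance,
      signalMeans = signalMeans, seed = as.integer(seed))
}

#' @rdname SectionConfig
#' @export
setClass("SectionConfig", representation(
  gridRows = "integer", gridCols = "integer", coreCenter = "integer",
  coreRadius = "integer", tpWidth = "integer", boWidth = "integer",
  libSizeLogMean = "numeric", libSizeLogSd = "numeric",
  nbDispersion = "numeric", nBackgroundGenes = "integer",
  programs = "list", signalCovariance = "list", signalMeans = "list",
  seed = "integer"
))

setValidity("SectionConfig", function(object) {
  if (object@coreRadius < 1L) return("coreRadius must be >= 1")
  if (object@tpWidth < 1L || object@boWidth < 1L) {
    return("ring widths must be >= 1")
  }
  if (object@nbDispersion <= 0) return("nbDispersion must be > 0")
  if (sum(object@coreCenter) %% 2L != 0L) {
    return("coreCenter must have even row + col parity")
  }
  R <- object@coreRadius + object@tpWidth + object@boWidth
  r0 <- object@coreCenter[1L]; c0 <- object@coreCenter[2L]
  if (r0 - R < 0L || r0 + R > object@gridRows - 1L ||
      c0 - 2L * R < 0L || c0 + 2L * R > object@gridCols - 1L) {
    return("core + rings exceed the grid extent")
  }
  gg <- unlist(lapply(object@programs, `[[`, "genes"))
  if (anyDuplicated(gg)) return("program gene names must be unique")
  for (r in .REGIONS) {
    S <- object@signalCovariance[[r]]
    if (is.null(S)) return(paste("signalCovariance missing region", r))
    if (!isSymmetric(unname(S))) {
      return(paste("signal covariance for", r, "is not symmetric"))
    }
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      return(paste("signal covariance for", r, "is not positive semidefinite"))
    }
  }
  TRUE
})

# Internal: all lattice spots of a config with truth region labels.
.sectionLattice <- function(config) {
  rows <- rep(0:(config@gridRows - 1L), each = config@gridCols)
  cols <- rep(0:(config@gridCols - 1L), times = config@gridRows)
  keep <- (rows + cols) %% 2L == 0L
  rows <- rows[keep]; cols <- cols[keep]
  d <- hexDistance(config@coreCenter[1L], config@coreCenter[2L], rows, cols)
  R1 <- config@coreRadius
  R2 <- R1 + config@tpWidth
  R3 <- R2 + config@boWidth
  region <- ifelse(d <= R1, "TC",
            ifelse(d <= R2, "TP",
            ifelse(d <= R3, "BO", "BR")))
  data.frame(array_row = rows, array_col = cols, hex_dist = d,
             region = factor(region, levels = .REGION_LEVELS))
}

#' Generate a ground-truthed synthetic glioma section
#'
#' Lays spots on the full hex lattice, labels them concentrically
#' (TC within `coreRadius` hex steps of the center, then a TP rim of
#' `tpWidth` rings completing the tumor mass, a BO ring of `boWidth` rings
#' outside it, and BR elsewhere), draws negative-binomial counts whose
#' per-spot expected total equals the spot's log-normal library size with
#' per-gene shares set by the program multipliers of the spot's region, and
#' draws per-spot cell-type signals from the configured per-region Gaussian.
#'
#' @param config A [SectionConfig()].
#' @return A [SpotExperiment-class] with assay `counts`, truth labels in
#'   `colData()$truth_region`, and `metadata()` entries `truth_signals`
#'   (spots x signals matrix) and `truth_params` (the config). The global RNG
#'   state is left untouched.
#' @export
generateSection <- function(config) {
  validObject(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config@seed)

  lat <- .sectionLattice(config)
  n <- nrow(lat)
  barcodes <- sprintf("SYN%05d-1", seq_len(n))

  progGenes <- unlist(lapply(config@programs, `[[`, "genes"))
  bg <- sprintf("Bg%04d", seq_len(config@nBackgroundGenes))
  genes <- c(progGenes, bg)
  nProg <- length(progGenes)

  # per-gene baseline expression (heterogeneous, region-independent part)
  base <- stats::rgamma(length(genes), shape = 2, rate = 2) + 0.1
  # per-region multiplier matrix genes x regions (background uniform)
  mult <- matrix(1, nrow = length(genes), ncol = 4L,
                 dimnames = list(genes, .REGIONS))
  for (p in config@programs) {
    mult[p$genes, ] <- matrix(p$profile, nrow = length(p$genes),
                              ncol = 4L, byrow = TRUE)
  }

  lib <- stats::rlnorm(n, config@libSizeLogMean, config@libSizeLogSd)
  counts <- matrix(0L, nrow = length(genes), ncol = n,
                   dimnames = list(genes, barcodes))
  for (r in .REGIONS) {
    spots <- which(lat$region == r)
    if (!length(spots)) next
    w <- base * mult[, r]
    share <- w / sum(w)
    mu <- outer(share, lib[spots])       # genes x spots in region
    counts[, spots] <- stats::rnbinom(length(mu), mu = mu,
                                      size = config@nbDispersion)
  }
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  # latent cell-type signals, region-wise Gaussian
  sigNames <- colnames(config@signalCovariance[[1L]])
  signals <- matrix(NA_real_, nrow = n, ncol = length(sigNames),
                    dimnames = list(barcodes, sigNames))
  for (r in .REGIONS) {
    spots <- which(lat$region == r)
    if (!length(spots)) next
    mu <- config@signalMeans[[r]][sigNames]
    signals[spots, ] <- MASS::mvrnorm(length(spots), mu = mu,
                                      Sigma = config@signalCovariance[[r]])
  }

  positions <- data.frame(
    barcode = barcodes, in_tissue = 1L,
    array_row = lat$array_row, array_col = lat$array_col,
    pxl_row = 100 + 60 * lat$array_row,
    pxl_col = 100 + 35 * lat$array_col
  )
  rd <- DataFrame(id = genes, symbol = genes, row.names = genes)
  se <- SpotExperiment(counts, positions, rowData = rd,
                       metadata = list(truth_signals = signals,
                                       truth_params = config))
  colData(se)$truth_region <- lat$region
  colData(se)$library_size <- lib
  se
}

#' Write a synthetic section as SpaceRanger-style text files
#'
#' Emits `matrix.mtx` (genes x spots, 1-based MatrixMarket),
#' `barcodes.tsv`, `features.tsv`, `tissue_positions.csv`, plus truth tables
#' `truth_labels.tsv` and `truth_signals.tsv`, all readable back through the
#' package's readers. Output is deterministic for a fixed section.
#'
#' @param section A [SpotExperiment-class] from [generateSection()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
writeSection <- function(section, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  paths <- c(
    matrix = file.path(dir, "matrix.mtx"),
    barcodes = file.path(dir, "barcodes.tsv"),
    features = file.path(dir, "features.tsv"),
    positions = file.path(dir, "tissue_positions.csv"),
    truth_labels = file.path(dir, "truth_labels.tsv"),
    truth_signals = file.path(dir, "truth_signals.tsv")
  )
  ok <- try({
    Matrix::writeMM(methods::as(assay(section, "counts"), "CsparseMatrix"),
                    paths["matrix"])
    writeLines(colnames(section), paths["barcodes"])
    rd <- rowData(section)
    utils::write.table(
      data.frame(id = rd$id, symbol = rd$symbol, type = "Gene Expression"),
      paths["features"], sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    cd <- colData(section)
    utils::write.table(
      data.frame(barcode = colnames(section), in_tissue = cd$in_tissue,
                 array_row = cd$array_row, array_col = cd$array_col,
                 pxl_row = cd$pxl_row, pxl_col = cd$pxl_col),
      paths["positions"], sep = ",", quote = FALSE,
      row.names = FALSE, col.names = TRUE)
    keep <- cd$in_tissue == 1L
    utils::write.table(
      data.frame(barcode = colnames(section)[keep],
                 region = as.character(cd$truth_region[keep])),
      paths["truth_labels"], sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- metadata(section)$truth_signals
    utils::write.table(
      data.frame(barcode = rownames(sig), sig[, , drop = FALSE],
                 check.names = FALSE),
      paths["truth_signals"], sep = "\t", quote = FALSE, row.names = FALSE)
  }, silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("failed writing section to ", dir, ": ", attr(ok, "condition")$message)
  }
  invisible(paths)
}
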