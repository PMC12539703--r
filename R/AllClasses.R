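#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assay<- assayNames colData colData<-
#'   rowData rowData<-
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

.REGIONS <- c("TC", "TP", "BO", "BR")
.REGION_LEVELS <- c(.REGIONS, "EXCLUDED")

#' SpotExperiment: expression plus hex-lattice geometry for one section
#'
#' A [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment-class]
#' subclass holding spot-level expression (genes in rows, spots in columns)
#' together with the Visium array geometry. The `colData` carries at least
#' `in_tissue`, `array_row`, `array_col`, `pxl_row`, `pxl_col`; region labels
#' and cluster assignments are added by the pipeline as `region` and
#' `cluster` columns.
#'
#' @slot ... inherited from `SingleCellExperiment`.
#' @export
setClass("SpotExperiment", contains = "SingleCellExperiment")

setValidity("SpotExperiment", function(object) {
  cd <- colData(object)
  need <- c("in_tissue", "array_row", "array_col")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    return(paste("colData is missing:", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(colnames(object))) return("duplicate barcode")
  rc <- cd$array_row + cd$array_col
  if (any((rc %% 2L != 0L) & cd$in_tissue == 1L)) {
    return("hex parity violation: in-tissue spot with odd array_row + array_col")
  }
  if (anyDuplicated(paste(cd$array_row, cd$array_col))) {
    return("duplicate (array_row, array_col)")
  }
  TRUE
})

#' Construct a SpotExperiment
#'
#' @param counts Sparse or dense nonnegative integer matrix, genes x spots;
#'   `dimnames` give gene ids and barcodes.
#' @param positions A `data.frame` or `DataFrame` with columns `barcode`,
#'   `in_tissue`, `array_row`, `array_col`, `pxl_row`, `pxl_col` (the
#'   tissue_positions dialect), covering every column of `counts`.
#' @param rowData Optional per-gene metadata (`id`, `symbol`).
#' @param metadata Optional list of section-level metadata.
#' @return A [SpotExperiment-class] object restricted to the barcodes present
#'   in `counts`, in `counts` column order.
#' @export
SpotExperiment <- function(counts, positions, rowData = NULL, metadata = list()) {
  positions <- as.data.frame(positions)
  if (is.null(colnames(counts))) stop("counts must have barcode colnames")
  m <- match(colnames(counts), positions$barcode)
  if (anyNA(m)) {
    stop("positions are missing ", sum(is.na(m)), " barcode(s), e.g. ",
         colnames(counts)[which(is.na(m))[1L]])
  }
  pos <- positions[m, , drop = FALSE]
  cd <- DataFrame(
    in_tissue = as.integer(pos$in_tissue),
    array_row = as.integer(pos$array_row),
    array_col = as.integer(pos$array_col),
    pxl_row = as.numeric(pos$pxl_row),
    pxl_col = as.numeric(pos$pxl_col),
    row.names = colnames(counts)
  )
  se <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd, metadata = metadata
  )
  if (!is.null(rowData)) rowData(se) <- rowData
  new("SpotExperiment", se)
}

#' @describeIn SpotExperiment-accessors array coordinates and pixel
#'   coordinates of every spot.
#' @export
spotPositions <- function(x) {
  colData(x)[, intersect(
    c("in_tissue", "array_row", "array_col", "pxl_row", "pxl_col"),
    colnames(colData(x))
  ), drop = FALSE]
}

#' Accessors for SpotExperiment annotation columns
#'
#' `regionLabels()` returns the per-spot region factor with levels
#' `TC, TP, BO, BR, EXCLUDED`; `clusterLabels()` the cluster assignment.
#' Both have setter forms.
#'
#' @param x A [SpotExperiment-class].
#' @param value Replacement labels, recycled/validated against the spots.
#' @name SpotExperiment-accessors
NULL

#' @rdname SpotExperiment-accessors
#' @export
regionLabels <- function(x) colData(x)$region

#' @rdname SpotExperiment-accessors
#' @export
`regionLabels<-` <- function(x, value) {
  value <- factor(as.character(value), levels = .REGION_LEVELS)
  if (length(value) != ncol(x)) stop("labels must cover every spot")
  if (anyNA(value)) stop("region labels must be in {",
                         paste(.REGION_LEVELS, collapse = ", "), "}")
  colData(x)$region <- value
  x
}

#' @rdname SpotExperiment-accessors
#' @export
clusterLabels <- function(x) colData(x)$cluster

#' @rdname SpotExperiment-accessors
#' @export
`clusterLabels<-` <- function(x, value) {
  if (length(value) != ncol(x)) stop("clusters must cover every spot")
  colData(x)$cluster <- as.integer(value)
  x
}

setMethod("show", "SpotExperiment", function(object) {
  callNextMethod()
  nt <- sum(colData(object)$in_tissue == 1L)
  cat("in-tissue spots:", nt, "\n")
  if (!is.null(regionLabels(object))) {
    cat("regions:", paste(names(table(regionLabels(object))),
                          table(regionLabels(object)),
                          sep = "=", collapse = " "), "\n")
  }
})

#' Principal component result with Marchenko-Pastur component selection
#'
#' @slot scores spots x k matrix of component scores (retained components).
#' @slot loadings genes x k matrix of loadings.
#' @slot eigenvalues all eigenvalues of the scaled-data covariance,
#'   nonincreasing.
#' @slot mpUpperEdge the operative upper noise-eigenvalue threshold.
#' @slot kRetained number of eigenvalues strictly above `mpUpperEdge`.
#' @slot nSpots,nGenes problem dimensions.
#' @export
setClass("SpotPCA", representation(
  scores = "matrix", loadings = "matrix", eigenvalues = "numeric",
  mpUpperEdge = "numeric", kRetained = "integer",
  nSpots = "integer", nGenes = "integer"
))

setValidity("SpotPCA", function(object) {
  ev <- object@eigenvalues
  if (is.unsorted(rev(ev), strictly = FALSE)) {
    return("eigenvalues must be nonincreasing")
  }
  if (object@kRetained != sum(ev > object@mpUpperEdge)) {
    return("kRetained must equal count(eigenvalue > mpUpperEdge)")
  }
  TRUE
})

setMethod("show", "SpotPCA", function(object) {
  cat("SpotPCA:", object@nSpots, "spots x", object@nGenes, "genes\n")
  cat("  MP upper edge:", format(object@mpUpperEdge, digits = 4),
      "| components retained:", object@kRetained, "\n")
})

#' Bootstrap co-occurrence result for one region
#'
#' Per signal pair: mean Pearson correlation over bootstrap replicates,
#' percentile confidence bounds, and the binary significance indicator
#' (CI excludes zero).
#'
#' @slot region region label the result belongs to.
#' @slot mean,ciLow,ciHigh,significant square matrices over signals.
#' @slot B replicates requested; `nSkipped` of them had a constant signal
#'   and were dropped.
#' @slot alpha CI significance level.
#' @slot replicates p x p x B array of per-replicate correlation matrices
#'   (NA slices for skipped replicates), kept for differential comparison.
#' @export
setClass("Cooccurrence", representation(
  region = "character", mean = "matrix", ciLow = "matrix", ciHigh = "matrix",
  significant = "matrix", B = "integer", alpha = "numeric",
  nSkipped = "integer", replicates = "array"
))

setValidity("Cooccurrence", function(object) {
  ok <- is.na(object@mean) |
    (object@ciLow <= object@mean + 1e-12 & object@mean <= object@ciHigh + 1e-12)
  if (!all(ok)) return("ciLow <= mean <= ciHigh violated")
  sig <- ifelse(object@ciLow > 0 | object@ciHigh < 0, 1, 0)
  same <- is.na(object@significant) | object@significant == sig
  if (!all(same | is.na(sig))) {
    return("significance flag must equal the CI-excludes-zero predicate")
  }
  TRUE
})

setMethod("show", "Cooccurrence", function(object) {
  cat("Cooccurrence [", object@region, "]: ",
      nrow(object@mean), " signals, B = ", object@B,
      " (", object@nSkipped, " skipped), alpha = ", object@alpha, "\n",
      sep = "")
  print(round(object@mean, 3))
})
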