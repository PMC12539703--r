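#' Read a 10x-style MTX triple into a counts SingleCellExperiment
#'
#' The on-disk convention is genes x spots; the orientation is auto-detected
#' by matching the MatrixMarket dimensions against the barcode and feature
#' counts, so a transposed matrix is accepted and corrected.
#'
#' @param mtxPath MatrixMarket file of nonnegative integer counts.
#' @param barcodesPath One barcode per line.
#' @param featuresPath Tab-separated `id`, `symbol`[, `type`] per line.
#' @return A `SingleCellExperiment` with assay `counts` (genes x spots) and
#'   `rowData` columns `id`, `symbol`.
#' @export
readSpotMatrix <- function(mtxPath, barcodesPath, featuresPath) {
  for (p in c(mtxPath, barcodesPath, featuresPath)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  m <- Matrix::readMM(mtxPath)
  barcodes <- readLines(barcodesPath)
  feats <- utils::read.delim(featuresPath, header = FALSE,
                             stringsAsFactors = FALSE)
  if (ncol(feats) < 2L) feats$V2 <- feats$V1
  if (anyDuplicated(barcodes)) stop("duplicate barcode in ", barcodesPath)
  if (anyDuplicated(feats$V1)) stop("duplicate feature id in ", featuresPath)
  if (nrow(m) == length(feats$V1) && ncol(m) == length(barcodes)) {
    # genes x spots, the 10x convention
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(feats$V1)) {
    m <- Matrix::t(m)
  } else {
    stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
         " but there are ", length(feats$V1), " features and ",
         length(barcodes), " barcodes")
  }
  if (any(m@x < 0)) stop("negative entries in counts matrix ", mtxPath)
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(feats$V1, barcodes)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    rowData = DataFrame(id = feats$V1, symbol = feats$V2,
                        row.names = feats$V1)
  )
}

#' Read a tissue_positions table
#'
#' Accepts both SpaceRanger dialects: headered
#' (`barcode,in_tissue,array_row,array_col,...`) and headerless six-column
#' CSV. Spots violating the hex parity convention (`array_row + array_col`
#' odd) are excluded with a warning.
#'
#' @param path CSV file with at least six columns.
#' @return A `data.frame` with columns `barcode`, `in_tissue`, `array_row`,
#'   `array_col`, `pxl_row`, `pxl_col`.
#' @export
readPositions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("barcode", first, ignore.case = TRUE)
  df <- utils::read.csv(path, header = hasHeader, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("positions file needs >= 6 columns: ", path)
  df <- df[, 1:6]
  colnames(df) <- c("barcode", "in_tissue", "array_row", "array_col",
                    "pxl_row", "pxl_col")
  df$in_tissue <- as.integer(df$in_tissue)
  df$array_row <- as.integer(df$array_row)
  df$array_col <- as.integer(df$array_col)
  bad <- (df$array_row + df$array_col) %% 2L != 0L
  if (any(bad)) {
    warning(sum(bad), " spot(s) violate hex parity (row + col odd); excluded")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a full section directory into a SpotExperiment
#'
#' Convenience wrapper joining [readSpotMatrix()] and [readPositions()] on
#' barcode, as written by [writeSection()].
#'
#' @param dir Directory holding `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`, `tissue_positions.csv`.
#' @param inTissueOnly Keep only `in_tissue == 1` spots (default `TRUE`).
#' @return A [SpotExperiment-class].
#' @export
readSection <- function(dir, inTissueOnly = TRUE) {
  sce <- readSpotMatrix(file.path(dir, "matrix.mtx"),
                        file.path(dir, "barcodes.tsv"),
                        file.path(dir, "features.tsv"))
  pos <- readPositions(file.path(dir, "tissue_positions.csv"))
  if (inTissueOnly) {
    keep <- colnames(sce) %in% pos$barcode[pos$in_tissue == 1L]
    sce <- sce[, keep]
  }
  se <- SpotExperiment(assay(sce, "counts"), pos, rowData = rowData(sce))
  lab <- file.path(dir, "truth_labels.tsv")
  if (file.exists(lab)) {
    tl <- utils::read.delim(lab, stringsAsFactors = FALSE)
    colData(se)$truth_region <- factor(
      tl$region[match(colnames(se), tl$barcode)], levels = .REGION_LEVELS)
  }
  se
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines `name<TAB>description<TAB>member...`. Members are
#' uppercased (cross-species symbol harmonization) and de-duplicated within
#' a set.
#'
#' @param path GMT file.
#' @return Named list of character vectors (possibly empty, with a warning,
#'   for an empty file).
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), names = character(0)))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields in ", path)
    }
    sets[[f[1L]]] <- unique(toupper(f[-(1:2)]))
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in ", path)
  sets
}

#' Write a tidy TSV with a provenance comment line
#'
#' All downstream tables are written through this helper: one `#` comment
#' line recording the package version and a config hash, then a headered
#' tab-separated table.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param configHash Character hash recorded in the header comment.
#' @return Invisibly, `path`.
#' @export
writeTidyTSV <- function(df, path, configHash = "none") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# glioscape %s config_hash=%s",
                     as.character(utils::packageVersion("glioscape")),
                     configHash), con)
  utils::write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
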