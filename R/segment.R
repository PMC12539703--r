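#' Mean z-scored marker expression per spot
#'
#' For each marker gene, lognorm values are z-scored across spots
#' (zero-variance genes contribute 0); the score is the mean over markers.
#'
#' @param x Object with a `lognorm` assay.
#' @param markers Character vector of gene ids; markers absent from the
#'   matrix are dropped with a warning, and an error is raised when none
#'   remain.
#' @param assay Assay to score on (default `"lognorm"`).
#' @return Named numeric vector of per-spot scores.
#' @export
markerScore <- function(x, markers, assay = "lognorm") {
  m <- SummarizedExperiment::assay(x, assay)
  miss <- setdiff(markers, rownames(m))
  if (length(miss) == length(markers)) {
    stop("no marker found in matrix: ", paste(miss, collapse = ", "))
  }
  if (length(miss)) {
    warning("markers not found, dropped: ", paste(miss, collapse = ", "))
  }
  markers <- setdiff(markers, miss)
  v <- as.matrix(m[markers, , drop = FALSE])
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  z <- (v - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  colMeans(z)
}

#' Segment spots into tumor core, periphery, border and brain
#'
#' Reproducible replacement for manual region delineation: (i) tumor
#' clusters are those whose mean tumor marker score exceeds
#' `scoreThreshold`; (ii) the tumor mass is the largest hex-connected
#' component of tumor-cluster spots (ties broken by smallest lexicographic
#' `(row, col)` minimum; smaller components are labeled `EXCLUDED` with a
#' warning); (iii) mass spots within `tpRings` hex steps of any in-tissue
#' non-mass spot become TP, the rest TC; (iv) non-mass spots within
#' `boRings` steps of the mass become BO; (v) everything else is BR. Hex
#' distances are BFS steps restricted to in-tissue spots. If no cluster
#' passes the threshold every spot is BR and a warning is raised.
#'
#' @param x A [SpotExperiment-class] (in-tissue spots).
#' @param clusters Cluster assignment: output of [clusterSpots()] or an
#'   integer vector aligned to spots.
#' @param tumorScore Per-spot tumor marker score ([markerScore()]).
#' @param scoreThreshold Mean-score threshold defining tumor clusters
#'   (default 0.5).
#' @param tpRings,boRings Ring widths in hex steps (default 2).
#' @return `x` with `colData()$region` set (factor levels
#'   `TC, TP, BO, BR, EXCLUDED`) and `colData()$region_provenance = "auto"`.
#' @export
segmentRegions <- function(x, clusters, tumorScore, scoreThreshold = 0.5,
                           tpRings = 2, boRings = 2) {
  cl <- if (is.data.frame(clusters)) {
    clusters$cluster[match(colnames(x), clusters$barcode)]
  } else as.integer(clusters)
  if (length(cl) != ncol(x) || anyNA(cl)) {
    stop("clusters and spots do not share barcodes")
  }
  coords <- cbind(colData(x)$array_row, colData(x)$array_col)
  n <- ncol(x)
  label <- rep("BR", n)

  meanScore <- tapply(tumorScore, cl, mean)
  tumorClusters <- as.integer(names(meanScore))[meanScore > scoreThreshold]
  if (!length(tumorClusters)) {
    warning("no cluster passes the tumor score threshold (",
            scoreThreshold, "); all spots labeled BR")
  } else {
    isTumor <- cl %in% tumorClusters
    tcoords <- coords[isTumor, , drop = FALSE]
    comp <- .hexComponents(tcoords)
    sizes <- table(comp)
    big <- names(sizes)[sizes == max(sizes)]
    big <- as.integer(big)
    if (length(big) > 1L) {
      # tie: component containing the lexicographically smallest (row, col)
      cand <- which(comp %in% big)
      cand <- cand[order(tcoords[cand, 1L], tcoords[cand, 2L])]
      big <- comp[cand[1L]]
    }
    mass <- rep(FALSE, n)
    mass[which(isTumor)[comp == big]] <- TRUE
    excluded <- isTumor & !mass
    if (any(excluded)) {
      warning(sum(excluded), " tumor spot(s) outside the largest component ",
              "labeled EXCLUDED")
    }
    # TP: mass spots near the outside; BFS sources = non-mass in-tissue spots
    if (any(!mass)) {
      dOut <- hexBFS(coords, !mass)
      label[mass & dOut <= tpRings] <- "TP"
      label[mass & dOut > tpRings] <- "TC"
    } else {
      label[mass] <- "TC"
    }
    dMass <- hexBFS(coords, mass)
    label[!mass & dMass <= boRings] <- "BO"
    label[excluded] <- "EXCLUDED"
  }
  regionLabels(x) <- label
  colData(x)$region_provenance <- "auto"
  x
}

#' Attach region labels from a file or vector
#'
#' Accepts a labels TSV (`barcode`, `region`) to reproduce a manual
#' segmentation; provenance is recorded as `"file"`.
#'
#' @param x A [SpotExperiment-class].
#' @param labels Path to a TSV or a named character vector/factor.
#' @return `x` with `colData()$region` set.
#' @export
setRegionLabels <- function(x, labels) {
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    tl <- utils::read.delim(labels, stringsAsFactors = FALSE,
                            comment.char = "#")
    labels <- stats::setNames(tl$region, tl$barcode)
  }
  if (!is.null(names(labels))) {
    labels <- labels[colnames(x)]
  }
  regionLabels(x) <- labels
  colData(x)$region_provenance <- "file"
  x
}

#' Per-region expression distribution summaries
#'
#' The numbers behind region violin plots: per gene and region, the count,
#' mean, median and quartiles of lognorm values. Empty regions produce rows
#' with `n = 0` and NA summaries.
#'
#' @param x Object with a `lognorm` assay and region labels.
#' @param genes Genes to summarize.
#' @param labels Optional labels (defaults to `regionLabels(x)`).
#' @param assay Assay name (default `"lognorm"`).
#' @return A `data.frame` with columns `gene`, `region`, `n`, `mean`,
#'   `median`, `q25`, `q75`.
#' @export
regionProfile <- function(x, genes, labels = regionLabels(x),
                          assay = "lognorm") {
  if (is.null(labels)) stop("no region labels assigned")
  m <- as.matrix(SummarizedExperiment::assay(x, assay)[genes, , drop = FALSE])
  out <- expand.grid(gene = genes, region = .REGIONS,
                     stringsAsFactors = FALSE)
  stats_ <- t(mapply(function(g, r) {
    v <- m[g, labels == r]
    if (!length(v)) return(c(n = 0, mean = NA, median = NA, q25 = NA, q75 = NA))
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    c(n = length(v), mean = mean(v), median = stats::median(v),
      q25 = q[1L], q75 = q[2L])
  }, out$gene, out$region))
  cbind(out, as.data.frame(stats_))
}
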