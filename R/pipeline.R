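.defaultRunConfig <- function() {
  list(
    scaleFactor = 10000, nHVG = 2000, minMean = 0.05,
    kNeighbors = 20, resolution = 0.75, kMax = 50,
    tumorMarkers = NULL, scoreThreshold = 0.5, tpRings = 2, boRings = 2,
    dePairs = list(c("TC", "TP"), c("TP", "BO"), c("BO", "BR")),
    gmt = NULL, nPerm = 1000,
    anchor = NULL, partners = NULL,
    markerLists = NULL, B = 1000, alpha = 0.05,
    minN = 10
  )
}

#' Validate and complete a pipeline configuration
#'
#' Checks every parameter's type and range, fills defaults, and returns all
#' problems at once rather than failing on the first.
#'
#' @param config A named list, or a path to a YAML file.
#' @return A list with `config` (defaults filled), `errors` (character
#'   vector, empty when valid) and `defaultsApplied` (names of filled
#'   fields).
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  errors <- character(0)
  defaults <- .defaultRunConfig()
  applied <- setdiff(names(defaults), names(config))
  for (nm in applied) config[[nm]] <- defaults[[nm]]
  chkNum <- function(nm, lo = -Inf, hi = Inf, msg = NULL) {
    v <- config[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || v < lo || v > hi) {
      errors <<- c(errors, if (!is.null(msg)) msg else
        sprintf("%s must be a number in [%s, %s]", nm, lo, hi))
    }
  }
  chkNum("scaleFactor", lo = 1e-12, msg = "scaleFactor must be > 0")
  chkNum("nHVG", lo = 1)
  chkNum("kNeighbors", lo = 1)
  chkNum("resolution", lo = 1e-12)
  chkNum("tpRings", lo = 1)
  chkNum("boRings", lo = 1)
  chkNum("alpha", lo = 1e-12, hi = 1 - 1e-12,
         msg = "alpha must lie strictly between 0 and 1")
  chkNum("B", lo = 100,
         msg = "B must be >= 100 (bootstrap co-occurrence precondition)")
  chkNum("nPerm", lo = 100)
  if (is.null(config$seed)) {
    errors <- c(errors, "seed is required and must be explicit")
  } else if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    errors <- c(errors, "seed must be a single integer")
  }
  list(config = config, errors = errors, defaultsApplied = applied)
}

# Internal: stable hash of the validated configuration.
.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[order(names(config))], file = f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline on one section
#'
#' Executes (optional) simulation, preprocessing, segmentation, pairwise
#' regional differential expression, gene-set enrichment, the anchor-gene
#' interactome, bootstrap co-occurrence with regional differentials, and
#' cluster-to-region similarity, writing each stage's tables plus a
#' manifest (file, md5) under `outDir`. Stage failures halt the run with
#' the stage named; outputs of earlier stages are retained. Deterministic
#' stages reproduce bit-identical outputs for identical configs.
#'
#' @param config Named list or YAML path; see [validateRunConfig()].
#'   Either `config$simulate = TRUE` (generate a section with
#'   `config$section` arguments) or `config$input` (a [writeSection()]
#'   style directory) must be supplied.
#' @param outDir Output directory.
#' @return Invisibly, a list with the `SpotExperiment`, the manifest and
#'   the stage outputs.
#' @export
runPipeline <- function(config, outDir) {
  vr <- validateRunConfig(config)
  if (length(vr$errors)) {
    stop("invalid config:\n  - ", paste(vr$errors, collapse = "\n  - "))
  }
  cfg <- vr$config
  hash <- .configHash(cfg)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  outputs <- list()
  log <- function(stage, msg) {
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  se <- stage("input", {
    if (isTRUE(cfg$simulate)) {
      log("input", "generating synthetic section")
      sc <- do.call(SectionConfig,
                    c(cfg$section, list(seed = cfg$seed)))
      generateSection(sc)
    } else if (!is.null(cfg$input)) {
      log("input", paste("reading", cfg$input))
      readSection(cfg$input)
    } else stop("config needs simulate = TRUE or an input directory")
  })

  se <- stage("preprocess", {
    log("preprocess", "lognormalize / scale / HVG / PCA / cluster")
    se <- logNormalize(se, scaleFactor = cfg$scaleFactor)
    se <- scaleGenes(se)
    hvg <- selectHVG(se, minMean = cfg$minMean, nTop = cfg$nHVG)
    writeTidyTSV(cbind(gene = rownames(hvg), as.data.frame(hvg)),
                 file.path(outDir, "hvg.tsv"), hash)
    pca <- pcaMP(se, genes = rownames(hvg)[hvg$selected], kMax = cfg$kMax)
    writeTidyTSV(data.frame(component = seq_along(pca@eigenvalues),
                            eigenvalue = pca@eigenvalues,
                            mp_upper_edge = pca@mpUpperEdge,
                            retained = seq_along(pca@eigenvalues) <=
                              pca@kRetained),
                 file.path(outDir, "eigenvalues.tsv"), hash)
    cl <- clusterSpots(pca, kNeighbors = cfg$kNeighbors,
                       resolution = cfg$resolution, seed = cfg$seed)
    writeTidyTSV(cl, file.path(outDir, "clusters.tsv"), hash)
    clusterLabels(se) <- cl$cluster
    metadata(se)$pca <- pca
    se
  })

  se <- stage("segment", {
    markers <- cfg$tumorMarkers
    if (is.null(markers)) {
      # default: genes of the core-enriched program when simulated
      markers <- grep("^Tum", rownames(se), value = TRUE)
    }
    if (!length(markers)) stop("no tumor markers available")
    score <- markerScore(se, markers)
    se <- segmentRegions(se, clusterLabels(se), score,
                         scoreThreshold = cfg$scoreThreshold,
                         tpRings = cfg$tpRings, boRings = cfg$boRings)
    writeTidyTSV(data.frame(barcode = colnames(se),
                            label = as.character(regionLabels(se)),
                            provenance = colData(se)$region_provenance),
                 file.path(outDir, "region_labels.tsv"), hash)
    se
  })

  deTables <- stage("de", {
    out <- list()
    for (pr in cfg$dePairs) {
      nm <- paste(pr, collapse = "_")
      tab <- tryCatch(wilcoxAUC(se, pr), error = function(e) NULL)
      if (is.null(tab)) { log("de", paste("skipping", nm)); next }
      writeTidyTSV(as.data.frame(tab),
                   file.path(outDir, paste0("de_", nm, ".tsv")), hash)
      out[[nm]] <- tab
    }
    out
  })

  gseaTables <- stage("gsea", {
    if (is.null(cfg$gmt) || !length(deTables)) list() else {
      sets <- readGMT(cfg$gmt)
      out <- list()
      for (nm in names(deTables)) {
        tab <- deTables[[nm]]
        r <- stats::setNames(tab$log2fc, tab$gene)
        g <- gseaPreranked(r, sets, nPerm = cfg$nPerm, seed = cfg$seed)
        keep <- setdiff(colnames(g), "leadingEdge")
        writeTidyTSV(as.data.frame(g[, keep]),
                     file.path(outDir, paste0("gsea_", nm, ".tsv")), hash)
        out[[nm]] <- g
      }
      out
    }
  })

  inter <- stage("interactome", {
    if (is.null(cfg$anchor) || is.null(cfg$partners)) NULL else {
      it <- interactomeTable(se, cfg$anchor, cfg$partners, minN = cfg$minN)
      writeTidyTSV(it$correlations,
                   file.path(outDir, "interactome_correlations.tsv"), hash)
      writeTidyTSV(it$comparisons,
                   file.path(outDir, "interactome_comparisons.tsv"), hash)
      it
    }
  })

  cooc <- stage("cooccur", {
    sig <- if (!is.null(cfg$markerLists)) {
      markerSignalMatrix(se, cfg$markerLists)
    } else if (!is.null(metadata(se)$truth_signals)) {
      metadata(se)$truth_signals[colnames(se), , drop = FALSE]
    } else NULL
    if (is.null(sig)) {
      res <- NULL
    } else {
    res <- cooccurrenceByRegion(sig, regionLabels(se),
                                B = cfg$B, alpha = cfg$alpha,
                                seed = cfg$seed)
    for (r in names(res)) {
      cc <- res[[r]]
      pairsIdx <- which(upper.tri(cc@mean), arr.ind = TRUE)
      writeTidyTSV(data.frame(
        signal1 = rownames(cc@mean)[pairsIdx[, 1L]],
        signal2 = colnames(cc@mean)[pairsIdx[, 2L]],
        mean_r = cc@mean[pairsIdx], ci_low = cc@ciLow[pairsIdx],
        ci_high = cc@ciHigh[pairsIdx],
        significant = cc@significant[pairsIdx]),
        file.path(outDir, paste0("cooccurrence_", r, ".tsv")), hash)
    }
    nm <- names(res)
    if (length(nm) >= 2L) {
      for (i in seq_len(length(nm) - 1L)) for (j in (i + 1L):length(nm)) {
        d <- differentialCooccurrence(res[[nm[i]]], res[[nm[j]]])
        writeTidyTSV(d, file.path(outDir, paste0(
          "cooccurrence_diff_", nm[i], "_", nm[j], ".tsv")), hash)
      }
    }
    }
    res
  })

  sim <- stage("similarity", {
    if (is.null(regionLabels(se)) || is.null(clusterLabels(se))) NULL else {
      inReg <- regionLabels(se) %in% c("TC", "TP", "BO", "BR")
      ref <- groupProfiles(se[, inReg],
                           droplevels(regionLabels(se)[inReg]))
      qry <- groupProfiles(se, paste0("cluster", clusterLabels(se)))
      sc <- scaledCosine(qry, ref)
      writeTidyTSV(cbind(query = rownames(sc$similarity),
                         as.data.frame(sc$similarity)),
                   file.path(outDir, "similarity.tsv"), hash)
      writeTidyTSV(sc$assignment,
                   file.path(outDir, "similarity_assignment.tsv"), hash)
      sc
    }
  })

  files <- setdiff(list.files(outDir, full.names = TRUE),
                   file.path(outDir, "manifest.tsv"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  writeTidyTSV(manifest, file.path(outDir, "manifest.tsv"), hash)
  log("done", paste(nrow(manifest), "files written"))
  invisible(list(se = se, manifest = manifest, de = deTables,
                 gsea = gseaTables, interactome = inter,
                 cooccurrence = cooc, similarity = sim))
}
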