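#' Bootstrap co-occurrence of cell-type signals
#'
#' The four-step bootstrap: (1) resample the spots with replacement (same
#' size), `B` times; (2) compute the full Pearson correlation matrix on each
#' resample, skipping replicates in which any signal is constant (count
#' reported); (3) aggregate as the mean correlation per signal pair over
#' valid replicates, with the empirical `(alpha/2, 1 - alpha/2)` quantiles
#' as confidence bounds; (4) flag as significant every pair whose confidence
#' interval does not cross zero.
#'
#' A signal constant over the whole region yields NA rows/columns with all
#' other pairs still computed; fewer than 50% valid replicates is an error.
#' Reproducible given `seed`; the global RNG state is left untouched.
#'
#' @param signals Numeric matrix, spots x signals (`>= 2` named columns).
#' @param B Bootstrap replicates, `>= 100` (default 1000).
#' @param alpha CI significance level (default 0.05).
#' @param seed Integer seed.
#' @param region Region label recorded in the result.
#' @return A [Cooccurrence-class].
#' @export
bootstrapCooccurrence <- function(signals, B = 1000, alpha = 0.05, seed = 1,
                                  region = "all") {
  signals <- as.matrix(signals)
  n <- nrow(signals); p <- ncol(signals)
  if (p < 2L) stop("need >= 2 signals")
  if (n < 10L) stop("need >= 10 spots in region, have ", n)
  if (B < 100L) stop("B must be >= 100")
  if (is.null(colnames(signals))) {
    colnames(signals) <- paste0("signal", seq_len(p))
  }
  constAll <- apply(signals, 2L, function(v) stats::sd(v) == 0)
  if (all(constAll)) stop("all signals are constant over the region")
  live <- which(!constAll)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  reps <- array(NA_real_, dim = c(p, p, B),
                dimnames = list(colnames(signals), colnames(signals), NULL))
  skipped <- 0L
  sub <- signals[, live, drop = FALSE]
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rs <- sub[idx, , drop = FALSE]
    # a constant signal in the resample makes Pearson undefined (NA)
    cm <- suppressWarnings(stats::cor(rs))
    if (anyNA(cm)) {
      skipped <- skipped + 1L
      next
    }
    reps[live, live, b] <- cm
  }
  valid <- B - skipped
  if (valid < B / 2) {
    stop("fewer than 50% valid bootstrap replicates (", valid, "/", B, ")")
  }
  mean_ <- apply(reps, c(1L, 2L), mean, na.rm = TRUE)
  qs <- apply(reps, c(1L, 2L), stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
  ciLow <- qs[1L, , ]; ciHigh <- qs[2L, , ]
  mean_[constAll, ] <- NA; mean_[, constAll] <- NA
  ciLow[constAll, ] <- NA; ciLow[, constAll] <- NA
  ciHigh[constAll, ] <- NA; ciHigh[, constAll] <- NA
  sig <- ifelse(ciLow > 0 | ciHigh < 0, 1, 0)
  new("Cooccurrence", region = region, mean = mean_, ciLow = ciLow,
      ciHigh = ciHigh, significant = sig, B = as.integer(B),
      alpha = alpha, nSkipped = skipped, replicates = reps)
}

#' Per-region bootstrap co-occurrence
#'
#' Applies [bootstrapCooccurrence()] separately to the spots of each
#' region. Each region gets its own reproducible bootstrap stream derived
#' from the root seed as `seed + region index` (in the order of `regions`).
#'
#' @param signals Spots x signals matrix aligned to `labels`.
#' @param labels Per-spot region labels.
#' @param regions Regions to process (default `TC, TP, BO, BR`).
#' @param B,alpha,seed As in [bootstrapCooccurrence()].
#' @return Named list of [Cooccurrence-class], one per region with enough
#'   spots.
#' @export
cooccurrenceByRegion <- function(signals, labels, regions = .REGIONS,
                                 B = 1000, alpha = 0.05, seed = 1) {
  signals <- as.matrix(signals)
  stopifnot(nrow(signals) == length(labels))
  out <- list()
  for (i in seq_along(regions)) {
    r <- regions[i]
    spots <- which(labels == r)
    if (length(spots) < 10L) {
      warning("region ", r, " has fewer than 10 spots; skipped")
      next
    }
    out[[r]] <- bootstrapCooccurrence(signals[spots, , drop = FALSE],
                                      B = B, alpha = alpha,
                                      seed = seed + i, region = r)
  }
  out
}

#' Differential co-occurrence between two regions
#'
#' Per signal pair, the difference of bootstrap mean correlations
#' `delta = mean_A - mean_B` (second region subtracted from the first),
#' with a bootstrap CI for the difference obtained by pairing the two
#' regions' independent replicate streams by index and taking the
#' `(alpha/2, 1 - alpha/2)` quantiles of the per-replicate differences.
#'
#' @param resA,resB [Cooccurrence-class] results with identical signal
#'   names.
#' @return A `data.frame` with one row per unordered signal pair:
#'   `delta`, `ciLow`, `ciHigh`, `excludesZero`, and the two regions. The
#'   sign convention is recorded in the `sign_convention` attribute.
#' @export
differentialCooccurrence <- function(resA, resB) {
  if (!identical(rownames(resA@mean), rownames(resB@mean))) {
    stop("signal names differ between the two results")
  }
  sig <- rownames(resA@mean)
  p <- length(sig)
  alpha <- resA@alpha
  dreps <- resA@replicates - resB@replicates   # NA where either is skipped
  rows <- list()
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      delta <- resA@mean[i, j] - resB@mean[i, j]
      ds <- dreps[i, j, ]
      ds <- ds[!is.na(ds)]
      if (is.na(delta) || !length(ds)) {
        rows[[length(rows) + 1L]] <- data.frame(
          signal1 = sig[i], signal2 = sig[j],
          regionA = resA@region, regionB = resB@region,
          delta = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
          excludesZero = NA)
        next
      }
      q <- stats::quantile(ds, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        signal1 = sig[i], signal2 = sig[j],
        regionA = resA@region, regionB = resB@region,
        delta = delta, ciLow = q[1L], ciHigh = q[2L],
        excludesZero = q[1L] > 0 | q[2L] < 0)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "sign_convention") <- "regionB subtracted from regionA"
  out
}

#' Marker-score cell-type signal matrix
#'
#' Default stand-in for externally supplied deconvolution: one signal per
#' marker list, each the [markerScore()] (mean z-scored lognorm expression)
#' of the list.
#'
#' @param x Object with a `lognorm` assay.
#' @param markerLists Named list of gene id vectors.
#' @param assay Assay name (default `"lognorm"`).
#' @return Spots x signals numeric matrix with attribute
#'   `provenance = "marker-score"`.
#' @export
markerSignalMatrix <- function(x, markerLists, assay = "lognorm") {
  stopifnot(length(markerLists) >= 1L, !is.null(names(markerLists)))
  cols <- lapply(names(markerLists), function(nm) {
    present <- intersect(markerLists[[nm]], rownames(x))
    if (!length(present)) {
      stop("marker list '", nm, "' has no genes present in the matrix")
    }
    markerScore(x, present, assay = assay)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- names(markerLists)
  rownames(out) <- colnames(x)
  attr(out, "provenance") <- "marker-score"
  out
}
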