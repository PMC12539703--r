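#' Region-stratified Spearman gene-pair correlation
#'
#' Midrank Spearman correlation per gene pair within each region's spots,
#' with p-values from the t-approximation (`n - 2` df) and BH adjustment
#' within each region across the tested pair family. Computed on lognorm
#' values by default.
#'
#' @param x Object with the chosen assay and region labels.
#' @param pairs Two-column matrix or data.frame of gene ids.
#' @param labels Optional labels (defaults to `regionLabels(x)`).
#' @param regions Regions to stratify on (default the four tissue strata).
#' @param minN Minimum spots per region (default 10); smaller regions are
#'   reported with NA and a reason.
#' @param assay Assay name (default `"lognorm"`).
#' @return A `data.frame` with `gene1`, `gene2`, `region`, `n`, `rho`, `p`,
#'   `q`, `reason`.
#' @export
spearmanByRegion <- function(x, pairs, labels = regionLabels(x),
                             regions = .REGIONS, minN = 10,
                             assay = "lognorm") {
  if (is.null(labels)) stop("no region labels assigned")
  pairs <- as.matrix(pairs)
  genes <- unique(as.vector(pairs))
  miss <- setdiff(genes, rownames(x))
  if (length(miss)) stop("genes not in matrix: ", paste(miss, collapse = ", "))
  m <- as.matrix(SummarizedExperiment::assay(x, assay)[genes, , drop = FALSE])
  rows <- list()
  for (r in regions) {
    spots <- which(labels == r)
    n <- length(spots)
    for (i in seq_len(nrow(pairs))) {
      g1 <- pairs[i, 1L]; g2 <- pairs[i, 2L]
      if (n < minN) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene1 = g1, gene2 = g2, region = r, n = n, rho = NA_real_,
          p = NA_real_, reason = "too few spots")
        next
      }
      v1 <- m[g1, spots]; v2 <- m[g2, spots]
      if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene1 = g1, gene2 = g2, region = r, n = n, rho = NA_real_,
          p = NA_real_, reason = "zero variance")
        next
      }
      rho <- stats::cor(v1, v2, method = "spearman")
      p <- if (abs(rho) >= 1) 0 else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        2 * stats::pt(-abs(tstat), df = n - 2)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene1 = g1, gene2 = g2, region = r, n = n, rho = rho, p = p,
        reason = "")
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (r in regions) {
    sel <- out$region == r
    out$q[sel] <- bhAdjust(out$p[sel])
  }
  out
}

#' Fisher-transformation comparison of two correlation coefficients
#'
#' `z_i = atanh(rho_i)`; the statistic
#' `(z1 - z2) / sqrt(1/(n1 - 3) + 1/(n2 - 3))` is referred two-sided to a
#' t-distribution with `n1 + n2 - 6` degrees of freedom (`ref = "t"`, the
#' default), or to the standard normal (`ref = "normal"`).
#'
#' @param rho1,rho2 Sample correlations with `|rho| < 1`.
#' @param n1,n2 Sample sizes, both `>= 4`.
#' @param ref Reference distribution.
#' @return A list with `statistic` and `p`.
#' @export
fisherCompare <- function(rho1, n1, rho2, n2, ref = c("t", "normal")) {
  ref <- match.arg(ref)
  if (any(abs(c(rho1, rho2)) >= 1)) stop("degenerate correlation: |rho| = 1")
  if (n1 < 4 || n2 < 4) stop("need n1, n2 >= 4")
  stat <- (atanh(rho1) - atanh(rho2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (ref == "t") {
    2 * stats::pt(-abs(stat), df = n1 + n2 - 6)
  } else {
    2 * stats::pnorm(-abs(stat))
  }
  list(statistic = stat, p = p)
}

#' Anchor-gene interactome across regions
#'
#' For one anchor gene and a set of partner genes, computes the
#' region-stratified Spearman correlations and, for every pair of regions,
#' the Fisher-transformation comparison of the two correlation
#' coefficients. BH adjustment runs across the full comparison family
#' emitted by the invocation.
#'
#' @param x Object with the chosen assay and region labels.
#' @param anchor Anchor gene id.
#' @param partners Character vector of partner gene ids.
#' @param labels,regions,minN,assay As in [spearmanByRegion()].
#' @param ref Reference distribution for [fisherCompare()].
#' @return A list with `correlations` (the [spearmanByRegion()] table) and
#'   `comparisons` (per partner x region pair: `rho1`, `n1`, `rho2`, `n2`,
#'   `statistic`, `p`, `q`, `reason`).
#' @export
interactomeTable <- function(x, anchor, partners,
                             labels = regionLabels(x), regions = .REGIONS,
                             minN = 10, assay = "lognorm",
                             ref = c("t", "normal")) {
  ref <- match.arg(ref)
  if (!anchor %in% rownames(x)) stop("anchor gene not found: ", anchor)
  pairs <- cbind(anchor, partners)
  cors <- spearmanByRegion(x, pairs, labels = labels, regions = regions,
                           minN = minN, assay = assay)
  rp <- t(utils::combn(regions, 2L))
  rows <- list()
  for (g in partners) {
    sub <- cors[cors$gene2 == g, ]
    for (i in seq_len(nrow(rp))) {
      r1 <- rp[i, 1L]; r2 <- rp[i, 2L]
      a <- sub[sub$region == r1, ]; b <- sub[sub$region == r2, ]
      row <- data.frame(anchor = anchor, partner = g,
                        region1 = r1, region2 = r2,
                        rho1 = a$rho, n1 = a$n, rho2 = b$rho, n2 = b$n,
                        statistic = NA_real_, p = NA_real_, reason = "")
      if (is.na(a$rho) || is.na(b$rho)) {
        row$reason <- paste(unique(c(a$reason, b$reason)[
          c(is.na(a$rho), is.na(b$rho))]), collapse = "; ")
      } else if (abs(a$rho) >= 1 || abs(b$rho) >= 1) {
        row$reason <- "degenerate correlation"
      } else {
        fc <- fisherCompare(a$rho, a$n, b$rho, b$n, ref = ref)
        row$statistic <- fc$statistic
        row$p <- fc$p
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  comp <- do.call(rbind, rows)
  comp$q <- bhAdjust(comp$p)
  attr(comp, "bh_family") <- sprintf("%d partners x %d region pairs",
                                     length(partners), nrow(rp))
  list(correlations = cors, comparisons = comp)
}
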