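#' Rank-sum (Wilcoxon) AUC differential expression between two regions
#'
#' Per gene, the Mann-Whitney U statistic of region A versus region B with
#' midrank tie handling; `auc = U / (nA * nB)` is the probability that a
#' random A spot exceeds a random B spot (ties counted half). P-values come
#' from exact enumeration (`nA * nB <= 10000`, no ties in the gene) or the
#' normal approximation with tie-corrected variance and continuity
#' correction; the effect size is the difference of mean lognorm values
#' rescaled to log2 units. BH adjustment is applied across genes within the
#' pair.
#'
#' @param x Object with a `lognorm` assay and region labels.
#' @param pair Character 2-vector, e.g. `c("TC", "TP")`: A then B.
#' @param labels Optional labels (defaults to `regionLabels(x)`).
#' @param assay Assay name (default `"lognorm"`).
#' @return A [S4Vectors::DataFrame] with per-gene `auc`, `log2fc`, `p`, `q`,
#'   `nA`, `nB`.
#' @export
wilcoxAUC <- function(x, pair, labels = regionLabels(x), assay = "lognorm") {
  if (is.null(labels)) stop("no region labels assigned")
  stopifnot(length(pair) == 2L)
  a <- which(labels == pair[1L]); b <- which(labels == pair[2L])
  for (i in 1:2) {
    if (length(list(a, b)[[i]]) < 3L) {
      stop("region ", pair[i], " has fewer than 3 spots")
    }
  }
  m <- as.matrix(SummarizedExperiment::assay(x, assay)[, c(a, b), drop = FALSE])
  nA <- length(a); nB <- length(b); N <- nA + nB
  exactOK <- nA * nB <= 10000
  res <- t(apply(m, 1L, function(v) {
    r <- rank(v)
    U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    ties <- table(v)
    tieSum <- sum(ties^3 - ties)
    if (exactOK && tieSum == 0) {
      p <- 2 * min(stats::pwilcox(U, nA, nB),
                   1 - stats::pwilcox(U - 1, nA, nB))
      p <- min(p, 1)
    } else {
      V <- nA * nB / 12 * ((N + 1) - tieSum / (N * (N - 1)))
      if (V <= 0) {
        p <- 1
      } else {
        z <- (U - nA * nB / 2)
        z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(V)
        p <- 2 * stats::pnorm(-abs(z))
      }
    }
    c(U / (nA * nB), p)
  }))
  lfc <- (rowMeans(m[, seq_len(nA), drop = FALSE]) -
          rowMeans(m[, nA + seq_len(nB), drop = FALSE])) / log(2)
  DataFrame(gene = rownames(m), auc = unname(res[, 1L]),
            log2fc = unname(lfc), p = unname(res[, 2L]),
            q = unname(bhAdjust(res[, 2L])),
            nA = nA, nB = nB, row.names = rownames(m))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`: p-values must
#' lie in `[0, 1]`; `NA`s are passed through and do not count toward the
#' number of tests.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
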