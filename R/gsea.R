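# Internal: enrichment score for hits at (sorted) positions `pos` in a
# ranking of length N with per-position weights |score|. The running sum
# gains |s_i|/sum(|s_hits|) at a hit and loses 1/(N - k) at each miss, and
# only needs evaluating just before and just after each hit: the maximum
# deviation over the whole walk occurs at one of those points (the sum is
# monotone decreasing between hits).
.esAtHits <- function(pos, w, N) {
  k <- length(pos)
  o <- order(pos)
  pos <- pos[o]; w <- abs(w[o])
  W <- sum(w)
  if (W == 0) return(NA_real_)
  miss <- 1 / (N - k)
  cumw <- cumsum(w) / W
  missesBefore <- pos - seq_len(k)
  after <- cumw - missesBefore * miss
  before <- after - w / W
  hi <- max(after, 0)
  lo <- min(before, 0)
  es <- if (hi >= -lo) hi else lo
  attr(es, "peak") <- if (hi >= -lo) pos[which.max(after)] else
    pos[which.min(before)]
  es
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment (weight exponent 1)
#' over a descending ranking: hits increment by `|score| / sum_set |score|`,
#' misses decrement by `1 / (N - size)`; the enrichment score ES is the
#' maximum deviation from zero. The null is built from `nPerm` random
#' same-size gene draws; the p-value is the one-sided empirical tail for
#' the observed sign with +1 smoothing, and `NES = ES / mean(|null ES|)`
#' over null draws of the same sign. Sets are filtered to genes present in
#' the ranking and to `minSize <= size <= maxSize`; a set spanning the whole
#' ranking is refused (the miss decrement is undefined).
#'
#' @param scores Named numeric vector of per-gene ranking scores (unique
#'   names), e.g. log2 fold-changes from [wilcoxAUC()].
#' @param sets Named list of character vectors ([readGMT()]); members are
#'   matched case-insensitively.
#' @param nPerm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param minSize,maxSize Set size bounds after filtering (defaults 5, 500).
#' @return A [S4Vectors::DataFrame] with per-set `ES`, `NES`, `p`, `q`,
#'   `size` and `leadingEdge` (list column).
#' @export
gseaPreranked <- function(scores, sets, nPerm = 1000, seed = 1,
                          minSize = 5, maxSize = 500) {
  if (anyDuplicated(names(scores))) stop("ranking has duplicate gene ids")
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  genesUp <- toupper(names(scores))
  N <- length(scores)
  w <- abs(scores)

  keep <- list(); posList <- list()
  for (s in names(sets)) {
    pos <- which(genesUp %in% toupper(sets[[s]]))
    if (length(pos) == N) {
      warning("set ", s, " spans the whole ranking; ",
              "miss decrement undefined, set refused")
    } else if (length(pos) >= minSize && length(pos) <= maxSize) {
      keep[[s]] <- TRUE; posList[[s]] <- pos
    }
  }
  if (!length(posList)) {
    return(DataFrame(set = character(0), ES = numeric(0), NES = numeric(0),
                     p = numeric(0), q = numeric(0), size = integer(0)))
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  sizes <- lengths(posList)
  nullES <- lapply(sort(unique(sizes)), function(k) {
    vapply(seq_len(nPerm), function(b) {
      pos <- sample.int(N, k)
      as.numeric(.esAtHits(pos, w[pos], N))
    }, numeric(1))
  })
  names(nullES) <- as.character(sort(unique(sizes)))

  res <- lapply(names(posList), function(s) {
    pos <- posList[[s]]
    es <- .esAtHits(pos, w[pos], N)
    if (is.na(es)) {
      warning("set ", s, " has zero total |score|; ES undefined")
      return(list(set = s, ES = NA_real_, NES = NA_real_, p = NA_real_,
                  size = length(pos), leadingEdge = list(character(0))))
    }
    peak <- attr(es, "peak"); es <- as.numeric(es)
    null <- nullES[[as.character(length(pos))]]
    if (es >= 0) {
      same <- null[null >= 0]
      p <- (1 + sum(same >= es)) / (1 + length(same))
      le <- names(scores)[intersect(pos, seq_len(peak))]
    } else {
      same <- null[null < 0]
      p <- (1 + sum(same <= es)) / (1 + length(same))
      le <- names(scores)[intersect(pos, peak:N)]
    }
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    list(set = s, ES = es, NES = nes, p = p, size = length(pos),
         leadingEdge = list(le))
  })
  out <- DataFrame(
    set = vapply(res, `[[`, character(1), "set"),
    ES = vapply(res, `[[`, numeric(1), "ES"),
    NES = vapply(res, `[[`, numeric(1), "NES"),
    p = vapply(res, `[[`, numeric(1), "p"),
    size = vapply(res, `[[`, integer(1), "size")
  )
  out$q <- bhAdjust(out$p)
  out$leadingEdge <- lapply(res, function(r) r$leadingEdge[[1L]])
  rownames(out) <- out$set
  out
}
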