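#' Mean expression profiles per group
#'
#' @param x Object with the chosen assay, or a genes x spots matrix.
#' @param grouping Per-spot labels (clusters or regions); spots with NA
#'   labels are excluded with a count warning.
#' @param assay Assay name (default `"lognorm"`).
#' @return A groups x genes numeric matrix with a `groupSizes` attribute.
#' @export
groupProfiles <- function(x, grouping, assay = "lognorm") {
  m <- if (methods::is(x, "SummarizedExperiment")) {
    as.matrix(SummarizedExperiment::assay(x, assay))
  } else as.matrix(x)
  grouping <- as.character(grouping)
  if (anyNA(grouping)) {
    warning(sum(is.na(grouping)), " unlabeled spot(s) excluded")
    m <- m[, !is.na(grouping), drop = FALSE]
    grouping <- grouping[!is.na(grouping)]
  }
  groups <- unique(grouping)
  prof <- t(vapply(groups, function(g) {
    rowMeans(m[, grouping == g, drop = FALSE])
  }, numeric(nrow(m))))
  rownames(prof) <- groups
  attr(prof, "groupSizes") <- stats::setNames(
    as.integer(table(grouping)[groups]), groups)
  prof
}

# Internal: plain cosine similarity between the rows of two matrices.
.cosineRows <- function(A, B) {
  num <- A %*% t(B)
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  out <- num / outer(na, nb)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Scaled cosine similarity of query profiles to reference profiles
#'
#' Restricts both profile matrices to their shared genes (matched by
#' uppercased symbol, or through an explicit ortholog map), z-scales each
#' gene across the union of query and reference groups, and computes the
#' cosine similarity between every query row and every reference row. Each
#' query group is assigned the reference label with the largest similarity.
#'
#' @param query,reference Groups x genes profile matrices
#'   ([groupProfiles()]).
#' @param scale Z-scale genes across the pooled groups first (default
#'   `TRUE`); `FALSE` gives the raw cosine kernel.
#' @param orthologMap Optional two-column data.frame (`from`, `to`) mapping
#'   query gene symbols to reference symbols before the uppercase match.
#' @return A list with `similarity` (query x reference matrix) and
#'   `assignment` (per query group: best reference label and similarity).
#' @export
scaledCosine <- function(query, reference, scale = TRUE, orthologMap = NULL) {
  if (is.null(rownames(query))) {
    rownames(query) <- paste0("query", seq_len(nrow(query)))
  }
  if (is.null(rownames(reference))) {
    rownames(reference) <- paste0("ref", seq_len(nrow(reference)))
  }
  qn <- toupper(colnames(query)); rn <- toupper(colnames(reference))
  if (!is.null(orthologMap)) {
    m <- match(qn, toupper(orthologMap[[1L]]))
    qn[!is.na(m)] <- toupper(orthologMap[[2L]])[m[!is.na(m)]]
  }
  shared <- intersect(qn, rn)
  if (length(shared) < 10L) {
    stop("only ", length(shared), " shared gene(s) after harmonization; ",
         "need >= 10")
  }
  Q <- query[, match(shared, qn), drop = FALSE]
  R <- reference[, match(shared, rn), drop = FALSE]
  M <- rbind(Q, R)
  if (scale) {
    mu <- colMeans(M)
    sdv <- apply(M, 2L, stats::sd)
    M <- sweep(M, 2L, mu, "-")
    M <- sweep(M, 2L, ifelse(sdv > 0, sdv, 1), "/")
    M[, sdv == 0] <- 0
  }
  Q <- M[seq_len(nrow(query)), , drop = FALSE]
  R <- M[nrow(query) + seq_len(nrow(reference)), , drop = FALSE]
  sim <- .cosineRows(Q, R)
  dimnames(sim) <- list(rownames(query), rownames(reference))
  best <- apply(sim, 1L, which.max)
  assignment <- data.frame(
    query = rownames(query),
    reference = rownames(reference)[best],
    similarity = sim[cbind(seq_len(nrow(sim)), best)]
  )
  list(similarity = sim, assignment = assignment)
}

#' Dot-plot summary statistics
#'
#' Per group and gene: the percentage of spots with nonzero expression
#' (dot size) and the mean lognorm expression over all group spots (dot
#' color).
#'
#' @param x Object with the chosen assay.
#' @param grouping Per-spot labels.
#' @param genes Genes to summarize; missing genes are reported in a warning
#'   and the rest computed.
#' @param assay Assay name (default `"lognorm"`).
#' @return A `data.frame` with `gene`, `group`, `pctExpressing`
#'   (in `[0, 100]`), `meanExpression`.
#' @export
dotStats <- function(x, grouping, genes, assay = "lognorm") {
  m <- SummarizedExperiment::assay(x, assay)
  miss <- setdiff(genes, rownames(m))
  if (length(miss)) {
    warning("genes not found, skipped: ", paste(miss, collapse = ", "))
    genes <- setdiff(genes, miss)
  }
  if (!length(genes)) stop("none of the requested genes are present")
  m <- as.matrix(m[genes, , drop = FALSE])
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  rows <- list()
  for (g in groups) {
    sub <- m[, grouping == g, drop = FALSE]
    rows[[g]] <- data.frame(
      gene = genes, group = g,
      pctExpressing = 100 * rowMeans(sub > 0),
      meanExpression = rowMeans(sub))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
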