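#' Visium hex-lattice geometry
#'
#' Visium spots sit on a hexagonal lattice encoded by array coordinates
#' `(row, col)` with `row + col` even. Each spot has six neighbors:
#' `(row ± 1, col ± 1)` and `(row, col ± 2)`.
#'
#' @param row,col Integer array coordinates of one spot; `row + col` must be
#'   even.
#' @return `hexNeighbors`: an integer matrix with 6 rows and columns
#'   `row`, `col` listing the lattice neighbors. Callers are responsible for
#'   intersecting with in-tissue spots.
#' @examples
#' hexNeighbors(2, 4)
#' @export
hexNeighbors <- function(row, col) {
  stopifnot(length(row) == 1L, length(col) == 1L)
  if ((row + col) %% 2L != 0L) {
    stop("hex parity violation: row + col must be even, got (",
         row, ", ", col, ")")
  }
  out <- cbind(
    row = as.integer(row + c(-1L, -1L, 1L, 1L, 0L, 0L)),
    col = as.integer(col + c(-1L, 1L, -1L, 1L, -2L, 2L))
  )
  out
}

#' Closed-form hex distance on the full lattice
#'
#' Maps `(row, col)` to axial coordinates `u = (col + row)/2`,
#' `v = (col - row)/2`, where the six neighbors become
#' `(±1, 0), (0, ±1), (±1, ±1)` (same sign), the standard axial hexagon.
#' Used by the synthetic generator (full-lattice geometry) and as an
#' independent oracle for the BFS distance.
#'
#' @param row1,col1,row2,col2 Vectors of array coordinates (even parity).
#' @return Integer vector of hex step distances.
#' @export
hexDistance <- function(row1, col1, row2, col2) {
  if (any((row1 + col1) %% 2L != 0L) || any((row2 + col2) %% 2L != 0L)) {
    stop("hex parity violation: row + col must be even")
  }
  du <- (col2 + row2 - col1 - row1) %/% 2L
  dv <- (col2 - row2 - col1 + row1) %/% 2L
  same <- sign(du) * sign(dv) >= 0
  ifelse(same, pmax(abs(du), abs(dv)), abs(du) + abs(dv))
}

# Internal: integer key for (row, col) pairs, for O(1) lattice lookups.
.hexKey <- function(row, col) row * 10000L + col

#' Multi-source BFS hex distance restricted to a spot set
#'
#' Breadth-first search over the 6-neighbor lattice restricted to the given
#' spots (typically the in-tissue spots). Distances are counted in hex steps
#' from the nearest source spot; spots unreachable from any source get `Inf`.
#'
#' @param coords Two-column integer matrix (`row`, `col`) of the traversable
#'   spots.
#' @param sources Logical or integer index of source spots within `coords`.
#' @return Numeric vector of distances aligned to the rows of `coords`.
#' @export
hexBFS <- function(coords, sources) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.logical(sources)) sources <- which(sources)
  key <- .hexKey(coords[, 1L], coords[, 2L])
  idx <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = idx)
  dist <- rep(Inf, n)
  dist[sources] <- 0
  frontier <- as.integer(sources)
  dr <- c(-1L, -1L, 1L, 1L, 0L, 0L)
  dc <- c(-1L, 1L, -1L, 1L, -2L, 2L)
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- integer(0)
    for (i in frontier) {
      nk <- .hexKey(coords[i, 1L] + dr, coords[i, 2L] + dc)
      for (k in nk) {
        j <- idx[[as.character(k)]]
        if (!is.null(j) && dist[j] > d) {
          dist[j] <- d
          nxt <- c(nxt, j)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# Internal: connected components of a spot set under hex adjacency.
# Returns an integer component id per row of coords.
.hexComponents <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    reach <- is.finite(hexBFS(coords, s))
    comp[reach] <- cur
  }
  comp
}
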