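#' Pearson correlation matrix of regional time series
#'
#' Correlates all region pairs; the diagonal is set to 0 by convention.
#'
#' @param ts a [RoiTimeSeries-class] with at least 3 time points.
#' @return a [ConnectivityMatrix-class].
#' @export
correlationMatrix <- function(ts) {
  stopifnot(is(ts, "RoiTimeSeries"))
  if (nrow(ts@data) < 3L) stop("need at least 3 time points")
  sds <- apply(ts@data, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(ts@roiLabels[sds == 0], collapse = ", "))
  r <- stats::cor(ts@data)
  diag(r) <- 0
  dimnames(r) <- NULL
  new("ConnectivityMatrix", r = r, roiLabels = ts@roiLabels)
}

#' The sparsity threshold grid
#'
#' @param low,high,step grid limits and spacing; defaults 0.10 to 0.34 in
#'   steps of 0.01 (25 values).
#' @return strictly increasing numeric vector of sparsity values in (0,1).
#' @export
sparsityGrid <- function(low = 0.10, high = 0.34, step = 0.01) {
  g <- seq(low, high, by = step)
  if (length(g) < 1L || any(g <= 0) || any(g >= 1) || is.unsorted(g, strictly = TRUE))
    stop("sparsity grid must be strictly increasing within (0,1)")
  g
}

# Upper-triangle pair order by decreasing |r|, ties broken by lowest (i, j)
# lexicographic index -- deterministic across platforms.
.rankedPairs <- function(r) {
  n <- nrow(r)
  ut <- .upperPairs(n)
  a <- abs(r[ut])
  ut[order(-a, ut[, 1], ut[, 2], method = "radix"), , drop = FALSE]
}

#' Binarize a connectivity matrix at a sparsity target
#'
#' Keeps exactly \code{K = round(s * N(N-1)/2)} edges: the K node pairs with
#' the largest absolute correlation (negative correlations can become edges),
#' K rounded half away from zero, ties at the cutoff broken by lowest (i, j)
#' lexicographic index. The result is symmetric with zero diagonal.
#'
#' @param C a [ConnectivityMatrix-class].
#' @param s sparsity in (0,1): target edge fraction of the N(N-1)/2 pairs.
#' @return an [AdjacencyMatrix-class] with exactly K edges.
#' @export
binarizeAtSparsity <- function(C, s) {
  stopifnot(is(C, "ConnectivityMatrix"), s > 0, s < 1)
  n <- nrow(C@r)
  M <- n * (n - 1) / 2
  K <- floor(s * M + 0.5)        # round half away from zero
  if (K < 1L) stop("sparsity target yields zero edges (degenerate network)")
  top <- .rankedPairs(C@r)[seq_len(K), , drop = FALSE]
  a <- matrix(0, n, n)
  a[top] <- 1
  a <- a + t(a)
  new("AdjacencyMatrix", a = a, sparsity = s)
}

#' Binarize across the whole sparsity grid
#'
#' One adjacency matrix per grid value; because the retained pairs are a
#' deterministic top-K prefix of the same ranking, edge sets are nested
#' along the grid.
#'
#' @param C a [ConnectivityMatrix-class].
#' @param grid numeric vector from [sparsityGrid()].
#' @return named list of [AdjacencyMatrix-class], one per grid value.
#' @export
sparsitySweep <- function(C, grid = sparsityGrid()) {
  stopifnot(is(C, "ConnectivityMatrix"))
  n <- nrow(C@r)
  M <- n * (n - 1) / 2
  ranked <- .rankedPairs(C@r)
  out <- lapply(grid, function(s) {
    K <- floor(s * M + 0.5)
    if (K < 1L) stop("sparsity target yields zero edges (degenerate network)")
    a <- matrix(0, n, n)
    a[ranked[seq_len(K), , drop = FALSE]] <- 1
    a <- a + t(a)
    new("AdjacencyMatrix", a = a, sparsity = s)
  })
  names(out) <- sprintf("%.2f", grid)
  out
}
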