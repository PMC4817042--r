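# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a label, so each
# subject / stage consumes an independent named sub-stream regardless of how
# many other draws happen elsewhere.
.deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Eigen-based multivariate normal sampler (zero mean, covariance Sigma).
.rmvn <- function(n, Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * ncol(Sigma)), n, ncol(Sigma))
  z %*% t(e$vectors %*% diag(sqrt(lam), length(lam)))
}

#' Project a symmetric matrix to the nearest positive semi-definite
#' correlation matrix
#'
#' Eigenvalue clipping followed by re-normalisation to unit diagonal. Used to
#' keep planted-effect target matrices valid covariance structures while
#' preserving the sign and (approximately) the magnitude of planted entries.
#'
#' @param S symmetric numeric matrix with unit diagonal.
#' @param epsilon smallest allowed eigenvalue after clipping.
#' @return a symmetric positive semi-definite matrix with unit diagonal.
#' @export
nearestPsdCorrelation <- function(S, epsilon = 1e-8) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) >= epsilon) return((S + t(S)) / 2)
  lam <- pmax(e$values, epsilon)
  R <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  (R + t(R)) / 2
}

# Upper-triangle index pairs (i < j) of an n x n matrix, in lexicographic
# order by (i, j).
.upperPairs <- function(n) {
  j <- rep(seq_len(n), times = seq_len(n) - 1L)
  i <- unlist(lapply(seq_len(n), function(k) seq_len(k - 1L)), use.names = FALSE)
  cbind(i = i, j = j)
}

# Union-find over n nodes; edges is a 2-column matrix. Returns component id
# per node (only nodes touching an edge are meaningful to callers).
.unionFind <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

# Fisher z-transform, clipped away from |r| = 1 for numerical safety.
.fisherZ <- function(r) atanh(pmin(pmax(r, -0.999999), 0.999999))
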