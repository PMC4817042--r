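# Brute-force graph-metric oracles, independent of the package internals:
# Floyd-Warshall distances, exhaustive neighbour-pair triangle counting, and
# betweenness by explicit enumeration of all shortest paths. Only meant for
# tiny graphs.

oracleDistances <- function(a) {
  n <- nrow(a)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[a > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracleClustering <- function(a) {
  n <- nrow(a)
  ci <- vapply(seq_len(n), function(i) {
    nbr <- which(a[i, ] > 0)
    k <- length(nbr)
    if (k < 2) return(0)
    t <- 0
    for (p in seq_len(k - 1)) for (q in (p + 1):k)
      if (a[nbr[p], nbr[q]] > 0) t <- t + 1
    2 * t / (k * (k - 1))
  }, numeric(1))
  list(Cp = mean(ci), perNode = ci)
}

oracleLp <- function(a) {
  D <- oracleDistances(a)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

oracleEglob <- function(a) {
  D <- oracleDistances(a)
  inv <- 1 / D[upper.tri(D)]
  mean(ifelse(is.finite(inv), inv, 0))
}

oracleEloc <- function(a) {
  per <- vapply(seq_len(nrow(a)), function(i) {
    nbr <- which(a[i, ] > 0)
    if (length(nbr) < 2) return(0)
    oracleEglob(a[nbr, nbr, drop = FALSE])
  }, numeric(1))
  list(Eloc = mean(per), perNode = per)
}

oracleNodalEfficiency <- function(a) {
  D <- oracleDistances(a)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (nrow(a) - 1)
}

# every shortest path between s and t, as a list of vertex sequences
.allShortestPaths <- function(a, s, t, D) {
  res <- list()
  recurse <- function(path, v) {
    if (v == t) {
      res[[length(res) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(a[v, ] > 0))
      if (is.finite(D[w, t]) && D[w, t] == D[v, t] - 1)
        recurse(c(path, w), w)
  }
  if (is.finite(D[s, t]) && D[s, t] > 0) recurse(s, s)
  res
}

oracleBetweenness <- function(a) {
  n <- nrow(a)
  D <- oracleDistances(a)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- .allShortestPaths(a, s, t, D)
    if (!length(paths)) next
    for (p in paths)
      for (v in setdiff(p, c(s, t))) b[v] <- b[v] + 1 / length(paths)
  }
  b
}

# Erdos-Renyi-style random adjacency with at least one edge
randomAdjacency <- function(n, p) {
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- as.numeric(stats::runif(sum(ut)) < p)
  if (sum(a) == 0) a[1, 2] <- 1
  a + t(a)
}

# adjacency from an explicit edge list on n nodes
adjFromEdges <- function(n, edges) {
  a <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    a[edges[k, 1], edges[k, 2]] <- 1
    a[edges[k, 2], edges[k, 1]] <- 1
  }
  a
}

# wrap a raw correlation-like matrix for the binarization API
asConnectivity <- function(r) {
  diag(r) <- 0
  new("ConnectivityMatrix", r = (r + t(r)) / 2,
      roiLabels = sprintf("ROI%03d", seq_len(nrow(r))))
}

# small cohort config used across tests; effects off unless asked for
testConfig <- function(...) {
  args <- utils::modifyList(
    list(nPerGroup = 4, nRois = 30, nVolumes = 60, seed = 11), list(...))
  do.call(cohortConfig, args)
}
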