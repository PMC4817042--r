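# All metrics operate on binary, symmetric, zero-diagonal adjacency
# matrices. Shortest-path hop distances are computed by breadth-first
# expansion with boolean matrix products: cheap for the dense ~100-node
# networks this package targets, and free of graph-object overhead inside
# the random-reference loops.

.adj <- function(A) if (is(A, "AdjacencyMatrix")) A@a else as.matrix(A)

# Hop-distance matrix; unreachable pairs are Inf, diagonal 0.
.shortestHops <- function(a) {
  n <- nrow(a)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[a > 0] <- 1
  reach <- a > 0
  diag(reach) <- TRUE
  s <- 1
  repeat {
    nxt <- (reach %*% a) > 0
    diag(nxt) <- TRUE
    new <- nxt & !reach
    if (!any(new)) break
    s <- s + 1
    D[new] <- s
    reach <- nxt
  }
  D
}

.triangles <- function(a) rowSums((a %*% a) * a) / 2

.cpOf <- function(a) {
  k <- rowSums(a)
  t <- .triangles(a)
  ci <- ifelse(k < 2, 0, 2 * t / (k * (k - 1)))
  list(Cp = mean(ci), perNode = ci)
}

.lpOf <- function(a) {
  if (sum(a) == 0) stop("characteristic path length undefined: no edges")
  D <- .shortestHops(a)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

.eglobOf <- function(a) {
  D <- .shortestHops(a)
  inv <- 1 / D[upper.tri(D)]
  mean(ifelse(is.finite(inv), inv, 0))
}

#' Clustering coefficient
#'
#' Per-node clustering \code{c_i = 2 t_i / (k_i (k_i - 1))} (triangles over
#' possible neighbour pairs; 0 when degree < 2) and its mean over all nodes.
#'
#' @param A an [AdjacencyMatrix-class] or binary matrix.
#' @return list with \code{Cp} (mean) and \code{perNode}.
#' @export
clusteringCoefficient <- function(A) .cpOf(.adj(A))

#' Characteristic path length
#'
#' Mean shortest-path hop distance over all reachable node pairs;
#' unreachable pairs are excluded from the average, which keeps the measure
#' finite on graphs that fragment at low sparsity.
#'
#' @param A an [AdjacencyMatrix-class] or binary matrix.
#' @return scalar Lp.
#' @export
characteristicPathLength <- function(A) .lpOf(.adj(A))

#' Global efficiency
#'
#' Mean over distinct node pairs of the inverse shortest-path distance
#' (with 1/Inf = 0 for unreachable pairs).
#'
#' @param A an [AdjacencyMatrix-class] or binary matrix.
#' @return scalar in [0, 1].
#' @export
globalEfficiency <- function(A) .eglobOf(.adj(A))

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's open
#' neighbourhood subgraph; a node of degree < 2 contributes 0.
#'
#' @param A an [AdjacencyMatrix-class] or binary matrix.
#' @return list with \code{Eloc} (mean) and \code{perNode}.
#' @export
localEfficiency <- function(A) {
  a <- .adj(A)
  per <- vapply(seq_len(nrow(a)), function(i) {
    nbr <- which(a[i, ] > 0)
    if (length(nbr) < 2) return(0)
    .eglobOf(a[nbr, nbr, drop = FALSE])
  }, numeric(1))
  list(Eloc = mean(per), perNode = per)
}

#' Nodal centralities: degree, betweenness, nodal efficiency
#'
#' Degree is the row sum; betweenness is unnormalized shortest-path
#' betweenness with fractional credit for tied paths (Brandes algorithm, via
#' igraph); nodal efficiency of node i is the mean inverse shortest-path
#' distance from i to every other node.
#'
#' @param A an [AdjacencyMatrix-class] or binary matrix.
#' @return data.frame with columns node, degree, betweenness,
#'   nodalEfficiency.
#' @export
nodalCentralities <- function(A) {
  a <- .adj(A)
  n <- nrow(a)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  D <- .shortestHops(a)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  data.frame(node = seq_len(n), degree = rowSums(a),
             betweenness = as.numeric(btw),
             nodalEfficiency = rowSums(inv) / (n - 1))
}

#' Degree-preserving random reference networks
#'
#' Produces randomized networks with the exact degree sequence of the input
#' via double-edge swaps (Maslov-Sneppen rewiring); no self-loops or
#' multi-edges are introduced. Reproducible under \code{seed}.
#'
#' @param A an [AdjacencyMatrix-class] or binary matrix.
#' @param nRandom number of reference networks (default 100).
#' @param nSwapsPerEdge attempted swaps per edge (default 10).
#' @param seed integer seed.
#' @return list of binary adjacency matrices.
#' @export
randomReference <- function(A, nRandom = 100, nSwapsPerEdge = 10, seed = 1) {
  a <- .adj(A)
  m <- sum(a) / 2
  if (m < 2) stop("need at least 2 edges to rewire")
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  niter <- ceiling(nSwapsPerEdge * m)
  lapply(seq_len(nRandom), function(i) {
    .withSeed(.deriveSeed(seed, paste0("rewire:", i)), {
      rg <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                     niter = niter))
      matrix(as.numeric(igraph::as_adjacency_matrix(rg, sparse = FALSE)),
             nrow(a), ncol(a))
    })
  })
}

# Mean Cp and Lp of the degree-preserving references of `a`, without
# materialising the rewired adjacency matrices. Consumes the same named seed
# sub-streams as randomReference(), so the references are the same graphs;
# igraph's localaverage transitivity (isolates as zero) and mean_distance
# (unreachable pairs excluded) implement exactly this package's conventions,
# which the test suite cross-checks.
.refCpLp <- function(a, nRandom, nSwapsPerEdge, seed) {
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  m <- igraph::gsize(g)
  if (m < 2) stop("need at least 2 edges to rewire")
  niter <- ceiling(nSwapsPerEdge * m)
  cp <- lp <- numeric(nRandom)
  for (i in seq_len(nRandom)) {
    rg <- .withSeed(.deriveSeed(seed, paste0("rewire:", i)),
                    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                             niter = niter)))
    cp[i] <- igraph::transitivity(rg, type = "localaverage",
                                  isolates = "zero")
    lp[i] <- igraph::mean_distance(rg, unconnected = TRUE)
  }
  list(cp = cp, lp = lp)
}

#' Normalized small-world indices
#'
#' gamma = Cp(A) / mean Cp(randoms); lambda = Lp(A) / mean Lp(randoms);
#' sigma = gamma / lambda. A network is called small-world when sigma > 1.
#'
#' @param A an [AdjacencyMatrix-class] or binary matrix.
#' @param randoms list of reference networks from [randomReference()].
#' @return list with gamma, lambda, sigma.
#' @export
normalizedSmallWorld <- function(A, randoms) {
  if (!length(randoms)) stop("need at least one random reference")
  a <- .adj(A)
  cpR <- mean(vapply(randoms, function(r) .cpOf(.adj(r))$Cp, numeric(1)))
  lpR <- mean(vapply(randoms, function(r) .lpOf(.adj(r)), numeric(1)))
  if (cpR == 0 || lpR == 0)
    stop("degenerate random references (zero mean Cp or Lp)")
  gamma <- .cpOf(a)$Cp / cpR
  lambda <- .lpOf(a) / lpR
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' All global metrics of one network
#'
#' @param A an [AdjacencyMatrix-class] or binary matrix.
#' @param randoms optional list of random references; without them the
#'   normalized indices are NA.
#' @return one-row data.frame: Cp, Lp, Eglob, Eloc, gamma, lambda, sigma.
#' @export
globalMetrics <- function(A, randoms = NULL) {
  a <- .adj(A)
  sw <- if (is.null(randoms)) list(gamma = NA_real_, lambda = NA_real_,
                                   sigma = NA_real_)
        else normalizedSmallWorld(a, randoms)
  if (sum(a) == 0) stop("characteristic path length undefined: no edges")
  D <- .shortestHops(a)
  d <- D[upper.tri(D)]
  inv <- 1 / d
  data.frame(Cp = .cpOf(a)$Cp, Lp = mean(d[is.finite(d)]),
             Eglob = mean(ifelse(is.finite(inv), inv, 0)),
             Eloc = localEfficiency(a)$Eloc,
             gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
}

#' Trapezoidal area under a metric-versus-sparsity curve
#'
#' @param values metric values, one per grid point (no missing values).
#' @param grid the sparsity grid (at least two points).
#' @return the trapezoidal integral over [min(grid), max(grid)].
#' @export
aucOverGrid <- function(values, grid) {
  if (length(grid) < 2L) stop("AUC needs at least two grid points")
  if (length(values) != length(grid) || anyNA(values))
    stop("curve must be defined at every grid value")
  sum(diff(grid) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Metric curves and AUC summaries for one subject
#'
#' Binarizes the subject's connectivity matrix at every grid value, computes
#' the global metrics (normalized against degree-preserving random
#' references) and, optionally, the nodal metrics, and summarises each curve
#' by its trapezoidal AUC.
#'
#' @param C a [ConnectivityMatrix-class].
#' @param grid sparsity grid (default [sparsityGrid()]).
#' @param nRandom random references per threshold (default 100).
#' @param nSwapsPerEdge rewiring intensity (default 10).
#' @param seed integer seed for the rewiring streams.
#' @param nodal compute nodal metrics too?
#' @return a [MetricCurves-class].
#' @export
metricCurves <- function(C, grid = sparsityGrid(), nRandom = 100,
                         nSwapsPerEdge = 10, seed = 1, nodal = TRUE) {
  adjs <- sparsitySweep(C, grid)
  glob <- vector("list", length(grid))
  n <- nrow(C@r)
  deg <- btw <- nef <- matrix(NA_real_, length(grid), n)
  for (k in seq_along(grid)) {
    ref <- .refCpLp(adjs[[k]]@a, nRandom = nRandom,
                    nSwapsPerEdge = nSwapsPerEdge,
                    seed = .deriveSeed(seed, paste0("grid:", k)))
    cpR <- mean(ref$cp)
    lpR <- mean(ref$lp)
    if (cpR == 0 || lpR == 0)
      stop("degenerate random references (zero mean Cp or Lp)")
    gm <- globalMetrics(adjs[[k]])
    gm$gamma <- gm$Cp / cpR
    gm$lambda <- gm$Lp / lpR
    gm$sigma <- gm$gamma / gm$lambda
    glob[[k]] <- gm
    if (nodal) {
      nc <- nodalCentralities(adjs[[k]])
      deg[k, ] <- nc$degree
      btw[k, ] <- nc$betweenness
      nef[k, ] <- nc$nodalEfficiency
    }
  }
  glob <- do.call(rbind, glob)
  aucGlobal <- vapply(glob, function(v) aucOverGrid(v, grid), numeric(1))
  nodalList <- list()
  aucNodal <- NULL
  if (nodal) {
    nodalList <- list(degree = deg, betweenness = btw, nodalEfficiency = nef)
    aucNodal <- cbind(
      degree = apply(deg, 2, aucOverGrid, grid = grid),
      betweenness = apply(btw, 2, aucOverGrid, grid = grid),
      nodalEfficiency = apply(nef, 2, aucOverGrid, grid = grid))
  }
  new("MetricCurves", grid = grid, global = glob, nodal = nodalList,
      auc = list(global = aucGlobal, nodal = aucNodal))
}

#' Metric curves and AUCs for a whole cohort
#'
#' @param connectivities named list of [ConnectivityMatrix-class], one per
#'   subject.
#' @param grid,nRandom,nSwapsPerEdge,seed,nodal as in [metricCurves()];
#'   each subject gets a derived sub-seed.
#' @return list with \code{curves} (per subject [MetricCurves-class]),
#'   \code{globalAuc} (data.frame subject x metric) and \code{nodalAuc}
#'   (list of subject x node matrices per nodal metric, or NULL).
#' @export
cohortMetrics <- function(connectivities, grid = sparsityGrid(),
                          nRandom = 100, nSwapsPerEdge = 10, seed = 1,
                          nodal = TRUE) {
  ids <- names(connectivities)
  curves <- lapply(ids, function(id)
    metricCurves(connectivities[[id]], grid = grid, nRandom = nRandom,
                 nSwapsPerEdge = nSwapsPerEdge,
                 seed = .deriveSeed(seed, paste0("subject:", id)),
                 nodal = nodal))
  names(curves) <- ids
  globalAuc <- do.call(rbind, lapply(curves, function(mc)
    as.data.frame(t(mc@auc$global))))
  globalAuc <- cbind(subjectId = ids, globalAuc, row.names = NULL)
  nodalAuc <- NULL
  if (nodal) {
    nodalAuc <- lapply(c("degree", "betweenness", "nodalEfficiency"),
      function(m) {
        mat <- t(vapply(curves, function(mc) mc@auc$nodal[, m],
                        numeric(nrow(curves[[1]]@auc$nodal))))
        rownames(mat) <- ids
        mat
      })
    names(nodalAuc) <- c("degree", "betweenness", "nodalEfficiency")
  }
  list(curves = curves, globalAuc = globalAuc, nodalAuc = nodalAuc)
}
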