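#' Select nodes showing a group difference in any nodal metric
#'
#' A node is included when the smallest of its per-metric ANOVA p-values
#' (degree, betweenness, nodal efficiency AUCs) is below \code{alpha};
#' deliberately uncorrected, matching the exploratory node-screening stage.
#'
#' @param nodalPvals matrix (nodes x metrics) of ANOVA p-values.
#' @param alpha significance level (default 0.05).
#' @return integer vector of selected node indices (possibly empty, in which
#'   case a notice is emitted and downstream NBS should be skipped).
#' @export
selectAffectedNodes <- function(nodalPvals, alpha = 0.05) {
  nodalPvals <- as.matrix(nodalPvals)
  sel <- which(apply(nodalPvals, 1, min, na.rm = TRUE) < alpha)
  if (!length(sel))
    message("no node shows a group difference in any nodal metric; ",
            "NBS should be skipped")
  as.integer(sel)
}

# Subjects x edges matrix of (optionally Fisher z-transformed) connectivity
# values restricted to the node subset. Returns the matrix plus the edge
# index pairs (within-subset indices).
.edgeValueMatrix <- function(connectivities, nodes = NULL, fisherZ = TRUE) {
  r1 <- if (is(connectivities[[1]], "ConnectivityMatrix"))
    connectivities[[1]]@r else connectivities[[1]]
  if (is.null(nodes)) nodes <- seq_len(nrow(r1))
  if (length(nodes) < 2L)
    stop("need at least 2 nodes to form an edge set")
  pairs <- .upperPairs(length(nodes))
  vals <- vapply(connectivities, function(C) {
    r <- if (is(C, "ConnectivityMatrix")) C@r else C
    v <- r[nodes, nodes, drop = FALSE][pairs]
    if (fisherZ) .fisherZ(v) else v
  }, numeric(nrow(pairs)))
  X <- if (nrow(pairs) == 1L) matrix(vals, ncol = 1L) else t(vals)
  list(X = X, pairs = pairs, nodes = as.integer(nodes))
}

# Pooled-variance two-sample t for every column of X; g1 are row indices of
# the first group. Zero pooled variance yields 0.
.colT <- function(X, X2, g1, n1, n2, S, Q) {
  s1 <- colSums(X[g1, , drop = FALSE])
  q1 <- colSums(X2[g1, , drop = FALSE])
  m1 <- s1 / n1
  m2 <- (S - s1) / n2
  ss1 <- q1 - n1 * m1^2
  ss2 <- (Q - q1) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tt[!is.finite(tt)] <- 0
  tt
}

#' Edge-wise two-sample statistics between two groups
#'
#' For every node pair within the subset, a pooled-variance two-sample t
#' statistic comparing (by default Fisher z-transformed) correlation values
#' between the two groups; positive values mean the first group of
#' \code{pair} is larger. Edges with zero pooled variance get statistic 0.
#'
#' @param connectivities named list of [ConnectivityMatrix-class].
#' @param groups character vector of group labels aligned with
#'   \code{connectivities}.
#' @param pair length-2 character, the two groups to compare.
#' @param nodes node subset (original indices); NULL for all nodes.
#' @param fisherZ apply the Fisher z-transform before testing?
#' @return symmetric matrix of t statistics over the subset (zero diagonal).
#' @export
edgewiseStatistics <- function(connectivities, groups,
                               pair = c("PFS", "HC"), nodes = NULL,
                               fisherZ = TRUE) {
  keep <- groups %in% pair
  ev <- .edgeValueMatrix(connectivities[keep], nodes, fisherZ)
  g <- groups[keep]
  if (min(table(factor(g, levels = pair))) < 2)
    stop("need at least 2 subjects per group")
  X <- ev$X
  X2 <- X^2
  g1 <- which(g == pair[1])
  tt <- .colT(X, X2, g1, length(g1), nrow(X) - length(g1),
              colSums(X), colSums(X2))
  m <- matrix(0, length(ev$nodes), length(ev$nodes))
  m[ev$pairs] <- tt
  m + t(m)
}

#' Suprathreshold connected components
#'
#' Keeps edges whose |statistic| exceeds the primary threshold and returns
#' the maximal connected components of that edge set. Component size is the
#' edge count (the NBS "extent" measure).
#'
#' @param statMatrix symmetric matrix of edge-wise statistics.
#' @param threshold primary statistic cutoff (strict inequality).
#' @return list of components, each with \code{nodes}, \code{edges}
#'   (two-column matrix of within-matrix indices) and \code{size}.
#' @export
extractComponents <- function(statMatrix, threshold) {
  n <- nrow(statMatrix)
  ut <- .upperPairs(n)
  supra <- ut[abs(statMatrix[ut]) > threshold, , drop = FALSE]
  if (!nrow(supra)) return(list())
  comp <- .unionFind(n, supra)
  edgeComp <- comp[supra[, 1]]
  out <- lapply(sort(unique(edgeComp)), function(cid) {
    e <- supra[edgeComp == cid, , drop = FALSE]
    list(nodes = sort(unique(as.integer(e))), edges = e, size = nrow(e))
  })
  out[order(-vapply(out, `[[`, integer(1), "size"))]
}

# Max suprathreshold component size (edge count) for a t vector over pairs.
.maxCompSize <- function(tt, pairs, n, threshold) {
  supra <- pairs[abs(tt) > threshold, , drop = FALSE]
  if (!nrow(supra)) return(0L)
  comp <- .unionFind(n, supra)
  max(tabulate(match(comp[supra[, 1]], unique(comp[supra[, 1]]))))
}

#' Network-based statistics permutation test
#'
#' Edge-wise two-sample statistics on the node subset, suprathreshold
#' component extraction, and a max-component-size permutation null obtained
#' by shuffling group labels without replacement. The corrected p-value of a
#' component of size s is \code{(1 + #\{perm max >= s\}) / (nPermutations + 1)}.
#' When fewer distinct label assignments exist than requested permutations,
#' the null is enumerated exhaustively instead (with a message) and the
#' p-value is the exact proportion.
#'
#' @param connectivities named list of [ConnectivityMatrix-class].
#' @param groups group labels aligned with \code{connectivities}.
#' @param pair the two groups to compare.
#' @param nodes node subset (original indices); NULL for all.
#' @param threshold primary statistic cutoff (default 2.0).
#' @param nPermutations permutation count (default 10000).
#' @param alpha significance level recorded in the result (default 0.05).
#' @param seed integer seed; the whole run is deterministic given
#'   (data, seed, config).
#' @param fisherZ Fisher z-transform edge values before testing?
#' @return an [NbsResult-class].
#' @export
nbsTest <- function(connectivities, groups, pair = c("PFS", "HC"),
                    nodes = NULL, threshold = 2.0, nPermutations = 10000,
                    alpha = 0.05, seed = 1, fisherZ = TRUE) {
  stopifnot(threshold > 0, nPermutations >= 100)
  keep <- groups %in% pair
  ev <- .edgeValueMatrix(connectivities[keep], nodes, fisherZ)
  g <- groups[keep]
  n1 <- sum(g == pair[1]); n2 <- sum(g == pair[2])
  if (min(n1, n2) < 2) stop("need at least 2 subjects per group")
  X <- ev$X
  X2 <- X^2
  S <- colSums(X); Q <- colSums(X2)
  nsub <- nrow(X)
  nNodes <- length(ev$nodes)
  obsT <- .colT(X, X2, which(g == pair[1]), n1, n2, S, Q)
  statMatrix <- matrix(0, nNodes, nNodes)
  statMatrix[ev$pairs] <- obsT
  statMatrix <- statMatrix + t(statMatrix)
  comps <- extractComponents(statMatrix, threshold)

  nDistinct <- choose(nsub, n1)
  exhaustive <- is.finite(nDistinct) && nDistinct <= nPermutations
  nullMax <- if (exhaustive) {
    message(sprintf(
      "only %d distinct label assignments; enumerating exhaustively",
      nDistinct))
    sets <- utils::combn(nsub, n1)
    vapply(seq_len(ncol(sets)), function(k)
      .maxCompSize(.colT(X, X2, sets[, k], n1, n2, S, Q),
                   ev$pairs, nNodes, threshold), integer(1))
  } else {
    .withSeed(.deriveSeed(seed, paste0("nbs:", paste(pair, collapse = ":"))), {
      vapply(seq_len(nPermutations), function(k)
        .maxCompSize(.colT(X, X2, sample.int(nsub, n1), n1, n2, S, Q),
                     ev$pairs, nNodes, threshold), integer(1))
    })
  }
  comps <- lapply(comps, function(cmp) {
    cmp$correctedP <- if (exhaustive) mean(nullMax >= cmp$size)
      else (1 + sum(nullMax >= cmp$size)) / (nPermutations + 1)
    cmp
  })
  new("NbsResult", components = comps, statMatrix = statMatrix,
      nullMaxSizes = as.numeric(nullMax), nodes = ev$nodes,
      config = list(pair = pair, threshold = threshold,
                    nPermutations = nPermutations, alpha = alpha,
                    seed = seed, fisherZ = fisherZ,
                    exhaustive = exhaustive))
}
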