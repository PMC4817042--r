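K4 <- matrix(1, 4, 4) - diag(4)
K5 <- matrix(1, 5, 5) - diag(5)
star4 <- adjFromEdges(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
path3 <- adjFromEdges(3, rbind(c(1, 2), c(2, 3)))

test_that("closed-form values on canonical graphs", {
  expect_equal(clusteringCoefficient(K4)$Cp, 1)
  expect_equal(clusteringCoefficient(star4)$Cp, 0)
  # 5-node graph: triangle 1-2-3 plus tail 3-4-5
  g5 <- adjFromEdges(5, rbind(c(1, 2), c(2, 3), c(3, 1), c(3, 4), c(4, 5)))
  expect_equal(clusteringCoefficient(g5)$Cp, 7 / 15)
  expect_equal(clusteringCoefficient(g5)$perNode, c(1, 1, 1 / 3, 0, 0))

  expect_equal(characteristicPathLength(K5), 1)
  expect_equal(characteristicPathLength(path3), 4 / 3)
  # unreachable pairs are excluded from Lp
  twoK2 <- adjFromEdges(4, rbind(c(1, 2), c(3, 4)))
  expect_equal(characteristicPathLength(twoK2), 1)
  expect_error(characteristicPathLength(matrix(0, 3, 3)), "no edges")

  expect_equal(globalEfficiency(K4), 1)
  expect_equal(localEfficiency(K4)$Eloc, 1)
  expect_equal(globalEfficiency(path3), 5 / 6)
  # leaf neighbourhoods of the star are edgeless: every node contributes 0
  expect_equal(localEfficiency(star4)$perNode[2], 0)
  expect_equal(localEfficiency(star4)$Eloc, 0)

  nc <- nodalCentralities(star4)
  expect_equal(nc$degree, c(3, 1, 1, 1))
  expect_equal(nc$betweenness, c(3, 0, 0, 0))
  expect_equal(nodalCentralities(K4)$betweenness, rep(0, 4))
  expect_equal(nodalCentralities(path3)$nodalEfficiency[1], 0.75)
})

test_that("metrics agree with brute-force oracles on random small graphs", {
  set.seed(77)
  for (k in 1:120) {
    n <- sample(3:7, 1)
    a <- randomAdjacency(n, runif(1, 0.25, 0.9))
    expect_equal(clusteringCoefficient(a)$perNode,
                 oracleClustering(a)$perNode, tolerance = 1e-10)
    expect_equal(characteristicPathLength(a), oracleLp(a), tolerance = 1e-10)
    expect_equal(globalEfficiency(a), oracleEglob(a), tolerance = 1e-10)
    expect_equal(localEfficiency(a)$perNode, oracleEloc(a)$perNode,
                 tolerance = 1e-10)
    nc <- nodalCentralities(a)
    expect_equal(nc$degree, rowSums(a))
    expect_equal(nc$betweenness, oracleBetweenness(a), tolerance = 1e-10)
    expect_equal(nc$nodalEfficiency, oracleNodalEfficiency(a),
                 tolerance = 1e-10)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(12)
  a <- randomAdjacency(12, 0.3)
  perm <- sample(12)
  b <- a[perm, perm]
  expect_equal(clusteringCoefficient(b)$Cp, clusteringCoefficient(a)$Cp)
  expect_equal(characteristicPathLength(b), characteristicPathLength(a))
  expect_equal(globalEfficiency(b), globalEfficiency(a))
  expect_equal(localEfficiency(b)$Eloc, localEfficiency(a)$Eloc)
  expect_equal(nodalCentralities(b)$betweenness,
               nodalCentralities(a)$betweenness[perm], tolerance = 1e-10)
})

test_that("degree-preserving rewiring keeps degrees and lowers clustering", {
  # ring lattice: each node tied to its two neighbours on either side
  n <- 60
  edges <- do.call(rbind, lapply(1:n, function(i)
    rbind(c(i, i %% n + 1), c(i, (i + 1) %% n + 1))))
  ring <- adjFromEdges(n, edges)
  expect_equal(clusteringCoefficient(ring)$Cp, 0.5)

  randoms <- randomReference(ring, nRandom = 50, nSwapsPerEdge = 100,
                             seed = 31)
  degs <- vapply(randoms, rowSums, numeric(n))
  expect_true(all(degs == 4))
  for (r in randoms[1:5]) {
    expect_equal(diag(r), rep(0, n))
    expect_true(all(r %in% c(0, 1)))
    expect_equal(r, t(r))
  }
  cps <- vapply(randoms, function(r) clusteringCoefficient(r)$Cp, numeric(1))
  expect_gte(mean(cps < 0.5), 0.95)

  # reproducible under seed
  again <- randomReference(ring, nRandom = 3, nSwapsPerEdge = 100, seed = 31)
  expect_identical(again[[1]], randoms[[1]])

  # a 4-cycle stays in the all-degree-2 class
  c4 <- adjFromEdges(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  for (r in randomReference(c4, nRandom = 5, seed = 2))
    expect_equal(rowSums(r), rep(2, 4))
})

test_that("normalized small-world indices behave at their fixed points", {
  set.seed(8)
  a <- randomAdjacency(20, 0.3)
  sw <- normalizedSmallWorld(a, list(a, a, a))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)

  # an Erdos-Renyi graph is its own null: gamma and lambda near 1
  set.seed(15)
  er <- randomAdjacency(60, 0.2)
  sw2 <- normalizedSmallWorld(er, randomReference(er, nRandom = 40, seed = 5))
  expect_lt(abs(sw2$gamma - 1), 0.15)
  expect_lt(abs(sw2$lambda - 1), 0.05)
  expect_equal(sw2$sigma, sw2$gamma / sw2$lambda, tolerance = 1e-12)
})

test_that("curve normalization equals the explicit random-reference route", {
  set.seed(41)
  C <- asConnectivity(cor(matrix(rnorm(120 * 20), 120, 20)))
  grid <- c(0.2, 0.3)
  mc <- metricCurves(C, grid = grid, nRandom = 6, seed = 17, nodal = FALSE)
  for (k in seq_along(grid)) {
    A <- binarizeAtSparsity(C, grid[k])
    rnd <- randomReference(A, nRandom = 6,
                           seed = connectograph:::.deriveSeed(
                             17, paste0("grid:", k)))
    sw <- normalizedSmallWorld(A, rnd)
    expect_equal(mc@global$gamma[k], sw$gamma, tolerance = 1e-12)
    expect_equal(mc@global$lambda[k], sw$lambda, tolerance = 1e-12)
    expect_equal(mc@global$sigma[k], sw$sigma, tolerance = 1e-12)
  }
})

test_that("AUC is the trapezoidal integral over the sparsity span", {
  grid <- sparsityGrid()
  expect_equal(aucOverGrid(rep(2, 25), grid), 0.48)
  expect_equal(aucOverGrid(grid, grid), (0.34^2 - 0.10^2) / 2)
  expect_error(aucOverGrid(2, 0.2), "two grid points")
  expect_error(aucOverGrid(c(1, NA, 1), c(0.1, 0.2, 0.3)), "every grid value")
})

test_that("per-subject curves assemble globals, nodals and their AUCs", {
  set.seed(33)
  C <- asConnectivity(cor(matrix(rnorm(100 * 15), 100, 15)))
  grid <- c(0.15, 0.25, 0.35)
  mc <- metricCurves(C, grid = grid, nRandom = 4, seed = 6)
  expect_s4_class(mc, "MetricCurves")
  expect_equal(nrow(mc@global), 3L)
  expect_equal(mc@global$sigma, mc@global$gamma / mc@global$lambda,
               tolerance = 1e-12)
  expect_equal(unname(aucValues(mc)$global["Cp"]),
               aucOverGrid(mc@global$Cp, grid))
  expect_equal(dim(aucValues(mc)$nodal), c(15L, 3L))
  # degree curves integrate the row sums of the swept adjacencies
  A1 <- binarizeAtSparsity(C, 0.15)
  expect_equal(mc@nodal$degree[1, ], rowSums(adjValues(A1)))
})
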