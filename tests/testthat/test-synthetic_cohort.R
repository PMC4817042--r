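test_that("default configuration reproduces the emulated study layout", {
  cfg <- cohortConfig()
  expect_equal(cfg@nPerGroup, 26L)
  expect_equal(cfg@nRois, 90L)
  expect_equal(cfg@nVolumes, 180L)
  expect_equal(cfg@trSeconds, 2.0)
  expect_equal(nrow(cfg@deficitEdges$PFS), 13L)
  expect_equal(length(unique(as.integer(cfg@deficitEdges$PFS))), 13L)
  expect_equal(nrow(cfg@deficitEdges$PSS), 12L)
  expect_equal(length(unique(as.integer(cfg@deficitEdges$PSS))), 12L)
  # both default circuits are connected
  for (g in c("PFS", "PSS")) {
    e <- cfg@deficitEdges[[g]]
    nodes <- sort(unique(as.integer(e)))
    relab <- match(e, nodes)
    comp <- connectograph:::.unionFind(length(nodes),
                                       matrix(relab, ncol = 2))
    expect_equal(length(unique(comp)), 1L)
  }
})

test_that("config validity rejects malformed planted structures", {
  expect_error(cohortConfig(withinModuleR = 0.2, betweenModuleR = 0.3),
               "betweenModuleR")
  expect_error(cohortConfig(nVolumes = 10), "nVolumes")
  expect_error(
    cohortConfig(deficitEdges = list(PFS = cbind(1L, 1L),
                                     PSS = cbind(3L, 4L))),
    "self-pairs")
  expect_error(
    cohortConfig(deficitEdges = list(PFS = cbind(1L, 2L),
                                     PSS = cbind(2L, 1L))),
    "disjoint")
})

test_that("cohort generation yields three matched groups, reproducibly", {
  cfg <- testConfig()
  coh <- generateCohort(cfg)
  pheno <- phenotype(coh)
  expect_equal(nrow(pheno), 12L)
  expect_equal(unname(table(pheno$group)[c("PFS", "PSS", "HC")]),
               rep(4L, 3), ignore_attr = TRUE)
  expect_true(all(vapply(cohortSeries(coh), function(s)
    all(dim(tsData(s)) == c(60, 30)), logical(1))))
  # balanced sex within groups
  expect_true(all(tapply(pheno$sex == "male", pheno$group, sum) == 2))
  # bit-for-bit reproducibility under the same seed
  coh2 <- generateCohort(cfg)
  expect_identical(phenotype(coh2), pheno)
  expect_identical(lapply(cohortSeries(coh2), tsData),
                   lapply(cohortSeries(coh), tsData))
  # a different seed changes data but not group sizes
  coh3 <- generateCohort(testConfig(seed = 99))
  expect_false(identical(tsData(cohortSeries(coh3)[[1]]),
                         tsData(cohortSeries(coh)[[1]])))
  expect_equal(table(phenotype(coh3)$group), table(pheno$group))
})

test_that("with planted effects off the three generative matrices coincide", {
  cfg <- testConfig(clusteringShift = 0, deficitEffect = 0)
  sig <- lapply(c("PFS", "PSS", "HC"), function(g)
    subjectCorrelation(cfg, g, severity = 1.3))
  expect_equal(sig[[1]], sig[[2]])
  expect_equal(sig[[2]], sig[[3]])
})

test_that("generative matrices are symmetric, unit-diagonal, PSD", {
  coh <- generateCohort(testConfig(seed = 5))
  for (S in groundTruth(coh)$subjectSigma) {
    expect_equal(S, t(S))
    expect_equal(diag(S), rep(1, nrow(S)))
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("planted deficits and clustering shift move the target entries", {
  cfg <- testConfig(seed = 5)
  hc <- subjectCorrelation(cfg, "HC")
  pfs <- subjectCorrelation(cfg, "PFS", severity = 1)
  e <- cfg@deficitEdges$PFS
  # planted edges are reduced relative to control (projection may smooth a
  # little, so compare with slack well below the planted 0.25 effect)
  expect_true(all(hc[e] - pfs[e] > 0.1))
  # within-module non-deficit entries drop under the clustering shift
  mod <- groundTruth(generateCohort(cfg))$moduleAssignment
  w <- which(outer(mod, mod, "==") & upper.tri(hc), arr.ind = TRUE)
  key <- paste(w[, 1], w[, 2])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  w <- w[!key %in% ekey, , drop = FALSE]
  expect_true(mean(pfs[w]) < mean(hc[w]) - 0.05)
})

test_that("an infeasible planted effect is rejected naming the edges", {
  cfg <- testConfig()
  expect_error(
    subjectCorrelation(
      cohortConfig(nPerGroup = 4, nRois = 30, nVolumes = 60,
                   deficitEffect = 1.5, clusteringShift = 0),
      "PFS", severity = 1),
    "infeasible.*1-2")
})

test_that("sample correlations converge to the generative matrix", {
  # law-of-large-numbers check on a within-module pair at r = 0.5
  cfg <- cohortConfig(nPerGroup = 2, nRois = 10, nModules = 2,
                      withinModuleR = 0.5, betweenModuleR = 0.1,
                      clusteringShift = 0, deficitEffect = 0,
                      deficitEdges = list(PFS = cbind(1L, 2L),
                                          PSS = cbind(3L, 4L)),
                      nVolumes = 10000, seed = 2)
  S <- subjectCorrelation(cfg, "HC")
  expect_equal(S[1, 2], 0.5, tolerance = 1e-6)
  X <- connectograph:::.withSeed(7, connectograph:::.rmvn(10000, S))
  expect_lt(abs(cor(X[, 1], X[, 2]) - 0.5), 0.02)
})

test_that("motion tables contain drift plus detectable injected spikes", {
  cfg <- testConfig(spikeRate = 0, nVolumes = 170)
  m0 <- generateMotion(cfg, seed = 3)
  expect_equal(dim(m0$motion), c(170L, 6L))
  expect_length(m0$spikeVolumes, 0)
  fd0 <- computeFd(m0$motion)
  expect_true(all(fdValues(fd0) < 0.5))

  # injected spike count across seeds stays inside the central 99% binomial
  # band for Bernoulli(0.05) over the eligible volumes
  cfg5 <- testConfig(spikeRate = 0.05, nVolumes = 170)
  counts <- vapply(1:40, function(s)
    length(generateMotion(cfg5, seed = s)$spikeVolumes), numeric(1))
  band <- qbinom(c(0.005, 0.995), 169, 0.05)
  expect_true(mean(counts) >= band[1] && mean(counts) <= band[2])

  # every injected spike exceeds the FD threshold downstream
  m5 <- generateMotion(cfg5, seed = 8)
  fd5 <- computeFd(m5$motion)
  expect_true(all(fdValues(fd5)[m5$spikeVolumes] > 0.5))
})

test_that("symptom scores respect PANSS ranges and the planted link", {
  cfg <- testConfig()
  coh <- generateCohort(cfg)
  p <- phenotype(coh)
  pat <- p$group != "HC"
  expect_true(all(is.na(p$panssTotal[!pat])))
  expect_true(all(p$panssNegative[pat] >= 7 & p$panssNegative[pat] <= 49))
  expect_true(all(p$panssPositive[pat] >= 7 & p$panssPositive[pat] <= 49))
  expect_equal(p$panssTotal[pat],
               p$panssPositive[pat] + p$panssNegative[pat] +
                 p$panssGeneral[pat])

  # zero link: severity and negative score uncorrelated in expectation;
  # strong noise-free link: correlation sign follows the slope
  sev <- groundTruth(coh)$severity[pat]
  for (link in c(-30, 30)) {
    cfgL <- testConfig(symptomLink = link, symptomNoiseSd = 0.01)
    ph <- generateSymptoms(cfgL, p, groundTruth(coh)$severity, seed = 4)
    r <- cor(sev, ph$panssNegative[pat])
    expect_true(sign(r) == sign(link))
  }
})
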