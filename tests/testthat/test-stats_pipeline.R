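test_that("one-way ANOVA matches hand-computed sums of squares", {
  # three identical groups: no between-group variance
  a0 <- anovaOneway(rep(c(1, 2, 3), 3), rep(c("x", "y", "z"), each = 3))
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)

  # {1,2}, {3,4}, {5,6}: SSB = 16, SSW = 1.5 -> F = 16 with df (2, 3)
  a <- anovaOneway(1:6, rep(c("a", "b", "c"), each = 2),
                   pairwiseGate = NULL)
  expect_equal(a$F, 16)
  expect_equal(unname(a$df), c(2, 3))
  expect_equal(nrow(a$pairwise), 3L)

  # permuting subjects within groups leaves F unchanged
  set.seed(2)
  v <- rnorm(15)
  g <- rep(c("a", "b", "c"), each = 5)
  perm <- unlist(lapply(split(seq_along(v), g), sample), use.names = FALSE)
  expect_equal(anovaOneway(v[perm], g[perm])$F, anovaOneway(v, g)$F)

  expect_error(anovaOneway(rep(1, 6), rep(c("a", "b"), each = 3)),
               "zero within-group variance")
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(6)
  v <- rnorm(20)
  g <- rep(c("a", "b"), each = 10)
  a <- anovaOneway(v, g, pairwiseGate = NULL)
  tt <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(a$p, tt$p.value, tolerance = 1e-12)
})

test_that("partial correlation reduces, saturates and adjusts correctly", {
  set.seed(3)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  # no covariates: plain Pearson
  pc <- partialCorrelation(x, y)
  expect_equal(pc$pr, cor(x, y))
  expect_equal(pc$df, 38L)
  expect_equal(pc$p, cor.test(x, y)$p.value, tolerance = 1e-10)

  # y = x exactly with a covariate leaving residual variance
  z <- rnorm(40)
  expect_equal(partialCorrelation(x, x, cbind(z))$pr, 1)

  # invariant to affine rescaling of covariates
  cov1 <- cbind(age = rnorm(40, 30, 5), sex = rbinom(40, 1, 0.5))
  cov2 <- cbind(100 + 3 * cov1[, 1], 7 - 2 * cov1[, 2])
  p1 <- partialCorrelation(x, y, cov1)
  p2 <- partialCorrelation(x, y, cov2)
  expect_equal(p1$pr, p2$pr, tolerance = 1e-12)
  expect_equal(p1$df, 36L)

  # a confound driving both x and y is removed
  conf <- rnorm(200)
  xx <- conf + rnorm(200, sd = 0.3)
  yy <- conf + rnorm(200, sd = 0.3)
  expect_gt(cor(xx, yy), 0.7)
  expect_lt(abs(partialCorrelation(xx, yy, cbind(conf))$pr), 0.15)

  # collinear covariates are dropped with a warning
  expect_warning(partialCorrelation(x, y, cbind(cov1[, 1], cov1[, 1] * 2)),
                 "collinear")
})

test_that("a planted correlation is recovered within its Fisher interval", {
  rho <- -0.5; n <- 26
  set.seed(14)
  # draw (x, y) with true correlation rho, age/sex independent of both
  hits <- vapply(1:20, function(k) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    cov <- cbind(rnorm(n, 30, 5), rbinom(n, 1, 0.5))
    pr <- partialCorrelation(x, y, cov)$pr
    ci <- tanh(atanh(rho) + c(-1, 1) * 1.96 / sqrt(n - 3))
    pr >= ci[1] && pr <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the end-to-end pipeline runs, reports and reproduces", {
  cfg <- testConfig(nVolumes = 80, seed = 21)
  grid <- c(0.12, 0.2, 0.28)
  res <- runPipeline(cfg, grid = grid, nRandom = 3, nPermutations = 100,
                     gsrVariants = c(TRUE, FALSE), nodal = TRUE)
  expect_named(res, c("cohort", "gsr", "noGsr"))
  for (vn in c("gsr", "noGsr")) {
    v <- res[[vn]]
    expect_equal(nrow(v$anovaGlobal), 7L)
    expect_equal(sort(v$anovaGlobal$metric),
                 sort(c("Cp", "Lp", "Eglob", "Eloc", "gamma", "lambda",
                        "sigma")))
    expect_equal(dim(v$nodalPvals), c(30L, 3L))
    expect_equal(nrow(v$globalAuc), 12L)
  }
  # GSR and no-GSR trees are keyed identically but differ numerically
  expect_equal(names(res$gsr), names(res$noGsr))
  expect_false(isTRUE(all.equal(res$gsr$globalAuc$Cp,
                                res$noGsr$globalAuc$Cp)))
  # rerun with the same seed reproduces the tables exactly
  res2 <- runPipeline(cfg, grid = grid, nRandom = 3, nPermutations = 100,
                      gsrVariants = TRUE, nodal = TRUE)
  expect_identical(res2$gsr$globalAuc, res$gsr$globalAuc)
  expect_identical(res2$gsr$anovaGlobal, res$gsr$anovaGlobal)
})

test_that("report files round-trip through the writers", {
  dir <- withr::local_tempdir()
  cfg <- testConfig(nVolumes = 80, seed = 22)
  res <- runPipeline(cfg, grid = c(0.15, 0.25), nRandom = 2,
                     nPermutations = 100, gsrVariants = TRUE,
                     nodal = FALSE, outDir = dir)
  expect_true(file.exists(file.path(dir, "phenotype.csv")))
  expect_true(file.exists(file.path(dir, "gsr", "anova_global.csv")))
  expect_true(file.exists(file.path(dir, "report.json")))
  tab <- read.csv(file.path(dir, "gsr", "anova_global.csv"))
  expect_equal(nrow(tab), 7L)

  cdir <- file.path(dir, "cohort")
  writeCohort(res$cohort, cdir)
  id <- phenotype(res$cohort)$subjectId[1]
  rt <- readRoiTimeSeries(file.path(cdir, paste0(id, "_timeseries.tsv")),
                          file.path(cdir, paste0(id, "_motion.tsv")),
                          trSeconds = 2)
  expect_equal(tsData(rt), tsData(cohortSeries(res$cohort)[[1]]),
               tolerance = 1e-12)
  expect_equal(motionParams(rt), motionParams(cohortSeries(res$cohort)[[1]]),
               tolerance = 1e-12)

  cfgFile <- file.path(dir, "cohort.json")
  jsonlite::write_json(list(nPerGroup = 3, nRois = 28, seed = 5),
                       cfgFile, auto_unbox = TRUE)
  cfg2 <- readPipelineConfig(cfgFile)
  expect_equal(cfg2@nPerGroup, 3L)
  expect_equal(cfg2@nRois, 28L)
})
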