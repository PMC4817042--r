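#' One-way ANOVA with pairwise follow-ups
#'
#' Classical between/within sums-of-squares F test (equal-variance one-way
#' ANOVA), with pooled-variance two-sample t tests for every group pair
#' computed only when the omnibus p falls below \code{pairwiseGate}.
#'
#' @param values numeric outcome vector.
#' @param groups group labels aligned with \code{values}.
#' @param pairwiseGate omnibus p-value below which pairwise follow-ups are
#'   computed (default 0.05); NULL computes them always.
#' @return list with \code{F}, \code{df} (between, within), \code{p},
#'   \code{groupMeans}, and \code{pairwise} (data.frame or NULL).
#' @export
anovaOneway <- function(values, groups, pairwiseGate = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || min(table(groups)) < 2)
    stop("need at least 2 groups with at least 2 subjects each")
  wvar <- tapply(values, groups, stats::var)
  if (all(wvar == 0))
    stop("zero within-group variance everywhere; F undefined")
  ow <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  res <- list(F = unname(ow$statistic),
              df = unname(ow$parameter),
              p = unname(ow$p.value),
              groupMeans = tapply(values, groups, mean),
              pairwise = NULL)
  if (is.null(pairwiseGate) || (is.finite(res$p) && res$p < pairwiseGate)) {
    pairs <- utils::combn(levels(groups), 2)
    res$pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- values[groups == pairs[1, k]]
      b <- values[groups == pairs[2, k]]
      tt <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = unname(tt$p.value), stringsAsFactors = FALSE)
    }))
  }
  res
}

#' Covariate-adjusted partial correlation
#'
#' Pearson correlation of the least-squares residuals of x and y after
#' regression on an intercept plus the covariates, with the p-value from the
#' t transform at \code{df = n - 2 - k} (k = number of covariate columns
#' retained). With no covariates this reduces to the ordinary Pearson
#' correlation. Collinear covariate columns are dropped with a warning.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame of nuisance covariates, or
#'   NULL. Binary factors (e.g. sex) must be supplied as 0/1 indicators.
#' @return list with \code{pr}, \code{p}, \code{df}, \code{n}.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  ok <- stats::complete.cases(x, y, if (is.null(covariates)) x else covariates)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  k <- 0L
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)[ok, , drop = FALSE]
    storage.mode(Z) <- "double"
    X <- cbind(1, Z)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      warning(sprintf("dropping %d collinear covariate column(s)",
                      ncol(X) - qx$rank))
      X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
      qx <- qr(X)
    }
    k <- ncol(X) - 1L
    if (n <= k + 2L) stop("too few observations for the covariate count")
    x <- qr.resid(qx, x)
    y <- qr.resid(qx, y)
  }
  pr <- stats::cor(x, y)
  df <- n - 2L - k
  tstat <- pr * sqrt(df / max(1 - pr^2, .Machine$double.eps))
  list(pr = pr, p = 2 * stats::pt(-abs(tstat), df), df = df, n = n)
}

# ANOVA table over the seven global AUC metrics.
.globalAnovaTable <- function(globalAuc, groups, alpha = 0.05) {
  metrics <- setdiff(names(globalAuc), "subjectId")
  do.call(rbind, lapply(metrics, function(m) {
    a <- anovaOneway(globalAuc[[m]], groups, pairwiseGate = alpha)
    row <- data.frame(metric = m, F = a$F, dfBetween = a$df[1],
                      dfWithin = a$df[2], p = a$p,
                      stringsAsFactors = FALSE)
    for (pp in c("HC.PFS", "HC.PSS", "PFS.PSS")) row[[paste0("p_", pp)]] <- NA_real_
    if (!is.null(a$pairwise))
      for (i in seq_len(nrow(a$pairwise)))
        row[[paste0("p_", a$pairwise$group1[i], ".", a$pairwise$group2[i])]] <-
          a$pairwise$p[i]
    row
  }))
}

# Node x metric matrix of omnibus ANOVA p-values on nodal AUCs.
.nodalAnovaPvals <- function(nodalAuc, groups) {
  vapply(nodalAuc, function(mat)
    apply(mat, 2, function(v) {
      if (all(tapply(v, groups, stats::var) == 0)) return(NA_real_)
      anovaOneway(v, groups, pairwiseGate = NULL)$p
    }), numeric(ncol(nodalAuc[[1]])))
}

# Partial correlations of significant global metrics with PANSS subscales
# within each patient group, age- and sex-adjusted.
.symptomCorrelations <- function(globalAuc, pheno, sigMetrics,
                                 subscales = c("panssPositive", "panssNegative",
                                               "panssGeneral", "panssTotal")) {
  rows <- list()
  for (grp in c("PFS", "PSS")) {
    sel <- pheno$group == grp
    if (sum(sel) < 6) {
      message("group ", grp, " too small for covariate-adjusted ",
              "correlations; skipped")
      next
    }
    cov <- cbind(age = pheno$age[sel],
                 sex = as.numeric(pheno$sex[sel] == "male"))
    for (m in sigMetrics) for (sc in subscales) {
      pc <- partialCorrelation(globalAuc[[m]][sel], pheno[[sc]][sel], cov)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, metric = m, subscale = sc, pr = pc$pr, p = pc$p,
        df = pc$df, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(group = character(), metric = character(),
                  subscale = character(), pr = numeric(), p = numeric(),
                  df = integer(), stringsAsFactors = FALSE)
}

#' Run the full group-comparison pipeline
#'
#' Generates (or accepts) a cohort, then for each global-signal-regression
#' variant: preprocesses every subject, builds correlation networks,
#' computes metric curves and AUCs over the sparsity grid, runs one-way
#' ANOVAs on every global and nodal AUC, screens nodes for the NBS stage,
#' runs the NBS permutation test for each group pair on the screened nodes,
#' and computes age/sex-adjusted partial correlations of significant global
#' metrics with PANSS subscales within each patient group. With the same
#' seed the whole report is reproduced identically.
#'
#' @param config a [CohortConfig-class].
#' @param cohort optional pre-generated [SyntheticCohort-class] (skips
#'   generation).
#' @param grid sparsity grid.
#' @param nRandom,nSwapsPerEdge random-reference settings.
#' @param nbsThreshold,nPermutations,alpha NBS settings.
#' @param gsrVariants logical vector of GSR settings to run (default both
#'   TRUE and FALSE).
#' @param nodal compute nodal metrics, nodal ANOVAs and NBS?
#' @param outDir optional directory for CSV/JSON report output (see
#'   [writeReport()]).
#' @param seed master seed for metric and NBS streams.
#' @return list with \code{cohort} and one result tree per variant
#'   (\code{gsr}, \code{noGsr}), each holding globalAuc, anovaGlobal,
#'   nodalPvals, affectedNodes, nbs (per pair), correlations, fdReport.
#' @export
runPipeline <- function(config, cohort = NULL, grid = sparsityGrid(),
                        nRandom = 100, nSwapsPerEdge = 10,
                        nbsThreshold = 2.0, nPermutations = 10000,
                        alpha = 0.05, gsrVariants = c(TRUE, FALSE),
                        nodal = TRUE, outDir = NULL, seed = NULL) {
  if (is.null(cohort)) cohort <- generateCohort(config)
  if (is.null(seed)) seed <- cohort@config@seed
  pheno <- cohort@phenotype
  groups <- pheno$group
  variants <- list()
  for (useGsr in gsrVariants) {
    vn <- if (useGsr) "gsr" else "noGsr"
    pre <- preprocessCohort(cohort, useGsr = useGsr)
    conn <- lapply(pre$series, correlationMatrix)
    met <- cohortMetrics(conn, grid = grid, nRandom = nRandom,
                         nSwapsPerEdge = nSwapsPerEdge,
                         seed = .deriveSeed(seed, paste0("metrics:", vn)),
                         nodal = nodal)
    anovaGlobal <- .globalAnovaTable(met$globalAuc, groups, alpha)
    res <- list(globalAuc = met$globalAuc, anovaGlobal = anovaGlobal,
                fdReport = pre$fdReport)
    if (nodal) {
      nodalPvals <- .nodalAnovaPvals(met$nodalAuc, groups)
      affected <- selectAffectedNodes(nodalPvals, alpha)
      res$nodalPvals <- nodalPvals
      res$affectedNodes <- affected
      res$nbs <- list()
      if (length(affected) >= 2) {
        for (pr in list(c("PFS", "HC"), c("PSS", "HC"), c("PFS", "PSS"))) {
          res$nbs[[paste(pr, collapse = ".")]] <- nbsTest(
            conn, groups, pair = pr, nodes = affected,
            threshold = nbsThreshold, nPermutations = nPermutations,
            alpha = alpha,
            seed = .deriveSeed(seed, paste0("nbs:", vn)))
        }
      }
    }
    sig <- anovaGlobal$metric[!is.na(anovaGlobal$p) & anovaGlobal$p < alpha]
    res$correlations <- .symptomCorrelations(met$globalAuc, pheno, sig)
    variants[[vn]] <- res
  }
  out <- c(list(cohort = cohort), variants)
  if (!is.null(outDir)) writeReport(out, outDir)
  invisible(out)
}
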