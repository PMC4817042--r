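#' Default planted deficit circuits
#'
#' Two disjoint connected circuits of reduced functional connectivity, one per
#' patient group: a 13-edge / 13-node circuit (a 12-ring plus a pendant node)
#' for the familial-schizophrenia analogue and a 12-edge / 12-node ring for
#' the sporadic analogue. Node identities are arbitrary indices placed in the
#' first two covariance modules.
#'
#' @param nRois number of regions; must be at least 27 so the two circuits
#'   fit on disjoint node sets.
#' @return list with two-column integer matrices \code{PFS} and \code{PSS}.
#' @export
defaultDeficitEdges <- function(nRois) {
  if (nRois < 27L)
    stop("default planted circuits need nRois >= 27; supply deficitEdges")
  pfs <- rbind(cbind(1:11, 2:12), c(12L, 1L), c(1L, 13L))
  pss <- cbind(16:27, c(17:27, 16L))
  list(PFS = matrix(as.integer(pfs), ncol = 2L),
       PSS = matrix(as.integer(pss), ncol = 2L))
}

#' Construct a validated cohort configuration
#'
#' Defaults mirror the emulated study design: three groups of 26 subjects,
#' 90 regions, 180 volumes at TR = 2 s (the first 10 discarded downstream),
#' six covariance modules, a 13-edge planted deficit circuit for the PFS
#' group and a 12-edge circuit for the PSS group, and a clustering
#' (randomization) shift applied to the PFS group only. Effect sizes are
#' generator choices, not reported quantities; see the package vignette.
#'
#' @param nPerGroup subjects per group.
#' @param nRois regions per subject.
#' @param nVolumes acquired volumes (first 10 discarded downstream).
#' @param trSeconds repetition time, seconds.
#' @param nModules number of covariance blocks.
#' @param withinModuleR target correlation inside a block.
#' @param betweenModuleR target correlation across blocks.
#' @param deficitEdges list of two-column matrices \code{PFS}, \code{PSS};
#'   NULL for the defaults.
#' @param deficitEffect correlation reduction per planted edge.
#' @param clusteringShift fractional reduction of within-module correlation
#'   for \code{shiftGroup}.
#' @param shiftGroup patient group receiving the clustering shift.
#' @param spikeRate per-volume motion spike probability.
#' @param spikeArtifact signal offset per mm of injected displacement.
#' @param severitySd sd of the subject-level severity multiplier.
#' @param symptomLink slope of PANSS negative score on severity.
#' @param symptomNoiseSd noise sd on the linked symptom score.
#' @param seed master integer seed.
#' @return a [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(nPerGroup = 4, nRois = 30, seed = 7)
#' @export
cohortConfig <- function(nPerGroup = 26, nRois = 90, nVolumes = 180,
                         trSeconds = 2.0, nModules = 6,
                         withinModuleR = 0.40, betweenModuleR = 0.08,
                         deficitEdges = NULL, deficitEffect = 0.25,
                         clusteringShift = 0.30, shiftGroup = "PFS",
                         spikeRate = 0.02, spikeArtifact = 2.0,
                         severitySd = 0.25, symptomLink = 24,
                         symptomNoiseSd = 3, seed = 1L) {
  if (is.null(deficitEdges)) deficitEdges <- defaultDeficitEdges(nRois)
  deficitEdges <- lapply(deficitEdges, function(e)
    matrix(as.integer(e), ncol = 2L))
  new("CohortConfig",
      nPerGroup = as.integer(nPerGroup), nRois = as.integer(nRois),
      nVolumes = as.integer(nVolumes), trSeconds = trSeconds,
      nModules = as.integer(nModules), withinModuleR = withinModuleR,
      betweenModuleR = betweenModuleR, deficitEdges = deficitEdges,
      deficitEffect = deficitEffect, clusteringShift = clusteringShift,
      shiftGroup = shiftGroup, spikeRate = spikeRate,
      spikeArtifact = spikeArtifact, severitySd = severitySd,
      symptomLink = symptomLink, symptomNoiseSd = symptomNoiseSd,
      seed = as.integer(seed))
}

# Contiguous module assignment of regions to covariance blocks.
.moduleAssignment <- function(config) {
  cut(seq_len(config@nRois), config@nModules, labels = FALSE)
}

#' Generative correlation matrix for one subject
#'
#' Builds the block-modular target correlation matrix, applies the group's
#' planted effects scaled by the subject-level severity multiplier, and
#' projects to the nearest positive semi-definite correlation matrix.
#'
#' @param config a [CohortConfig-class].
#' @param group one of "PFS", "PSS", "HC".
#' @param severity subject severity multiplier (ignored for HC).
#' @return an nRois x nRois correlation matrix.
#' @export
subjectCorrelation <- function(config, group, severity = 1) {
  mod <- .moduleAssignment(config)
  S <- matrix(config@betweenModuleR, config@nRois, config@nRois)
  same <- outer(mod, mod, "==")
  w <- config@withinModuleR
  if (group == config@shiftGroup && config@clusteringShift > 0)
    w <- config@withinModuleR * max(0, 1 - config@clusteringShift * severity)
  S[same] <- w
  diag(S) <- 1
  if (group %in% c("PFS", "PSS")) {
    e <- config@deficitEdges[[group]]
    if (nrow(e)) {
      idx <- cbind(e[, 1], e[, 2])
      S[idx] <- S[idx] - config@deficitEffect * severity
      S[idx[, 2:1, drop = FALSE]] <- S[idx]
      bad <- abs(S[idx]) > 1
      if (any(bad))
        stop("infeasible correlation structure after planting; offending ",
             "edges: ",
             paste(e[bad, 1], e[bad, 2], sep = "-", collapse = ", "))
    }
  }
  nearestPsdCorrelation(S)
}

#' Simulate one subject's rigid-body motion table
#'
#' Smooth low-amplitude random-walk drift on all six parameters (translations
#' in mm, rotations in radians) plus one-volume x-translation excursions at
#' Bernoulli(spikeRate) volumes, sized 0.6-1.5 mm so each injected spike
#' exceeds the downstream 0.5 mm frame-wise-displacement threshold.
#'
#' @param config a [CohortConfig-class].
#' @param seed integer seed for this subject's motion stream.
#' @return list with \code{motion} (nVolumes x 6 matrix), \code{spikeVolumes}
#'   (ground-truth injected volumes) and \code{spikeSizes} (mm).
#' @export
generateMotion <- function(config, seed) {
  T <- config@nVolumes
  .withSeed(seed, {
    motion <- cbind(
      apply(matrix(stats::rnorm(3 * T, 0, 0.010), T), 2, cumsum),
      apply(matrix(stats::rnorm(3 * T, 0, 0.0001), T), 2, cumsum))
    spikeVolumes <- which(stats::runif(T) < config@spikeRate)
    spikeVolumes <- spikeVolumes[spikeVolumes > 1L]
    spikeSizes <- stats::runif(length(spikeVolumes), 0.6, 1.5)
    motion[spikeVolumes, 1] <- motion[spikeVolumes, 1] + spikeSizes
    list(motion = motion, spikeVolumes = spikeVolumes,
         spikeSizes = spikeSizes)
  })
}

#' Fill PANSS symptom scores for patient subjects
#'
#' Positive and general subscales are drawn independently; the negative
#' subscale is linked to the subject-level planted effect magnitude
#' (severity) through \code{symptomLink}, so the downstream partial
#' correlation stage has a recoverable planted association. Scores are
#' integers clipped to the legal PANSS ranges (positive/negative subscales
#' in [7, 49], general in [16, 112]); the total is the sum of the three.
#'
#' @param config a [CohortConfig-class].
#' @param pheno phenotype data.frame with a \code{group} column.
#' @param severity numeric vector aligned with \code{pheno} rows (NA for HC).
#' @param seed integer seed for the symptom stream.
#' @return \code{pheno} with panssPositive/Negative/General/Total filled for
#'   patients and NA for controls.
#' @export
generateSymptoms <- function(config, pheno, severity, seed) {
  pat <- pheno$group != "HC"
  n <- sum(pat)
  .withSeed(seed, {
    pos <- pmin(pmax(round(stats::rnorm(n, 18, 5)), 7), 49)
    gen <- pmin(pmax(round(stats::rnorm(n, 36, 8)), 16), 112)
    neg <- round(20 + config@symptomLink * (severity[pat] - 1) +
                   stats::rnorm(n, 0, config@symptomNoiseSd))
    neg <- pmin(pmax(neg, 7), 49)
    pheno$panssPositive <- NA_integer_
    pheno$panssNegative <- NA_integer_
    pheno$panssGeneral <- NA_integer_
    pheno$panssTotal <- NA_integer_
    pheno$panssPositive[pat] <- as.integer(pos)
    pheno$panssNegative[pat] <- as.integer(neg)
    pheno$panssGeneral[pat] <- as.integer(gen)
    pheno$panssTotal[pat] <- as.integer(pos + neg + gen)
    pheno
  })
}

#' Generate a synthetic three-group resting-state cohort
#'
#' Draws, for every subject, a regional time series from a multivariate
#' normal whose correlation structure is block-modular with the group's
#' planted effects (edge-strength deficits and, for the designated group, a
#' within-module clustering shift) scaled by a subject-level severity
#' multiplier; adds slow sinusoidal drift and motion-coupled signal offsets
#' at injected spike volumes; simulates the aligned motion table; and fills
#' demographics and PANSS scores. Identical seeds reproduce identical
#' cohorts bit-for-bit; each subject consumes a named sub-stream of the
#' master seed.
#'
#' @param config a [CohortConfig-class].
#' @return a [SyntheticCohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(nPerGroup = 3, nRois = 30, seed = 1))
#' table(phenotype(coh)$group)
#' @export
generateCohort <- function(config) {
  validObject(config)
  groups <- rep(c("PFS", "PSS", "HC"), each = config@nPerGroup)
  ids <- sprintf("%s%02d", groups, sequence(rep(config@nPerGroup, 3)))
  pheno <- data.frame(subjectId = ids, group = groups,
                      stringsAsFactors = FALSE)

  # demographics and severity from a dedicated stream; ages matched across
  # groups by construction, sex balanced within group
  phenoSeed <- .deriveSeed(config@seed, "phenotype")
  demo <- .withSeed(phenoSeed, {
    age <- round(stats::rnorm(length(ids), 32.5, 7), 1)
    sev <- rep(NA_real_, length(ids))
    pat <- groups != "HC"
    s <- stats::rnorm(sum(pat), 1, config@severitySd)
    sev[pat] <- pmin(pmax(s, 0.25), 1.75)
    list(age = age, sev = sev)
  })
  pheno$age <- demo$age
  # balanced sex within each contiguous group block
  pheno$sex <- unlist(lapply(unique(groups), function(g)
    rep_len(c("female", "male"), sum(groups == g))), use.names = FALSE)
  pheno <- generateSymptoms(config, pheno, demo$sev,
                            .deriveSeed(config@seed, "symptoms"))

  roiLab <- sprintf("ROI%03d", seq_len(config@nRois))
  tIdx <- seq_len(config@nVolumes) - 1L
  series <- vector("list", length(ids))
  names(series) <- ids
  sigmas <- vector("list", length(ids))
  names(sigmas) <- ids
  spikes <- vector("list", length(ids))
  names(spikes) <- ids

  for (k in seq_along(ids)) {
    sv <- if (groups[k] == "HC") 1 else demo$sev[k]
    Sigma <- subjectCorrelation(config, groups[k], sv)
    sigmas[[k]] <- Sigma
    mot <- generateMotion(config, .deriveSeed(config@seed,
                                              paste0("motion:", ids[k])))
    X <- .withSeed(.deriveSeed(config@seed, paste0("series:", ids[k])), {
      x <- .rmvn(config@nVolumes, Sigma)
      # slow scanner drift, removed by the band-pass stage
      phase <- stats::runif(config@nRois, 0, 2 * pi)
      x + sin(outer(2 * pi * 0.005 * tIdx * config@trSeconds, phase, "+"))
    })
    if (length(mot$spikeVolumes))
      X[mot$spikeVolumes, ] <- X[mot$spikeVolumes, ] +
        config@spikeArtifact * mot$spikeSizes
    series[[k]] <- new("RoiTimeSeries", data = X, trSeconds = config@trSeconds,
                       roiLabels = roiLab, motion = mot$motion)
    spikes[[k]] <- mot$spikeVolumes
  }

  truth <- list(subjectSigma = sigmas, severity = stats::setNames(demo$sev, ids),
                spikeVolumes = spikes, deficitEdges = config@deficitEdges,
                shiftGroup = config@shiftGroup,
                moduleAssignment = .moduleAssignment(config))
  new("SyntheticCohort", phenotype = pheno, series = series, truth = truth,
      config = config)
}
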