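#' @import methods
NULL

#' Configuration of the synthetic three-group cohort
#'
#' Holds every knob of the synthetic resting-state cohort generator: cohort
#' layout (subjects per group, regions, volumes, TR), the block-modular
#' correlation structure, the planted group effects (edge-strength deficits
#' per patient group, a fractional clustering shift for one group), the motion
#' model, and the symptom-link model tying PANSS negative scores to the
#' subject-level planted effect magnitude.
#'
#' @slot nPerGroup integer, subjects per group (three groups: PFS, PSS, HC).
#' @slot nRois integer, number of regions (network nodes).
#' @slot nVolumes integer, acquired volumes per subject; the first 10 are
#'   meant to be discarded downstream.
#' @slot trSeconds numeric, repetition time in seconds.
#' @slot nModules integer, number of covariance blocks (functional modules).
#' @slot withinModuleR numeric, target correlation inside a module.
#' @slot betweenModuleR numeric, target correlation across modules.
#' @slot deficitEdges list with elements \code{PFS} and \code{PSS}, each a
#'   two-column integer matrix of node pairs whose correlation is reduced in
#'   that patient group.
#' @slot deficitEffect numeric, correlation reduction per planted edge.
#' @slot clusteringShift numeric in [0,1), fractional reduction of
#'   within-module correlation applied to \code{shiftGroup}.
#' @slot shiftGroup character, the patient group receiving the clustering
#'   shift ("PFS" or "PSS").
#' @slot spikeRate numeric, per-volume probability of a motion spike.
#' @slot spikeArtifact numeric, signal offset (a.u. per mm of injected
#'   displacement) added to every region at a spike volume.
#' @slot severitySd numeric, sd of the subject-level severity multiplier
#'   (truncated normal around 1) that scales the planted effects.
#' @slot symptomLink numeric, slope (PANSS negative points per severity unit)
#'   tying the negative-symptom score to the planted effect magnitude.
#' @slot symptomNoiseSd numeric, sd of the noise on the linked symptom score.
#' @slot seed integer, master seed; per-subject sub-streams are derived from
#'   it so identical seeds reproduce identical cohorts bit-for-bit.
#' @seealso [cohortConfig()] for the validated constructor with defaults.
#' @export
setClass("CohortConfig",
  representation(
    nPerGroup = "integer", nRois = "integer", nVolumes = "integer",
    trSeconds = "numeric", nModules = "integer",
    withinModuleR = "numeric", betweenModuleR = "numeric",
    deficitEdges = "list", deficitEffect = "numeric",
    clusteringShift = "numeric", shiftGroup = "character",
    spikeRate = "numeric", spikeArtifact = "numeric",
    severitySd = "numeric", symptomLink = "numeric",
    symptomNoiseSd = "numeric", seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be >= 2")
  if (object@nVolumes <= 10L)
    msg <- c(msg, "nVolumes must exceed 10 (volumes discarded downstream)")
  if (object@nRois < object@nModules)
    msg <- c(msg, "nRois must be >= nModules")
  if (!(object@betweenModuleR >= 0 &&
        object@betweenModuleR < object@withinModuleR &&
        object@withinModuleR < 1))
    msg <- c(msg, "need 0 <= betweenModuleR < withinModuleR < 1")
  if (object@clusteringShift < 0 || object@clusteringShift >= 1)
    msg <- c(msg, "clusteringShift must be in [0, 1)")
  if (!object@shiftGroup %in% c("PFS", "PSS"))
    msg <- c(msg, "shiftGroup must be 'PFS' or 'PSS'")
  for (g in c("PFS", "PSS")) {
    e <- object@deficitEdges[[g]]
    if (!is.matrix(e) || ncol(e) != 2L)
      msg <- c(msg, sprintf("deficitEdges$%s must be a two-column matrix", g))
    else {
      if (any(e[, 1] == e[, 2]))
        msg <- c(msg, sprintf("deficitEdges$%s contains self-pairs", g))
      if (nrow(e) && max(e) > object@nRois)
        msg <- c(msg, sprintf("deficitEdges$%s references nodes beyond nRois", g))
    }
  }
  ek <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (is.matrix(object@deficitEdges$PFS) && is.matrix(object@deficitEdges$PSS) &&
      length(intersect(ek(object@deficitEdges$PFS),
                       ek(object@deficitEdges$PSS))))
    msg <- c(msg, "the two planted edge lists must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Regional-mean time series with an aligned motion table
#'
#' A T x N matrix of regional mean signals (one column per region of
#' interest), the repetition time, and optionally the subject's T x 6
#' rigid-body motion-parameter table (three translations in mm, three
#' rotations in radians).
#'
#' @slot data numeric matrix, T time points x N regions.
#' @slot trSeconds numeric, repetition time in seconds.
#' @slot roiLabels character, N region labels.
#' @slot motion numeric matrix, T x 6 motion parameters, or a 0-row matrix
#'   when no motion table is attached.
#' @export
setClass("RoiTimeSeries",
  representation(data = "matrix", trSeconds = "numeric",
                 roiLabels = "character", motion = "matrix")
)

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  if (nrow(object@data) < 2L || ncol(object@data) < 2L)
    msg <- c(msg, "need at least 2 time points and 2 regions")
  if (anyNA(object@data)) msg <- c(msg, "time series contains missing values")
  if (length(object@roiLabels) != ncol(object@data))
    msg <- c(msg, "roiLabels length must match the number of regions")
  if (nrow(object@motion) > 0L) {
    if (ncol(object@motion) != 6L)
      msg <- c(msg, "motion table must have 6 columns")
    if (nrow(object@motion) != nrow(object@data))
      msg <- c(msg, "motion table must have exactly T rows")
  }
  if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
  if (length(msg)) msg else TRUE
})

#' Frame-wise displacement series
#'
#' Per-volume frame-wise displacement (FD, in mm) summarising volume-to-volume
#' head motion, the spike threshold, and the resulting spike flags
#' (strictly-greater-than comparison). \code{fd[1] = 0} by convention.
#'
#' @slot fd numeric, length-T FD vector in mm.
#' @slot threshold numeric, spike threshold in mm.
#' @slot spikeFlags logical, length-T; TRUE where \code{fd > threshold}.
#' @export
setClass("FdSeries",
  representation(fd = "numeric", threshold = "numeric",
                 spikeFlags = "logical")
)

setValidity("FdSeries", function(object) {
  msg <- character()
  if (length(object@fd) && object@fd[1] != 0)
    msg <- c(msg, "fd[1] must be 0 by convention")
  if (any(object@fd < 0)) msg <- c(msg, "fd must be non-negative")
  if (length(object@spikeFlags) != length(object@fd))
    msg <- c(msg, "spikeFlags must align with fd")
  if (!identical(object@spikeFlags, object@fd > object@threshold))
    msg <- c(msg, "spikeFlags must equal fd > threshold")
  if (length(msg)) msg else TRUE
})

#' Subject-level functional connectivity matrix
#'
#' N x N symmetric matrix of Pearson correlations between regional mean time
#' series; the diagonal is set to 0 by convention.
#'
#' @slot r numeric matrix, N x N correlations with zero diagonal.
#' @slot roiLabels character, N region labels.
#' @export
setClass("ConnectivityMatrix",
  representation(r = "matrix", roiLabels = "character")
)

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  r <- object@r
  if (nrow(r) != ncol(r)) msg <- c(msg, "matrix must be square")
  if (max(abs(r - t(r))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
  if (any(abs(diag(r)) > 0)) msg <- c(msg, "diagonal must be 0 by convention")
  if (max(abs(r)) > 1 + 1e-12) msg <- c(msg, "|r| must not exceed 1")
  if (length(object@roiLabels) != nrow(r))
    msg <- c(msg, "roiLabels length must match matrix dimension")
  if (length(msg)) msg else TRUE
})

#' Binary adjacency matrix at a fixed sparsity
#'
#' Symmetric 0/1 matrix with zero diagonal obtained by keeping the strongest
#' \code{round(s * N(N-1)/2)} connections by absolute correlation.
#'
#' @slot a numeric matrix of 0/1 entries, symmetric, zero diagonal.
#' @slot sparsity numeric in (0,1), realised edge fraction target.
#' @export
setClass("AdjacencyMatrix",
  representation(a = "matrix", sparsity = "numeric")
)

setValidity("AdjacencyMatrix", function(object) {
  msg <- character()
  a <- object@a
  if (nrow(a) != ncol(a)) msg <- c(msg, "matrix must be square")
  if (!all(a %in% c(0, 1))) msg <- c(msg, "entries must be 0/1")
  if (any(diag(a) != 0)) msg <- c(msg, "diagonal must be zero")
  if (!identical(a, t(a))) msg <- c(msg, "matrix must be symmetric")
  if (object@sparsity <= 0 || object@sparsity >= 1)
    msg <- c(msg, "sparsity must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' A synthetic cohort with ground truth
#'
#' The generated cohort: a phenotype table (id, group, age, sex, PANSS
#' scores), one [RoiTimeSeries-class] per subject, and the generative ground
#' truth (per-subject correlation matrices, severity multipliers, planted
#' circuits, injected spike volumes) against which downstream recovery can be
#' scored.
#'
#' @slot phenotype data.frame with one row per subject.
#' @slot series named list of [RoiTimeSeries-class], one per subject.
#' @slot truth list of generative ground truth.
#' @slot config the [CohortConfig-class] that produced the cohort.
#' @export
setClass("SyntheticCohort",
  representation(phenotype = "data.frame", series = "list",
                 truth = "list", config = "CohortConfig")
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (nrow(object@phenotype) != length(object@series))
    msg <- c(msg, "phenotype rows must match number of series")
  if (!all(object@phenotype$group %in% c("PFS", "PSS", "HC")))
    msg <- c(msg, "group labels limited to PFS/PSS/HC")
  p <- object@phenotype
  pat <- p$group != "HC"
  if (any(pat)) {
    tot <- p$panssPositive[pat] + p$panssNegative[pat] + p$panssGeneral[pat]
    if (!isTRUE(all(p$panssTotal[pat] == tot)))
      msg <- c(msg, "panssTotal must equal the sum of the three subscales")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a network-based statistics (NBS) permutation test
#'
#' Suprathreshold connected components of the edge-wise group-difference
#' statistic matrix, with family-wise-error-corrected p-values from the
#' max-component-size permutation null.
#'
#' @slot components list; each element has \code{nodes} (integer node ids
#'   within the tested subset), \code{edges} (two-column matrix), \code{size}
#'   (edge count) and \code{correctedP}.
#' @slot statMatrix numeric matrix of observed edge-wise statistics.
#' @slot nullMaxSizes numeric, max component size per permutation.
#' @slot nodes integer, the node subset (original indices) the test ran on.
#' @slot config list echoing threshold, permutations, alpha, seed, pair.
#' @export
setClass("NbsResult",
  representation(components = "list", statMatrix = "matrix",
                 nullMaxSizes = "numeric", nodes = "integer",
                 config = "list")
)

setValidity("NbsResult", function(object) {
  msg <- character()
  np <- length(object@nullMaxSizes)
  for (cmp in object@components) {
    if (cmp$correctedP < 1 / (np + 1) - 1e-12 || cmp$correctedP > 1)
      msg <- c(msg, "corrected p outside [1/(n_perm+1), 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Per-subject metric curves over the sparsity grid
#'
#' Global and nodal graph metrics evaluated at each sparsity threshold, plus
#' their trapezoidal area-under-curve (AUC) summaries.
#'
#' @slot grid numeric, the sparsity grid.
#' @slot global data.frame, one row per grid value with columns Cp, Lp,
#'   Eglob, Eloc, gamma, lambda, sigma.
#' @slot nodal list of arrays (grid x node) named degree, betweenness,
#'   nodalEfficiency; empty when nodal metrics were not requested.
#' @slot auc list with \code{global} (named numeric) and \code{nodal}
#'   (node x metric matrix, or NULL).
#' @export
setClass("MetricCurves",
  representation(grid = "numeric", global = "data.frame",
                 nodal = "list", auc = "list")
)
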