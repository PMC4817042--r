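#' Accessors for time-series objects
#'
#' @param x a [RoiTimeSeries-class], [ConnectivityMatrix-class] or related
#'   object.
#' @return `tsData`: the T x N signal matrix; `trSeconds`: the repetition
#'   time; `roiLabels`: region labels; `motionParams`: the T x 6 motion table
#'   or NULL when absent.
#' @name tsData
#' @aliases trSeconds roiLabels motionParams
NULL

#' @rdname tsData
#' @export
setMethod("tsData", "RoiTimeSeries", function(x) x@data)

#' @rdname tsData
#' @export
setMethod("trSeconds", "RoiTimeSeries", function(x) x@trSeconds)

#' @rdname tsData
#' @export
setMethod("roiLabels", "RoiTimeSeries", function(x) x@roiLabels)

#' @rdname tsData
#' @export
setMethod("motionParams", "RoiTimeSeries", function(x) {
  if (nrow(x@motion)) x@motion else NULL
})

#' @rdname tsData
#' @export
setMethod("roiLabels", "ConnectivityMatrix", function(x) x@roiLabels)

#' Accessors for frame-wise displacement
#'
#' @param x an [FdSeries-class].
#' @return `fdValues`: the per-volume FD vector (mm); `spikeFlags`: logical
#'   flags where FD exceeds the threshold.
#' @name fdValues
#' @aliases spikeFlags
NULL

#' @rdname fdValues
#' @export
setMethod("fdValues", "FdSeries", function(x) x@fd)

#' @rdname fdValues
#' @export
setMethod("spikeFlags", "FdSeries", function(x) x@spikeFlags)

#' Accessors for connectivity and adjacency matrices
#'
#' @param x a [ConnectivityMatrix-class] or [AdjacencyMatrix-class].
#' @return `corValues`: the N x N correlation matrix; `adjValues`: the binary
#'   adjacency matrix; `sparsity`: the realised sparsity target.
#' @name corValues
#' @aliases adjValues sparsity
NULL

#' @rdname corValues
#' @export
setMethod("corValues", "ConnectivityMatrix", function(x) x@r)

#' @rdname corValues
#' @export
setMethod("adjValues", "AdjacencyMatrix", function(x) x@a)

#' @rdname corValues
#' @export
setMethod("sparsity", "AdjacencyMatrix", function(x) x@sparsity)

#' Accessors for synthetic cohorts
#'
#' @param x a [SyntheticCohort-class].
#' @return `phenotype`: the subject table; `cohortSeries`: named list of
#'   [RoiTimeSeries-class]; `groundTruth`: the generative ground-truth list.
#' @name phenotype
#' @aliases cohortSeries groundTruth
NULL

#' @rdname phenotype
#' @export
setMethod("phenotype", "SyntheticCohort", function(x) x@phenotype)

#' @rdname phenotype
#' @export
setMethod("cohortSeries", "SyntheticCohort", function(x) x@series)

#' @rdname phenotype
#' @export
setMethod("groundTruth", "SyntheticCohort", function(x) x@truth)

#' Accessors for NBS results
#'
#' @param x an [NbsResult-class].
#' @return `nbsComponents`: list of suprathreshold components;
#'   `correctedP`: numeric vector of corrected p-values, one per component.
#' @name nbsComponents
#' @aliases correctedP
NULL

#' @rdname nbsComponents
#' @export
setMethod("nbsComponents", "NbsResult", function(x) x@components)

#' @rdname nbsComponents
#' @export
setMethod("correctedP", "NbsResult", function(x)
  vapply(x@components, function(cmp) cmp$correctedP, numeric(1)))

#' AUC summaries of metric curves
#'
#' @param x a [MetricCurves-class].
#' @return list with `global` (named numeric AUC per global metric) and
#'   `nodal` (node x metric AUC matrix, or NULL).
#' @name aucValues
NULL

#' @rdname aucValues
#' @export
setMethod("aucValues", "MetricCurves", function(x) x@auc)

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries: %d volumes x %d regions, TR = %gs, motion %s\n",
              nrow(object@data), ncol(object@data), object@trSeconds,
              if (nrow(object@motion)) "attached" else "absent"))
})

setMethod("show", "FdSeries", function(object) {
  cat(sprintf("FdSeries: %d volumes, mean FD %.3f mm, %d spikes (> %g mm)\n",
              length(object@fd), mean(object@fd), sum(object@spikeFlags),
              object@threshold))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix: %d x %d Pearson correlations\n",
              nrow(object@r), ncol(object@r)))
})

setMethod("show", "AdjacencyMatrix", function(object) {
  cat(sprintf("AdjacencyMatrix: %d nodes, %d edges (sparsity %.2f)\n",
              nrow(object@a), sum(object@a) / 2, object@sparsity))
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@phenotype$group)
  cat(sprintf("SyntheticCohort: %d subjects (%s), %d regions, %d volumes\n",
              nrow(object@phenotype),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              object@config@nRois, object@config@nVolumes))
})

setMethod("show", "NbsResult", function(object) {
  cat(sprintf(
    "NbsResult (%s): %d suprathreshold component(s), %d permutations\n",
    paste(object@config$pair, collapse = " vs "),
    length(object@components), length(object@nullMaxSizes)))
  for (cmp in object@components)
    cat(sprintf("  %d nodes / %d edges, corrected p = %.4g\n",
                length(cmp$nodes), cmp$size, cmp$correctedP))
})

setMethod("show", "MetricCurves", function(object) {
  cat(sprintf(
    "MetricCurves: %d sparsity values in [%.2f, %.2f], nodal metrics %s\n",
    length(object@grid), min(object@grid), max(object@grid),
    if (length(object@nodal)) "present" else "absent"))
})
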