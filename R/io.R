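# Plain-text readers/writers for the pipeline's standard artefacts:
# tab-delimited time-series and motion tables, CSV phenotype and result
# tables, JSON ground truth and report summaries.

#' Write a synthetic cohort to a directory
#'
#' Per-subject time series as tab-delimited text (T rows x N regions, header
#' row of region labels) and motion tables as tab-delimited T x 6; the
#' phenotype table as CSV; the planted ground truth as JSON.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort@series)) {
    ts <- cohort@series[[id]]
    df <- as.data.frame(ts@data)
    names(df) <- ts@roiLabels
    utils::write.table(df, file.path(dir, paste0(id, "_timeseries.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(ts@motion),
                       file.path(dir, paste0(id, "_motion.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  utils::write.csv(cohort@phenotype, file.path(dir, "phenotype.csv"),
                   row.names = FALSE)
  truth <- cohort@truth
  jsonlite::write_json(
    list(severity = as.list(truth$severity),
         spikeVolumes = truth$spikeVolumes,
         deficitEdges = lapply(truth$deficitEdges, unclass),
         shiftGroup = truth$shiftGroup,
         moduleAssignment = truth$moduleAssignment),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a regional time series (and optional motion table) from disk
#'
#' @param path tab-delimited T x N file with a header row of region labels.
#' @param motionPath optional tab-delimited T x 6 motion file (no header).
#' @param trSeconds repetition time in seconds.
#' @return a [RoiTimeSeries-class].
#' @export
readRoiTimeSeries <- function(path, motionPath = NULL, trSeconds = 2.0) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  motion <- NULL
  if (!is.null(motionPath))
    motion <- as.matrix(utils::read.table(motionPath, header = FALSE,
                                          sep = "\t"))
  roiTimeSeries(as.matrix(df), trSeconds = trSeconds,
                roiLabels = names(df), motion = motion)
}

#' Write a connectivity matrix as tab-delimited text
#'
#' @param C a [ConnectivityMatrix-class].
#' @param path output file.
#' @export
writeConnectivity <- function(C, path) {
  df <- as.data.frame(C@r)
  names(df) <- C@roiLabels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an adjacency matrix as an edge-list CSV
#'
#' @param A an [AdjacencyMatrix-class].
#' @param path output file.
#' @param labels optional node labels; indices are used when NULL.
#' @export
writeEdgeList <- function(A, path, labels = NULL) {
  ut <- .upperPairs(nrow(A@a))
  e <- ut[A@a[ut] > 0, , drop = FALSE]
  lab <- function(k) if (is.null(labels)) k else labels[k]
  utils::write.csv(data.frame(i = lab(e[, 1]), j = lab(e[, 2])),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' Accepts a YAML or JSON file whose top-level keys match the arguments of
#' [cohortConfig()]; \code{deficitEdges}, when present, must be a mapping of
#' \code{PFS}/\code{PSS} to lists of two-element node pairs.
#'
#' @param path configuration file (.yaml/.yml or .json).
#' @return a [CohortConfig-class].
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$deficitEdges))
    cfg$deficitEdges <- lapply(cfg$deficitEdges, function(e)
      matrix(as.integer(unlist(e)), ncol = 2, byrow = TRUE))
  do.call(cohortConfig, cfg)
}

#' Write the pipeline report to disk
#'
#' CSV tables (ANOVA results, NBS components, symptom correlations, FD
#' report, AUC table) per GSR variant plus a JSON summary, mirroring the
#' in-memory report returned by [runPipeline()].
#'
#' @param report list returned by [runPipeline()].
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cohort@phenotype, file.path(dir, "phenotype.csv"),
                   row.names = FALSE)
  summary <- list()
  for (vn in intersect(names(report), c("gsr", "noGsr"))) {
    vdir <- file.path(dir, vn)
    dir.create(vdir, showWarnings = FALSE)
    res <- report[[vn]]
    utils::write.csv(res$anovaGlobal, file.path(vdir, "anova_global.csv"),
                     row.names = FALSE)
    utils::write.csv(res$globalAuc, file.path(vdir, "auc_global.csv"),
                     row.names = FALSE)
    utils::write.csv(res$fdReport, file.path(vdir, "fd_report.csv"),
                     row.names = FALSE)
    if (!is.null(res$nodalPvals))
      utils::write.csv(
        data.frame(node = seq_len(nrow(res$nodalPvals)), res$nodalPvals),
        file.path(vdir, "anova_nodal.csv"), row.names = FALSE)
    utils::write.csv(res$correlations, file.path(vdir, "correlations.csv"),
                     row.names = FALSE)
    nbsRows <- list()
    for (pn in names(res$nbs)) {
      r <- res$nbs[[pn]]
      for (ci in seq_along(r@components)) {
        cmp <- r@components[[ci]]
        nbsRows[[length(nbsRows) + 1L]] <- data.frame(
          pair = pn, component = ci, nNodes = length(cmp$nodes),
          nEdges = cmp$size, correctedP = cmp$correctedP)
      }
    }
    utils::write.csv(
      if (length(nbsRows)) do.call(rbind, nbsRows)
      else data.frame(pair = character(), component = integer(),
                      nNodes = integer(), nEdges = integer(),
                      correctedP = numeric()),
      file.path(vdir, "nbs_components.csv"), row.names = FALSE)
    summary[[vn]] <- list(
      significantGlobalMetrics = res$anovaGlobal$metric[
        !is.na(res$anovaGlobal$p) & res$anovaGlobal$p < 0.05],
      affectedNodeCount = length(res$affectedNodes),
      nbs = lapply(res$nbs, function(r)
        lapply(r@components, function(cmp)
          list(nNodes = length(cmp$nodes), nEdges = cmp$size,
               correctedP = cmp$correctedP))))
  }
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
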