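#' Construct a regional time-series object
#'
#' @param data numeric T x N matrix of regional mean signals.
#' @param trSeconds repetition time in seconds.
#' @param roiLabels optional region labels (defaults to column names or
#'   ROI001...).
#' @param motion optional T x 6 motion-parameter matrix (mm, radians).
#' @return a [RoiTimeSeries-class].
#' @export
roiTimeSeries <- function(data, trSeconds = 2.0, roiLabels = NULL,
                          motion = NULL) {
  data <- as.matrix(data)
  if (is.null(roiLabels))
    roiLabels <- colnames(data)
  if (is.null(roiLabels))
    roiLabels <- sprintf("ROI%03d", seq_len(ncol(data)))
  dimnames(data) <- NULL
  if (is.null(motion)) motion <- matrix(numeric(0), 0, 6)
  motion <- as.matrix(motion)
  dimnames(motion) <- NULL
  new("RoiTimeSeries", data = data, trSeconds = trSeconds,
      roiLabels = as.character(roiLabels), motion = motion)
}

#' Discard initial volumes
#'
#' Drops the first \code{k} volumes (signal-equilibration period) from the
#' time series and, when present, the aligned motion table.
#'
#' @param ts a [RoiTimeSeries-class].
#' @param k number of initial volumes to discard (default 10).
#' @return the trimmed [RoiTimeSeries-class].
#' @export
discardInitialVolumes <- function(ts, k = 10) {
  stopifnot(is(ts, "RoiTimeSeries"))
  T <- nrow(ts@data)
  if (T <= k)
    stop(sprintf("cannot discard %d volumes from a series of length %d", k, T))
  if (k == 0) return(ts)
  keep <- (k + 1):T
  motion <- if (nrow(ts@motion)) ts@motion[keep, , drop = FALSE]
            else ts@motion
  new("RoiTimeSeries", data = ts@data[keep, , drop = FALSE],
      trSeconds = ts@trSeconds, roiLabels = ts@roiLabels, motion = motion)
}

#' Frame-wise displacement from motion parameters
#'
#' FD at volume t is the sum over the six rigid-body parameters of the
#' absolute backward difference, with each rotation converted to arc length
#' on a 50 mm sphere before summing (Power convention). \code{fd[1] = 0}.
#'
#' @param motion T x 6 matrix: three translations (mm) then three rotations
#'   (radians).
#' @param threshold spike threshold in mm (default 0.5); volumes with
#'   FD strictly greater than it are flagged.
#' @param headRadius sphere radius (mm) for the rotation arc length.
#' @return an [FdSeries-class].
#' @export
computeFd <- function(motion, threshold = 0.5, headRadius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion table must have exactly 6 columns (3 translations, 3 rotations)")
  d <- abs(apply(motion, 2, function(p) c(0, diff(p))))
  d <- matrix(d, ncol = 6)
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    headRadius * rowSums(d[, 4:6, drop = FALSE])
  fd[1] <- 0
  new("FdSeries", fd = fd, threshold = threshold,
      spikeFlags = fd > threshold)
}

#' Flag spike volumes
#'
#' Strictly-greater-than comparison of FD against the threshold.
#'
#' @param fd an [FdSeries-class] or numeric FD vector.
#' @param threshold mm (default 0.5).
#' @return logical vector of spike flags.
#' @export
flagSpikes <- function(fd, threshold = 0.5) {
  v <- if (is(fd, "FdSeries")) fd@fd else as.numeric(fd)
  v > threshold
}

#' Regress nuisance covariates from regional time series
#'
#' Replaces each regional series by its ordinary-least-squares residual
#' against a design of: intercept, linear trend, the six motion parameters,
#' their first differences (first row backfilled with 0), optionally the
#' global signal (mean over regions), optional extra confound columns (e.g.
#' white-matter or CSF signals when available), and one indicator column per
#' flagged spike volume (scrubbing-by-regression). Collinear design columns
#' are dropped with a warning.
#'
#' @param ts a [RoiTimeSeries-class] with a motion table attached.
#' @param spikeFlags logical length-T vector, or NULL for none.
#' @param useGsr include the global-signal column?
#' @param extraConfounds optional T x k matrix of additional confounds.
#' @return the residual [RoiTimeSeries-class] (zero mean per region, exactly
#'   orthogonal to every retained design column).
#' @export
regressNuisance <- function(ts, spikeFlags = NULL, useGsr = TRUE,
                            extraConfounds = NULL) {
  stopifnot(is(ts, "RoiTimeSeries"))
  if (!nrow(ts@motion))
    stop("nuisance regression requires an attached motion table")
  T <- nrow(ts@data)
  mot <- ts@motion
  dmot <- rbind(0, diff(mot))
  X <- cbind(1, seq_len(T) / T, mot, dmot)
  if (useGsr) X <- cbind(X, rowMeans(ts@data))
  if (!is.null(extraConfounds)) X <- cbind(X, as.matrix(extraConfounds))
  if (!is.null(spikeFlags) && any(spikeFlags)) {
    ind <- outer(seq_len(T), which(spikeFlags), "==") * 1
    X <- cbind(X, ind)
  }
  if (ncol(X) + 1L >= T)
    stop("more confounds than time points; cannot regress")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    warning(sprintf("dropping %d collinear design column(s)",
                    ncol(X) - qx$rank))
    qx <- qr(X[, keep, drop = FALSE])
  }
  res <- qr.resid(qx, ts@data)
  new("RoiTimeSeries", data = res, trSeconds = ts@trSeconds,
      roiLabels = ts@roiLabels, motion = ts@motion)
}

# Zero-phase (forward-backward) IIR filtering of every column at once:
# zero-pad, forward pass (FIR part then the AR recursion), reverse, repeat,
# truncate. Matches signal::filtfilt applied per column exactly.
.filtMatrix <- function(b, a, M) {
  nb <- length(b)
  M1 <- rbind(matrix(0, nb - 1, ncol(M)), M)
  y <- stats::filter(M1, b / a[1], sides = 1)
  y <- y[nb:nrow(M1), , drop = FALSE]
  if (length(a) >= 2)
    y <- stats::filter(y, -a[-1] / a[1], method = "recursive")
  matrix(as.numeric(y), nrow(M), ncol(M))
}

.filtfiltMatrix <- function(b, a, M) {
  npad <- 2 * max(length(a), length(b))
  Y <- .filtMatrix(b, a, rbind(M, matrix(0, npad, ncol(M))))
  Y <- .filtMatrix(b, a, Y[nrow(Y):1, , drop = FALSE])
  Y[nrow(Y):1, , drop = FALSE][seq_len(nrow(M)), , drop = FALSE]
}

#' Band-pass filter regional time series
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass, the
#' standard choice for resting-state regional signals. Attenuates power
#' outside the pass band while preserving pass-band amplitude and phase.
#'
#' @param ts a [RoiTimeSeries-class].
#' @param low lower pass-band edge in Hz (default 0.01).
#' @param high upper pass-band edge in Hz (default 0.08).
#' @param order Butterworth order (default 4).
#' @return the filtered [RoiTimeSeries-class].
#' @export
bandpassFilter <- function(ts, low = 0.01, high = 0.08, order = 4) {
  stopifnot(is(ts, "RoiTimeSeries"))
  nyquist <- 1 / (2 * ts@trSeconds)
  if (!(low > 0 && low < high && high < nyquist))
    stop(sprintf("need 0 < low < high < Nyquist (%.3f Hz)", nyquist))
  bf <- signal::butter(order, c(low, high) / nyquist, type = "pass")
  filt <- .filtfiltMatrix(bf$b, bf$a, ts@data)
  new("RoiTimeSeries", data = filt,
      trSeconds = ts@trSeconds, roiLabels = ts@roiLabels,
      motion = ts@motion)
}

#' Full preprocessing of one subject's regional time series
#'
#' Fixed stage order: discard initial volumes, compute frame-wise
#' displacement and flag spikes, regress nuisance covariates (with spike
#' indicator columns), band-pass filter.
#'
#' @param ts a [RoiTimeSeries-class] with motion attached.
#' @param discard initial volumes to drop (default 10).
#' @param fdThreshold spike threshold in mm (default 0.5).
#' @param useGsr include global-signal regression?
#' @param low,high band-pass edges in Hz.
#' @param extraConfounds optional extra confound columns (post-discard rows).
#' @return list with \code{series} (the cleaned [RoiTimeSeries-class]) and
#'   \code{fd} (the [FdSeries-class] on the retained volumes).
#' @export
preprocessSeries <- function(ts, discard = 10, fdThreshold = 0.5,
                             useGsr = TRUE, low = 0.01, high = 0.08,
                             extraConfounds = NULL) {
  ts <- discardInitialVolumes(ts, discard)
  fd <- computeFd(ts@motion, threshold = fdThreshold)
  cleaned <- regressNuisance(ts, spikeFlags = fd@spikeFlags,
                             useGsr = useGsr,
                             extraConfounds = extraConfounds)
  filtered <- bandpassFilter(cleaned, low = low, high = high)
  list(series = filtered, fd = fd)
}

#' Preprocess every subject of a cohort
#'
#' @param cohort a [SyntheticCohort-class] (or named list of
#'   [RoiTimeSeries-class]).
#' @param ... passed to [preprocessSeries()].
#' @return list with \code{series} (named list of cleaned series) and
#'   \code{fdReport} (data.frame: subject, meanFd, spikeCount).
#' @export
preprocessCohort <- function(cohort, ...) {
  series <- if (is(cohort, "SyntheticCohort")) cohort@series else cohort
  out <- lapply(series, preprocessSeries, ...)
  fdReport <- data.frame(
    subjectId = names(series),
    meanFd = vapply(out, function(o) mean(o$fd@fd), numeric(1)),
    spikeCount = vapply(out, function(o) sum(o$fd@spikeFlags), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(series = lapply(out, `[[`, "series"), fdReport = fdReport)
}
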