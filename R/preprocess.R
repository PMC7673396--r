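#' Construct a BoldRun
#'
#' Wraps a 4D array as a \linkS4class{BoldRun}. If no mask is given, voxels
#' with finite, non-constant time series are marked valid.
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param tr repetition time in seconds.
#' @param validMask optional 3D logical array.
#' @param runId character label.
#' @return A \linkS4class{BoldRun}.
#' @export
boldRun <- function(data, tr, validMask = NULL, runId = "run") {
    if (length(dim(data)) != 4L)
        stop("data must be a 4D array (x, y, z, time)")
    if (is.null(validMask)) {
        vox <- matrix(data, prod(dim(data)[1:3]), dim(data)[4L])
        ok <- apply(vox, 1L, function(x) all(is.finite(x))) &
            matrixStats_rowSds(vox) > 0
        validMask <- array(ok, dim(data)[1:3])
    }
    new("BoldRun", data = data, tr = tr, validMask = validMask,
        runId = runId)
}

# row SDs without extra deps
matrixStats_rowSds <- function(x) {
    m <- rowMeans(x)
    sqrt(rowSums((x - m)^2) / (ncol(x) - 1L))
}

#' Remove a linear trend from a time series
#'
#' Ordinary least-squares line removal; the residual has mean (numerically)
#' zero and zero correlation with the time index.
#'
#' @param series numeric vector, length >= 3.
#' @return Detrended numeric vector of the same length.
#' @export
detrendLinear <- function(series) {
    n <- length(series)
    if (n < 3L) stop("series must have length >= 3")
    if (!all(is.finite(series))) stop("series must be finite")
    t <- seq_len(n) - (n + 1) / 2          # centered index
    beta <- sum(t * series) / sum(t * t)
    series - mean(series) - beta * t
}

# detrend every column of a time x voxel matrix (closed-form OLS)
.detrendColumns <- function(x) {
    n <- nrow(x)
    t <- seq_len(n) - (n + 1) / 2
    beta <- as.vector(crossprod(t, x)) / sum(t * t)
    x - rep(colMeans(x), each = n) - outer(t, beta)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth band-pass. The input
#' is reflect-padded by one filter settling length before filtering so run
#' edges do not pick up transient-driven spurious lags; the output has no
#' group delay and the same length as the input.
#'
#' @param series numeric vector (or a time-by-voxel matrix; each column is
#'   filtered).
#' @param tr sampling interval, seconds.
#' @param low,high pass-band edges in Hz; defaults 0.01 and 0.1, the
#'   standard resting-state analysis band.
#' @param order Butterworth order (applied twice, forward and backward).
#' @return Filtered series/matrix, same dimensions as the input.
#' @export
bandpass <- function(series, tr, low = 0.01, high = 0.1, order = 4L) {
    nyq <- 1 / (2 * tr)
    if (!(low > 0 && high > low && high < nyq))
        stop("band must satisfy 0 < low < high < Nyquist (", signif(nyq, 4),
             " Hz)")
    bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
    one <- function(x) {
        n <- length(x)
        pad <- min(n - 1L, ceiling(1 / (low * tr)))  # ~ settling length
        xp <- c(2 * x[1L] - x[(pad + 1L):2L],        # odd reflection
                x,
                2 * x[n] - x[(n - 1L):(n - pad)])
        y <- signal::filtfilt(bf, xp)
        y[(pad + 1L):(pad + n)]
    }
    if (is.matrix(series)) apply(series, 2L, one) else one(series)
}

#' Threshold a gray-matter probability map into a mask
#'
#' @param probabilityMap 3D array of probabilities in [0, 1].
#' @param threshold inclusion threshold; a voxel is included iff its
#'   probability is >= threshold. Default 0.3 (30\% gray-matter probability).
#' @return 3D logical array.
#' @export
makeGrayMask <- function(probabilityMap, threshold = 0.3) {
    if (any(probabilityMap < 0 | probabilityMap > 1, na.rm = TRUE))
        stop("probabilities must lie in [0, 1]")
    mask <- !is.na(probabilityMap) & probabilityMap >= threshold
    if (!any(mask))
        warning("gray-matter mask is empty at threshold ", threshold)
    mask
}

#' Compute the global mean signal (GMS)
#'
#' Unweighted mean across in-mask voxels at each time point.
#'
#' @param run a \linkS4class{BoldRun} (typically preprocessed).
#' @param grayMask 3D logical array on the run's grid.
#' @return A \linkS4class{ReferenceSignal} with label \code{GMS}.
#' @export
computeGMS <- function(run, grayMask) {
    stopifnot(is(run, "BoldRun"))
    if (!identical(dim(grayMask), dim(run@data)[1:3]))
        stop("mask grid must match the run grid")
    use <- grayMask & run@validMask
    if (!any(use)) stop("mask selects no valid voxels")
    vox <- matrix(run@data, prod(dim(run@data)[1:3]), dim(run@data)[4L])
    gms <- colMeans(vox[as.vector(use), , drop = FALSE])
    new("ReferenceSignal", values = gms, tr = run@tr, label = "GMS")
}

#' Temporal preprocessing of a run
#'
#' Linear detrending followed by zero-phase band-pass filtering of every
#' voxel time series, in that order. Voxels with (numerically) zero variance
#' after filtering are dropped from the validity mask, since their
#' correlations downstream would be undefined.
#'
#' @param run a \linkS4class{BoldRun}.
#' @inheritParams bandpass
#' @return A preprocessed \linkS4class{BoldRun}.
#' @export
preprocessRun <- function(run, low = 0.01, high = 0.1) {
    stopifnot(is(run, "BoldRun"))
    d <- dim(run@data)
    vox <- t(matrix(run@data, prod(d[1:3]), d[4L]))      # time x voxel
    idx <- which(as.vector(run@validMask))
    y <- .detrendColumns(vox[, idx, drop = FALSE])
    y <- bandpass(y, run@tr, low, high)
    out <- matrix(0, nrow(vox), ncol(vox))
    out[, idx] <- y
    sds <- matrixStats_rowSds(t(y))
    keep <- rep(FALSE, ncol(vox))
    keep[idx] <- sds > 1e-12 * max(sds, 1e-300)
    new("BoldRun", data = array(t(out), d), tr = run@tr,
        validMask = array(keep, d[1:3]), runId = run@runId)
}

#' Concatenate runs in time / split a concatenated series back into runs
#'
#' Runs must share the spatial grid and TR. Boundaries are recorded as
#' half-open frame intervals \code{[start, end)} (1-based start, exclusive
#' end), so deconcatenation reconstructs the exact per-run lengths:
#' concatenation followed by deconcatenation is the identity on time courses.
#'
#' @param runs list of \linkS4class{BoldRun}s.
#' @return \code{concatenateRuns}: list with \code{run} (the concatenated
#'   \linkS4class{BoldRun}; its valid mask is the intersection of the runs'
#'   masks) and \code{boundaries} (integer matrix, columns \code{start},
#'   \code{end}).
#' @export
concatenateRuns <- function(runs) {
    stopifnot(length(runs) >= 1L, all(vapply(runs, is, TRUE, "BoldRun")))
    grids <- lapply(runs, function(r) dim(r@data)[1:3])
    trs <- vapply(runs, function(r) r@tr, 1)
    if (!all(vapply(grids, identical, TRUE, grids[[1L]])) ||
        max(abs(trs - trs[1L])) > 1e-9)
        stop("all runs must share the same grid and TR")
    lens <- vapply(runs, function(r) dim(r@data)[4L], 1L)
    ends <- cumsum(lens)
    starts <- c(1L, head(ends, -1L) + 1L)
    data <- array(0, c(grids[[1L]], sum(lens)))
    for (i in seq_along(runs))
        data[, , , starts[i]:ends[i]] <- runs[[i]]@data
    mask <- Reduce(`&`, lapply(runs, function(r) r@validMask))
    list(run = new("BoldRun", data = data, tr = trs[1L], validMask = mask,
                   runId = "concatenated"),
         boundaries = cbind(start = starts, end = ends + 1L))
}

#' @rdname concatenateRuns
#' @param series numeric vector or time-by-k matrix of concatenated frames.
#' @param boundaries boundary matrix from \code{concatenateRuns}.
#' @return \code{deconcatenate}: list of per-run series (or matrices).
#' @export
deconcatenate <- function(series, boundaries) {
    n <- if (is.matrix(series)) nrow(series) else length(series)
    if (max(boundaries[, "end"]) - 1L != n)
        stop("boundaries do not match the series length")
    lapply(seq_len(nrow(boundaries)), function(i) {
        idx <- boundaries[i, "start"]:(boundaries[i, "end"] - 1L)
        if (is.matrix(series)) series[idx, , drop = FALSE] else series[idx]
    })
}
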