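# Lag-map comparison statistics, composite-map assembly and group-level
# inference.

#' Zero-center a lag map
#'
#' Shifts the valid-voxel lags to mean zero. Lag maps measured against
#' different references have arbitrary absolute offsets; centering makes
#' them comparable. Idempotent.
#'
#' @param lagMap a \linkS4class{LagMap}.
#' @return The centered \linkS4class{LagMap}. Note the centered lags are in
#'   general no longer integer multiples of the grid step, so the result is
#'   for comparison, not for further grid-based processing.
#' @export
centerLags <- function(lagMap) {
    stopifnot(is(lagMap, "LagMap"))
    if (sum(lagMap@validMask) < 2L)
        stop("lag map needs at least 2 valid voxels")
    m <- mean(lagMap@lag[lagMap@validMask])
    out <- lagMap
    out@lag[out@validMask] <- out@lag[out@validMask] - m
    # centered lags leave the grid; relax the grid bookkeeping accordingly
    out@gridStep <- NA_real_
    out@searchHalfwidth <- out@searchHalfwidth + abs(m)
    out
}

# valid-voxel lags of a LagMap as a vector plus the joint mask helper
.jointMask <- function(a, b) a@validMask & b@validMask

#' Voxelwise correlation between two lag maps
#'
#' Pearson correlation of the two maps' lags over the joint valid mask
#' (intersection). Centering is immaterial to the correlation; maps are
#' compared as-is.
#'
#' @param mapA,mapB \linkS4class{LagMap}s (or
#'   \linkS4class{CompositeLagMap}) on the same grid.
#' @return The correlation, with attributes \code{nVoxels} (joint-mask
#'   size) and \code{lowConfidence} (TRUE when the joint mask has fewer
#'   than 10 voxels, also flagged by a warning).
#' @export
compareLagMaps <- function(mapA, mapB) {
    if (!identical(dim(mapA@lag), dim(mapB@lag)))
        stop("maps must share a grid")
    joint <- .jointMask(mapA, mapB)
    n <- sum(joint)
    if (n < 2L) stop("joint valid mask is empty")
    low <- n < 10L
    if (low)
        warning("joint mask has fewer than 10 voxels; low-confidence ",
                "comparison")
    r <- cor(mapA@lag[joint], mapB@lag[joint])
    structure(r, nVoxels = n, lowConfidence = low)
}

#' Group test of per-run lag-map correlations
#'
#' Fisher-Z transforms the per-run correlations and applies a one-sample
#' two-tailed t test against zero (no correlation). The degenerate all-zero
#' case returns t = 0, p = 1.
#'
#' @param perRunR numeric vector of per-run correlations, each |r| < 1,
#'   length >= 2.
#' @param nVoxelsPerRun optional integer vector of joint-mask sizes.
#' @param jointMaskRule label recorded in the result.
#' @return A \linkS4class{ComparisonStats}.
#' @export
groupTest <- function(perRunR, nVoxelsPerRun = NULL,
                      jointMaskRule = "intersection") {
    n <- length(perRunR)
    if (n < 2L) stop("need at least 2 runs")
    if (any(abs(perRunR) >= 1))
        stop("|r| = 1 gives an infinite Fisher Z; cannot test")
    z <- atanh(perRunR)
    s <- sd(z)
    if (s == 0) {
        tStat <- if (mean(z) == 0) 0 else sign(mean(z)) * Inf
    } else {
        tStat <- mean(z) / (s / sqrt(n))
    }
    p <- 2 * pt(-abs(tStat), df = n - 1L)
    if (is.null(nVoxelsPerRun)) nVoxelsPerRun <- rep(NA_integer_, n)
    new("ComparisonStats", perRunR = perRunR, fisherZ = z,
        tStat = tStat, pTwoTailed = p,
        nVoxelsPerRun = as.integer(nVoxelsPerRun),
        jointMaskRule = jointMaskRule)
}

#' Build a composite lag map from per-IC maps
#'
#' Each IC lag map is shifted by a per-IC constant offset so that the
#' midpoint of its valid-lag range (default; \code{method = "mean"} uses
#' the mean of the values instead) equals that of the GMS lag map, then the
#' maps are superimposed: a voxel covered by several ICs is assigned to the
#' IC with the highest magnitude there. Offsets are per-IC constants, so
#' within-IC lag contrasts are never altered.
#'
#' @param icLagMaps list of \linkS4class{LagMap}, one per IC (>= 1).
#' @param gmsLagMap the GMS-referenced \linkS4class{LagMap}.
#' @param method how "mean of the lag range" is read: \code{"midpoint"}
#'   ((min+max)/2, default) or \code{"mean"} (mean of all valid lags).
#' @return A \linkS4class{CompositeLagMap}.
#' @export
buildComposite <- function(icLagMaps, gmsLagMap,
                           method = c("midpoint", "mean")) {
    method <- match.arg(method)
    stopifnot(length(icLagMaps) >= 1L, is(gmsLagMap, "LagMap"))
    d <- dim(gmsLagMap@lag)
    mid <- function(v) if (method == "midpoint")
        (min(v) + max(v)) / 2 else mean(v)
    if (!any(gmsLagMap@validMask)) stop("GMS lag map has no valid voxels")
    gmsMid <- mid(gmsLagMap@lag[gmsLagMap@validMask])
    lag <- array(NA_real_, d)
    bestMag <- array(-Inf, d)
    contrib <- array(0L, d)
    offsets <- numeric(length(icLagMaps))
    for (i in seq_along(icLagMaps)) {
        m <- icLagMaps[[i]]
        if (!identical(dim(m@lag), d)) stop("maps must share a grid")
        if (!any(m@validMask)) { offsets[i] <- 0; next }
        offsets[i] <- gmsMid - mid(m@lag[m@validMask])
        upd <- m@validMask & (m@magnitude > bestMag | contrib == 0L)
        upd[is.na(upd)] <- FALSE
        lag[upd] <- m@lag[upd] + offsets[i]
        bestMag[upd] <- m@magnitude[upd]
        contrib[upd] <- i
    }
    valid <- contrib > 0L
    if (!any(valid)) stop("composite has no valid voxels")
    new("CompositeLagMap", lag = lag, contributor = contrib,
        offsetsApplied = offsets, validMask = valid)
}

#' Pooled 2D histogram of paired lag values
#'
#' Pools voxelwise (lagA, lagB) pairs over the joint masks of each map
#' pair (typically one pair per run) and bins them on the upsampled lag
#' grid, with bin edges aligned to grid steps.
#'
#' @param mapPairs list of list(a =, b =) \linkS4class{LagMap} pairs.
#' @return integer matrix of counts; \code{dimnames} give the bin-center
#'   lags of map a (rows) and map b (columns); attribute \code{n} is the
#'   total pair count (the sum of joint-mask sizes).
#' @export
pooledHistogram <- function(mapPairs) {
    stopifnot(length(mapPairs) >= 1L)
    step <- mapPairs[[1L]]$a@gridStep
    la <- c(); lb <- c()
    for (p in mapPairs) {
        joint <- .jointMask(p$a, p$b)
        la <- c(la, p$a@lag[joint])
        lb <- c(lb, p$b@lag[joint])
    }
    ka <- round(la / step); kb <- round(lb / step)
    ra <- range(ka); rb <- range(kb)
    counts <- matrix(0L, ra[2L] - ra[1L] + 1L, rb[2L] - rb[1L] + 1L,
                     dimnames = list(a = (ra[1L]:ra[2L]) * step,
                                     b = (rb[1L]:rb[2L]) * step))
    for (i in seq_along(ka))
        counts[ka[i] - ra[1L] + 1L, kb[i] - rb[1L] + 1L] <-
            counts[ka[i] - ra[1L] + 1L, kb[i] - rb[1L] + 1L] + 1L
    structure(counts, n = length(ka))
}

#' Correlation implied by a pooled 2D lag histogram
#'
#' Weighted Pearson correlation of the bin centers, weights = counts;
#' agrees with the pooled voxelwise correlation up to binning.
#'
#' @param counts matrix from \code{\link{pooledHistogram}}.
#' @return correlation coefficient.
#' @export
histogramCorrelation <- function(counts) {
    a <- as.numeric(rownames(counts))
    b <- as.numeric(colnames(counts))
    w <- counts / sum(counts)
    ma <- sum(rowSums(w) * a)
    mb <- sum(colSums(w) * b)
    cov <- sum(w * outer(a - ma, b - mb))
    va <- sum(rowSums(w) * (a - ma)^2)
    vb <- sum(colSums(w) * (b - mb)^2)
    cov / sqrt(va * vb)
}
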