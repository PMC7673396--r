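# Extracranial artery ROI extraction, artery-vs-periphery intensity
# comparison, and artery-vs-GMS cross-correlation. Unlike the voxelwise
# lag estimator (positive fits only), the arterial analysis searches both
# signs of correlation: the physiological finding of interest is a
# negative coupling between the arterial inflow signal and the GMS.

#' Extract a bright artery ROI by intensity thresholding
#'
#' Semi-automatic artery segmentation: within a search region, voxels at or
#' above an intensity threshold are selected (arteries are bright on the
#' mean image through the time-of-flight inflow effect) and the largest
#' 26-connected component is retained; ties break deterministically toward
#' the component containing the smallest linear voxel index.
#'
#' @param meanIntensityImage 3D array (e.g. temporal mean of a run).
#' @param searchRegion 3D logical array; must be nonempty.
#' @param intensityThreshold inclusion threshold.
#' @return 3D logical artery mask. If the mask covers more than half of
#'   the search region a warning flags the threshold as suspicious.
#' @export
extractArteryROI <- function(meanIntensityImage, searchRegion,
                             intensityThreshold) {
    if (!any(searchRegion)) stop("search region is empty")
    cand <- searchRegion & meanIntensityImage >= intensityThreshold
    if (!any(cand))
        stop("no voxel above the intensity threshold; lower the threshold")
    labels <- .connectedComponents(cand, connectivity = 26L)
    sizes <- tabulate(labels[labels > 0L])
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
        # lexicographic (linear index) tie-break
        firstIdx <- vapply(best, function(l) min(which(labels == l)), 1L)
        best <- best[which.min(firstIdx)]
    }
    mask <- labels == best
    if (sum(mask) > 0.5 * sum(searchRegion))
        warning("artery ROI covers more than half of the search region; ",
                "the threshold may be too low")
    mask
}

# 6-connectivity morphological dilation by `radius` iterations
.dilate6 <- function(mask, radius = 1L) {
    d <- dim(mask)
    out <- mask
    for (r in seq_len(radius)) {
        grown <- out
        grown[-1, , ] <- grown[-1, , ] | out[-d[1L], , ]
        grown[-d[1L], , ] <- grown[-d[1L], , ] | out[-1, , ]
        grown[, -1, ] <- grown[, -1, ] | out[, -d[2L], ]
        grown[, -d[2L], ] <- grown[, -d[2L], ] | out[, -1, ]
        grown[, , -1] <- grown[, , -1] | out[, , -d[3L]]
        grown[, , -d[3L]] <- grown[, , -d[3L]] | out[, , -1]
        out <- grown
    }
    out
}

#' Peripheral ROI around an artery mask
#'
#' Inflates the artery ROI by morphological dilation (6-connectivity ball)
#' and subtracts the original, yielding a disjoint shell of surrounding
#' tissue.
#'
#' @param arteryMask 3D logical array.
#' @param radiusVoxels dilation radius in voxels (>= 1; default 2).
#' @return 3D logical shell mask, disjoint from \code{arteryMask}. A
#'   warning is raised when the dilation is clipped at the image boundary.
#' @export
peripheralROI <- function(arteryMask, radiusVoxels = 2L) {
    if (radiusVoxels < 1L) stop("radiusVoxels must be >= 1")
    d <- dim(arteryMask)
    dil <- .dilate6(arteryMask, radiusVoxels)
    border <- array(FALSE, d)
    border[c(1L, d[1L]), , ] <- TRUE
    border[, c(1L, d[2L]), ] <- TRUE
    border[, , c(1L, d[3L])] <- TRUE
    if (any(dil & border))
        warning("dilated ROI reaches the image boundary; shell is clipped")
    dil & !arteryMask
}

#' Paired artery-vs-periphery intensity comparison
#'
#' For each artery, the temporal-mean intensity of the artery ROI and of
#' its peripheral shell are computed from the (non-smoothed) run, and the
#' per-artery differences are tested with a paired two-tailed t test.
#'
#' @param runs a single \linkS4class{BoldRun} or a list of runs, one per
#'   artery (a single run is recycled across arteries).
#' @param arteryMasks,peripheryMasks lists of 3D logical masks, one pair
#'   per artery (>= 2 pairs).
#' @return list with \code{meanArtery}, \code{meanPeriphery} (per-artery
#'   temporal-mean intensities), \code{t}, \code{p} (two-tailed),
#'   \code{df}. Zero-variance differences yield \code{t = NA} with a
#'   warning (degenerate case).
#' @export
compareArteryPeriphery <- function(runs, arteryMasks, peripheryMasks) {
    if (is(runs, "BoldRun"))
        runs <- rep(list(runs), length(arteryMasks))
    nPairs <- length(arteryMasks)
    if (nPairs < 2L) stop("need at least 2 artery/periphery pairs")
    stopifnot(length(peripheryMasks) == nPairs, length(runs) == nPairs)
    roiMean <- function(run, mask) {
        d <- dim(run@data)
        mean(matrix(run@data, prod(d[1:3]), d[4L])[as.vector(mask), ,
                                                   drop = FALSE])
    }
    ma <- mapply(roiMean, runs, arteryMasks)
    mp <- mapply(roiMean, runs, peripheryMasks)
    diffs <- ma - mp
    if (sd(diffs) == 0) {
        warning("zero variance across artery-periphery differences; ",
                "paired t is degenerate")
        return(list(meanArtery = ma, meanPeriphery = mp, t = NA_real_,
                    p = NA_real_, df = nPairs - 1L))
    }
    tt <- t.test(ma, mp, paired = TRUE)
    list(meanArtery = ma, meanPeriphery = mp,
         t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter))
}

# full cross-correlation function over the symmetric upsampled lag grid;
# positive lag = x later than y
.xcorrFunction <- function(x, y, tr, searchHalfwidth, factor,
                           minOverlap = 0.8) {
    step <- tr / factor
    K <- floor(searchHalfwidth / step + 1e-9)
    xu <- upsampleSeries(x, factor)
    yu <- upsampleSeries(y, factor)
    N <- length(xu)
    lags <- (-K:K) * step
    r <- rep(NA_real_, length(lags))
    for (i in seq_along(lags)) {
        k <- -K + i - 1L
        if (k >= 0L) { a <- xu[(1L + k):N]; b <- yu[1L:(N - k)] }
        else { a <- xu[1L:(N + k)]; b <- yu[(1L - k):N] }
        if (length(a) < minOverlap * N) next
        r[i] <- cor(a, b)
    }
    keep <- !is.na(r)
    list(lag = lags[keep], r = r[keep], gridStep = step)
}

#' Cross-correlation of the arterial signal with the GMS
#'
#' Computes the full cross-correlation function between the artery series
#' and the global mean signal over the symmetric upsampled lag grid and
#' reports both signed extrema; the headline peak is the extremum of
#' largest |r|. Positive lag means the artery series occurs later than the
#' GMS.
#'
#' @param arterySeries numeric vector or \linkS4class{ReferenceSignal}
#'   (preprocessed).
#' @param gms numeric vector or \linkS4class{ReferenceSignal}
#'   (preprocessed), same length.
#' @param tr sampling interval, seconds.
#' @param searchHalfwidth lag window half-width, seconds.
#' @param factor upsampling factor.
#' @return An \linkS4class{ArterialResult}.
#' @export
arteryGmsXcorr <- function(arterySeries, gms, tr, searchHalfwidth = 5.8,
                           factor = 4L) {
    if (is(arterySeries, "ReferenceSignal")) arterySeries <- arterySeries@values
    if (is(gms, "ReferenceSignal")) gms <- gms@values
    if (length(arterySeries) != length(gms))
        stop("series must have equal length")
    if (sd(arterySeries) == 0 || sd(gms) == 0)
        stop("constant input series")
    cf <- .xcorrFunction(arterySeries, gms, tr, searchHalfwidth, factor)
    pos <- which(cf$r > 0)
    neg <- which(cf$r < 0)
    posPeak <- if (length(pos)) {
        i <- pos[which.max(cf$r[pos])]
        list(lag = cf$lag[i], r = cf$r[i])
    } else list()
    negPeak <- if (length(neg)) {
        i <- neg[which.min(cf$r[neg])]
        list(lag = cf$lag[i], r = cf$r[i])
    } else list()
    i <- which.max(abs(cf$r))
    new("ArterialResult",
        arterySeries = arterySeries, peripherySeries = numeric(0),
        lagGrid = cf$lag, r = cf$r,
        peakLag = cf$lag[i], peakR = cf$r[i],
        positivePeak = posPeak, negativePeak = negPeak)
}

#' Group summary of arterial cross-correlation results
#'
#' Averages peak lags and correlations over arteries, both across all
#' arteries and restricted to the negatively coupled ones (peak r < -0.3,
#' the coupling criterion used for artery-vs-GMS analyses); arteries whose
#' extremum is positive or weak are thereby reported separately rather than
#' silently pooled. Also returns the group-mean cross-correlation curve.
#'
#' @param results list of \linkS4class{ArterialResult} sharing a lag grid.
#' @return list with \code{all} and \code{negativeCoupled} summaries
#'   (meanLag, sdLag, meanR, n), \code{lagGrid} and \code{meanCurve}.
#' @export
arteryGroupSummary <- function(results) {
    stopifnot(length(results) >= 1L,
              all(vapply(results, is, TRUE, "ArterialResult")))
    lags <- vapply(results, function(x) x@peakLag, 1)
    rs <- vapply(results, function(x) x@peakR, 1)
    grid <- results[[1L]]@lagGrid
    curves <- vapply(results, function(x) {
        if (!isTRUE(all.equal(x@lagGrid, grid)))
            stop("all results must share the same lag grid")
        x@r
    }, numeric(length(grid)))
    neg <- rs < -0.3
    summ <- function(keep) list(meanLag = mean(lags[keep]),
                                sdLag = sd(lags[keep]),
                                meanR = mean(rs[keep]),
                                n = sum(keep))
    list(all = summ(rep(TRUE, length(rs))),
         negativeCoupled = summ(neg),
         lagGrid = grid,
         meanCurve = rowMeans(curves))
}
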