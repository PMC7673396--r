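# Voxelwise time-lag estimation by cross-correlation on an upsampled grid.
#
# Both series are band-limited-interpolated to TR/factor resolution; for
# every candidate shift on that grid the Pearson correlation is computed
# over the overlapping segment only, with means and SDs recomputed per
# shift (zero-padded correlation would bias toward small shifts). The
# reported lag is the shift maximizing r among shifts with r > 0 ("best
# positive fit"); positive lag means the voxel series occurs later than
# the reference.

# shift bookkeeping: overlap index ranges for shift k (upsampled samples)
# voxel lags reference by k: voxel[t] ~ ref[t - k]
#   k >= 0: voxel[(1+k):N]  vs ref[1:(N-k)]
#   k <  0: voxel[1:(N+k)]  vs ref[(1-k):N]

#' Lag and correlation of one voxel series against a reference
#'
#' Single-series version of the estimator. Both series are upsampled by
#' \code{factor} (band-limited interpolation), then the Pearson correlation
#' is evaluated over the overlapping segment at every candidate shift within
#' \code{+/- searchHalfwidth}; shifts retaining less than \code{minOverlap}
#' of the series are excluded. The best positive fit wins; at exactly equal
#' r the smaller |lag| wins, and among equal |lag| the negative lag.
#'
#' @param voxelSeries,refSeries numeric vectors of equal length, not
#'   constant.
#' @param tr sampling interval, seconds.
#' @param searchHalfwidth search window half-width, seconds (default 5.8,
#'   i.e. 8 TR at a 0.725 s TR).
#' @param factor upsampling factor; the lag grid step is \code{tr/factor}.
#' @param minOverlap minimum fraction of the upsampled series that must
#'   overlap at a candidate shift.
#' @return list(lag, r, valid): lag in seconds on the grid, the correlation
#'   at that lag, and whether any shift gave r > 0 (if not, lag and r are
#'   NA and valid is FALSE).
#' @export
xcorrLag <- function(voxelSeries, refSeries, tr, searchHalfwidth = 5.8,
                     factor = 4L, minOverlap = 0.8) {
    n <- length(voxelSeries)
    if (length(refSeries) != n)
        stop("series must have equal length")
    if (sd(voxelSeries) == 0 || sd(refSeries) == 0)
        stop("constant input series")
    if (searchHalfwidth > n * tr / 4)
        stop("searchHalfwidth must be <= (n * tr) / 4")
    res <- .lagEngine(matrix(voxelSeries, ncol = 1L), refSeries, tr,
                      searchHalfwidth, factor, minOverlap)
    list(lag = res$lag[1L], r = res$r[1L], valid = res$valid[1L])
}

# vectorized engine: vox = time x V matrix, ref = vector
.lagEngine <- function(vox, ref, tr, searchHalfwidth, factor,
                       minOverlap = 0.8) {
    factor <- as.integer(factor)
    step <- tr / factor
    K <- floor(searchHalfwidth / step + 1e-9)
    V <- .upsampleMatrix(vox, factor)
    u <- upsampleSeries(ref, factor)
    N <- length(u)
    nv <- ncol(V)
    # cumulative sums for O(1) segment moments per shift
    cs1 <- apply(V, 2L, cumsum)
    cs2 <- apply(V * V, 2L, cumsum)
    segSum <- function(cs, a, b) {
        if (a == 1L) cs[b, ] else cs[b, ] - cs[a - 1L, ]
    }
    bestR <- rep(-Inf, nv)
    bestK <- rep(NA_integer_, nv)
    minLen <- minOverlap * N
    for (k in -K:K) {
        if (k >= 0L) { va <- 1L + k; vb <- N; ua <- 1L; ub <- N - k }
        else { va <- 1L; vb <- N + k; ua <- 1L - k; ub <- N }
        L <- vb - va + 1L
        if (L < minLen) next
        useg <- u[ua:ub]
        su <- sum(useg); suu <- sum(useg * useg)
        sv <- segSum(cs1, va, vb)
        svv <- segSum(cs2, va, vb)
        suv <- as.vector(crossprod(V[va:vb, , drop = FALSE], useg))
        num <- suv - sv * su / L
        den2 <- (svv - sv^2 / L) * (suu - su^2 / L)
        r <- ifelse(den2 > 0, num / sqrt(den2), NA_real_)
        # strict improvement, or an exact tie resolved toward smaller |lag|
        # and, among equal |lag|, the negative lag (-K..K order visits the
        # negative one first, so ties at equal |lag| keep the incumbent)
        upd <- !is.na(r) &
            (r > bestR |
             (r == bestR & !is.na(bestK) & abs(k) < abs(bestK)))
        bestR[upd] <- r[upd]
        bestK[upd] <- k
    }
    valid <- is.finite(bestR) & bestR > 0
    list(lag = ifelse(valid, bestK * step, NA_real_),
         r = ifelse(valid, pmin(bestR, 1), NA_real_),
         valid = valid, gridStep = step)
}

#' Compute a voxelwise lag map against a reference signal
#'
#' Runs the cross-correlation lag estimator at every valid voxel of a
#' (preprocessed) run. The valid mask of the result keeps voxels whose best
#' positive-fit correlation exceeds \code{rThreshold} (default 0.3, the
#' standard time-series correlation threshold for lag mapping).
#'
#' @param run a preprocessed \linkS4class{BoldRun}.
#' @param reference a \linkS4class{ReferenceSignal} (or numeric vector)
#'   matching the run's frames.
#' @inheritParams xcorrLag
#' @param rThreshold magnitude threshold for the valid mask.
#' @return A \linkS4class{LagMap}.
#' @export
computeLagMap <- function(run, reference, searchHalfwidth = 5.8,
                          rThreshold = 0.3, factor = 4L, minOverlap = 0.8) {
    stopifnot(is(run, "BoldRun"))
    label <- "GMS"
    if (is(reference, "ReferenceSignal")) {
        label <- reference@label
        reference <- reference@values
    }
    d <- dim(run@data)
    if (length(reference) != d[4L])
        stop("reference length must match the run's frames")
    if (sd(reference) == 0) stop("constant reference signal")
    if (searchHalfwidth > d[4L] * run@tr / 4)
        stop("searchHalfwidth must be <= (n * tr) / 4")
    idx <- which(as.vector(run@validMask))
    vox <- t(matrix(run@data, prod(d[1:3]), d[4L])[idx, , drop = FALSE])
    res <- .lagEngine(vox, reference, run@tr, searchHalfwidth, factor,
                      minOverlap)
    keep <- res$valid & res$r > rThreshold
    lag <- array(NA_real_, d[1:3])
    mag <- array(NA_real_, d[1:3])
    msk <- array(FALSE, d[1:3])
    lag[idx[keep]] <- res$lag[keep]
    mag[idx[keep]] <- res$r[keep]
    msk[idx[keep]] <- TRUE
    if (!any(msk))
        warning("no voxel passed the correlation threshold; lag map is empty")
    new("LagMap", lag = lag, magnitude = mag, validMask = msk,
        referenceLabel = label, searchHalfwidth = searchHalfwidth,
        gridStep = res$gridStep)
}

#' Autocorrelation-adjusted significance of a sample correlation
#'
#' Standardizes a sample correlation by a variance estimate that accounts
#' for the temporal autocorrelation of both series: the variance of r is
#' built from the two sample autocorrelation functions and the sample
#' cross-correlation function, with the lag sums truncated adaptively at
#' the first lag where the ACF stays inside its +/- 2/sqrt(n) band for two
#' consecutive lags. Larger autocorrelation therefore yields a smaller |z|
#' for the same r. For white-noise pairs the estimate reduces to the
#' classical (1 - r^2)^2 / n.
#'
#' @param r the sample correlation between \code{x} and \code{y} (at the
#'   chosen lag).
#' @param x,y the two series, equal length >= 30.
#' @param maxZ cap on |z| guarding the degenerate r -> 1 case; a capped
#'   result carries attribute \code{capped = TRUE}.
#' @return z score (r divided by the estimated SD of r), with attributes
#'   \code{varR} (the variance estimate) and \code{truncLag}.
#' @export
autocorrAdjustedZ <- function(r, x, y, maxZ = 38) {
    n <- length(x)
    if (length(y) != n) stop("series must have equal length")
    if (n < 30L) stop("series too short for the adaptive truncation rule")
    maxLag <- min(n - 10L, 2L * floor(sqrt(n)) + 20L)
    rx <- as.vector(acf(x, lag.max = maxLag, plot = FALSE)$acf)  # lags 0..M
    ry <- as.vector(acf(y, lag.max = maxLag, plot = FALSE)$acf)
    cc <- as.vector(ccf(x, y, lag.max = maxLag, plot = FALSE)$acf)
    # ccf lags -maxLag..maxLag; rxy(j) = cor(x[t+j], y[t])
    rxy <- function(j) cc[j + maxLag + 1L]
    band <- 2 / sqrt(n)
    truncAt <- function(rho) {
        for (m in 1L:(maxLag - 1L))
            if (abs(rho[m + 1L]) < band && abs(rho[m + 2L]) < band)
                return(m - 1L)    # keep lags 0..m-1
        maxLag - 1L
    }
    M <- max(truncAt(rx), truncAt(ry))
    js <- -M:M
    a <- rx[abs(js) + 1L]
    b <- ry[abs(js) + 1L]
    cj <- vapply(js, rxy, 1)
    cmj <- vapply(-js, rxy, 1)
    terms <- a * b + cj * cmj - 2 * r * (a * cj + b * cmj) +
        r^2 * (cj^2 + 0.5 * a^2 + 0.5 * b^2)
    varR <- max(sum(terms) / n, 1e-12)
    z <- r / sqrt(varR)
    capped <- FALSE
    if (!is.finite(z) || abs(z) > maxZ) {
        z <- sign(z) * maxZ
        capped <- TRUE
    }
    structure(z, varR = varR, truncLag = M, capped = capped)
}

#' Naive Fisher z statistic for a sample correlation
#'
#' The classical \code{atanh(r) * sqrt(n - 3)} statistic, which assumes
#' serially independent samples; provided as the uncorrected baseline the
#' adjusted z is compared against.
#'
#' @param r sample correlation.
#' @param n number of samples.
#' @return z statistic.
#' @export
fisherZNaive <- function(r, n) atanh(r) * sqrt(n - 3)
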