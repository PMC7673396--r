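# Block-design GLM activation mapping and construction of the task
# reference signal for lag mapping inside the activated region.

#' Canonical double-gamma HRF kernel
#'
#' The widely used double-gamma hemodynamic response function (response
#' gamma with shape \code{peakDelay}, undershoot gamma with shape
#' \code{undershootDelay}, undershoot amplitude \code{ratio}), sampled at
#' TR over \code{lengthSec} seconds and normalized to unit peak. The peak
#' falls near 5 s post-onset and the tail at 32 s is far below 1\% of the
#' peak.
#'
#' @param tr sampling interval, seconds.
#' @param peakDelay response gamma shape (default 6).
#' @param undershootDelay undershoot gamma shape (default 16).
#' @param ratio undershoot-to-peak ratio (default 1/6).
#' @param lengthSec kernel support, seconds (default 32).
#' @return numeric kernel of \code{ceiling(lengthSec / tr)} samples.
#' @export
canonicalHRF <- function(tr, peakDelay = 6, undershootDelay = 16,
                         ratio = 1 / 6, lengthSec = 32) {
    if (tr <= 0) stop("tr must be positive")
    t <- (seq_len(ceiling(lengthSec / tr)) - 1L) * tr
    h <- stats::dgamma(t, shape = peakDelay, rate = 1) -
        ratio * stats::dgamma(t, shape = undershootDelay, rate = 1)
    h / max(h)
}

#' Build a GLM design matrix for a block task
#'
#' Columns: the HRF-convolved task regressor, any nuisance regressors, and
#' a mutually orthonormal discrete-cosine drift set implementing a
#' high-pass at \code{1/highpassSec} Hz, plus the intercept.
#'
#' @param design a \linkS4class{TaskDesign}.
#' @param hrf optional kernel; default \code{canonicalHRF(design@tr)}.
#' @param nuisance optional frames x q matrix of nuisance regressors (e.g.
#'   motion parameters).
#' @param highpassSec high-pass period in seconds (default 128).
#' @return numeric matrix with named columns (\code{task} first); a
#'   rank-deficient matrix raises an error naming the collinear columns.
#' @export
buildDesignMatrix <- function(design, hrf = NULL, nuisance = NULL,
                              highpassSec = 128) {
    stopifnot(is(design, "TaskDesign"))
    n <- design@runLength
    if (is.null(hrf)) hrf <- canonicalHRF(design@tr)
    task <- .taskRegressor(design, hrf)
    X <- cbind(task = task)
    if (!is.null(nuisance)) {
        nuisance <- as.matrix(nuisance)
        if (nrow(nuisance) != n)
            stop("nuisance regressors must match the run's frames")
        colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
        X <- cbind(X, nuisance)
    }
    # DCT drift basis: cosines below the high-pass cutoff, orthonormal
    nDrift <- max(0L, floor(2 * n * design@tr / highpassSec))
    if (nDrift > 0L) {
        t <- seq_len(n) - 0.5
        D <- vapply(seq_len(nDrift),
                    function(k) cos(pi * k * t / n) * sqrt(2 / n),
                    numeric(n))
        colnames(D) <- paste0("drift", seq_len(nDrift))
        X <- cbind(X, D)
    }
    X <- cbind(X, intercept = rep(1, n))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        stop("design matrix is rank deficient; collinear columns: ",
             paste(bad, collapse = ", "))
    }
    X
}

#' Voxelwise OLS fit of a design matrix; t map for the task column
#'
#' Ordinary least squares at every valid voxel; the returned map holds
#' \code{t = estimate / SE} for the \code{task} column. Zero-variance
#' voxels yield NA and are excluded.
#'
#' @param run a \linkS4class{BoldRun}.
#' @param designMatrix matrix from \code{\link{buildDesignMatrix}}.
#' @return list with \code{tMap} (3D array) and \code{betaMap} (3D array of
#'   task-column estimates).
#' @export
fitGLM <- function(run, designMatrix) {
    stopifnot(is(run, "BoldRun"))
    X <- as.matrix(designMatrix)
    d <- dim(run@data)
    if (nrow(X) != d[4L]) stop("design matrix frames must match the run")
    taskCol <- if (!is.null(colnames(X))) which(colnames(X) == "task") else 1L
    idx <- which(as.vector(run@validMask))
    Y <- t(matrix(run@data, prod(d[1:3]), d[4L])[idx, , drop = FALSE])
    qrX <- qr(X)
    beta <- qr.coef(qrX, Y)                      # p x V
    res <- Y - X %*% beta
    dfres <- nrow(X) - qrX$rank
    sigma2 <- colSums(res^2) / dfres
    xtxinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * xtxinv[taskCol, taskCol])
    tval <- beta[taskCol, ] / se
    tval[se == 0 | !is.finite(tval)] <- NA_real_
    tMap <- array(NA_real_, d[1:3])
    bMap <- array(NA_real_, d[1:3])
    tMap[idx] <- tval
    bMap[idx] <- beta[taskCol, ]
    list(tMap = tMap, betaMap = bMap, df = dfres)
}

#' Threshold and cluster a t map; build the task reference signal
#'
#' Suprathreshold voxels are grouped by 26-connectivity; clusters larger
#' than \code{minCluster} voxels are kept. The reference signal is the mean
#' in-mask time series of \code{run}.
#'
#' @param tMap 3D array of t values.
#' @param run the \linkS4class{BoldRun} the reference is averaged from
#'   (typically the preprocessed run).
#' @param threshold voxel-level t threshold.
#' @param minCluster minimum cluster extent; clusters of size
#'   \code{<= minCluster} are discarded (default 10, i.e. ">10 voxels").
#' @return An \linkS4class{ActivationResult}.
#' @export
activationMaskAndReference <- function(tMap, run, threshold,
                                       minCluster = 10L) {
    stopifnot(is(run, "BoldRun"))
    supra <- !is.na(tMap) & tMap > threshold
    labels <- .connectedComponents(supra, connectivity = 26L)
    keep <- array(FALSE, dim(tMap))
    if (max(labels) > 0L) {
        sizes <- tabulate(labels[labels > 0L])
        good <- which(sizes > minCluster)
        keep <- array(labels %in% good & labels > 0L, dim(tMap))
    }
    if (!any(keep))
        stop("activation mask is empty; lower the threshold or the ",
             "minimum cluster size")
    d <- dim(run@data)
    vox <- matrix(run@data, prod(d[1:3]), d[4L])
    ref <- colMeans(vox[as.vector(keep), , drop = FALSE])
    new("ActivationResult", tMap = tMap, activationMask = keep,
        reference = new("ReferenceSignal", values = ref, tr = run@tr,
                        label = "task_mean"))
}

# 3D connected components by breadth-first flood fill.
# connectivity 6 (faces) or 26 (faces+edges+corners).
.connectedComponents <- function(mask, connectivity = 26L) {
    d <- dim(mask)
    stopifnot(length(d) == 3L, connectivity %in% c(6L, 26L))
    offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
    if (connectivity == 6L)
        offs <- offs[rowSums(abs(offs)) == 1L, , drop = FALSE]
    labels <- array(0L, d)
    nextLab <- 0L
    idxAll <- which(mask)
    coord <- arrayInd(idxAll, d)
    rownames(coord) <- as.character(idxAll)
    for (start in idxAll) {
        if (labels[start] != 0L) next
        nextLab <- nextLab + 1L
        queue <- start
        labels[start] <- nextLab
        while (length(queue)) {
            cur <- queue[1L]
            queue <- queue[-1L]
            cc <- arrayInd(cur, d)
            nb <- sweep(offs, 2L, as.integer(cc), `+`)
            ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
                nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
                nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
            nb <- nb[ok, , drop = FALSE]
            lin <- nb[, 1L] + d[1L] * (nb[, 2L] - 1L) +
                d[1L] * d[2L] * (nb[, 3L] - 1L)
            lin <- lin[mask[lin] & labels[lin] == 0L]
            if (length(lin)) {
                labels[lin] <- nextLab
                queue <- c(queue, lin)
            }
        }
    }
    labels
}
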