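# Two-stage decomposition: group spatial ICA for dimensionality reduction,
# then temporal ICA on the recovered time courses, with Icasso-style
# reproducibility clustering (repeated randomized runs, agglomerative
# clustering of the pooled estimates on 1 - |r|, one centrotype per
# cluster, iq = mean intra- minus mean extra-cluster similarity).

#' Group spatial ICA of a (concatenated) run
#'
#' Spatial ICA as the dimensionality-reduction stage preceding the temporal
#' ICA: the voxel pattern of each component is the independent quantity,
#' and the associated time courses (one per component) feed the temporal
#' stage. Deterministic given \code{seed}.
#'
#' @param run a preprocessed (possibly concatenated) \linkS4class{BoldRun}.
#' @param nSpatialComponents number of spatial components; must be below
#'   the number of frames. Rank deficiency reduces the count with a
#'   warning.
#' @param seed integer seed.
#' @return list with \code{timecourses} (frames x components, unit
#'   variance), \code{spatialMaps} (list of 3D arrays of source weights),
#'   \code{spatialSources} (voxel x component matrix) and
#'   \code{voxelIndex}.
#' @export
groupSpatialICA <- function(run, nSpatialComponents, seed = 1L) {
    stopifnot(is(run, "BoldRun"))
    d <- dim(run@data)
    if (nSpatialComponents >= d[4L])
        stop("nSpatialComponents must be below the number of frames")
    idx <- which(as.vector(run@validMask))
    X <- matrix(run@data, prod(d[1:3]), d[4L])[idx, , drop = FALSE] # V x T
    # center each voxel's time series (NOT each time point across voxels:
    # that would remove any spatially uniform source)
    Xc <- X - rowMeans(X)
    fit <- .fastICA(Xc, nSpatialComponents, type = "deflation",
                    seed = seed, center = FALSE)
    S <- fit$S                                  # V x k spatial sources
    # time courses by least squares: Xc ~ S %*% B, timecourses = t(B)
    B <- solve(crossprod(S), crossprod(S, Xc))  # k x T
    tc <- t(B)
    sds <- apply(tc, 2L, sd)
    tc <- sweep(tc, 2L, pmax(sds, 1e-300), "/")
    maps <- lapply(seq_len(fit$nComp), function(i) {
        m <- array(0, d[1:3])
        m[idx] <- S[, i] * sds[i]
        m
    })
    list(timecourses = tc, spatialMaps = maps,
         spatialSources = S, voxelIndex = idx)
}

#' Temporal ICA with Icasso reproducibility clustering
#'
#' Runs temporal FastICA \code{nRepeats} times from random initializations
#' (per-repeat seeds derived from \code{seed} by a fixed counter scheme),
#' pools all estimated components, clusters them by average-linkage
#' agglomeration on the dissimilarity 1 - |r|, cuts at
#' \code{nComponents} clusters and returns one centrotype per cluster (the
#' member most similar to its cluster). The cluster-quality index iq is the
#' mean intra-cluster minus the mean extra-cluster absolute correlation: a
#' reproducible component re-appears in (almost) every repeat, giving iq
#' near 1.
#'
#' @param timecourses frames x m matrix (from
#'   \code{\link{groupSpatialICA}}).
#' @param nComponents number of temporal components to extract.
#' @param nRepeats number of randomized repeats (>= 10).
#' @param seed master integer seed; repeat i uses seed
#'   \code{(seed * 1000 + i) mod 2^31}.
#' @return An \linkS4class{ICADecomposition} (components ordered by
#'   decreasing iq; labels \code{"unclassified"} until
#'   \code{\link{classifyComponents}}).
#' @export
temporalICAIcasso <- function(timecourses, nComponents, nRepeats = 20L,
                              seed = 1L) {
    X <- as.matrix(timecourses)
    if (nRepeats < 10L) stop("nRepeats must be >= 10")
    if (nComponents > ncol(X))
        stop("nComponents cannot exceed the number of input time courses")
    pool <- list()
    dropped <- 0L
    for (i in seq_len(nRepeats)) {
        si <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
        fit <- .fastICA(X, nComponents, type = "deflation", seed = si)
        if (!fit$converged || fit$nComp < nComponents) {
            dropped <- dropped + 1L
            next
        }
        pool[[length(pool) + 1L]] <- fit$S
    }
    if (dropped > nRepeats / 2)
        stop("more than half of the ICA repeats failed to converge")
    P <- do.call(cbind, pool)                     # frames x (repeats * k)
    sim <- abs(cor(P))
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
    cl <- stats::cutree(hc, k = nComponents)
    comp <- matrix(0, nrow(P), nComponents)
    iq <- numeric(nComponents)
    for (c in seq_len(nComponents)) {
        members <- which(cl == c)
        intra <- sim[members, members, drop = FALSE]
        extra <- sim[members, -members, drop = FALSE]
        iq[c] <- mean(intra) -
            (if (ncol(extra)) mean(extra) else 0)
        # centrotype: member with the largest total intra-cluster similarity
        cent <- members[which.max(rowSums(intra))]
        s <- P[, cent]
        # deterministic orientation: positive correlation with the
        # sign-aligned cluster mean
        signs <- sign(cor(P[, members, drop = FALSE], s))
        m <- P[, members, drop = FALSE] %*% as.vector(signs)
        if (cor(s, m) < 0) s <- -s
        comp[, c] <- (s - mean(s)) / sd(s)
    }
    iq <- pmin(pmax(iq, 0), 1)
    ord <- order(iq, decreasing = TRUE)
    new("ICADecomposition",
        timecourses = comp[, ord, drop = FALSE],
        spatialMaps = list(),
        iq = iq[ord],
        labels = rep("unclassified", nComponents),
        nComponents = as.integer(nComponents))
}

#' Magnitude and lag map for every temporal IC
#'
#' Runs the lag estimator against each IC time course. When the
#' decomposition was fitted on concatenated runs, pass \code{boundaries}
#' and \code{runIndex} so each IC time course is de-concatenated back to
#' the frames of \code{run}.
#'
#' @param run the (preprocessed) \linkS4class{BoldRun} to map.
#' @param decomposition an \linkS4class{ICADecomposition}.
#' @inheritParams computeLagMap
#' @param boundaries optional boundary matrix from
#'   \code{\link{concatenateRuns}}.
#' @param runIndex which concatenated segment corresponds to \code{run}.
#' @return list of \linkS4class{LagMap}, one per IC.
#' @export
magnitudeAndLagPerIC <- function(run, decomposition, searchHalfwidth = 5.8,
                                 rThreshold = 0.3, factor = 4L,
                                 boundaries = NULL, runIndex = 1L) {
    stopifnot(is(run, "BoldRun"), is(decomposition, "ICADecomposition"))
    tc <- decomposition@timecourses
    if (!is.null(boundaries))
        tc <- deconcatenate(tc, boundaries)[[runIndex]]
    if (nrow(tc) != dim(run@data)[4L])
        stop("IC time courses do not match the run's frames; ",
             "pass boundaries/runIndex to de-concatenate")
    lapply(seq_len(ncol(tc)), function(i) {
        ref <- new("ReferenceSignal", values = tc[, i], tr = run@tr,
                   label = "IC")
        computeLagMap(run, ref, searchHalfwidth = searchHalfwidth,
                      rThreshold = rThreshold, factor = factor)
    })
}

#' Attach IC magnitude maps to a decomposition
#'
#' Copies the magnitude arrays of per-IC lag maps into the decomposition's
#' \code{spatialMaps} slot (zero outside each map's valid mask), making the
#' object self-contained for \code{\link{classifyComponents}}.
#'
#' @param decomposition an \linkS4class{ICADecomposition}.
#' @param lagMaps list of \linkS4class{LagMap} from
#'   \code{\link{magnitudeAndLagPerIC}}.
#' @return The updated \linkS4class{ICADecomposition}.
#' @export
setSpatialMaps <- function(decomposition, lagMaps) {
    stopifnot(length(lagMaps) == decomposition@nComponents)
    decomposition@spatialMaps <- lapply(lagMaps, function(lm) {
        m <- lm@magnitude
        m[!lm@validMask] <- 0
        m
    })
    validObject(decomposition)
    decomposition
}

#' Label components as local or global by gray-matter coverage
#'
#' A component is labeled \code{"global"} when the fraction of gray-mask
#' voxels whose magnitude exceeds \code{rThreshold} is above
#' \code{coverageCutoff}, and \code{"local"} otherwise. This coverage
#' heuristic operationalizes the spatial-pattern judgement used for
#' local-vs-global component triage; it is a stand-in for visual
#' classification, not a literature rule.
#'
#' @param decomposition an \linkS4class{ICADecomposition} with spatial
#'   maps attached (see \code{\link{setSpatialMaps}}).
#' @param grayMask 3D logical array.
#' @param rThreshold magnitude threshold (default 0.3).
#' @param coverageCutoff coverage fraction above which a component is
#'   global (default 0.5).
#' @return character vector of labels, one per component.
#' @export
classifyComponents <- function(decomposition, grayMask, rThreshold = 0.3,
                               coverageCutoff = 0.5) {
    stopifnot(is(decomposition, "ICADecomposition"))
    if (!length(decomposition@spatialMaps))
        stop("decomposition has no spatial maps; run magnitudeAndLagPerIC ",
             "and setSpatialMaps first")
    ng <- sum(grayMask)
    vapply(decomposition@spatialMaps, function(m) {
        cov <- sum(m[grayMask] > rThreshold) / ng
        if (cov > coverageCutoff) "global" else "local"
    }, "")
}

#' Which ICs consistently survive the correlation threshold across runs
#'
#' An IC is retained iff at least one voxel passes the magnitude threshold
#' in every run (the run-consistency inclusion rule, scaled to the number
#' of runs at hand).
#'
#' @param lagMapsByRun list (one element per run) of lists of
#'   \linkS4class{LagMap} (one per IC, same order in every run).
#' @return logical vector, one element per IC.
#' @export
selectConsistentICs <- function(lagMapsByRun) {
    nIC <- length(lagMapsByRun[[1L]])
    vapply(seq_len(nIC), function(i) {
        joint <- Reduce(`&`, lapply(lagMapsByRun,
                                    function(run) run[[i]]@validMask))
        any(joint)
    }, TRUE)
}
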