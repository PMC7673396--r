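#' @import methods
#' @importFrom stats acf ccf cor fft mvfft pt rnorm sd t.test var
#' @importFrom utils head
NULL

.validLabels <- c("GMS", "IC", "task_mean", "arterial")

#' BoldRun: a 4D BOLD fMRI run
#'
#' The unit every analysis stage consumes: a voxel-by-time dataset with its
#' repetition time (TR) and a validity mask marking voxels that carry usable
#' signal (finite values, non-zero variance).
#'
#' @slot data four-dimensional numeric array (x, y, z, time), signal units.
#' @slot tr repetition time in seconds.
#' @slot validMask 3D logical array matching the spatial grid of \code{data}.
#' @slot runId character label identifying the run.
#'
#' @exportClass BoldRun
setClass("BoldRun",
    representation(
        data = "array",
        tr = "numeric",
        validMask = "array",
        runId = "character"
    ),
    prototype(tr = 0.72, runId = "run")
)

setValidity("BoldRun", function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 4L)
        msg <- c(msg, "data must be a 4D array (x, y, z, time)")
    if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
        msg <- c(msg, "tr must be a single positive number")
    if (length(dim(object@data)) == 4L) {
        if (dim(object@data)[4L] < 2L)
            msg <- c(msg, "run must have at least 2 timepoints")
        if (!identical(dim(object@validMask), dim(object@data)[1:3]))
            msg <- c(msg, "validMask grid must match the data grid")
        if (!is.logical(object@validMask))
            msg <- c(msg, "validMask must be logical")
        else if (any(object@validMask)) {
            vox <- matrix(object@data, prod(dim(object@data)[1:3]),
                          dim(object@data)[4L])[as.vector(object@validMask), ,
                                                drop = FALSE]
            if (!all(is.finite(vox)))
                msg <- c(msg, "non-finite values inside validMask")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' ReferenceSignal: a labeled 1D time series
#'
#' Houses the global mean signal (GMS), an IC time course, the task-evoked
#' mean series, or an arterial ROI signal, at the sampling rate of the run it
#' is compared against.
#'
#' @slot values numeric vector, signal units.
#' @slot tr sampling interval in seconds.
#' @slot label one of \code{"GMS"}, \code{"IC"}, \code{"task_mean"},
#'   \code{"arterial"}.
#'
#' @exportClass ReferenceSignal
setClass("ReferenceSignal",
    representation(values = "numeric", tr = "numeric", label = "character"),
    prototype(label = "GMS", tr = 0.72)
)

setValidity("ReferenceSignal", function(object) {
    msg <- NULL
    if (!all(is.finite(object@values)))
        msg <- c(msg, "values must be finite")
    if (length(object@tr) != 1L || object@tr <= 0)
        msg <- c(msg, "tr must be a single positive number")
    if (length(object@label) != 1L || !(object@label %in% .validLabels))
        msg <- c(msg, sprintf("label must be one of %s",
                              paste(.validLabels, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' LagMap: voxelwise lag and magnitude against one reference
#'
#' Per-voxel best-fit time shift (seconds, positive = voxel later than the
#' reference), the Pearson correlation attained at that shift (the magnitude
#' map), and the validity mask of voxels passing the correlation threshold.
#' Lags live on the upsampled grid: each is an integer multiple of
#' \code{gridStep} (TR / upsampling factor).
#'
#' @slot lag 3D numeric array of lags in seconds (NA outside validMask).
#' @slot magnitude 3D numeric array of correlations at the best lag.
#' @slot validMask 3D logical array.
#' @slot referenceLabel label of the reference signal used.
#' @slot searchHalfwidth half-width of the lag search window, seconds.
#' @slot gridStep lag grid resolution, seconds.
#'
#' @exportClass LagMap
setClass("LagMap",
    representation(
        lag = "array",
        magnitude = "array",
        validMask = "array",
        referenceLabel = "character",
        searchHalfwidth = "numeric",
        gridStep = "numeric"
    )
)

setValidity("LagMap", function(object) {
    msg <- NULL
    d <- dim(object@lag)
    if (length(d) != 3L)
        msg <- c(msg, "lag must be a 3D array")
    if (!identical(dim(object@magnitude), d) ||
        !identical(dim(object@validMask), d))
        msg <- c(msg, "lag, magnitude and validMask grids must agree")
    if (any(object@validMask)) {
        lg <- object@lag[object@validMask]
        mg <- object@magnitude[object@validMask]
        if (any(!is.finite(lg)) || any(!is.finite(mg)))
            msg <- c(msg, "non-finite lag/magnitude inside validMask")
        else {
            if (any(abs(lg) > object@searchHalfwidth + 1e-9))
                msg <- c(msg, "|lag| exceeds searchHalfwidth on valid voxels")
            if (any(mg <= 0 | mg > 1 + 1e-12))
                msg <- c(msg, "magnitude must lie in (0, 1] on valid voxels")
            if (is.finite(object@gridStep)) {
                k <- lg / object@gridStep
                if (any(abs(k - round(k)) > 1e-6))
                    msg <- c(msg, "lags must be integer multiples of gridStep")
            }
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' SourceSet: band-limited source signals for simulation
#'
#' A unit-variance global source plus mutually near-independent network
#' sources, all band-limited to the analysis band (default 0.01-0.1 Hz).
#'
#' @slot nTimepoints number of frames.
#' @slot tr sampling interval, seconds.
#' @slot globalSource numeric vector, unit variance.
#' @slot networkSources list of numeric vectors, unit variance.
#' @slot band numeric length-2, (low, high) in Hz.
#'
#' @exportClass SourceSet
setClass("SourceSet",
    representation(
        nTimepoints = "integer",
        tr = "numeric",
        globalSource = "numeric",
        networkSources = "list",
        band = "numeric"
    )
)

setValidity("SourceSet", function(object) {
    msg <- NULL
    if (length(object@globalSource) != object@nTimepoints)
        msg <- c(msg, "globalSource length must equal nTimepoints")
    if (!all(vapply(object@networkSources, length, 1L) == object@nTimepoints))
        msg <- c(msg, "all network sources must have nTimepoints samples")
    if (length(object@band) != 2L || object@band[1L] <= 0 ||
        object@band[2L] <= object@band[1L])
        msg <- c(msg, "band must be (low, high) with 0 < low < high")
    if (is.null(msg)) TRUE else msg
})

#' DelayField: a smooth voxelwise hemodynamic delay field
#'
#' Ground-truth per-voxel delays in seconds, spatially smooth, bounded by the
#' stated range which must fit inside the downstream lag search window.
#'
#' @slot values 3D numeric array of seconds.
#' @slot range numeric length-2 (min, max) seconds.
#'
#' @exportClass DelayField
setClass("DelayField",
    representation(values = "array", range = "numeric")
)

setValidity("DelayField", function(object) {
    msg <- NULL
    if (length(dim(object@values)) != 3L)
        msg <- c(msg, "values must be a 3D array")
    if (length(object@range) != 2L || object@range[1L] > object@range[2L])
        msg <- c(msg, "range must be (min, max) with min <= max")
    else if (any(object@values < object@range[1L] - 1e-9) ||
             any(object@values > object@range[2L] + 1e-9))
        msg <- c(msg, "delay values outside stated range")
    if (is.null(msg)) TRUE else msg
})

#' GroundTruth: full scenario description for a simulated run
#'
#' Everything needed to render a synthetic run and later score recovery:
#' the delay field, the source set, per-voxel mixing weights, the noise
#' level, arterial parameters and the seed. Serializes losslessly to a JSON
#' sidecar (\code{\link{writeGroundTruth}}).
#'
#' @slot delayField a \code{DelayField}.
#' @slot sources a \code{SourceSet}.
#' @slot weights list with elements \code{global} (3D array) and
#'   \code{network} (list of 3D arrays), one weight per voxel per source.
#' @slot noiseSigma additive noise SD, signal units.
#' @slot arterial list(gain, shift, intensityOffset): signed gain applied to
#'   the global source, time shift in seconds, and baseline intensity offset
#'   of artery voxels relative to surrounding tissue.
#' @slot noiseAR1 AR(1) coefficient for temporally autocorrelated noise
#'   (0 = white).
#' @slot seed integer RNG seed the scenario was rendered with.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(
        delayField = "DelayField",
        sources = "SourceSet",
        weights = "list",
        noiseSigma = "numeric",
        arterial = "list",
        noiseAR1 = "numeric",
        seed = "integer"
    ),
    prototype(noiseAR1 = 0)
)

setValidity("GroundTruth", function(object) {
    msg <- NULL
    if (!all(c("global", "network") %in% names(object@weights)))
        msg <- c(msg, "weights must have elements 'global' and 'network'")
    else {
        shp <- dim(object@delayField@values)
        if (!identical(dim(object@weights$global), shp))
            msg <- c(msg, "global weight grid must match delay field grid")
        if (!all(vapply(object@weights$network,
                        function(w) identical(dim(w), shp), TRUE)))
            msg <- c(msg, "network weight grids must match delay field grid")
    }
    if (!all(c("gain", "shift", "intensityOffset") %in% names(object@arterial)))
        msg <- c(msg, "arterial must have gain, shift, intensityOffset")
    if (object@noiseSigma < 0)
        msg <- c(msg, "noiseSigma must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' ICADecomposition: temporal ICA result with reproducibility indices
#'
#' Component time courses (unit variance), per-component spatial magnitude
#' maps (shifted-correlation r), Icasso cluster-quality indices in [0, 1],
#' and local/global labels.
#'
#' @slot timecourses numeric matrix, time by components.
#' @slot spatialMaps list of 3D arrays (may be empty until
#'   \code{\link{magnitudeAndLagPerIC}} is run).
#' @slot iq numeric vector of cluster-quality indices in [0, 1].
#' @slot labels character vector, each \code{"local"}, \code{"global"} or
#'   \code{"unclassified"}.
#' @slot nComponents integer count.
#'
#' @exportClass ICADecomposition
setClass("ICADecomposition",
    representation(
        timecourses = "matrix",
        spatialMaps = "list",
        iq = "numeric",
        labels = "character",
        nComponents = "integer"
    )
)

setValidity("ICADecomposition", function(object) {
    msg <- NULL
    if (ncol(object@timecourses) != object@nComponents)
        msg <- c(msg, "timecourses column count must equal nComponents")
    if (length(object@spatialMaps) &&
        length(object@spatialMaps) != object@nComponents)
        msg <- c(msg, "spatialMaps count must equal nComponents")
    if (length(object@iq) && (any(object@iq < -1e-9 | object@iq > 1 + 1e-9)))
        msg <- c(msg, "iq must lie in [0, 1]")
    if (length(object@labels) &&
        !all(object@labels %in% c("local", "global", "unclassified")))
        msg <- c(msg, "labels must be local/global/unclassified")
    if (is.null(msg)) TRUE else msg
})

#' TaskDesign: block-design task timing
#'
#' @slot onsets block onsets, seconds from run start, sorted.
#' @slot durations block durations, seconds.
#' @slot runLength run length in frames.
#' @slot tr repetition time, seconds.
#'
#' @exportClass TaskDesign
setClass("TaskDesign",
    representation(onsets = "numeric", durations = "numeric",
                   runLength = "integer", tr = "numeric")
)

setValidity("TaskDesign", function(object) {
    msg <- NULL
    if (length(object@onsets) == 0L)
        msg <- c(msg, "design must contain at least one block")
    if (length(object@onsets) != length(object@durations))
        msg <- c(msg, "onsets and durations must have equal length")
    if (is.unsorted(object@onsets))
        msg <- c(msg, "onsets must be sorted")
    if (length(object@onsets) == length(object@durations) &&
        any(object@onsets + object@durations >
            object@runLength * object@tr + 1e-9))
        msg <- c(msg, "blocks must fit within the run duration")
    if (is.null(msg)) TRUE else msg
})

#' ActivationResult: GLM activation map, mask and task reference
#'
#' @slot tMap 3D array of t statistics (NA where undefined).
#' @slot activationMask 3D logical array of suprathreshold clustered voxels.
#' @slot reference \code{ReferenceSignal} with label \code{task_mean}: the
#'   mean in-mask time series.
#'
#' @exportClass ActivationResult
setClass("ActivationResult",
    representation(tMap = "array", activationMask = "array",
                   reference = "ReferenceSignal")
)

setValidity("ActivationResult", function(object) {
    msg <- NULL
    if (!identical(dim(object@tMap), dim(object@activationMask)))
        msg <- c(msg, "tMap and activationMask grids must agree")
    if (any(object@activationMask & !is.finite(object@tMap)))
        msg <- c(msg, "activationMask must lie within finite-t voxels")
    if (is.null(msg)) TRUE else msg
})

#' ArterialResult: artery-vs-GMS cross-correlation summary
#'
#' The full cross-correlation function on the symmetric upsampled lag grid,
#' with both signed extrema reported; \code{peakLag}/\code{peakR} is the
#' extremum of largest |r|. Positive lag means the artery series occurs later
#' than the GMS.
#'
#' @slot arterySeries numeric vector.
#' @slot peripherySeries numeric vector (may be length 0).
#' @slot lagGrid numeric vector of lags, seconds, symmetric about 0.
#' @slot r cross-correlation values on \code{lagGrid}.
#' @slot peakLag lag of the extremum of largest |r|, seconds.
#' @slot peakR correlation at \code{peakLag}.
#' @slot positivePeak list(lag, r) of the positive maximum, or empty list if
#'   no positive value exists in the window.
#' @slot negativePeak list(lag, r) of the negative minimum, or empty list.
#'
#' @exportClass ArterialResult
setClass("ArterialResult",
    representation(
        arterySeries = "numeric",
        peripherySeries = "numeric",
        lagGrid = "numeric",
        r = "numeric",
        peakLag = "numeric",
        peakR = "numeric",
        positivePeak = "list",
        negativePeak = "list"
    )
)

setValidity("ArterialResult", function(object) {
    msg <- NULL
    if (length(object@lagGrid) != length(object@r))
        msg <- c(msg, "lagGrid and r must have equal length")
    if (max(abs(object@lagGrid + rev(object@lagGrid))) > 1e-9)
        msg <- c(msg, "lagGrid must be symmetric about 0")
    if (length(object@peakR) && is.finite(object@peakR) &&
        abs(object@peakR) > 1 + 1e-12)
        msg <- c(msg, "|peakR| must be <= 1")
    if (is.null(msg)) TRUE else msg
})

#' ComparisonStats: group-level lag-map similarity statistics
#'
#' Per-run Pearson correlations between two lag maps, their Fisher-Z
#' transforms, and the one-sample two-tailed t test of the transformed values
#' against zero.
#'
#' @slot perRunR numeric vector of per-run correlations.
#' @slot fisherZ \code{atanh(perRunR)}.
#' @slot tStat t statistic.
#' @slot pTwoTailed two-tailed p value.
#' @slot nVoxelsPerRun integer vector of joint-mask sizes per run.
#' @slot jointMaskRule label of the joint-mask rule used.
#'
#' @exportClass ComparisonStats
setClass("ComparisonStats",
    representation(
        perRunR = "numeric",
        fisherZ = "numeric",
        tStat = "numeric",
        pTwoTailed = "numeric",
        nVoxelsPerRun = "integer",
        jointMaskRule = "character"
    )
)

setValidity("ComparisonStats", function(object) {
    msg <- NULL
    if (any(abs(object@perRunR) > 1))
        msg <- c(msg, "|perRunR| must be <= 1")
    if (length(object@fisherZ) != length(object@perRunR) ||
        any(abs(object@fisherZ - atanh(object@perRunR)) > 1e-9, na.rm = TRUE))
        msg <- c(msg, "fisherZ must equal atanh(perRunR) elementwise")
    if (length(object@nVoxelsPerRun) != length(object@perRunR))
        msg <- c(msg, "nVoxelsPerRun must be recorded for every run")
    if (is.null(msg)) TRUE else msg
})

#' CompositeLagMap: superposition of IC lag maps on a common offset
#'
#' Each IC lag map is shifted by a per-IC constant so that the midpoint of
#' its lag range matches that of the GMS map, then superimposed; overlap
#' voxels are assigned to the IC with the highest magnitude there.
#'
#' @slot lag 3D numeric array, seconds.
#' @slot contributor 3D integer array of IC indices (0 = none).
#' @slot offsetsApplied per-IC offsets, seconds.
#' @slot validMask 3D logical array.
#'
#' @exportClass CompositeLagMap
setClass("CompositeLagMap",
    representation(lag = "array", contributor = "array",
                   offsetsApplied = "numeric", validMask = "array")
)

setValidity("CompositeLagMap", function(object) {
    msg <- NULL
    if (!identical(dim(object@lag), dim(object@contributor)) ||
        !identical(dim(object@lag), dim(object@validMask)))
        msg <- c(msg, "lag, contributor and validMask grids must agree")
    if (any(object@validMask & object@contributor == 0L))
        msg <- c(msg, "every valid voxel must have exactly one contributor")
    if (!all(is.finite(object@offsetsApplied)))
        msg <- c(msg, "offsets must be finite")
    if (is.null(msg)) TRUE else msg
})
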