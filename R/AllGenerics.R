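#' Accessors for boldlag classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a boldlag S4 object.
#' @return The slot contents; see each class for units.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("boldData", function(object) standardGeneric("boldData"))
#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(object) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("runId", function(object) standardGeneric("runId"))
#' @rdname accessors
#' @export
setGeneric("refValues", function(object) standardGeneric("refValues"))
#' @rdname accessors
#' @export
setGeneric("refLabel", function(object) standardGeneric("refLabel"))
#' @rdname accessors
#' @export
setGeneric("lagSeconds", function(object) standardGeneric("lagSeconds"))
#' @rdname accessors
#' @export
setGeneric("magnitudeR", function(object) standardGeneric("magnitudeR"))
#' @rdname accessors
#' @export
setGeneric("gridStep", function(object) standardGeneric("gridStep"))
#' @rdname accessors
#' @export
setGeneric("timecourses", function(object) standardGeneric("timecourses"))
#' @rdname accessors
#' @export
setGeneric("spatialMaps", function(object) standardGeneric("spatialMaps"))
#' @rdname accessors
#' @export
setGeneric("iqIndex", function(object) standardGeneric("iqIndex"))
#' @rdname accessors
#' @export
setGeneric("componentLabels", function(object) standardGeneric("componentLabels"))
#' @rdname accessors
#' @export
setGeneric("delayValues", function(object) standardGeneric("delayValues"))

#' @rdname accessors
#' @export
setMethod("boldData", "BoldRun", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("repetitionTime", "BoldRun", function(object) object@tr)
#' @rdname accessors
#' @export
setMethod("validMask", "BoldRun", function(object) object@validMask)
#' @rdname accessors
#' @export
setMethod("runId", "BoldRun", function(object) object@runId)
#' @rdname accessors
#' @export
setMethod("repetitionTime", "ReferenceSignal", function(object) object@tr)
#' @rdname accessors
#' @export
setMethod("refValues", "ReferenceSignal", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("refLabel", "ReferenceSignal", function(object) object@label)
#' @rdname accessors
#' @export
setMethod("lagSeconds", "LagMap", function(object) object@lag)
#' @rdname accessors
#' @export
setMethod("magnitudeR", "LagMap", function(object) object@magnitude)
#' @rdname accessors
#' @export
setMethod("validMask", "LagMap", function(object) object@validMask)
#' @rdname accessors
#' @export
setMethod("gridStep", "LagMap", function(object) object@gridStep)
#' @rdname accessors
#' @export
setMethod("refLabel", "LagMap", function(object) object@referenceLabel)
#' @rdname accessors
#' @export
setMethod("timecourses", "ICADecomposition", function(object) object@timecourses)
#' @rdname accessors
#' @export
setMethod("spatialMaps", "ICADecomposition", function(object) object@spatialMaps)
#' @rdname accessors
#' @export
setMethod("iqIndex", "ICADecomposition", function(object) object@iq)
#' @rdname accessors
#' @export
setMethod("componentLabels", "ICADecomposition",
          function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("delayValues", "DelayField", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("lagSeconds", "CompositeLagMap", function(object) object@lag)
#' @rdname accessors
#' @export
setMethod("validMask", "CompositeLagMap", function(object) object@validMask)

setMethod("show", "BoldRun", function(object) {
    d <- dim(object@data)
    cat(sprintf("BoldRun '%s': %d x %d x %d voxels, %d frames, TR = %.3g s\n",
                object@runId, d[1L], d[2L], d[3L], d[4L], object@tr))
    cat(sprintf("  valid voxels: %d / %d\n",
                sum(object@validMask), prod(d[1:3])))
})

setMethod("show", "ReferenceSignal", function(object) {
    cat(sprintf("ReferenceSignal [%s]: %d samples, TR = %.3g s\n",
                object@label, length(object@values), object@tr))
})

setMethod("show", "LagMap", function(object) {
    d <- dim(object@lag)
    nv <- sum(object@validMask)
    cat(sprintf("LagMap vs %s: %d x %d x %d grid, %d valid voxels\n",
                object@referenceLabel, d[1L], d[2L], d[3L], nv))
    cat(sprintf("  search +/- %.3g s on a %.3g s grid\n",
                object@searchHalfwidth, object@gridStep))
    if (nv > 0L)
        cat(sprintf("  lag range [%.2f, %.2f] s, median magnitude %.2f\n",
                    min(object@lag[object@validMask]),
                    max(object@lag[object@validMask]),
                    stats::median(object@magnitude[object@validMask])))
})

setMethod("show", "ICADecomposition", function(object) {
    cat(sprintf("ICADecomposition: %d components, %d frames\n",
                object@nComponents, nrow(object@timecourses)))
    if (length(object@iq))
        cat(sprintf("  iq: %s\n",
                    paste(sprintf("%.2f", object@iq), collapse = " ")))
    if (length(object@labels))
        cat(sprintf("  labels: %s\n", paste(object@labels, collapse = " ")))
})

setMethod("show", "ComparisonStats", function(object) {
    cat(sprintf("ComparisonStats over %d runs: mean r = %.3f, t = %.3f, p = %.3g\n",
                length(object@perRunR), mean(object@perRunR),
                object@tStat, object@pTwoTailed))
})

setMethod("show", "ArterialResult", function(object) {
    cat(sprintf("ArterialResult: peak r = %.3f at lag %.2f s\n",
                object@peakR, object@peakLag))
    if (length(object@negativePeak))
        cat(sprintf("  negative peak r = %.3f at %.2f s\n",
                    object@negativePeak$r, object@negativePeak$lag))
    if (length(object@positivePeak))
        cat(sprintf("  positive peak r = %.3f at %.2f s\n",
                    object@positivePeak$r, object@positivePeak$lag))
})

setMethod("show", "GroundTruth", function(object) {
    d <- dim(object@delayField@values)
    cat(sprintf("GroundTruth: %d x %d x %d grid, %d frames, seed %d\n",
                d[1L], d[2L], d[3L], object@sources@nTimepoints, object@seed))
    cat(sprintf("  delay range [%.2f, %.2f] s, noise sigma %.3g, AR1 %.2f\n",
                object@delayField@range[1L], object@delayField@range[2L],
                object@noiseSigma, object@noiseAR1))
})
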