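# File interfaces: 4D/3D NIfTI-1 via RNifti, reference signals as
# two-column TSV (time_s, value), task designs as three-column TSV
# (onset, duration, condition), ground truth as a JSON sidecar.

#' Read / write a BoldRun as NIfTI-1
#'
#' The TR is stored in / read from the NIfTI time-step field (pixdim4).
#'
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @param tr repetition time override; default uses the header time step.
#' @param runId label for the run.
#' @return \code{readBoldNifti}: a \linkS4class{BoldRun}.
#' @export
readBoldNifti <- function(path, tr = NULL, runId = basename(path)) {
    img <- RNifti::readNifti(path)
    dat <- array(as.numeric(img), dim(img))
    if (length(dim(dat)) == 3L) dim(dat) <- c(dim(dat), 1L)
    if (is.null(tr)) {
        tr <- RNifti::pixdim(img)[4L]
        if (!is.finite(tr) || tr <= 0)
            stop("no usable TR in the NIfTI header; pass tr explicitly")
    }
    boldRun(dat, tr = tr, runId = runId)
}

#' @rdname readBoldNifti
#' @param run a \linkS4class{BoldRun}.
#' @return \code{writeBoldNifti}: the path, invisibly.
#' @export
writeBoldNifti <- function(run, path) {
    stopifnot(is(run, "BoldRun"))
    img <- RNifti::asNifti(run@data)
    RNifti::pixdim(img) <- c(1, 1, 1, run@tr)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read / write a 3D volume (mask, delay field, t map) as NIfTI-1
#'
#' @param vol 3D array (logical volumes are written as 0/1).
#' @param path file path.
#' @return \code{readVolumeNifti}: a 3D numeric array;
#'   use \code{> 0.5} to recover a mask.
#' @export
writeVolumeNifti <- function(vol, path) {
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(vol), dim(vol))),
                       path)
    invisible(path)
}

#' @rdname writeVolumeNifti
#' @export
readVolumeNifti <- function(path) {
    img <- RNifti::readNifti(path)
    array(as.numeric(img), dim(img))
}

#' Write a lag map as a NIfTI triplet
#'
#' Writes \code{<prefix>_lag.nii.gz} (seconds; 0 outside the valid mask),
#' \code{<prefix>_magnitude.nii.gz} (r) and \code{<prefix>_valid.nii.gz}
#' (0/1).
#'
#' @param lagMap a \linkS4class{LagMap}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return character vector of the three paths, invisibly.
#' @export
writeLagMapNifti <- function(lagMap, dir, prefix = "lagmap") {
    stopifnot(is(lagMap, "LagMap"))
    lag <- lagMap@lag; lag[!lagMap@validMask] <- 0
    mag <- lagMap@magnitude; mag[!lagMap@validMask] <- 0
    paths <- file.path(dir, paste0(prefix, c("_lag", "_magnitude",
                                             "_valid"), ".nii.gz"))
    writeVolumeNifti(lag, paths[1L])
    writeVolumeNifti(mag, paths[2L])
    writeVolumeNifti(lagMap@validMask, paths[3L])
    invisible(paths)
}

#' Read / write a reference signal as two-column TSV
#'
#' Columns \code{time_s} and \code{value}; the TR is recovered from the
#' time column.
#'
#' @param ref a \linkS4class{ReferenceSignal}.
#' @param path file path.
#' @param label label for the read signal.
#' @return \code{readReferenceTSV}: a \linkS4class{ReferenceSignal}.
#' @export
writeReferenceTSV <- function(ref, path) {
    stopifnot(is(ref, "ReferenceSignal"))
    df <- data.frame(time_s = (seq_along(ref@values) - 1L) * ref@tr,
                     value = ref@values)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' @rdname writeReferenceTSV
#' @export
readReferenceTSV <- function(path, label = "GMS") {
    df <- utils::read.table(path, header = TRUE, sep = "\t")
    tr <- if (nrow(df) > 1L) df$time_s[2L] - df$time_s[1L] else 1
    new("ReferenceSignal", values = df$value, tr = tr, label = label)
}

#' Read / write a task design as three-column TSV
#'
#' Columns \code{onset}, \code{duration}, \code{condition} (seconds).
#'
#' @param design a \linkS4class{TaskDesign}.
#' @param path file path.
#' @param condition condition label written with each block.
#' @param runLength,tr run geometry for the read design.
#' @return \code{readDesignTSV}: a \linkS4class{TaskDesign}.
#' @export
writeDesignTSV <- function(design, path, condition = "task") {
    stopifnot(is(design, "TaskDesign"))
    df <- data.frame(onset = design@onsets, duration = design@durations,
                     condition = condition)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' @rdname writeDesignTSV
#' @export
readDesignTSV <- function(path, runLength, tr) {
    df <- utils::read.table(path, header = TRUE, sep = "\t")
    new("TaskDesign", onsets = df$onset, durations = df$duration,
        runLength = as.integer(runLength), tr = tr)
}

#' Serialize / restore a ground-truth scenario as a JSON sidecar
#'
#' Full double precision is written (\code{digits = NA}) so the scenario
#' round-trips losslessly.
#'
#' @param groundTruth a \linkS4class{GroundTruth}.
#' @param path file path (\code{.json}).
#' @return \code{readGroundTruth}: a \linkS4class{GroundTruth} identical to
#'   the one written.
#' @export
writeGroundTruth <- function(groundTruth, path) {
    gt <- groundTruth
    stopifnot(is(gt, "GroundTruth"))
    obj <- list(
        shape = dim(gt@delayField@values),
        delay = list(values = as.vector(gt@delayField@values),
                     range = gt@delayField@range),
        sources = list(nTimepoints = gt@sources@nTimepoints,
                       tr = gt@sources@tr,
                       globalSource = gt@sources@globalSource,
                       networkSources = gt@sources@networkSources,
                       band = gt@sources@band),
        weights = list(global = as.vector(gt@weights$global),
                       network = lapply(gt@weights$network, as.vector)),
        noiseSigma = gt@noiseSigma,
        noiseAR1 = gt@noiseAR1,
        arterial = gt@arterial,
        seed = gt@seed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
    o <- jsonlite::read_json(path, simplifyVector = TRUE)
    shape <- as.integer(o$shape)
    # jsonlite simplifies a list of equal-length vectors to a matrix with
    # one ROW per list element
    asRowList <- function(x) {
        if (is.null(x) || length(x) == 0L) list()
        else if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ])
        else if (is.list(x)) lapply(x, as.numeric)
        else list(as.numeric(x))
    }
    net <- asRowList(o$sources$networkSources)
    wnet <- asRowList(o$weights$network)
    new("GroundTruth",
        delayField = new("DelayField",
                         values = array(o$delay$values, shape),
                         range = o$delay$range),
        sources = new("SourceSet",
                      nTimepoints = as.integer(o$sources$nTimepoints),
                      tr = o$sources$tr,
                      globalSource = o$sources$globalSource,
                      networkSources = net,
                      band = o$sources$band),
        weights = list(global = array(o$weights$global, shape),
                       network = lapply(wnet, array, dim = shape)),
        noiseSigma = o$noiseSigma,
        noiseAR1 = o$noiseAR1,
        arterial = as.list(o$arterial),
        seed = as.integer(o$seed))
}
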