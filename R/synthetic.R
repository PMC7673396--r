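# Synthetic 4D BOLD generator with known ground truth.
#
# The generator emulates the statistical structure the lag analysis assumes:
# band-limited (0.01-0.1 Hz) global and network sources, a smooth voxelwise
# hemodynamic delay field spanning several seconds with late watershed-like
# zones, additive (optionally AR(1)) noise, block-design task responses with
# voxelwise-delayed HRFs, and an arterial voxel cluster carrying an
# inverted, time-shifted copy of the global source on an elevated baseline.

#' Generate band-limited source signals
#'
#' Builds a unit-variance global source plus \code{nNetworks} mutually
#' independent network sources by filtering white noise with a zero-phase
#' band-pass realized as a raised-cosine spectral mask supported on
#' \code{[band[1], band[2]]} (flat over the interior 40\% of the band,
#' tapering to zero exactly at the band edges), then standardizing. A slow
#' positive amplitude envelope (squared low-pass noise) makes each source
#' burst-like and super-Gaussian, so a temporal ICA can identify it; the
#' envelope is slow enough that the modulated signal stays inside the band.
#' Sources are drawn independently; a seeded redraw rule keeps finite-sample
#' pairwise correlations below 0.15.
#'
#' @param nTimepoints number of frames (>= 128).
#' @param tr sampling interval, seconds.
#' @param band numeric length-2, (low, high) in Hz; default \code{c(0.01,
#'   0.1)}, the resting-state analysis band.
#' @param nNetworks number of network sources.
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @return A \linkS4class{SourceSet}.
#' @export
makeSources <- function(nTimepoints, tr, band = c(0.01, 0.1),
                        nNetworks = 3L, seed = 1L) {
    n <- as.integer(nTimepoints)
    if (n < 128L) stop("nTimepoints must be >= 128")
    nyq <- 1 / (2 * tr)
    if (!(band[1L] > 0 && band[2L] > band[1L] && band[2L] < nyq))
        stop("band must satisfy 0 < low < high < Nyquist")
    # one independent amplitude-modulated band-limited source per sub-seed:
    # carrier and envelope noise are drawn independently, so distinct
    # sources are mutually independent processes
    gen <- function(subSeed) .withSeed(subSeed, {
        carrier <- .brickBandpass(rnorm(n), tr, band)
        env <- .lowpassEnvelope(rnorm(n), tr,
                                cutoff = 0.08 * (band[2L] - band[1L]))
        s <- carrier * (0.15 + env^2)   # sparse bursts: super-Gaussian
        s <- .brickBandpass(s, tr, band)   # AM broadens the spectrum a bit
        (s - mean(s)) / sd(s)
    })
    base <- as.numeric(seed) %% 2000000
    src <- list(gen(base * 1000))
    for (k in seq_len(nNetworks)) {
        # keep finite-sample correlations small: redraw a source whose
        # correlation with any earlier one reaches 0.15
        for (attempt in 0:49) {
            cand <- gen(base * 1000 + k + 100 * attempt)
            if (max(abs(vapply(src, cor, 1, cand))) < 0.15) break
        }
        src[[k + 1L]] <- cand
    }
    new("SourceSet",
        nTimepoints = n, tr = tr,
        globalSource = src[[1L]],
        networkSources = src[-1L],
        band = as.numeric(band))
}

# zero-phase band-pass via raised-cosine spectral mask confined to [low,
# high]; flat passband over the interior of the band so that a subsequent
# Butterworth band-pass at the same edges retains >= 95% of the power
.brickBandpass <- function(x, tr, band, taper = 0.3) {
    n <- length(x)
    fr <- (seq_len(n) - 1) / (n * tr)
    fr <- pmin(fr, 1 / tr - fr)                # two-sided frequency
    low <- band[1L]; high <- band[2L]
    d <- taper * (high - low)
    p1 <- low + d; p2 <- high - d
    mask <- numeric(n)
    mask[fr >= p1 & fr <= p2] <- 1
    up <- fr >= low & fr < p1
    mask[up] <- 0.5 * (1 - cos(pi * (fr[up] - low) / d))
    dn <- fr > p2 & fr <= high
    mask[dn] <- 0.5 * (1 + cos(pi * (fr[dn] - p2) / d))
    Re(fft(fft(x) * mask, inverse = TRUE)) / n
}

# positive-biased slow envelope: low-pass the noise below `cutoff` Hz
.lowpassEnvelope <- function(x, tr, cutoff) {
    n <- length(x)
    fr <- (seq_len(n) - 1) / (n * tr)
    fr <- pmin(fr, 1 / tr - fr)
    mask <- as.numeric(fr <= cutoff)
    e <- Re(fft(fft(x) * mask, inverse = TRUE)) / n
    e / max(sd(e), 1e-12)
}

#' Construct a ground-truth delay field
#'
#' Smooth per-voxel delays in seconds. Patterns: \code{"gradient"} is a
#' monotone ramp along the x axis spanning \code{range}; \code{"watershed"}
#' adds late (delayed) smooth blobs at fixed fractional coordinates,
#' mimicking watershed-like zones at perfusion borders, then rescales back
#' into \code{range}; \code{"constant"} fills the grid with the range
#' midpoint. Neighbor delay differences are bounded (default 0.5 s) so the
#' field is spatially smooth.
#'
#' @param shape integer length-3 grid size.
#' @param pattern \code{"gradient"}, \code{"watershed"} or
#'   \code{"constant"}.
#' @param range numeric length-2 (min, max) delay in seconds.
#' @param seed integer, stored for provenance (the patterns themselves are
#'   deterministic).
#' @param searchHalfwidth downstream lag search half-width, seconds; the
#'   range must fit inside it.
#' @return A \linkS4class{DelayField}.
#' @export
makeDelayField <- function(shape, pattern = c("gradient", "watershed",
                                              "constant"),
                           range = c(-2, 2), seed = 1L,
                           searchHalfwidth = 5.8) {
    pattern <- match.arg(pattern)
    shape <- as.integer(shape)
    if (length(shape) != 3L || any(shape < 1L))
        stop("shape must be a 3D grid size")
    if (max(abs(range)) > searchHalfwidth)
        stop("delay range must lie within the downstream search window (+/- ",
             searchHalfwidth, " s)")
    nx <- shape[1L]; ny <- shape[2L]; nz <- shape[3L]
    if (pattern == "constant" || diff(range) == 0) {
        vals <- array(mean(range), shape)
        return(new("DelayField", values = vals, range = as.numeric(range)))
    }
    ramp <- if (nx > 1L) (seq_len(nx) - 1) / (nx - 1) else rep(0.5, 1L)
    field <- array(rep(ramp, times = ny * nz), shape)
    if (pattern == "watershed") {
        # late zones at fixed fractional coordinates (anterior/posterior
        # watershed analogues); smooth Gaussian bumps toward the late end
        centers <- rbind(c(0.30, 0.70, 0.50), c(0.75, 0.30, 0.50))
        sig <- max(2.5, min(shape) / 4)
        g <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
        for (i in seq_len(nrow(centers))) {
            cz <- centers[i, ] * (shape - 1L) + 1
            d2 <- (g$x - cz[1L])^2 + (g$y - cz[2L])^2 + (g$z - cz[3L])^2
            field <- field + array(0.45 * exp(-d2 / (2 * sig^2)), shape)
        }
    }
    # rescale into the stated range (shrinking preserves smoothness)
    field <- (field - min(field)) / (max(field) - min(field))
    vals <- range[1L] + field * diff(range)
    new("DelayField", values = vals, range = as.numeric(range))
}

# smooth compact Gaussian blob weights for the network sources, centers
# spread along x so pairwise voxel overlap stays small
.networkWeights <- function(shape, nNetworks, supportCut = 0.05) {
    nx <- shape[1L]; ny <- shape[2L]; nz <- shape[3L]
    g <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
    sig <- max(1.5, nx / (3.5 * nNetworks))
    lapply(seq_len(nNetworks), function(k) {
        cx <- (k - 0.5) / nNetworks * (nx - 1L) + 1
        d2 <- (g$x - cx)^2 + (g$y - (ny + 1) / 2)^2 + (g$z - (nz + 1) / 2)^2
        w <- exp(-d2 / (2 * sig^2))
        w[w < supportCut] <- 0
        array(w, shape)
    })
}

#' Assemble a ground-truth scenario
#'
#' Convenience constructor bundling a delay field, sources, mixing weights
#' (global weight 1 everywhere; network weights as smooth compact blobs),
#' noise level and arterial parameters. The defaults are the desk-scale
#' study conditions used throughout the package: a 20 x 20 x 12 grid,
#' a typical multiband TR of 0.72 s, delays spanning +/- 2 s, and additive noise at a
#' raw voxelwise SNR giving voxel-vs-source correlation about 0.6.
#'
#' @param shape grid size, default \code{c(20, 20, 12)}.
#' @param nTimepoints frames, default 600.
#' @param tr seconds, default 0.72.
#' @param pattern delay-field pattern, see \code{\link{makeDelayField}}.
#' @param range delay range in seconds.
#' @param nNetworks number of network sources (0 for a single-global-source
#'   scenario).
#' @param noiseSigma additive noise SD in signal units; the default 4/3
#'   yields raw voxel-vs-source correlation 0.6 for a unit-variance source.
#' @param noiseAR1 AR(1) coefficient of the noise (0 = white).
#' @param arterial list(gain, shift, intensityOffset); defaults to an
#'   inverted copy of the global source leading it by 2.7 s on a +20
#'   baseline offset, the arterial scenario studied downstream.
#' @param band analysis band, Hz.
#' @param seed integer seed.
#' @return A \linkS4class{GroundTruth}.
#' @export
makeGroundTruth <- function(shape = c(20L, 20L, 12L), nTimepoints = 600L,
                            tr = 0.72, pattern = "gradient",
                            range = c(-2, 2), nNetworks = 0L,
                            noiseSigma = sqrt(1 / 0.36 - 1),
                            noiseAR1 = 0,
                            arterial = list(gain = -1, shift = -2.7,
                                            intensityOffset = 20),
                            band = c(0.01, 0.1), seed = 1L) {
    shape <- as.integer(shape)
    sources <- makeSources(nTimepoints, tr, band,
                           nNetworks = max(nNetworks, 1L), seed = seed)
    if (nNetworks == 0L) sources@networkSources <- list()
    field <- makeDelayField(shape, pattern, range, seed = seed)
    weights <- list(global = array(1, shape),
                    network = .networkWeights(shape, nNetworks))
    new("GroundTruth", delayField = field, sources = sources,
        weights = weights, noiseSigma = noiseSigma,
        arterial = arterial, noiseAR1 = noiseAR1,
        seed = as.integer(seed))
}

# noise matrix (time x voxels), white or AR(1) with unit marginal SD
.noiseMatrix <- function(n, nvox, ar1 = 0) {
    e <- matrix(rnorm(n * nvox), n, nvox)
    if (ar1 != 0) {
        e <- apply(e, 2L, function(x)
            as.numeric(stats::filter(x, ar1, method = "recursive")))
        e <- e * sqrt(1 - ar1^2)   # restore unit marginal variance
    }
    e
}

#' Render a resting-state run from a ground-truth scenario
#'
#' Signal model: voxel v at time t carries
#' \code{y_v(t) = sum_k w_kv s_k(t - d_v) + sigma eps}, i.e. every source is
#' delayed by the voxel's delay-field value. Sub-sample delays are applied
#' by frequency-domain phase shifting (with edge padding), never by
#' nearest-sample rounding, so the ground truth is finer than the
#' estimator's lag grid. Deterministic given the scenario seed.
#'
#' @param groundTruth a \linkS4class{GroundTruth}.
#' @param runId label for the rendered run.
#' @return A \linkS4class{BoldRun}.
#' @export
renderRestingRun <- function(groundTruth, runId = "synthetic-rest") {
    gt <- groundTruth
    stopifnot(is(gt, "GroundTruth"))
    n <- gt@sources@nTimepoints
    tr <- gt@sources@tr
    shape <- dim(gt@delayField@values)
    nvox <- prod(shape)
    if (max(abs(gt@delayField@values)) >= n * tr / 4)
        stop("delays exceed the series support")
    W <- cbind(as.vector(gt@weights$global),
               do.call(cbind, c(lapply(gt@weights$network, as.vector),
                                list(matrix(0, nvox, 0)))))
    S <- cbind(gt@sources@globalSource,
               do.call(cbind, c(gt@sources@networkSources,
                                list(matrix(0, n, 0)))))
    mixed <- S %*% t(W)                               # time x voxel
    shifted <- phaseShiftSeries(mixed, as.vector(gt@delayField@values), tr)
    data <- .withSeed(gt@seed, {
        shifted + gt@noiseSigma * .noiseMatrix(n, nvox, gt@noiseAR1)
    })
    boldRun(array(t(data), c(shape, n)), tr = tr,
            validMask = array(TRUE, shape), runId = runId)
}

#' Construct a block task design
#'
#' @param nCycles number of on/off cycles.
#' @param onSec,offSec block and control durations, seconds.
#' @param tr repetition time, seconds.
#' @param preSec lead-in before the first onset, seconds.
#' @param runLength run length in frames; default just covers the design.
#' @return A \linkS4class{TaskDesign}.
#' @export
blockDesign <- function(nCycles, onSec, offSec, tr, preSec = 0,
                        runLength = NULL) {
    onsets <- preSec + (seq_len(nCycles) - 1L) * (onSec + offSec)
    if (is.null(runLength))
        runLength <- ceiling((preSec + nCycles * (onSec + offSec)) / tr)
    new("TaskDesign", onsets = onsets,
        durations = rep(onSec, nCycles),
        runLength = as.integer(runLength), tr = tr)
}

#' Render a block-design task run with voxelwise-delayed responses
#'
#' Active voxels contain the HRF-convolved block regressor shifted by the
#' delay-field value (frequency-domain phase shift) plus noise; inactive
#' voxels contain noise only.
#'
#' @param design a \linkS4class{TaskDesign}.
#' @param delayField a \linkS4class{DelayField} on the run grid.
#' @param hrfParams list passed to \code{\link{canonicalHRF}} (e.g.
#'   \code{peakDelay}, \code{undershootDelay}, \code{ratio}).
#' @param noiseSigma additive white-noise SD relative to a unit-amplitude
#'   response.
#' @param seed integer seed.
#' @param activeMask 3D logical array of responding voxels; default is a
#'   central ellipsoid covering roughly a third of the grid (the synthetic
#'   "activation" region).
#' @param amplitude response amplitude of active voxels.
#' @return list with \code{run} (a \linkS4class{BoldRun}), \code{regressor}
#'   (the undelayed convolved task regressor) and \code{activeMask}.
#' @export
renderTaskRun <- function(design, delayField, hrfParams = list(),
                          noiseSigma = 0.5, seed = 1L, activeMask = NULL,
                          amplitude = 1) {
    stopifnot(is(design, "TaskDesign"), is(delayField, "DelayField"))
    if (length(design@onsets) == 0L) stop("empty design")
    shape <- dim(delayField@values)
    n <- design@runLength
    tr <- design@tr
    hrf <- do.call(canonicalHRF, c(list(tr = tr), hrfParams))
    reg <- .taskRegressor(design, hrf)
    if (is.null(activeMask)) {
        g <- expand.grid(x = seq_len(shape[1L]), y = seq_len(shape[2L]),
                         z = seq_len(shape[3L]))
        c0 <- (shape + 1) / 2
        r2 <- ((g$x - c0[1L]) / (shape[1L] / 2.9))^2 +
            ((g$y - c0[2L]) / (shape[2L] / 2.9))^2 +
            ((g$z - c0[3L]) / (shape[3L] / 2.9))^2
        activeMask <- array(r2 <= 1, shape)
    }
    nvox <- prod(shape)
    idx <- which(as.vector(activeMask))
    sig <- matrix(0, n, nvox)
    if (length(idx)) {
        delays <- as.vector(delayField@values)[idx]
        sig[, idx] <- phaseShiftSeries(
            matrix(rep(reg, length(idx)), n), delays, tr) * amplitude
    }
    data <- .withSeed(seed, sig + noiseSigma * .noiseMatrix(n, nvox))
    run <- boldRun(array(t(data), c(shape, n)), tr = tr,
                   validMask = array(TRUE, shape), runId = "synthetic-task")
    list(run = run, regressor = reg, activeMask = activeMask)
}

# boxcar sampled at frame times, convolved with the HRF kernel
.taskRegressor <- function(design, hrf) {
    n <- design@runLength
    tr <- design@tr
    tt <- (seq_len(n) - 1L) * tr
    box <- numeric(n)
    for (i in seq_along(design@onsets))
        box[tt >= design@onsets[i] - 1e-9 &
            tt < design@onsets[i] + design@durations[i] - 1e-9] <- 1
    full <- stats::convolve(box, rev(hrf), type = "open")
    full[seq_len(n)]
}

#' Render an arterial voxel patch with its periphery
#'
#' Artery voxels carry \code{baseline + intensityOffset +
#' gain * globalSource(t - shift) + noise}; periphery voxels carry
#' \code{baseline + noise}. With the default negative gain the arterial
#' signal is an inverted copy of the global source, emulating the inverse
#' coupling between the internal carotid artery signal and the global mean
#' signal; the positive intensity offset emulates the time-of-flight
#' inflow brightening of arteries.
#'
#' @param groundTruth a \linkS4class{GroundTruth}; uses its global source,
#'   arterial parameters, noise level and seed.
#' @param patchShape grid of the rendered neck patch.
#' @param baseline tissue baseline intensity.
#' @return list(run, arteryMask, peripheryMask): a \linkS4class{BoldRun}
#'   patch and two disjoint 3D masks.
#' @export
renderArterialVoxels <- function(groundTruth, patchShape = c(7L, 7L, 5L),
                                 baseline = 100) {
    gt <- groundTruth
    stopifnot(is(gt, "GroundTruth"))
    art <- gt@arterial
    if (art$gain == 0) stop("arterial gain must be non-zero")
    n <- gt@sources@nTimepoints
    tr <- gt@sources@tr
    patchShape <- as.integer(patchShape)
    # artery: a 2x2 tube along z in the patch center
    cx <- patchShape[1L] %/% 2L
    cy <- patchShape[2L] %/% 2L
    arteryMask <- array(FALSE, patchShape)
    arteryMask[cx + 0:1, cy + 0:1, 2:(patchShape[3L] - 1L)] <- TRUE
    peripheryMask <- .dilate6(arteryMask, 1L) & !arteryMask
    if (any(arteryMask & peripheryMask))
        stop("artery and periphery masks overlap")
    s <- phaseShiftSeries(gt@sources@globalSource, art$shift, tr)
    nvox <- prod(patchShape)
    data <- .withSeed(gt@seed + 1L, {
        d <- matrix(baseline, n, nvox) +
            gt@noiseSigma * .noiseMatrix(n, nvox)
        ai <- which(as.vector(arteryMask))
        d[, ai] <- d[, ai] + art$intensityOffset + art$gain * s
        d
    })
    run <- boldRun(array(t(data), c(patchShape, n)), tr = tr,
                   validMask = array(TRUE, patchShape),
                   runId = "synthetic-artery")
    list(run = run, arteryMask = arteryMask, peripheryMask = peripheryMask)
}
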