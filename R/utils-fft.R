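# Fourier helpers shared by the generator and the lag estimator.
# All interpolation here is band-limited: the signals of interest live in
# 0.01-0.1 Hz, far below Nyquist, so spectral zero-padding and phase
# rotation are exact for them up to edge effects (handled by padding).

# run expr with a temporary RNG state seeded by `seed`
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# zero-pad the spectrum of each column of x (time in rows) by `factor`,
# splitting the Nyquist bin for even lengths so the interpolant stays real
# and passes through the original samples. Returns the full periodic
# upsampled matrix of factor*n rows.
.fourierUpsampleFull <- function(x, factor) {
    x <- as.matrix(x)
    n <- nrow(x)
    m <- n * factor
    X <- mvfft(x)
    Y <- matrix(0 + 0i, m, ncol(x))
    h <- n %/% 2L
    Y[1:(h + 1L), ] <- X[1:(h + 1L), , drop = FALSE]
    if (n %% 2L == 0L) {
        Y[h + 1L, ] <- X[h + 1L, , drop = FALSE] / 2
        Y[m - h + 1L, ] <- X[h + 1L, , drop = FALSE] / 2
        if (h >= 2L)
            Y[(m - h + 2L):m, ] <- X[(h + 2L):n, , drop = FALSE]
    } else {
        Y[(m - h + 1L):m, ] <- X[(h + 2L):n, , drop = FALSE]
    }
    Re(mvfft(Y, inverse = TRUE)) / n
}

#' Band-limited upsampling of a time series
#'
#' Fourier (zero-padded spectrum) interpolation onto a grid \code{factor}
#' times finer. The output has \code{factor * (n - 1) + 1} samples and
#' reproduces the original samples exactly at their grid positions. Intended
#' for band-limited series (the 0.01-0.1 Hz analysis band is far below
#' Nyquist); a cubic-spline alternative is available via
#' \code{method = "spline"}.
#'
#' @param series numeric vector.
#' @param factor integer upsampling factor >= 1; the default 4 turns a
#'   0.72 s TR into a 0.18 s lag grid.
#' @param method \code{"fourier"} (default) or \code{"spline"}.
#' @return numeric vector of length \code{factor * (length(series) - 1) + 1}.
#' @export
upsampleSeries <- function(series, factor = 4L,
                           method = c("fourier", "spline")) {
    method <- match.arg(method)
    if (length(factor) != 1L || factor < 1 || factor != round(factor))
        stop("factor must be an integer >= 1")
    factor <- as.integer(factor)
    if (factor == 1L) return(series)
    n <- length(series)
    if (method == "spline") {
        t0 <- seq_len(n)
        t1 <- seq(1, n, by = 1 / factor)
        return(stats::spline(t0, series, xout = t1)$y)
    }
    full <- .fourierUpsampleFull(matrix(series, ncol = 1L), factor)[, 1L]
    full[seq_len(factor * (n - 1L) + 1L)]
}

# matrix version used by the voxelwise engine (columns = voxels)
.upsampleMatrix <- function(x, factor) {
    n <- nrow(x)
    if (factor == 1L) return(x)
    .fourierUpsampleFull(x, factor)[seq_len(factor * (n - 1L) + 1L), ,
                                    drop = FALSE]
}

#' Shift a series in time by a (fractional) delay
#'
#' Applies \code{y(t) = x(t - delay)} by frequency-domain phase rotation.
#' Sub-sample delays are represented exactly for band-limited content;
#' periodic wrap-around is suppressed by odd-reflection edge padding which is
#' trimmed after the shift.
#'
#' @param series numeric vector (or time-by-k matrix; each column shifted by
#'   the matching element of \code{delay}).
#' @param delay delay in seconds (positive = output occurs later).
#' @param tr sampling interval, seconds.
#' @param pad padding length in samples; default covers the delay plus a
#'   margin.
#' @return shifted series, same dimensions as the input.
#' @export
phaseShiftSeries <- function(series, delay, tr, pad = NULL) {
    x <- as.matrix(series)
    n <- nrow(x)
    if (max(abs(delay)) >= n * tr / 2)
        stop("delay exceeds the series support")
    if (length(delay) == 1L) delay <- rep(delay, ncol(x))
    if (length(delay) != ncol(x))
        stop("delay must be scalar or one value per column")
    if (is.null(pad))
        pad <- min(n - 1L, max(32L, ceiling(max(abs(delay)) / tr) + 8L))
    # odd reflection about both end points
    top <- 2 * x[rep(1L, pad), , drop = FALSE] - x[(pad + 1L):2L, , drop = FALSE]
    bot <- 2 * x[rep(n, pad), , drop = FALSE] -
        x[(n - 1L):(n - pad), , drop = FALSE]
    xp <- rbind(top, x, bot)
    P <- nrow(xp)
    fr <- (seq_len(P) - 1) / (P * tr)
    fr <- ifelse(fr > 1 / (2 * tr), fr - 1 / tr, fr)
    X <- mvfft(xp)
    ph <- exp(-2i * pi * outer(fr, delay))
    y <- Re(mvfft(X * ph, inverse = TRUE)) / P
    out <- y[(pad + 1L):(pad + n), , drop = FALSE]
    if (is.matrix(series)) out else out[, 1L]
}
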