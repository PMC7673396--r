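# Internal FastICA: PCA whitening followed by fixed-point iteration with
# the log-cosh contrast. Deflation (one unit at a time, Gram-Schmidt
# decorrelation) is the default; symmetric decorrelation is available.
# Written for the two ICA stages of this package; not a general toolbox.

# X: observations in rows. Returns S (n x k sources, unit variance),
# the orthogonal unmixing W in whitened space, and convergence info.
.fastICA <- function(X, nComp, type = c("deflation", "symmetric"),
                     alpha = 1, maxit = 300L, tol = 1e-5, seed = 1L,
                     center = TRUE) {
    type <- match.arg(type)
    X <- as.matrix(X)
    n <- nrow(X)
    Xc <- if (center) sweep(X, 2L, colMeans(X)) else X
    sv <- svd(Xc, nu = min(n, ncol(X)), nv = 0L)
    rank <- sum(sv$d > max(sv$d) * 1e-9)
    if (rank < nComp) {
        warning("rank ", rank, " < requested ", nComp,
                " components; reducing")
        nComp <- rank
    }
    Z <- sv$u[, seq_len(nComp), drop = FALSE] * sqrt(n)   # whitened, cov = I
    g <- function(u) tanh(alpha * u)
    dg <- function(u) alpha * (1 - tanh(alpha * u)^2)
    converged <- TRUE
    W <- .withSeed(seed, matrix(rnorm(nComp * nComp), nComp))
    if (type == "deflation") {
        for (i in seq_len(nComp)) {
            w <- W[, i]
            if (i > 1L) {
                B <- W[, seq_len(i - 1L), drop = FALSE]
                w <- w - B %*% crossprod(B, w)
            }
            w <- w / sqrt(sum(w^2))
            ok <- FALSE
            for (it in seq_len(maxit)) {
                zw <- Z %*% w
                wn <- crossprod(Z, g(zw)) / n - mean(dg(zw)) * w
                if (i > 1L) {
                    B <- W[, seq_len(i - 1L), drop = FALSE]
                    wn <- wn - B %*% crossprod(B, wn)
                }
                wn <- wn / sqrt(sum(wn^2))
                if (sum(wn * w) < 0) wn <- -wn       # sign-align
                if (abs(sum(wn * w) - 1) < tol) {
                    w <- wn; ok <- TRUE; break
                }
                # damp after an initial burn-in to break 2-cycles
                if (it > 50L) {
                    wn <- wn + w
                    wn <- wn / sqrt(sum(wn^2))
                }
                w <- wn
            }
            if (!ok) converged <- FALSE
            W[, i] <- w
        }
    } else {
        # symmetric: update all units, then orthogonalize jointly
        sym <- function(M) {
            e <- eigen(crossprod(M), symmetric = TRUE)
            M %*% e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-15)),
                                     nComp) %*% t(e$vectors)
        }
        W <- sym(W)
        ok <- FALSE
        for (it in seq_len(maxit)) {
            ZW <- Z %*% W
            Wn <- crossprod(Z, g(ZW)) / n -
                W %*% diag(colMeans(dg(ZW)), nComp)
            Wn <- sym(Wn)
            if (max(abs(abs(colSums(Wn * W)) - 1)) < tol) {
                W <- Wn; ok <- TRUE; break
            }
            W <- Wn
        }
        converged <- ok
    }
    S <- Z %*% W
    list(S = S, W = W, converged = converged, nComp = nComp,
         d = sv$d[seq_len(nComp)])
}
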