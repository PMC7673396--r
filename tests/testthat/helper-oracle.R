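# Independent brute-force lag oracle: explicit loop over every candidate
# shift, textbook Pearson formula over the overlap, same tie-break rule
# (max r among r > 0; ties -> smaller |lag|, then the negative lag).
bruteForceLag <- function(vox, ref, tr, searchHalfwidth, factor = 4L,
                          minOverlap = 0.8) {
    vu <- upsampleSeries(vox, factor)
    ru <- upsampleSeries(ref, factor)
    N <- length(vu)
    step <- tr / factor
    K <- floor(searchHalfwidth / step + 1e-9)
    bestR <- -Inf
    bestK <- NA_integer_
    for (k in -K:K) {
        if (k >= 0L) { a <- vu[(1 + k):N]; b <- ru[1:(N - k)] }
        else { a <- vu[1:(N + k)]; b <- ru[(1 - k):N] }
        L <- length(a)
        if (L < minOverlap * N) next
        ma <- sum(a) / L
        mb <- sum(b) / L
        num <- sum((a - ma) * (b - mb))
        den <- sqrt(sum((a - ma)^2) * sum((b - mb)^2))
        if (den <= 0) next
        r <- num / den
        if (r > bestR || (r == bestR && !is.na(bestK) && abs(k) < abs(bestK))) {
            bestR <- r
            bestK <- k
        }
    }
    if (!is.finite(bestR) || bestR <= 0)
        return(list(valid = FALSE, lag = NA_real_, r = NA_real_))
    list(valid = TRUE, lag = bestK * step, r = bestR)
}

# fraction of spectral power inside [low, high] Hz
bandPowerFraction <- function(x, tr, low, high) {
    n <- length(x)
    sp <- Mod(fft(x))^2
    fr <- (seq_len(n) - 1) / (n * tr)
    fr <- pmin(fr, 1 / tr - fr)
    sum(sp[fr >= low & fr <= high]) / sum(sp)
}

# maximum absolute difference between 6-neighbors of a 3D field
maxNeighborDiff <- function(v) {
    max(max(abs(apply(v, c(2, 3), diff))),
        max(abs(apply(v, c(1, 3), diff))),
        max(abs(apply(v, c(1, 2), diff))))
}

# greedy one-to-one matching of recovered components to sources by |r|
matchComponents <- function(est, truth) {
    M <- abs(cor(est, truth))
    k <- ncol(truth)
    out <- numeric(k)
    used <- rep(FALSE, ncol(est))
    for (j in seq_len(k)) {
        i <- which.max(ifelse(used, -Inf, M[, j]))
        out[j] <- M[i, j]
        used[i] <- TRUE
    }
    out
}
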