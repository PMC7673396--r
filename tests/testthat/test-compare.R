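# helper: wrap a lag array (NA = invalid) in a LagMap
mkLagMap <- function(lag, mag = NULL, step = 0.18, label = "IC") {
    v <- !is.na(lag)
    if (is.null(mag)) { mag <- lag; mag[v] <- 0.9 }
    new("LagMap", lag = lag, magnitude = mag, validMask = v,
        referenceLabel = label, searchHalfwidth = 6, gridStep = step)
}

test_that("lag centering is exact and idempotent", {
    lag <- array(NA_real_, c(4, 4, 2))
    lag[1:10] <- (1:10) * 0.18
    m <- mkLagMap(lag)
    c1 <- centerLags(m)
    expect_equal(mean(c1@lag[c1@validMask]), 0, tolerance = 1e-12)
    c2 <- centerLags(c1)
    expect_equal(c2@lag, c1@lag, tolerance = 1e-12)
    # constant map centers to all zeros
    lagC <- array(NA_real_, c(4, 4, 2)); lagC[1:10] <- 0.72
    cc <- centerLags(mkLagMap(lagC))
    expect_true(all(cc@lag[cc@validMask] == 0))
    expect_error(centerLags(mkLagMap(array(NA_real_, c(4, 4, 2)))),
                 "at least 2")
})

test_that("lag-map comparison is symmetric, offset-invariant, joint-masked", {
    set.seed(1)
    lagA <- array(NA_real_, c(6, 6, 3))
    lagA[1:80] <- sample(-10:10, 80, TRUE) * 0.18
    lagB <- lagA + 0.36              # constant offset
    lagB[70:85] <- NA                # partial mask mismatch
    lagB[6, 6, 3] <- 0
    a <- mkLagMap(lagA); b <- mkLagMap(lagB)
    expect_equal(as.numeric(compareLagMaps(a, a)), 1)
    neg <- mkLagMap(-lagA)
    expect_equal(as.numeric(compareLagMaps(a, neg)), -1)
    rAB <- compareLagMaps(a, b)
    expect_equal(as.numeric(rAB), 1, tolerance = 1e-12)
    expect_equal(attr(rAB, "nVoxels"), sum(a@validMask & b@validMask))
    expect_equal(as.numeric(compareLagMaps(b, a)), as.numeric(rAB))
    # small joint mask flagged
    lagSmall <- array(NA_real_, c(6, 6, 3)); lagSmall[1:5] <- (1:5) * 0.18
    expect_warning(compareLagMaps(a, mkLagMap(lagSmall)), "low-confidence")
})

test_that("group test equals the textbook one-sample t on Fisher Z", {
    # hand-computed 3-run example
    r <- c(0.3, 0.5, 0.4)
    z <- atanh(r)
    tHand <- mean(z) / (sd(z) / sqrt(3))
    pHand <- 2 * pt(-abs(tHand), 2)
    st <- groupTest(r)
    expect_equal(st@tStat, tHand, tolerance = 1e-12)
    expect_equal(st@pTwoTailed, pHand, tolerance = 1e-12)
    expect_equal(st@fisherZ, z)
    # degenerate all-zero: t = 0, p = 1
    st0 <- groupTest(c(0, 0, 0))
    expect_equal(st0@tStat, 0)
    expect_equal(st0@pTwoTailed, 1)
    expect_error(groupTest(c(0.5, 1)), "infinite")
    expect_error(groupTest(0.5), "at least 2")
    # null calibration: p approximately uniform
    set.seed(6)
    ps <- replicate(400, groupTest(tanh(rnorm(5, 0, 0.2)))@pTwoTailed)
    expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
    # power grows with runs
    set.seed(7)
    pFew <- median(replicate(100,
        groupTest(tanh(0.3 + rnorm(4, 0, 0.15)))@pTwoTailed))
    pMany <- median(replicate(100,
        groupTest(tanh(0.3 + rnorm(12, 0, 0.15)))@pTwoTailed))
    expect_lt(pMany, pFew)
})

test_that("composite assembly aligns offsets and resolves overlaps", {
    # one IC identical to the GMS map: composite == GMS map
    set.seed(2)
    lag <- array(NA_real_, c(5, 5, 2))
    lag[1:40] <- sample(-8:8, 40, TRUE) * 0.18
    gms <- mkLagMap(lag, label = "GMS")
    comp1 <- buildComposite(list(mkLagMap(lag)), gms)
    expect_equal(comp1@lag[comp1@validMask], lag[!is.na(lag)])
    expect_equal(as.numeric(compareLagMaps(comp1, gms)), 1)
    # overlap voxel goes to the IC with larger magnitude
    l1 <- array(NA_real_, c(3, 3, 1)); l1[1:6] <- 0.18
    m1 <- array(NA_real_, c(3, 3, 1)); m1[1:6] <- 0.8
    l2 <- array(NA_real_, c(3, 3, 1)); l2[4:9] <- 0.36
    m2 <- array(NA_real_, c(3, 3, 1)); m2[4:9] <- 0.4
    gmsFlat <- array(NA_real_, c(3, 3, 1)); gmsFlat[1:9] <- 0
    comp2 <- buildComposite(list(mkLagMap(l1, m1), mkLagMap(l2, m2)),
                            mkLagMap(gmsFlat, label = "GMS"))
    expect_true(all(comp2@contributor[4:6] == 1L))
    expect_true(all(comp2@contributor[7:9] == 2L))
    # offsets are per-IC constants: within-IC contrasts preserved
    expect_equal(diff(comp2@lag[c(1, 2)]), diff(l1[c(1, 2)]))
    # midpoint alignment: each shifted IC range is centered on the GMS mid
    sh1 <- l1 + comp2@offsetsApplied[1]
    expect_equal((min(sh1, na.rm = TRUE) + max(sh1, na.rm = TRUE)) / 2, 0)
})

test_that("pooled 2D histograms conserve counts and imply the pooled r", {
    set.seed(11)
    lagA <- array(NA_real_, c(8, 8, 4))
    lagA[1:200] <- sample(-10:10, 200, TRUE) * 0.18
    noiseK <- array(sample(-2:2, 256, TRUE) * 0.18, c(8, 8, 4))
    lagB <- lagA + noiseK
    a <- mkLagMap(lagA); b <- mkLagMap(lagB)
    h <- pooledHistogram(list(list(a = a, b = b)))
    expect_equal(attr(h, "n"), sum(a@validMask & b@validMask))
    expect_equal(sum(h), attr(h, "n"))
    # identical maps: all mass on the diagonal
    hd <- pooledHistogram(list(list(a = a, b = a)))
    da <- as.numeric(rownames(hd)); db <- as.numeric(colnames(hd))
    offDiag <- outer(da, db, function(x, y) abs(x - y) > 1e-9)
    expect_equal(sum(hd[offDiag]), 0)
    # histogram correlation matches the voxelwise correlation
    rVox <- as.numeric(compareLagMaps(a, b))
    expect_lt(abs(histogramCorrelation(h) - rVox), 0.02)
})
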