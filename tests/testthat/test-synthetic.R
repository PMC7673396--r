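test_that("sources are band-limited, unit variance and reproducible", {
    ss <- makeSources(1200, 0.72, c(0.01, 0.1), nNetworks = 3, seed = 1)
    expect_s4_class(ss, "SourceSet")
    expect_length(ss@globalSource, 1200)
    expect_length(ss@networkSources, 3)
    all5 <- c(list(ss@globalSource), ss@networkSources)
    for (s in all5) {
        expect_equal(sd(s), 1, tolerance = 1e-12)
        expect_gte(bandPowerFraction(s, 0.72, 0.01, 0.1), 0.95)
    }
    # pairwise near-independence among network sources
    C <- cor(do.call(cbind, ss@networkSources))
    expect_lt(max(abs(C[upper.tri(C)])), 0.2)
    # determinism
    ss2 <- makeSources(1200, 0.72, c(0.01, 0.1), nNetworks = 3, seed = 1)
    expect_identical(ss@globalSource, ss2@globalSource)
    expect_identical(ss@networkSources, ss2@networkSources)
    # parameter errors
    expect_error(makeSources(100, 0.72), ">= 128")
    expect_error(makeSources(400, 0.72, band = c(0.01, 0.8)), "Nyquist")
})

test_that("sources pass the analysis band-pass with >= 95% power retention", {
    for (seed in 1:3) {
        s <- makeSources(600, 0.72, seed = seed)@globalSource
        expect_gte(var(bandpass(s, 0.72)) / var(s), 0.95)
    }
})

test_that("delay fields are smooth, bounded and pattern-shaped", {
    f <- makeDelayField(c(20, 20, 12), "gradient", c(-2, 2))
    expect_equal(min(f@values), -2)
    expect_equal(max(f@values), 2)
    expect_lte(maxNeighborDiff(f@values), 0.5)
    # the gradient pattern is a monotone ramp along x
    prof <- apply(f@values, 1, mean)
    expect_true(all(diff(prof) > 0))

    w <- makeDelayField(c(20, 20, 12), "watershed", c(-2, 2))
    expect_lte(maxNeighborDiff(w@values), 0.5)
    expect_equal(range(w@values), c(-2, 2))

    z <- makeDelayField(c(8, 8, 4), "constant", c(0, 0))
    expect_true(all(z@values == 0))

    expect_error(makeDelayField(c(8, 8, 4), "gradient", c(-7, 7)),
                 "search window")
})

test_that("resting runs implement the delayed-source model", {
    # noise-free, constant zero delay: every voxel is the source exactly
    gt <- makeGroundTruth(shape = c(6, 6, 4), nTimepoints = 256,
                          pattern = "constant", range = c(0, 0),
                          noiseSigma = 0, seed = 3)
    run <- renderRestingRun(gt)
    s <- gt@sources@globalSource
    vox <- matrix(run@data, prod(dim(run@data)[1:3]), 256)
    for (v in c(1L, 50L, 144L))
        expect_equal(cor(vox[v, ], s), 1, tolerance = 1e-9)

    # noise-free single delay recovered by brute-force cross-correlation
    gt2 <- makeGroundTruth(shape = c(3, 3, 2), nTimepoints = 400,
                           pattern = "constant", range = c(1.44, 1.44),
                           noiseSigma = 0, seed = 4)
    run2 <- renderRestingRun(gt2)
    v1 <- run2@data[1, 1, 1, ]
    est <- bruteForceLag(v1, gt2@sources@globalSource, 0.72, 5.8)
    expect_lte(abs(est$lag - 1.44), 0.18)

    # determinism: bit-identical volumes for a fixed seed
    gt3 <- makeGroundTruth(seed = 9, nTimepoints = 200)
    expect_identical(renderRestingRun(gt3)@data, renderRestingRun(gt3)@data)
})

test_that("task runs contain delayed HRF responses only in active voxels", {
    des1 <- blockDesign(6, 12, 36, tr = 0.75, preSec = 17)
    f <- makeDelayField(c(8, 8, 4), "constant", c(0, 0))
    tk <- renderTaskRun(des1, f, noiseSigma = 0, seed = 2)
    reg <- tk$regressor
    # regressor has 6 response epochs (plateaus above half maximum)
    runs <- rle(reg > max(reg) / 2)
    expect_equal(sum(runs$values), 6)
    # task 2 geometry: 10 cycles
    des2 <- blockDesign(10, 6, 24, tr = 0.75, preSec = 17)
    f2 <- makeDelayField(c(4, 4, 2), "constant", c(0, 0))
    reg2 <- renderTaskRun(des2, f2, noiseSigma = 0, seed = 2)$regressor
    expect_equal(sum(rle(reg2 > max(reg2) / 2)$values), 10)
    # zero delay, zero noise: active voxel equals the regressor up to scale
    act <- which(tk$activeMask, arr.ind = TRUE)[1, ]
    v <- tk$run@data[act[1], act[2], act[3], ]
    expect_equal(cor(v, reg), 1, tolerance = 1e-6)
    # inactive voxels carry no signal
    ina <- which(!tk$activeMask, arr.ind = TRUE)[1, ]
    expect_true(all(tk$run@data[ina[1], ina[2], ina[3], ] == 0))
    expect_error(blockDesign(0, 12, 36, tr = 0.75), "at least one block")
})

test_that("arterial voxels carry an offset, inverted, shifted global copy", {
    gt <- makeGroundTruth(nTimepoints = 400, noiseSigma = 0, seed = 6,
                          arterial = list(gain = -1, shift = -2.7,
                                          intensityOffset = 20))
    av <- renderArterialVoxels(gt)
    expect_false(any(av$arteryMask & av$peripheryMask))
    d <- dim(av$run@data)
    vox <- matrix(av$run@data, prod(d[1:3]), d[4])
    aMean <- mean(vox[as.vector(av$arteryMask), ])
    pMean <- mean(vox[as.vector(av$peripheryMask), ])
    expect_gt(aMean, pMean)
    # gain = -1, shift = -2.7: cross-correlation minimum at -2.7 s
    aser <- colMeans(vox[as.vector(av$arteryMask), , drop = FALSE])
    cf <- arteryGmsXcorr(aser - mean(aser), gt@sources@globalSource,
                         tr = 0.72, searchHalfwidth = 5.8)
    expect_lt(cf@peakR, 0)
    expect_lte(abs(cf@peakLag - (-2.7)), 0.18)
    # gain = +1, shift = 0: peak +1 at lag 0
    gt2 <- makeGroundTruth(nTimepoints = 400, noiseSigma = 0, seed = 6,
                           arterial = list(gain = 1, shift = 0,
                                           intensityOffset = 20))
    av2 <- renderArterialVoxels(gt2)
    vox2 <- matrix(av2$run@data, prod(d[1:3]), d[4])
    aser2 <- colMeans(vox2[as.vector(av2$arteryMask), , drop = FALSE])
    # window short enough that the band-limited autocorrelation stays
    # positive throughout
    cf2 <- arteryGmsXcorr(aser2 - mean(aser2), gt2@sources@globalSource,
                          tr = 0.72, searchHalfwidth = 2.16)
    expect_equal(cf2@peakLag, 0)
    expect_equal(cf2@peakR, 1, tolerance = 1e-9)
    expect_length(cf2@negativePeak, 0)
})

test_that("network weights are compact blobs with limited overlap", {
    gt <- makeGroundTruth(nNetworks = 3, nTimepoints = 400, seed = 2)
    supp <- sapply(gt@weights$network, function(w) as.vector(w) > 0)
    for (i in 1:2) for (j in (i + 1):3) {
        ov <- sum(supp[, i] & supp[, j]) /
            min(sum(supp[, i]), sum(supp[, j]))
        expect_lte(ov, 0.2)
    }
})

test_that("ground truth serializes losslessly through the JSON sidecar", {
    gt <- makeGroundTruth(shape = c(5, 4, 3), nTimepoints = 256,
                          nNetworks = 2, noiseAR1 = 0.3, seed = 12)
    path <- tempfile(fileext = ".json")
    writeGroundTruth(gt, path)
    gt2 <- readGroundTruth(path)
    expect_equal(gt2@delayField@values, gt@delayField@values)
    expect_equal(gt2@sources@globalSource, gt@sources@globalSource)
    expect_equal(gt2@sources@networkSources, gt@sources@networkSources)
    expect_equal(gt2@weights, gt@weights)
    expect_equal(gt2@arterial, gt@arterial)
    expect_identical(gt2@seed, gt@seed)
    expect_identical(gt2@noiseAR1, gt@noiseAR1)
})
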