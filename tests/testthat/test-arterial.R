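test_that("artery ROI extraction picks the bright connected tube", {
    img <- array(10, c(10, 10, 6))
    region <- array(TRUE, c(10, 10, 6))
    img[3, 3, 2:5] <- 100
    img[3, 4, 2:5] <- 100              # 8-voxel bright tube
    m <- extractArteryROI(img, region, 50)
    expect_equal(sum(m), 8)
    expect_true(all(m[3, 3:4, 2:5]))
    # threshold below region minimum: whole region, flagged
    expect_warning(m2 <- extractArteryROI(img, region, 5),
                   "more than half")
    expect_true(all(m2[region]))
    # two tubes: larger wins; equal sizes break ties lexicographically
    img2 <- array(10, c(10, 10, 6))
    img2[2, 2, 1:3] <- 100             # 3 voxels
    img2[8, 8, 1:5] <- 100             # 5 voxels
    expect_equal(sum(extractArteryROI(img2, region, 50) &
                     img2 == 100 & rep(TRUE, 600)), 5)
    img3 <- array(10, c(10, 10, 6))
    img3[2, 2, 1:3] <- 100
    img3[8, 8, 1:3] <- 100
    m3 <- extractArteryROI(img3, region, 50)
    expect_true(all(m3[2, 2, 1:3]))    # smaller linear index wins
    expect_error(extractArteryROI(img, region, 1e6), "threshold")
})

test_that("peripheral shells are disjoint dilations that grow with radius", {
    m <- array(FALSE, c(9, 9, 9))
    m[5, 5, 5] <- TRUE
    shell1 <- peripheralROI(m, 1)
    expect_equal(sum(shell1), 6)       # 6-connectivity shell
    expect_false(any(shell1 & m))
    sizes <- sapply(1:3, function(r) sum(peripheralROI(m, r)))
    expect_true(all(diff(sizes) > 0))
    # boundary clipping warns
    mEdge <- array(FALSE, c(5, 5, 5))
    mEdge[1, 3, 3] <- TRUE
    expect_warning(peripheralROI(mEdge, 1), "boundary")
    expect_error(peripheralROI(m, 0), ">= 1")
})

test_that("paired artery-periphery test detects the inflow offset", {
    gts <- lapply(1:18, function(i)
        makeGroundTruth(nTimepoints = 200, seed = 400 + i,
                        arterial = list(gain = -1, shift = -2.7,
                                        intensityOffset = 15)))
    avs <- lapply(gts, renderArterialVoxels)
    res <- compareArteryPeriphery(lapply(avs, `[[`, "run"),
                                  lapply(avs, `[[`, "arteryMask"),
                                  lapply(avs, `[[`, "peripheryMask"))
    expect_gt(res$t, 0)
    expect_lt(res$p, 0.05)
    expect_true(all(res$meanArtery > res$meanPeriphery))
    # degenerate zero-variance differences are flagged
    runsSame <- rep(list(avs[[1]]$run), 2)
    expect_warning(
        deg <- compareArteryPeriphery(runsSame,
                                      rep(list(avs[[1]]$arteryMask), 2),
                                      rep(list(avs[[1]]$peripheryMask), 2)),
        "degenerate")
    expect_true(is.na(deg$t))
    expect_error(compareArteryPeriphery(avs[[1]]$run,
                                        list(avs[[1]]$arteryMask),
                                        list(avs[[1]]$peripheryMask)),
                 "at least 2")
})

test_that("artery-GMS cross-correlation reports both signed extrema", {
    tr <- 0.72
    gms <- makeSources(400, tr, seed = 44)@globalSource
    # exact inversion: peak -1 at lag 0
    res <- arteryGmsXcorr(-gms, gms, tr)
    expect_equal(res@peakLag, 0)
    expect_equal(res@peakR, -1, tolerance = 1e-9)
    # inverted and artery leads by 2.7 s, moderate noise
    set.seed(3)
    art <- -phaseShiftSeries(gms, -2.7, tr) +
        0.5 * bandpass(rnorm(400), tr)
    res2 <- arteryGmsXcorr(art, gms, tr, searchHalfwidth = 5.8)
    expect_lt(res2@peakR, -0.3)
    expect_lte(abs(res2@peakLag - (-2.7)), tr / 4 + 1e-9)
    expect_lt(res2@negativePeak$r, -0.3)
    # positive copy: positive peak, no negative extremum required
    res3 <- arteryGmsXcorr(gms, gms, tr)
    expect_equal(res3@positivePeak$lag, 0)
    expect_gt(res3@positivePeak$r, 0.999)
    # full function antisymmetry under argument swap
    a <- makeSources(300, tr, seed = 45)@globalSource
    b <- makeSources(300, tr, seed = 46)@globalSource
    f1 <- arteryGmsXcorr(a, b, tr)
    f2 <- arteryGmsXcorr(b, a, tr)
    expect_equal(f1@r, rev(f2@r), tolerance = 1e-10)
    expect_error(arteryGmsXcorr(rep(1, 300), a, tr), "constant")
})

test_that("group-average cross-correlation recovers the injected shift", {
    tr <- 0.72
    shift <- -2.7
    set.seed(77)
    curves <- replicate(12, {
        g <- makeSources(300, tr, seed = sample.int(1e6, 1))@globalSource
        art <- -phaseShiftSeries(g, shift, tr) + 0.8 * bandpass(rnorm(300), tr)
        arteryGmsXcorr(art, g, tr)@r
    })
    lagGrid <- arteryGmsXcorr(makeSources(300, tr, seed = 1)@globalSource,
                              makeSources(300, tr, seed = 2)@globalSource,
                              tr)@lagGrid
    avg <- rowMeans(curves)
    expect_lte(abs(lagGrid[which.max(abs(avg))] - shift), tr / 4 + 1e-9)
    expect_lt(avg[which.max(abs(avg))], 0)
})

test_that("group summary separates negative-coupled arteries", {
    tr <- 0.72
    set.seed(19)
    mk <- function(seed, gain) {
        g <- makeSources(300, tr, seed = seed)@globalSource
        art <- gain * phaseShiftSeries(g, -2.7, tr) +
            0.4 * bandpass(rnorm(300), tr)
        arteryGmsXcorr(art, g, tr)
    }
    res <- c(lapply(1:6, mk, gain = -1), list(mk(7, gain = +1)))
    gs <- arteryGroupSummary(res)
    expect_equal(gs$all$n, 7)
    expect_equal(gs$negativeCoupled$n, 6)
    expect_lte(abs(gs$negativeCoupled$meanLag - (-2.7)), tr / 4 + 1e-9)
    expect_lt(gs$negativeCoupled$meanR, -0.3)
    # group-mean curve extremum recovers the injected shift
    expect_lte(abs(gs$lagGrid[which.max(abs(gs$meanCurve[1:56]))] - (-2.7)),
               tr / 4 + 1e-9)
})
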