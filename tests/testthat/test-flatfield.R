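# Inverse-profile correction and its consequences, including the
# background-amplification artifact.

flatProfile <- function() fixture("flatProfile", function() {
    w <- detectWells(sceneImage(renderRUD(alignedConfig(
        extentMM = 20, imageSize = 160L))), rudParams())
    fitSurface(poolSamples(w), "bspline")
})

radialProfile <- function() fixture("radialProfile", function() {
    illum <- IlluminationField("radial_gaussian", sigmaFrac = 0.42)
    w <- detectWells(sceneImage(renderRUD(alignedConfig(
        extentMM = 40, imageSize = 260L, illumination = illum,
        background = 60))), rudParams())
    fitSurface(poolSamples(w), "rbf")
})

test_that("correction gains are the reciprocal profile, floored and bounded", {
    mapFlat <- buildCorrection(flatProfile())
    g <- mapFlat@gain
    expect_lt(max(abs(g[!is.na(g)] - 1)), 1e-4)   # flat profile: gain = 1
    map <- buildCorrection(radialProfile(), floor = 0.05)
    g <- map@gain
    expect_true(all(g[!is.na(g)] >= 1 - 1e-6))     # profile <= 1 => gain >= 1
    expect_true(all(g[!is.na(g)] <= 1 / 0.05 + 1e-9))
    # gain equals 1/value at interior lattice points (reciprocal contract)
    pr <- radialProfile()
    v <- evalProfile(pr, 130, 130)
    expect_equal(map@gain[131, 131], 1 / max(v, 0.05), tolerance = 1e-9)
    expect_error(buildCorrection(radialProfile(), floor = 0), "floor")
})

test_that("profile values below the floor are clamped and counted", {
    pr <- radialProfile()              # profile dips to ~0.25 at the corners
    expect_lt(min(profileValues(pr), na.rm = TRUE), 0.5)
    map <- buildCorrection(pr, floor = 0.5)
    expect_gt(map@clamped, 0)
    expect_equal(max(map@gain, na.rm = TRUE), 1 / 0.5, tolerance = 1e-9)
    # clamped pixels are exactly those whose profile value is under the floor
    mapFree <- buildCorrection(pr, floor = 1e-6)
    v <- 1 / mapFree@gain
    expect_identical(map@clamped, sum(v[!is.na(v)] < 0.5))
})

test_that("correcting the profile itself yields a constant image", {
    pr <- radialProfile()
    map <- buildCorrection(pr, floor = 1e-4, marginPx = 0)
    img <- 1 / map@gain          # the (floored) profile as an image
    img[is.na(img)] <- 0.5
    corr <- applyCorrection(img, map)
    inside <- !is.na(map@gain)
    expect_lt(max(abs(corr[inside] - 1)), 1e-9)
    expect_identical(attr(corr, "outsideValidRegion"), map@outside)
    expect_error(applyCorrection(matrix(1, 10, 10), map),
        "frame mismatch")
})

test_that("flat-field round trip restores a flat surface", {
    # noise-free: 4 positions x 1 orientation, RBF profile, b-spline refit
    illum <- IlluminationField("radial_gaussian", sigmaFrac = 0.45)
    mk <- function(off) renderRUD(alignedConfig(extentMM = 24,
        imageSize = 220L, illumination = illum, offsetMM = off))
    renders <- lapply(list(c(-9, -9), c(9, -9), c(-9, 9), c(9, 9)), mk)
    wl <- detectAllRenders(renders)
    prof <- fitSurface(poolSamples(wl), "rbf")
    map <- buildCorrection(prof)
    cw <- lapply(renders, function(r)
        detectWells(applyCorrection(sceneImage(r), map), rudParams()))
    fl <- evaluateFlatness(poolSamples(cw))
    expect_gte(fl$min, 0.99)
    expect_equal(fl$max, 1)
    # without correction the same scenes are far from flat
    fl0 <- evaluateFlatness(poolSamples(wl))
    expect_lt(fl0$min, 0.8)
})

test_that("additive background makes correction overshoot dim regions", {
    # corrected background at illumination I is b/I > b: the edge control
    # exceeds the center control after correction
    illum <- IlluminationField("radial_gaussian", sigmaFrac = 0.42)
    map <- buildCorrection(radialProfile())
    mkCyl <- function(off) renderCylinders(c(100, 0), SceneConfig(
        imageSize = c(260L, 260L), mmPerPx = 0.2, psfSigma = 1.2,
        illumination = illum, wellPeak = 20000, background = 600,
        offsetMM = off))
    roiMeans <- function(render, img) {
        tr <- sceneTruth(render)
        vapply(1:2, function(i) measureDiskROI(img,
            unlist(tr[i, c("x_true_px", "y_true_px")]),
            (10 / 0.2 / 2) * 2 / 3)$mean, numeric(1))
    }
    cen <- mkCyl(c(0, 0)); edg <- mkCyl(c(-12.5, 0))
    rawCen <- roiMeans(cen, sceneImage(cen))
    rawEdg <- roiMeans(edg, sceneImage(edg))
    corCen <- roiMeans(cen, applyCorrection(sceneImage(cen), map))
    corEdg <- roiMeans(edg, applyCorrection(sceneImage(edg), map))
    # uncorrected: the fluorescent cylinder dims toward the edge, the
    # background-only control does not change
    expect_lt(rawEdg[1], 0.9 * rawCen[1])
    expect_equal(rawEdg[2], rawCen[2], tolerance = 0.01)
    # corrected: the 100 nM cylinder is restored, the control overshoots
    expect_equal(corEdg[1], corCen[1], tolerance = 0.05)
    expect_gt(corEdg[2], corCen[2])
    # and the corrected control exceeds pure background b at the edge
    expect_gt(corEdg[2], 600)
})

test_that("background lowers corrected flatness relative to background-free", {
    # gain = 1/I comes from a calibration scene without background; applied
    # to a scene with additive offset b the corrected wells are s + b/I
    # instead of s, so flatness degrades (arithmetic of (s*I + b)/I)
    illum <- IlluminationField("radial_gaussian", sigmaFrac = 0.55)
    offs <- list(c(-9, -9), c(9, -9), c(-9, 9), c(9, 9))
    calib <- detectAllRenders(lapply(offs, function(off)
        renderRUD(alignedConfig(extentMM = 24, imageSize = 220L,
            illumination = illum, offsetMM = off, wellPeak = 30000,
            background = 0))))
    map <- buildCorrection(fitSurface(poolSamples(calib), "rbf"))
    flatnessWithBg <- function(bg) {
        renders <- lapply(offs, function(off)
            renderRUD(alignedConfig(extentMM = 24, imageSize = 220L,
                illumination = illum, offsetMM = off, wellPeak = 3000,
                background = bg)))
        cw <- lapply(renders, function(r) detectWells(
            applyCorrection(sceneImage(r), map), rudParams()))
        evaluateFlatness(poolSamples(cw))$min
    }
    expect_lt(flatnessWithBg(300), flatnessWithBg(0))
    expect_gt(flatnessWithBg(0), 0.98)
})

test_that("ROI-then-correct equals correct-then-ROI for near-uniform gain", {
    map <- buildCorrection(radialProfile())
    cfg <- SceneConfig(imageSize = c(260L, 260L), mmPerPx = 0.2,
        psfSigma = 1.2, wellPeak = 20000, background = 100,
        offsetMM = c(-6, 0))
    r <- renderCylinders(c(100, 0), cfg)
    tr <- sceneTruth(r)
    ctr <- unlist(tr[1, c("x_true_px", "y_true_px")])
    corr <- applyCorrection(sceneImage(r), map)
    roiCorr <- measureDiskROI(corr, ctr, 12)$mean
    roiRaw <- measureDiskROI(sceneImage(r), ctr, 12)$mean
    gROI <- measureDiskROI(map@gain, ctr, 12)
    expect_lt(gROI$sd / gROI$mean, 0.05)          # gain varies < 5% here
    expect_equal(roiCorr, roiRaw * gROI$mean, tolerance = 0.01 * roiCorr)
})
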