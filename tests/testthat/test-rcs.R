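# Dilution-series ROI extraction, baselining/normalization, and the
# log-log power-law fit y = 10^C x^m.

analyticWells <- function(conc = rcsDefaultConcentrations(),
        fun = function(x) 5 * x, bg = 0) {
    roi <- fun(conc) + bg
    df <- data.frame(well = seq_along(conc), conc_nM = conc,
        roi_mean = roi, roi_sd = 0, n_px = 100)
    df$baselined <- df$roi_mean - df$roi_mean[df$conc_nM == 0]
    df$excluded <- df$conc_nM > 0 & df$baselined <= 0
    df$reason <- ifelse(df$excluded, "non-positive", "")
    usable <- df$conc_nM > 0 & !df$excluded
    df$normalized <- df$baselined / max(df$baselined[usable])
    df
}

test_that("exact power laws are recovered to machine precision", {
    f1 <- fitLinearity(analyticWells(fun = function(x) 5 * x))
    expect_equal(linearitySlope(f1), 1, tolerance = 1e-9)
    expect_equal(f1@r2, 1, tolerance = 1e-12)
    f2 <- fitLinearity(analyticWells(fun = function(x) 0.01 * x^2))
    expect_equal(linearitySlope(f2), 2, tolerance = 1e-9)
    # the fitted intercept reproduces the model: y = 10^C x^m
    w <- analyticWells(fun = function(x) 5 * x)
    expect_equal(10^f1@C * 100^f1@m,
        w$normalized[w$conc_nM == 100], tolerance = 1e-9)
})

test_that("baselining removes shared offsets; scaling leaves m unchanged", {
    base <- fitLinearity(analyticWells())
    shifted <- fitLinearity(analyticWells(bg = 321.5))
    expect_equal(linearitySlope(shifted), linearitySlope(base),
        tolerance = 1e-12)
    scaled <- fitLinearity(analyticWells(fun = function(x) 5 * x * 7.7))
    expect_equal(linearitySlope(scaled), linearitySlope(base),
        tolerance = 1e-12)
})

test_that("wells driven negative by baselining are excluded with a reason", {
    # the control comes out brighter than the 1 nM well: that well must be
    # dropped from the fit and reported
    f <- fitLinearity(analyticWells(fun = function(x)
        ifelse(x == 0, 10, ifelse(x == 1, 8, 5 * x))))
    expect_identical(nrow(excludedWells(f)), 1L)
    expect_identical(excludedWells(f)$conc_nM, 1)
    expect_match(excludedWells(f)$reason, "non-positive")
    expect_identical(f@nIncluded, 7L)
    # fewer than 3 usable wells is an error listing the exclusions
    w <- analyticWells(fun = function(x) ifelse(x > 100, 5 * x, 0))
    expect_error(fitLinearity(w), "fewer than 3")
})

test_that("extraction uses half-diameter ROIs and validates the layout", {
    cfg <- SceneConfig(imageSize = c(300L, 300L), mmPerPx = 0.25,
        psfSigma = 1.2, wellPeak = 30000, background = 100)
    conc <- rcsDefaultConcentrations()
    r <- renderRCS(conc, cfg)
    tr <- sceneTruth(r)
    centers <- cbind(tr$x_true_px, tr$y_true_px)
    w <- extractRCSWells(sceneImage(r), centers, 10 / 0.25, conc)
    # ROI radius = diameter/4: pixel count matches a quarter-diameter disk
    expect_equal(w$n_px[1], sum(outer((-12:12)^2, (-12:12)^2, "+") <= 10^2),
        tolerance = 2)
    # noise-free means match truth
    expect_equal(w$roi_mean, tr$intensity_true, tolerance = 1e-3)
    # normalization: max normalized value is exactly 1 among usable wells
    expect_equal(max(w$normalized[w$conc_nM > 0 & !w$excluded]), 1)
    expect_error(extractRCSWells(sceneImage(r), centers[1:8, ],
        10 / 0.25, conc[1:8]), "9 wells")
    expect_error(extractRCSWells(sceneImage(r), centers, 10 / 0.25,
        replace(conc, 1, 5)), "control")
})

test_that("rendered means stay within noise standard errors of truth", {
    cfg <- SceneConfig(imageSize = c(300L, 300L), mmPerPx = 0.25,
        psfSigma = 1.2, wellPeak = 30000, background = 100,
        noise = "poisson_like", noiseStrength = 2, seed = 11L)
    conc <- rcsDefaultConcentrations()
    r <- renderRCS(conc, cfg)
    tr <- sceneTruth(r)
    w <- extractRCSWells(sceneImage(r), cbind(tr$x_true_px, tr$y_true_px),
        10 / 0.25, conc)
    se <- w$roi_sd / sqrt(w$n_px)
    expect_true(all(abs(w$roi_mean - tr$intensity_true) < 4 * se))
})

test_that("the full pipeline recovers the true exponent from renders", {
    cfg <- SceneConfig(imageSize = c(300L, 300L), mmPerPx = 0.25,
        psfSigma = 1.2, wellPeak = 30000, background = 100)
    conc <- rcsDefaultConcentrations()
    for (mTrue in c(1, 2)) {
        r <- renderRCS(conc, cfg, mTrue = mTrue)
        tr <- sceneTruth(r)
        f <- fitLinearity(extractRCSWells(sceneImage(r),
            cbind(tr$x_true_px, tr$y_true_px), 10 / 0.25, conc))
        expect_equal(linearitySlope(f), mTrue, tolerance = 1e-6)
    }
})

test_that("linearity before/after correction across placements", {
    illum <- IlluminationField("radial_gaussian", sigmaFrac = 0.35)
    calib <- detectAllRenders(lapply(list(c(-12, -12), c(12, -12),
        c(-12, 12), c(12, 12)), function(off)
        renderRUD(alignedConfig(extentMM = 40, imageSize = 400L,
            illumination = illum, offsetMM = off))))
    prof <- fitSurface(poolSamples(calib), "rbf")
    sceneFun <- function(off, rot) renderRCS(rcsDefaultConcentrations(),
        SceneConfig(imageSize = c(400L, 400L), mmPerPx = 0.25,
            psfSigma = 1.2, wellPeak = 30000, background = 50,
            illumination = illum, offsetMM = off, rotationDeg = rot),
        wellDiameterMM = 6, spacingMM = 8)
    placements <- data.frame(
        label = c("center", "edge_0", "edge_180"),
        offset_x_mm = c(0, -30, -30), offset_y_mm = 0,
        rotation_deg = c(0, 0, 180))
    res <- linearityExperiment(sceneFun, placements, prof,
        wellDiameterMM = 6)
    # near-unity, near-uniform gain at the center: pre and post agree
    expect_equal(res$m_pre[1], res$m_post[1], tolerance = 0.01)
    # edge placements: correction moves m, and the direction matches the
    # closed-form oracle built from scene truth (s*I + b vs (s*I + b)/I)
    for (k in 2:3) {
        tr <- sceneTruth(sceneFun(c(placements$offset_x_mm[k], 0),
            placements$rotation_deg[k]))
        oracle <- function(vals) {
            df <- data.frame(well = tr$well, conc_nM = tr$conc_nM,
                roi_mean = vals, roi_sd = 0, n_px = 1)
            df$baselined <- df$roi_mean - df$roi_mean[df$conc_nM == 0]
            df$excluded <- df$conc_nM > 0 & df$baselined <= 0
            df$reason <- ""
            ok <- df$conc_nM > 0 & !df$excluded
            df$normalized <- df$baselined / max(df$baselined[ok])
            linearitySlope(fitLinearity(df))
        }
        mPreOracle <- oracle(tr$signal_true + 50)
        mPostOracle <- oracle((tr$signal_true + 50) / tr$illum)
        expect_equal(res$m_pre[k], mPreOracle, tolerance = 0.02)
        expect_identical(sign(res$m_post[k] - res$m_pre[k]),
            sign(mPostOracle - mPreOracle))
        expect_gt(abs(res$m_post[k] - res$m_pre[k]), 0.02)
    }
    # the two orientations shift m in opposite directions
    expect_lt(sign(res$m_post[2] - res$m_pre[2]) *
              sign(res$m_post[3] - res$m_pre[3]), 0)
})

test_that("uniform illumination keeps m at 1 before and after correction", {
    calib <- detectAllRenders(list(renderRUD(alignedConfig(
        extentMM = 30, imageSize = 280L))))
    prof <- fitSurface(poolSamples(calib), "bspline")
    sceneFun <- function(off, rot) renderRCS(rcsDefaultConcentrations(),
        SceneConfig(imageSize = c(280L, 280L), mmPerPx = 0.25,
            psfSigma = 1.2, wellPeak = 30000, background = 0,
            offsetMM = off, rotationDeg = rot),
        wellDiameterMM = 6, spacingMM = 8)
    res <- linearityExperiment(sceneFun,
        data.frame(label = "center", offset_x_mm = 0, offset_y_mm = 0,
            rotation_deg = 0), prof, wellDiameterMM = 6)
    expect_equal(res$m_pre, 1, tolerance = 1e-4)
    expect_equal(res$m_post, 1, tolerance = 1e-3)
})
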