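# Pooling, surface fitting, normalization, iso-maps and line profiles.

radialIllum <- function(sigmaFrac = 0.5, center = c(0.5, 0.5))
    IlluminationField("radial_gaussian", sigmaFrac = sigmaFrac,
        center = center)

# one mid-size radial-Gaussian scene reused across several blocks
radialScene <- function() fixture("radialScene", function() {
    cfg <- alignedConfig(extentMM = 36, imageSize = 240L,
        illumination = radialIllum())
    r <- renderRUD(cfg)
    list(render = r, wells = detectWells(sceneImage(r), rudParams()))
})

test_that("pooling: single image, duplicate averaging, frame checks", {
    w <- radialScene()$wells
    s1 <- poolSamples(w)
    expect_identical(nrow(samples(s1)), nrow(w))
    # detections and samples share the (y, x) ordering
    expect_equal(samples(s1)$intensity, w$mean_intensity,
        tolerance = 1e-12)
    expect_equal(samples(s1)$x_px, w$x_px, tolerance = 1e-12)
    # two identical images collapse to the same samples as one (idempotence)
    s2 <- poolSamples(list(w, w))
    expect_identical(nrow(samples(s2)), nrow(samples(s1)))
    expect_equal(samples(s2)$intensity, samples(s1)$intensity,
        tolerance = 1e-12)
    expect_true(all(samples(s2)$n_obs == 2L))
    # mixed frames are refused
    wSmall <- detectWells(sceneImage(renderRUD(alignedConfig(
        extentMM = 8, imageSize = 80L))), rudParams())
    expect_error(poolSamples(list(w, wSmall)), "frame mismatch")
})

test_that("pooling offset acquisitions improves the fitted surface", {
    illum <- radialIllum(0.45)
    mk <- function(off) {
        r <- renderRUD(alignedConfig(extentMM = 20, imageSize = 240L,
            illumination = illum, offsetMM = off))
        detectWells(sceneImage(r), rudParams())
    }
    offs <- list(c(-9, -9), c(9, -9), c(-9, 9), c(9, 9))
    wl <- lapply(offs, mk)
    rmseVsTruth <- function(profile) {
        msk <- validMask(profile)
        gx <- profile@gridX; gy <- profile@gridY
        tru <- matrix(evalIllumination(illum, rep(gx, each = length(gy)),
            rep(gy, length(gx)), c(240, 240)), length(gy))
        tru <- tru / max(tru[msk])
        sqrt(mean((profileValues(profile)[msk] - tru[msk])^2))
    }
    single <- fitSurface(poolSamples(wl[[1]]), "bspline")
    pooled <- fitSurface(poolSamples(wl), "bspline")
    nPooled <- nrow(samples(poolSamples(wl)))
    # the four offsets share a central strip: overlapping wells merge
    expect_lte(nPooled, sum(vapply(wl, nrow, integer(1))))
    expect_gt(nPooled, max(vapply(wl, nrow, integer(1))))
    expect_lt(rmseVsTruth(pooled), rmseVsTruth(single))
})

test_that("constant samples normalize to a flat unit surface", {
    w <- detectWells(sceneImage(renderRUD(alignedConfig(
        extentMM = 20, imageSize = 160L, wellPeak = 0.8))),
        detectionParams(mmPerPx = 0.2, wellDiameterMM = 1,
            threshold = "fixed", thresholdValue = 0.1))
    pr <- fitSurface(poolSamples(w), "bspline")
    v <- profileValues(pr)[validMask(pr)]
    expect_equal(max(v), 1)                    # exact normalization
    expect_lt(max(abs(v - 1)), 1e-5)
})

test_that("noise-free smooth fields are recovered within 1% RMS", {
    sc <- radialScene()
    illum <- radialIllum()
    for (meth in c("bspline", "rbf")) {
        pr <- fitSurface(poolSamples(sc$wells), meth)
        msk <- validMask(pr)
        gx <- pr@gridX; gy <- pr@gridY
        tru <- matrix(evalIllumination(illum, rep(gx, each = length(gy)),
            rep(gy, length(gx)), c(240, 240)), length(gy))
        tru <- tru / max(tru[msk])
        rms <- sqrt(mean((profileValues(pr)[msk] - tru[msk])^2))
        expect_lt(rms, 0.01)
    }
})

test_that("gain invariance: scaling intensities leaves the profile unchanged", {
    w <- radialScene()$wells
    w2 <- w; w2$mean_intensity <- w2$mean_intensity * 5.3
    for (meth in c("bspline", "rbf")) {
        a <- fitSurface(poolSamples(w), meth)
        b <- fitSurface(poolSamples(w2), meth)
        expect_equal(profileValues(b), profileValues(a), tolerance = 1e-8)
        expect_equal(normConstant(b), 5.3 * normConstant(a),
            tolerance = 1e-8)
    }
})

test_that("the RBF fit retains a sharp dip that the b-spline smooths out", {
    xs <- seq(-1, 1, length.out = 50)
    d <- sqrt(outer(xs^2, xs^2, "+"))
    v <- 1 - 0.35 * (d > 0.75 & d < 0.9)   # annular dip at the pattern edge
    illum <- IlluminationField("tabulated", values = v)
    w <- detectWells(sceneImage(renderRUD(alignedConfig(
        extentMM = 36, imageSize = 220L, illumination = illum))),
        rudParams())
    s <- poolSamples(w)
    dip <- samples(s)[which.min(samples(s)$intensity), ]
    res <- vapply(c(bspline = "bspline", rbf = "rbf"), function(meth) {
        pr <- fitSurface(s, meth)
        abs(evalProfile(pr, dip$x_px, dip$y_px) * normConstant(pr) -
            dip$intensity)
    }, numeric(1))
    expect_lt(res["rbf"], res["bspline"])
    expect_lt(res["rbf"], 0.02 * dip$intensity)
})

test_that("iso-maps: flat field, nesting, analytic level-set area", {
    # flat profile: every fraction is 1
    wFlat <- detectWells(sceneImage(renderRUD(alignedConfig(
        extentMM = 20, imageSize = 160L))), rudParams())
    prFlat <- fitSurface(poolSamples(wFlat), "bspline")
    expect_equal(unname(isoMap(prFlat)$fractions), rep(1, 4))
    # unsorted / out-of-range thresholds are refused
    expect_error(isoMap(prFlat, c(0.95, 0.60)), "increasing")
    expect_error(isoMap(prFlat, c(0.5, 1.2)), "increasing|\\(0, 1\\)")
    # masks nest for an asymmetric smooth field
    prR <- fitSurface(poolSamples(radialScene()$wells), "bspline")
    iso <- isoMap(prR, c(0.6, 0.7, 0.8, 0.9, 0.95))
    for (k in seq_len(length(iso$masks) - 1))
        expect_true(all(iso$masks[[k]][iso$masks[[k + 1]]]))
    # analytic check: Gaussian level set is a disk; with the disk inside the
    # sampled square, fraction = pi r^2 / hull area
    illum <- radialIllum(0.28)
    # 0.1 mm/px so even wells at 10% illumination clear a fixed threshold
    w <- detectWells(sceneImage(renderRUD(alignedConfig(
        extentMM = 44, imageSize = 520L, mmPerPx = 0.1,
        illumination = illum))),
        detectionParams(mmPerPx = 0.1, wellDiameterMM = 1,
            threshold = "fixed", thresholdValue = 500))
    pr <- fitSurface(poolSamples(w), "bspline")
    frac <- isoMap(pr, c(0.60))$fractions[[1]]
    sigma <- 0.28 * 520
    r60 <- sigma * sqrt(2 * log(1 / 0.6))
    side <- 44 / 0.1                      # sampled square, px
    expect_lt(r60, side / 2)              # disk fits inside the hull
    analytic <- pi * r60^2 / side^2
    expect_lt(abs(frac - analytic) / analytic, 0.02)
})

test_that("line profiles: flat curves, symmetry, separable factors", {
    wFlat <- detectWells(sceneImage(renderRUD(alignedConfig(
        extentMM = 20, imageSize = 160L))), rudParams())
    prFlat <- fitSurface(poolSamples(wFlat), "bspline")
    lp <- lineProfiles(prFlat)
    expect_lt(max(abs(lp$value[!is.na(lp$value)] - 1)), 1e-5)
    # positions must be fractions; lines outside the valid region warn
    expect_error(lineProfiles(prFlat, positions = c(0, 0.5)), "fractions")
    expect_warning(lineProfiles(prFlat, positions = 0.01), "outside")
    # symmetric field: center vertical profile symmetric about the midpoint
    prR <- fitSurface(poolSamples(radialScene()$wells), "bspline")
    v <- lineProfiles(prR, "vertical", 0.5)
    ok <- !is.na(v$value)
    expect_lt(max(abs(v$value[ok] - rev(v$value[ok]))), 0.01)
    # separable field: horizontal curves proportional to the x factor
    illum <- IlluminationField("separable_polynomial",
        coefX = c(1, 0, -0.45), coefY = c(1, -0.1, -0.3))
    w <- detectWells(sceneImage(renderRUD(alignedConfig(
        extentMM = 36, imageSize = 240L, illumination = illum))),
        rudParams())
    pr <- fitSurface(poolSamples(w), "bspline")
    h <- lineProfiles(pr, "horizontal", c(0.35, 0.65))
    a <- h[h$position == 0.35, ]; b <- h[h$position == 0.65, ]
    ok <- !is.na(a$value) & !is.na(b$value)
    ratio <- a$value[ok] / b$value[ok]
    expect_lt(stats::sd(ratio) / mean(ratio), 0.01)
})

test_that("degenerate sample geometries are refused", {
    s <- new("UniformitySamples", samples = data.frame(
        x_px = seq(0, 60, length.out = 20), y_px = seq(0, 60,
            length.out = 20), intensity = rep(5, 20), n_obs = 1L),
        imageDim = c(100L, 100L))
    expect_error(fitSurface(s), "collinear")
    few <- new("UniformitySamples", samples = data.frame(
        x_px = runif(10, 0, 99), y_px = runif(10, 0, 99),
        intensity = rep(5, 10), n_obs = 1L), imageDim = c(100L, 100L))
    expect_error(fitSurface(few), "16 samples")
})
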