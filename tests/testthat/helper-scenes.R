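# Shared scene fixtures (built lazily, cached for the whole run) and an
# independent oracle for the geometric distortion map.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
    if (!exists(name, envir = .fixtures))
        assign(name, build(), envir = .fixtures)
    get(name, envir = .fixtures)
}

# Small aligned dot-grid scene: pitch 10 px, wells 5 px across, on-lattice
# (integer pitch, zero rotation/offset) so centroid quantization is
# common-mode.
alignedConfig <- function(extentMM = 30, imageSize = 220L, mmPerPx = 0.2,
        ...) {
    SceneConfig(grid = GridSpec(extentMM = extentMM),
        imageSize = c(imageSize, imageSize), mmPerPx = mmPerPx,
        psfSigma = 1.2, ...)
}

rudParams <- function(mmPerPx = 0.2)
    detectionParams(mmPerPx = mmPerPx, wellDiameterMM = 1)

# Full-size default grid (2601 wells), shared by scene and acceptance tests.
defaultRUD <- function() fixture("defaultRUD", function()
    renderRUD(SceneConfig(grid = GridSpec(), imageSize = c(540L, 540L),
        mmPerPx = 0.2, psfSigma = 1)))

# Independent implementation of the forward distortion map (keystone about a
# horizontal axis through the image center with focal length = image
# diagonal, then the two-term Brown radial model normalized by half the
# diagonal). Kept free of any package internals on purpose.
oracleDistort <- function(xy, dim, k1 = 0, k2 = 0, tiltDeg = 0) {
    W <- dim[2]; H <- dim[1]
    cx <- (W - 1) / 2; cy <- (H - 1) / 2
    f <- sqrt((W - 1)^2 + (H - 1)^2)
    th <- tiltDeg * pi / 180
    dx <- xy[, 1] - cx; dy <- xy[, 2] - cy
    den <- 1 - dy * sin(th) / f
    dx <- dx / den; dy <- dy * cos(th) / den
    rn2 <- (dx^2 + dy^2) / (f / 2)^2
    s <- 1 + k1 * rn2 + k2 * rn2^2
    cbind(cx + dx * s, cy + dy * s)
}

# Match each detection to its nearest truth record; returns truth row index.
matchToTruth <- function(wells, truth) {
    vapply(seq_len(nrow(wells)), function(i)
        which.min((truth$x_true_px - wells$x_px[i])^2 +
                  (truth$y_true_px - wells$y_px[i])^2), integer(1))
}

# The 16-image flat-field study: 4 target positions x 4 rotations of 90 deg
# under a fixed off-center Gaussian illumination with shot-like noise.
flatfieldStudy <- function(seed = 1L) {
    illum <- IlluminationField("radial_gaussian", sigmaFrac = 0.45,
        center = c(0.45, 0.55))
    offs <- list(c(-9, -9), c(9, -9), c(-9, 9), c(9, 9))
    rots <- c(0, 90, 180, 270)
    k <- 0
    renders <- list()
    for (off in offs) for (rot in rots) {
        k <- k + 1
        renders[[k]] <- renderRUD(SceneConfig(
            grid = GridSpec(extentMM = 24), imageSize = c(220L, 220L),
            mmPerPx = 0.2, psfSigma = 1.2, illumination = illum,
            wellPeak = 30000, background = 50, noise = "poisson_like",
            noiseStrength = 1, seed = seed * 1000L + k,
            offsetMM = off, rotationDeg = rot))
    }
    renders
}

detectAllRenders <- function(renders, params = rudParams()) {
    lapply(seq_along(renders), function(i)
        detectWells(sceneImage(renders[[i]]), params,
            imageId = paste0("img", i)))
}
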