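# Synthetic phantom-scene rendering: the ground-truth generator behind every
# analysis stage. Disks are anti-aliased by supersampling their edge pixels;
# illumination multiplies well signal only; the background offset is additive
# and spatially constant; PSF blur and noise are applied image-wide.

# Add anti-aliased disks to an image. centers: n x 2 (x, y); radius and
# amplitude recycled per disk. Supersampling is applied to the one-pixel-wide
# annulus straddling the disk edge; strictly interior/exterior pixels are 1/0.
.renderDisks <- function(image, centers, radius, amplitude, ss = 4L) {
    H <- nrow(image); W <- ncol(image)
    n <- nrow(centers)
    radius <- rep_len(radius, n)
    amplitude <- rep_len(amplitude, n)
    offs <- ((seq_len(ss) - 0.5) / ss) - 0.5
    for (i in seq_len(n)) {
        cx <- centers[i, 1]; cy <- centers[i, 2]; r <- radius[i]
        xs <- max(0, floor(cx - r - 1)):min(W - 1, ceiling(cx + r + 1))
        ys <- max(0, floor(cy - r - 1)):min(H - 1, ceiling(cy + r + 1))
        if (!length(xs) || !length(ys)) next
        px <- rep(xs, times = length(ys))
        py <- rep(ys, each = length(xs))
        d <- sqrt((px - cx)^2 + (py - cy)^2)
        cov <- as.numeric(d <= r - 0.75)
        edge <- which(d > r - 0.75 & d < r + 0.75)
        if (length(edge)) {
            acc <- numeric(length(edge))
            dxe <- px[edge] - cx; dye <- py[edge] - cy
            for (oy in offs) for (ox in offs)
                acc <- acc + ((dxe + ox)^2 + (dye + oy)^2 <= r^2)
            cov[edge] <- acc / (ss * ss)
        }
        keep <- cov > 0
        idx <- cbind(py[keep] + 1, px[keep] + 1)
        image[idx] <- image[idx] + amplitude[i] * cov[keep]
    }
    image
}

# PSF blur + background + noise + clamping, shared by all renderers.
.finishScene <- function(image, config, signalForNoise = NULL) {
    if (config@psfSigma > 0)
        image <- EBImage::gblur(image, sigma = config@psfSigma)
    image <- image + config@background
    set.seed(config@seed)
    if (config@noise != "none" && config@noiseStrength > 0) {
        sd <- switch(config@noise,
            gaussian = config@noiseStrength,
            poisson_like = config@noiseStrength * sqrt(pmax(image, 0)))
        image <- image + stats::rnorm(length(image), sd = sd)
    }
    maxCount <- 2^config@bitDepth - 1
    pmin(pmax(image, 0), maxCount)
}

# Map target-frame mm positions (n x 2, relative to the target center) to
# ideal pixel positions given placement, then distort.
.placeOnFrame <- function(posMM, config) {
    ctr <- imageCenter(config@imageSize)
    posMM <- rotateXY(posMM, config@rotationDeg)
    posMM <- sweep(posMM, 2, config@offsetMM, "+")
    cbind(ctr[1] + posMM[, 1] / config@mmPerPx,
          ctr[2] + posMM[, 2] / config@mmPerPx)
}

#' Render a dot-grid (RUD) phantom scene
#'
#' Renders the square lattice of fluorescent wells described by
#' \code{config@grid} under the scene's illumination, distortion, PSF, and
#' noise models, and returns the image together with per-well ground truth.
#' Wells whose footprint (disk plus anti-aliasing and blur support) is not
#' fully inside the frame are neither rendered nor listed in the truth.
#'
#' @param config a [SceneConfig-class].
#' @return a [PhantomRender-class]; truth columns: well_row, well_col,
#'   x_true_px, y_true_px (distorted), x_undist_px, y_undist_px, illum,
#'   intensity_true (= wellPeak * illum + background).
#' @examples
#' cfg <- SceneConfig(grid = GridSpec(extentMM = 20), imageSize = c(160, 160),
#'     mmPerPx = 0.2, psfSigma = 1)
#' rud <- renderRUD(cfg)
#' nrow(sceneTruth(rud))
#' @export
renderRUD <- function(config) {
    validObject(config)
    g <- config@grid
    H <- config@imageSize[1]; W <- config@imageSize[2]
    rPx <- g@wellDiameterMM / 2 / config@mmPerPx
    pitchPx <- g@pitchMM / config@mmPerPx
    if (2 * rPx < 2)
        stop("invalid config: well footprint is under 2 pixels across; ",
             "decrease mmPerPx")
    if (pitchPx <= 2 * rPx)
        stop("invalid config: wells overlap in pixels (pitch <= diameter)")
    n <- wellsPerAxis(g)
    idx <- seq_len(n) - (n + 1) / 2
    wellIJ <- expand.grid(well_col = seq_len(n), well_row = seq_len(n))
    posMM <- cbind((wellIJ$well_col - (n + 1) / 2) * g@pitchMM,
                   (wellIJ$well_row - (n + 1) / 2) * g@pitchMM)
    undist <- .placeOnFrame(posMM, config)
    dist <- distortPoints(config@distortion, undist, config@imageSize)
    margin <- rPx + 1 + 3 * config@psfSigma
    keep <- dist[, 1] >= margin & dist[, 1] <= W - 1 - margin &
            dist[, 2] >= margin & dist[, 2] <= H - 1 - margin
    if (!any(keep))
        stop("degenerate scene: image too small to contain any well")
    undist <- undist[keep, , drop = FALSE]
    dist <- dist[keep, , drop = FALSE]
    wellIJ <- wellIJ[keep, , drop = FALSE]
    illum <- evalIllumination(config@illumination, dist[, 1], dist[, 2],
        config@imageSize)
    image <- matrix(0, H, W)
    image <- .renderDisks(image, dist, rPx, config@wellPeak * illum,
        config@supersample)
    image <- .finishScene(image, config)
    truth <- data.frame(well_row = wellIJ$well_row,
        well_col = wellIJ$well_col,
        x_true_px = dist[, 1], y_true_px = dist[, 2],
        x_undist_px = undist[, 1], y_undist_px = undist[, 2],
        illum = illum,
        intensity_true = config@wellPeak * illum + config@background)
    truth <- truth[order(truth$y_true_px, truth$x_true_px), ]
    rownames(truth) <- NULL
    new("PhantomRender", image = image, truth = truth, config = config)
}

#' Render a nine-well dilution-series (RCS) target scene
#'
#' Renders a 3 x 3 arrangement of large wells whose noise-free signal follows
#' a power law of the fluorophore concentration,
#' signal = wellPeak * (c / max(c))^mTrue, modulated by the illumination at
#' each (distorted) well center, on top of the constant background offset.
#' Exactly one concentration must be 0 (the control well). Wells are placed
#' row-major: the first concentration lands top-left.
#'
#' @param concentrations nine concentrations in nM, exactly one equal to 0.
#' @param config a [SceneConfig-class] (placement, illumination, noise ...).
#' @param mTrue true response exponent (1 = perfectly linear response).
#' @param wellDiameterMM,spacingMM well diameter and center-to-center
#'   spacing of the 3 x 3 layout, in mm.
#' @return a [PhantomRender-class]; truth columns: well, well_row, well_col,
#'   conc_nM, x_true_px, y_true_px, x_undist_px, y_undist_px, illum,
#'   signal_true, intensity_true.
#' @examples
#' cfg <- SceneConfig(imageSize = c(256, 256), mmPerPx = 0.25)
#' rcs <- renderRCS(c(0, 1, 3, 10, 30, 60, 100, 300, 1000), cfg)
#' sceneTruth(rcs)$intensity_true
#' @export
renderRCS <- function(concentrations, config, mTrue = 1,
        wellDiameterMM = 10, spacingMM = 15) {
    validObject(config)
    if (length(concentrations) != 9)
        stop("invalid config: exactly 9 concentrations required")
    if (sum(concentrations == 0) != 1)
        stop("invalid config: exactly one control (0 nM) well required")
    if (any(concentrations < 0))
        stop("invalid config: concentrations must be >= 0")
    if (spacingMM <= wellDiameterMM)
        stop("invalid config: wells overlap (spacing <= diameter)")
    H <- config@imageSize[1]; W <- config@imageSize[2]
    rPx <- wellDiameterMM / 2 / config@mmPerPx
    ij <- expand.grid(well_col = 1:3, well_row = 1:3)
    posMM <- cbind((ij$well_col - 2) * spacingMM,
                   (ij$well_row - 2) * spacingMM)
    undist <- .placeOnFrame(posMM, config)
    dist <- distortPoints(config@distortion, undist, config@imageSize)
    margin <- rPx + 1 + 3 * config@psfSigma
    if (any(dist[, 1] < margin | dist[, 1] > W - 1 - margin |
            dist[, 2] < margin | dist[, 2] > H - 1 - margin))
        stop("invalid config: RCS wells fall outside the frame")
    illum <- evalIllumination(config@illumination, dist[, 1], dist[, 2],
        config@imageSize)
    signal <- config@wellPeak * (concentrations / max(concentrations))^mTrue
    image <- matrix(0, H, W)
    image <- .renderDisks(image, dist, rPx, signal * illum,
        config@supersample)
    image <- .finishScene(image, config)
    truth <- data.frame(well = seq_len(9), well_row = ij$well_row,
        well_col = ij$well_col, conc_nM = concentrations,
        x_true_px = dist[, 1], y_true_px = dist[, 2],
        x_undist_px = undist[, 1], y_undist_px = undist[, 2],
        illum = illum, signal_true = signal * illum,
        intensity_true = signal * illum + config@background)
    new("PhantomRender", image = image, truth = truth, config = config)
}

#' Render a pair of fluorescent cylinders
#'
#' Renders two large disks (default 10 mm diameter) side by side at a given
#' field-of-view position, with noise-free intensity
#' background + concentration * countsPerNM * illumination. Used to probe
#' flat-field behaviour of signal vs. additive background at different
#' illumination levels.
#'
#' @param concentrationPair two concentrations in nM, e.g. c(100, 0).
#' @param config a [SceneConfig-class]; \code{config@offsetMM} and
#'   \code{config@rotationDeg} place the pair in the field of view.
#' @param diameterMM cylinder diameter in mm.
#' @param separationMM center-to-center separation, must exceed diameterMM.
#' @param countsPerNM signal per nM at illumination 1; default scales so
#'   100 nM reaches \code{config@wellPeak}.
#' @return a [PhantomRender-class]; truth columns: cylinder, conc_nM,
#'   x_true_px, y_true_px, illum, signal_true, intensity_true.
#' @examples
#' cfg <- SceneConfig(imageSize = c(200, 200), mmPerPx = 0.25)
#' cyl <- renderCylinders(c(100, 0), cfg)
#' sceneTruth(cyl)
#' @export
renderCylinders <- function(concentrationPair, config, diameterMM = 10,
        separationMM = 12, countsPerNM = config@wellPeak / 100) {
    validObject(config)
    if (length(concentrationPair) != 2 || any(concentrationPair < 0))
        stop("invalid config: concentrationPair must be two non-negative nM values")
    if (separationMM <= diameterMM)
        stop("invalid config: cylinders overlap (separation <= diameter)")
    H <- config@imageSize[1]; W <- config@imageSize[2]
    rPx <- diameterMM / 2 / config@mmPerPx
    posMM <- cbind(c(-separationMM / 2, separationMM / 2), c(0, 0))
    centers <- .placeOnFrame(posMM, config)
    centers <- distortPoints(config@distortion, centers, config@imageSize)
    margin <- rPx + 1 + 3 * config@psfSigma
    if (any(centers[, 1] < margin | centers[, 1] > W - 1 - margin |
            centers[, 2] < margin | centers[, 2] > H - 1 - margin))
        stop("invalid config: cylinder disks fall outside the frame")
    illum <- evalIllumination(config@illumination, centers[, 1],
        centers[, 2], config@imageSize)
    signal <- concentrationPair * countsPerNM
    image <- matrix(0, H, W)
    image <- .renderDisks(image, centers, rPx, signal * illum,
        config@supersample)
    image <- .finishScene(image, config)
    truth <- data.frame(cylinder = 1:2, conc_nM = concentrationPair,
        x_true_px = centers[, 1], y_true_px = centers[, 2], illum = illum,
        signal_true = signal * illum,
        intensity_true = signal * illum + config@background)
    new("PhantomRender", image = image, truth = truth, config = config)
}
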