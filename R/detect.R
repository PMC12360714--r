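# Well detection: thresholding + connected components, the shared front end
# of the uniformity and distortion analyses.

#' Detection parameters
#'
#' @param threshold thresholding method: "otsu" (default; parameter-free and
#'   robust to overall gain), "fixed" (absolute counts in
#'   \code{thresholdValue}), or "quantile" (\code{thresholdValue} is the
#'   probability, default 0.95).
#' @param thresholdValue value for the "fixed"/"quantile" methods.
#' @param minArea,maxArea connected-component area filter in pixels. When
#'   \code{minArea} is NULL it defaults to 25% of the nominal well footprint
#'   (if \code{mmPerPx} and \code{wellDiameterMM} are given) or 5 px.
#' @param borderMargin components whose bounding box comes within this many
#'   pixels of the image border are discarded (their centroids are biased).
#' @param centroid "weighted" (default): centroid weighted by intensity above
#'   threshold, more accurate under illumination gradients; or "geometric".
#' @param mmPerPx,wellDiameterMM optional scene scale used for the default
#'   \code{minArea}.
#' @param satLevel counts at/above which a pixel is considered saturated;
#'   default \code{2^bitDepth - 1} when the image records its bit depth.
#' @return a list of class \code{DetectionParams}.
#' @export
detectionParams <- function(threshold = c("otsu", "fixed", "quantile"),
        thresholdValue = NULL, minArea = NULL, maxArea = Inf,
        borderMargin = 2, centroid = c("weighted", "geometric"),
        mmPerPx = NA_real_, wellDiameterMM = NA_real_, satLevel = NULL) {
    threshold <- match.arg(threshold)
    centroid <- match.arg(centroid)
    if (threshold == "fixed" && is.null(thresholdValue))
        stop("fixed threshold requires thresholdValue")
    if (!is.null(minArea) && !is.infinite(maxArea) && minArea >= maxArea)
        stop("minArea must be < maxArea")
    if (borderMargin < 0) stop("borderMargin must be >= 0")
    structure(list(threshold = threshold, thresholdValue = thresholdValue,
        minArea = minArea, maxArea = maxArea, borderMargin = borderMargin,
        centroid = centroid, mmPerPx = mmPerPx,
        wellDiameterMM = wellDiameterMM, satLevel = satLevel),
        class = "DetectionParams")
}

.threshold <- function(image, params) {
    switch(params$threshold,
        otsu = {
            rng <- range(image)
            if (diff(rng) == 0) return(rng[2] + 1)  # blank image: nothing above
            as.numeric(EBImage::otsu(image, range = rng, levels = 256L))
        },
        fixed = params$thresholdValue,
        quantile = stats::quantile(image, params$thresholdValue %||% 0.95,
            names = FALSE))
}

#' Detect fluorescent wells in a phantom image
#'
#' Thresholds the image, labels connected components, and returns one record
#' per component that survives the area and border filters, sorted by (y, x).
#' An empty result is a warning, not an error. Components containing any
#' saturated pixel are flagged.
#'
#' When the scene scale is known (\code{mmPerPx} and \code{wellDiameterMM}
#' in \code{params}), \code{mean_intensity} is measured over a fixed disk of
#' half the well diameter centered on the component centroid — the
#' half-diameter ROI rule. A fixed ROI keeps the mean proportional to the
#' well's true brightness; the extent of the thresholded component itself
#' shrinks for dim wells, which would otherwise bias their component mean
#' upward relative to bright wells. Without a scale the component mean is
#' reported (also kept in \code{mean_component} in both cases).
#'
#' @param image numeric matrix of counts (see [loadImage()]).
#' @param params a [detectionParams()] list.
#' @param imageId identifier stored with each record.
#' @return data.frame with columns image_id, x_px, y_px (sub-pixel centroid,
#'   0-based), mean_intensity (mean counts over component pixels), area_px,
#'   saturated, xmin, ymin, xmax, ymax; attributes \code{imageDim} and
#'   \code{threshold}.
#' @examples
#' cfg <- SceneConfig(grid = GridSpec(extentMM = 8), imageSize = c(80, 80),
#'     mmPerPx = 0.2)
#' wells <- detectWells(sceneImage(renderRUD(cfg)))
#' nrow(wells)
#' @export
detectWells <- function(image, params = detectionParams(), imageId = "") {
    stopifnot(is.matrix(image))
    if (any(!is.finite(image))) stop("image contains non-finite values")
    H <- nrow(image); W <- ncol(image)
    th <- .threshold(image, params)
    mask <- image > th
    empty <- data.frame(image_id = character(0), x_px = numeric(0),
        y_px = numeric(0), mean_intensity = numeric(0),
        area_px = integer(0), saturated = logical(0), xmin = integer(0),
        ymin = integer(0), xmax = integer(0), ymax = integer(0))
    attr(empty, "imageDim") <- c(H, W)
    attr(empty, "threshold") <- th
    if (!any(mask)) {
        warning("no wells detected")
        return(empty)
    }
    lab <- EBImage::bwlabel(mask)
    idx <- which(lab > 0)
    labs <- lab[idx]
    ypix <- (idx - 1) %% H          # 0-based row
    xpix <- (idx - 1) %/% H         # 0-based col
    inten <- image[idx]
    minArea <- params$minArea
    if (is.null(minArea)) {
        minArea <- if (!is.na(params$mmPerPx) && !is.na(params$wellDiameterMM))
            0.25 * pi * (params$wellDiameterMM / 2 / params$mmPerPx)^2
        else 5
    }
    satLevel <- params$satLevel
    if (is.null(satLevel)) {
        bd <- attr(image, "bitDepth")
        satLevel <- if (is.null(bd)) Inf else 2^bd - 1
    }
    w <- pmax(inten - th, 0)
    bylab <- function(v) as.numeric(rowsum(v, labs))
    area <- bylab(rep(1, length(labs)))
    sumw <- bylab(w)
    cx <- if (params$centroid == "weighted") bylab(w * xpix) / sumw
          else bylab(xpix) / area
    cy <- if (params$centroid == "weighted") bylab(w * ypix) / sumw
          else bylab(ypix) / area
    meanComp <- bylab(inten) / area
    roiRadius <- if (!is.na(params$mmPerPx) && !is.na(params$wellDiameterMM))
        params$wellDiameterMM / 4 / params$mmPerPx else NA_real_
    meanI <- if (is.na(roiRadius)) meanComp else
        vapply(seq_along(cx), function(i)
            .diskMeanClipped(image, c(cx[i], cy[i]), roiRadius), numeric(1))
    sat <- bylab(as.numeric(inten >= satLevel)) > 0
    xmin <- tapply(xpix, labs, min); xmax <- tapply(xpix, labs, max)
    ymin <- tapply(ypix, labs, min); ymax <- tapply(ypix, labs, max)
    df <- data.frame(image_id = imageId, x_px = cx, y_px = cy,
        mean_intensity = meanI, mean_component = meanComp,
        area_px = as.integer(area), saturated = sat,
        xmin = as.integer(xmin), ymin = as.integer(ymin),
        xmax = as.integer(xmax), ymax = as.integer(ymax))
    m <- params$borderMargin
    keep <- df$area_px >= minArea & df$area_px <= params$maxArea &
        df$xmin >= m & df$ymin >= m & df$xmax <= W - 1 - m &
        df$ymax <= H - 1 - m
    df <- df[keep, , drop = FALSE]
    if (!nrow(df)) {
        warning("no wells detected")
        return(empty)
    }
    # sort keys rounded to 0.01 px: wells in one lattice row differ only by
    # float noise in y, and an exact sort would reorder them between runs
    df <- df[order(round(df$y_px, 2), round(df$x_px, 2)), ]
    rownames(df) <- NULL
    attr(df, "imageDim") <- c(H, W)
    attr(df, "threshold") <- th
    df
}

# Disk mean clipped to the frame (used for per-well fixed ROIs, where a
# border-adjacent centroid must not abort the whole detection pass).
.diskMeanClipped <- function(image, center, radius) {
    H <- nrow(image); W <- ncol(image)
    xs <- max(0, floor(center[1] - radius)):min(W - 1, ceiling(center[1] + radius))
    ys <- max(0, floor(center[2] - radius)):min(H - 1, ceiling(center[2] + radius))
    px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
    keep <- (px - center[1])^2 + (py - center[2])^2 <= radius^2
    if (!any(keep)) {
        px <- round(center[1]); py <- round(center[2]); keep <- TRUE
    }
    mean(image[cbind(py[keep] + 1, px[keep] + 1)])
}

#' Mean and spread of a circular region of interest
#'
#' @param image numeric matrix of counts.
#' @param center (x, y) pixel coordinates of the disk center.
#' @param radius disk radius in pixels; pixels whose center lies within
#'   \code{radius} of \code{center} are included, so a radius of 0.5 px
#'   still covers the center pixel.
#' @return list(mean, sd, n); sd is 0 for a single-pixel ROI.
#' @examples
#' img <- matrix(7, 32, 32)
#' measureDiskROI(img, c(15, 15), 5)
#' @export
measureDiskROI <- function(image, center, radius) {
    H <- nrow(image); W <- ncol(image)
    if (center[1] - radius < -0.5 || center[1] + radius > W - 0.5 ||
        center[2] - radius < -0.5 || center[2] + radius > H - 0.5)
        stop("disk ROI clipped by the image frame")
    xs <- max(0, floor(center[1] - radius)):min(W - 1, ceiling(center[1] + radius))
    ys <- max(0, floor(center[2] - radius)):min(H - 1, ceiling(center[2] + radius))
    px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
    keep <- (px - center[1])^2 + (py - center[2])^2 <= radius^2
    if (!any(keep)) {  # tiny radius: fall back to the nearest pixel
        px <- round(center[1]); py <- round(center[2]); keep <- TRUE
    }
    v <- image[cbind(py[keep] + 1, px[keep] + 1)]
    list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
        n = length(v))
}

#' Write a detected-wells table as CSV
#'
#' Columns: image_id, x_px, y_px, mean_intensity, area_px, saturated.
#'
#' @param wells output of [detectWells()] (rows from several images may be
#'   bound together).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeWellsCSV <- function(wells, path) {
    writeTableCSV(wells[c("image_id", "x_px", "y_px", "mean_intensity",
        "area_px", "saturated")], path)
}
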