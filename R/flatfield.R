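# Flat-field correction by the inverse of the fitted uniformity profile,
# and evaluation of its consequences.

#' Build a per-pixel flat-field correction map
#'
#' Evaluates the normalized uniformity profile at every pixel of the camera
#' frame and takes its reciprocal. Profile values below \code{floor} are
#' clamped before inversion, bounding the gain at 1/floor (the profile can
#' approach 0 at the unilluminated frame edge, where an unbounded gain would
#' amplify noise without limit); the number of clamped pixels is recorded so
#' downstream artifact analyses stay honest.
#'
#' The profile's valid region is the convex hull of well centroids, but image
#' features extend about a well radius beyond the outermost centroid, so the
#' profile is extrapolated over a narrow band of width \code{marginPx} around
#' the region (avoiding a spurious gain seam through the outermost wells);
#' pixels beyond the margin get gain NA and are passed through unchanged on
#' application.
#'
#' @param profile a [UniformityProfile-class].
#' @param floor minimum profile value (> 0) used in the reciprocal.
#' @param imageDim dimensions of the frame to correct; defaults to the
#'   profile's frame.
#' @param marginPx width (pixels) of the extrapolation band around the valid
#'   region.
#' @return a [CorrectionMap-class].
#' @examples
#' cfg <- SceneConfig(grid = GridSpec(extentMM = 20), imageSize = c(160, 160),
#'     mmPerPx = 0.2, illumination = IlluminationField("radial_gaussian"))
#' s <- poolSamples(detectWells(sceneImage(renderRUD(cfg))))
#' cm <- buildCorrection(fitSurface(s, "bspline"))
#' range(cm@gain, na.rm = TRUE)
#' @export
buildCorrection <- function(profile, floor = 0.05, imageDim = NULL,
        marginPx = 5) {
    stopifnot(is(profile, "UniformityProfile"))
    if (floor <= 0) stop("floor must be > 0")
    dim <- as.integer(imageDim %||% profile@imageDim)
    H <- dim[1]; W <- dim[2]
    gx <- rep(0:(W - 1), each = H)
    gy <- rep(0:(H - 1), times = W)
    v <- evalProfile(profile, gx, gy)         # NA outside valid region
    if (marginPx > 0) {
        # extrapolate over the margin band: points inside the hull grown by
        # marginPx about its centroid-weighted center
        hull <- profile@hull
        hc <- colMeans(hull)
        grow <- sweep(sweep(hull, 2, hc), 1,
            1 + marginPx / sqrt(rowSums(sweep(hull, 2, hc)^2)), "*")
        grow <- sweep(grow, 2, hc, "+")
        band <- is.na(v) & pointsInHull(grow, gx, gy)
        if (any(band))
            v[band] <- evalProfile(profile, gx[band], gy[band],
                extrapolate = TRUE)
    }
    inside <- !is.na(v)
    if (!any(inside)) stop("valid region is empty on this frame")
    clamped <- sum(v[inside] < floor)
    gain <- 1 / pmax(v, floor)
    new("CorrectionMap", gain = matrix(gain, H, W), floor = floor,
        clamped = as.integer(clamped), outside = as.integer(sum(!inside)),
        provenance = profile@method)
}

#' Apply a flat-field correction to an image
#'
#' Pixelwise product of the image with the correction gain. Pixels outside
#' the map's valid region are passed through unchanged; their count, and the
#' count of gain-clamped pixels, are attached as attributes
#' \code{outsideValidRegion} and \code{clampedPixels}. Counts stay floating
#' point; re-quantization happens only on export ([writeSceneImage()]).
#'
#' @param image numeric matrix sharing the map's frame.
#' @param map a [CorrectionMap-class].
#' @return corrected numeric matrix.
#' @export
applyCorrection <- function(image, map) {
    stopifnot(is(map, "CorrectionMap"))
    if (!all(dim(image) == dim(map@gain)))
        stop("frame mismatch: image and correction map differ in size")
    g <- map@gain
    g[is.na(g)] <- 1
    out <- image * g
    attr(out, "outsideValidRegion") <- map@outside
    attr(out, "clampedPixels") <- map@clamped
    out
}

#' Flatness of a corrected scene's refit uniformity surface
#'
#' Refits corrected well samples with the b-spline method (the smooth fitter,
#' so high-frequency residuals do not dominate) and reports how flat the
#' resulting normalized surface is: its minimum over the valid region (the
#' maximum is 1 by construction), and quantiles of the surface values. A
#' perfectly corrected scene gives min = max = 1.
#'
#' @param samples a [UniformitySamples-class] of corrected detections.
#' @param probs quantiles of the normalized surface to report.
#' @param ... passed to [fitSurface()].
#' @return list(min, max, flatness = min/max, quantiles, profile).
#' @export
evaluateFlatness <- function(samples, probs = c(0.01, 0.05, 0.5, 0.95, 0.99),
        ...) {
    profile <- fitSurface(samples, method = "bspline", ...)
    v <- profile@values[profile@mask]
    list(min = min(v), max = max(v), flatness = min(v) / max(v),
        quantiles = stats::quantile(v, probs), profile = profile)
}

#' Write a correction map as a CSV grid
#'
#' @param map a [CorrectionMap-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeCorrectionCSV <- function(map, path) {
    utils::write.table(signif(map@gain, 6), path, sep = ",",
        row.names = FALSE, col.names = FALSE, na = "")
    invisible(path)
}
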