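# Fluorescence-uniformity surface: pooling ("stitching"), fitting,
# normalization, iso-maps and line profiles.

#' Pool well detections from one or more images into uniformity samples
#'
#' Concatenates (x, y, intensity) records from images acquired in the same
#' camera frame — the phantom moves between acquisitions, the camera does
#' not, so no registration is performed. Near-duplicate samples (within the
#' same integer pixel) are averaged.
#'
#' @param wells a detected-wells data.frame (from [detectWells()]) or a list
#'   of them. All must share image dimensions.
#' @param imageDim c(height, width); defaults to the \code{imageDim}
#'   attribute of the detections.
#' @return a [UniformitySamples-class].
#' @examples
#' cfg <- SceneConfig(grid = GridSpec(extentMM = 8), imageSize = c(80, 80),
#'     mmPerPx = 0.2)
#' w <- detectWells(sceneImage(renderRUD(cfg)))
#' poolSamples(list(w, w))   # duplicate averaging: same samples as one image
#' @export
poolSamples <- function(wells, imageDim = NULL) {
    if (is.data.frame(wells)) wells <- list(wells)
    dims <- lapply(wells, attr, "imageDim")
    dims <- dims[!vapply(dims, is.null, logical(1))]
    if (is.null(imageDim)) {
        if (!length(dims)) stop("imageDim required (detections carry none)")
        imageDim <- dims[[1]]
    }
    for (d in dims)
        if (!all(d == imageDim))
            stop("frame mismatch: images have different dimensions")
    df <- do.call(rbind, lapply(wells, function(w)
        data.frame(x_px = w$x_px, y_px = w$y_px,
            intensity = w$mean_intensity)))
    bad <- df$intensity <= 0
    if (any(bad)) {
        warning(sum(bad), " non-positive sample intensities dropped")
        df <- df[!bad, , drop = FALSE]
    }
    cl <- .clusterWithin(df$x_px, df$y_px, radius = 1)
    agg <- function(v) as.numeric(tapply(v, cl, mean))
    out <- data.frame(x_px = agg(df$x_px), y_px = agg(df$y_px),
        intensity = agg(df$intensity),
        n_obs = as.integer(tapply(df$x_px, cl, length)))
    out <- out[order(round(out$y_px, 2), round(out$x_px, 2)), ]
    rownames(out) <- NULL
    new("UniformitySamples", samples = out, imageDim = as.integer(imageDim))
}

# Greedy single-linkage clustering of sample positions within `radius` px,
# via a unit-cell spatial hash. Deterministic: samples are processed in
# (y, x) order and join the nearest existing cluster center in range.
# Repeated acquisitions of the same well land in one cluster even when the
# well sits exactly on a half-integer pixel (where integer binning would
# split them).
.clusterWithin <- function(x, y, radius = 1) {
    ord <- order(y, x)
    cl <- integer(length(x))
    cellOf <- function(cx, cy) paste(floor(cx / radius), floor(cy / radius))
    centers <- list()   # per-cluster running centroid: c(x, y, n)
    hash <- new.env(parent = emptyenv())
    for (i in ord) {
        fx <- floor(x[i] / radius); fy <- floor(y[i] / radius)
        best <- 0L; bestD <- Inf
        for (dx in -1:1) for (dy in -1:1) {
            key <- paste(fx + dx, fy + dy)
            for (j in get0(key, envir = hash, ifnotfound = integer(0))) {
                c0 <- centers[[j]]
                d <- sqrt((x[i] - c0[1])^2 + (y[i] - c0[2])^2)
                if (d <= radius && d < bestD) { best <- j; bestD <- d }
            }
        }
        if (best == 0L) {
            centers[[length(centers) + 1L]] <- c(x[i], y[i], 1)
            best <- length(centers)
            key <- cellOf(x[i], y[i])
            assign(key, c(get0(key, envir = hash,
                ifnotfound = integer(0)), best), envir = hash)
        } else {
            c0 <- centers[[best]]
            centers[[best]] <- c((c0[1] * c0[3] + x[i]) / (c0[3] + 1),
                (c0[2] * c0[3] + y[i]) / (c0[3] + 1), c0[3] + 1)
        }
        cl[i] <- best
    }
    cl
}

#' Fit a normalized fluorescence-uniformity surface
#'
#' Fits a smooth surface to pooled well samples and normalizes it by its
#' fitted maximum over the valid region (the convex hull of the samples), so
#' the reported profile peaks at exactly 1. Two fitters are available:
#' \describe{
#'   \item{bspline}{tensor-product cubic regression spline
#'     (\code{mgcv::gam}), smoothing chosen by generalized cross-validation;
#'     the default, produces a smoothed surface.}
#'   \item{rbf}{thin-plate radial basis interpolation with a small ridge;
#'     slower and noise-sensitive but preserves high-frequency structure
#'     (e.g. sharp dips at the edge of an illumination pattern) that the
#'     b-spline smooths out.}
#' }
#'
#' @param samples a [UniformitySamples-class] with at least 16 non-collinear
#'   samples.
#' @param method "bspline" or "rbf".
#' @param smoothing optional smoothing override: the \code{sp} of the
#'   tensor-product spline, or the ridge of the RBF (default 1e-6).
#' @param k optional per-axis basis dimension of the b-spline.
#' @param gridStep evaluation-lattice spacing in pixels (default: ~1 point
#'   per pixel up to a 160-point axis).
#' @param maxCenters RBF only: interpolate through at most this many samples.
#' @return a [UniformityProfile-class].
#' @examples
#' cfg <- SceneConfig(grid = GridSpec(extentMM = 20), imageSize = c(160, 160),
#'     mmPerPx = 0.2, illumination = IlluminationField("radial_gaussian"))
#' s <- poolSamples(detectWells(sceneImage(renderRUD(cfg))))
#' fitSurface(s, "bspline")
#' @export
fitSurface <- function(samples, method = c("bspline", "rbf"),
        smoothing = NULL, k = NULL, gridStep = NULL, maxCenters = 3000L) {
    stopifnot(is(samples, "UniformitySamples"))
    method <- match.arg(method)
    s <- samples@samples
    n <- nrow(s)
    if (n < 16) stop("at least 16 samples are required to fit a surface")
    if (qr(cbind(1, s$x_px, s$y_px))$rank < 3)
        stop("rank-deficient sample geometry: samples are collinear")
    dim <- samples@imageDim
    fit <- if (method == "bspline") {
        kd <- k %||% max(4L, min(12L, as.integer(floor(sqrt(n / 2)))))
        dat <- data.frame(x = s$x_px, y = s$y_px, z = s$intensity)
        g <- mgcv::gam(z ~ te(x, y, bs = "cr", k = c(kd, kd)), data = dat,
            sp = if (is.null(smoothing)) NULL else rep(smoothing, 2))
        list(type = "bspline", gam = g)
    } else {
        .tpsFit(s$x_px, s$y_px, s$intensity, scale = imageDiagonal(dim),
            ridge = smoothing %||% 1e-6, maxCenters = maxCenters)
    }
    step <- gridStep %||% max(1L, as.integer(floor(min(dim) / 160)))
    gridX <- seq(0, dim[2] - 1, by = step)
    gridY <- seq(0, dim[1] - 1, by = step)
    hull <- as.matrix(s[grDevices::chull(s$x_px, s$y_px),
        c("x_px", "y_px")])
    gx <- rep(gridX, each = length(gridY))
    gy <- rep(gridY, times = length(gridX))
    mask <- matrix(pointsInHull(hull, gx, gy), nrow = length(gridY))
    raw <- matrix(.predictSurface(fit, gx, gy), nrow = length(gridY))
    normConst <- max(raw[mask])
    if (!is.finite(normConst) || normConst <= 0)
        stop("fitted surface has no positive maximum over the valid region")
    vals <- raw / normConst
    clipped <- sum(vals < 0 & mask)
    if (clipped > 0)
        warning(clipped, " fitted lattice values were negative and clipped to 0")
    vals <- pmin(pmax(vals, 0), 1)
    vals[!mask] <- NA_real_
    new("UniformityProfile", method = method, fit = fit,
        normConst = normConst, gridX = gridX, gridY = gridY, values = vals,
        mask = mask, hull = hull, imageDim = as.integer(dim),
        clipped = as.integer(clipped))
}

.predictSurface <- function(fit, x, y) {
    if (fit$type == "bspline")
        as.numeric(mgcv::predict.gam(fit$gam,
            newdata = data.frame(x = x, y = y)))
    else
        .tpsPredict(fit, x, y)
}

#' Evaluate a fitted uniformity profile at pixel positions
#'
#' Returns normalized profile values (clipped to [0, 1]). Points outside the
#' valid region (the sample convex hull) return NA unless
#' \code{extrapolate = TRUE}: edge behaviour of both fitters outside the
#' sampled region is unreliable.
#'
#' @param profile a [UniformityProfile-class].
#' @param x,y pixel coordinates.
#' @param extrapolate evaluate outside the valid region (default FALSE).
#' @return numeric vector of normalized values.
#' @export
evalProfile <- function(profile, x, y, extrapolate = FALSE) {
    stopifnot(is(profile, "UniformityProfile"))
    v <- .predictSurface(profile@fit, x, y) / profile@normConst
    v <- pmin(pmax(v, 0), 1)
    if (!extrapolate)
        v[!pointsInHull(profile@hull, x, y)] <- NA_real_
    v
}

#' Iso-map: regions at or above fractions of the fitted maximum
#'
#' Computes, for each threshold, the mask of the valid region whose
#' normalized fitted intensity is at least that fraction of the maximum, and
#' the fraction of the valid region covered. Masks are nested: each higher
#' threshold's mask is contained in the lower ones.
#'
#' @param profile a [UniformityProfile-class].
#' @param thresholds strictly increasing fractions in (0, 1); default
#'   c(0.60, 0.80, 0.90, 0.95).
#' @return list with \code{thresholds}, \code{fractions} (named numeric in
#'   [0, 1]) and \code{masks} (list of logical matrices on the profile
#'   lattice).
#' @export
isoMap <- function(profile, thresholds = c(0.60, 0.80, 0.90, 0.95)) {
    stopifnot(is(profile, "UniformityProfile"))
    if (any(thresholds <= 0 | thresholds >= 1) ||
        any(diff(thresholds) <= 0))
        stop("thresholds must be strictly increasing fractions in (0, 1)")
    nValid <- sum(profile@mask)
    masks <- lapply(thresholds, function(t) {
        m <- profile@values >= t & profile@mask
        m[is.na(m)] <- FALSE
        m
    })
    fractions <- vapply(masks, function(m) sum(m) / nValid, numeric(1))
    names(fractions) <- sprintf("%g%%", 100 * thresholds)
    list(thresholds = thresholds, fractions = fractions, masks = masks)
}

#' Line profiles through a uniformity surface
#'
#' Samples the normalized surface along full rows (axis = "horizontal") or
#' columns ("vertical") at the stated fractions of the frame, by default at
#' quarters. Points outside the valid region are NA; a position whose entire
#' line falls outside the valid region yields an empty (all-NA) curve with a
#' warning.
#'
#' @param profile a [UniformityProfile-class].
#' @param axis "horizontal" (profiles along x at fixed y) or "vertical".
#' @param positions fractions of the frame in (0, 1).
#' @return data.frame: axis, position, coord_px, value.
#' @export
lineProfiles <- function(profile, axis = c("horizontal", "vertical"),
        positions = c(0.25, 0.5, 0.75)) {
    stopifnot(is(profile, "UniformityProfile"))
    axis <- match.arg(axis)
    if (any(positions <= 0 | positions >= 1))
        stop("positions must be fractions in (0, 1)")
    dim <- profile@imageDim
    out <- lapply(positions, function(p) {
        if (axis == "horizontal") {
            coord <- profile@gridX
            v <- evalProfile(profile, coord, rep(p * (dim[1] - 1),
                length(coord)))
        } else {
            coord <- profile@gridY
            v <- evalProfile(profile, rep(p * (dim[2] - 1), length(coord)),
                coord)
        }
        if (all(is.na(v)))
            warning(sprintf("line at %s position %g lies outside the valid region",
                axis, p))
        data.frame(axis = axis, position = p, coord_px = coord, value = v)
    })
    do.call(rbind, out)
}

#' Write a uniformity profile as a CSV grid with a metadata sidecar
#'
#' The normalized values are written as a plain-text matrix (rows = y of the
#' evaluation lattice), with a YAML sidecar recording the lattice, method and
#' normalization constant.
#'
#' @param profile a [UniformityProfile-class].
#' @param path output CSV path; the sidecar is written at
#'   \code{<path>.meta.yaml}.
#' @return the path, invisibly.
#' @export
writeProfileCSV <- function(profile, path) {
    m <- signif(profile@values, 6)
    utils::write.table(m, path, sep = ",", row.names = FALSE,
        col.names = FALSE, na = "")
    yaml::write_yaml(list(method = profile@method,
        normConst = profile@normConst, gridX = profile@gridX,
        gridY = profile@gridY, imageDim = profile@imageDim),
        paste0(path, ".meta.yaml"))
    invisible(path)
}
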