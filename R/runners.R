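# Pipeline runners: the tested surface behind the command-line front end.
# Each runner is deterministic given its inputs/config and writes CSV
# artifacts (6 significant digits); figures are optional, flag-gated
# products — the acceptance surface is the CSV data behind them.

.logmsg <- function(verbose, ...) {
    if (verbose)
        message(format(Sys.time(), "%H:%M:%S "), ...)
}

#' Render a synthetic scene to disk
#'
#' Writes the rendered image (16-bit TIFF), the ground-truth CSV and the
#' scene config (YAML) into \code{outDir}.
#'
#' @param config a [SceneConfig-class].
#' @param outDir output directory (created if needed).
#' @param what "rud", "rcs" or "cylinders".
#' @param prefix file-name prefix.
#' @param verbose log progress to stderr.
#' @param ... extra arguments for the renderer (e.g. \code{concentrations}
#'   for "rcs").
#' @return invisible list of written paths.
#' @export
runSimulate <- function(config, outDir, what = c("rud", "rcs", "cylinders"),
        prefix = NULL, verbose = TRUE, ...) {
    what <- match.arg(what)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    prefix <- prefix %||% what
    render <- switch(what,
        rud = renderRUD(config),
        rcs = renderRCS(config = config, ...),
        cylinders = renderCylinders(config = config, ...))
    if (what == "rcs" && !"concentrations" %in% names(list(...)))
        stop("rcs simulation requires concentrations")
    paths <- list(
        image = file.path(outDir, paste0(prefix, ".tif")),
        truth = file.path(outDir, paste0(prefix, "_truth.csv")),
        config = file.path(outDir, paste0(prefix, "_config.yaml")))
    writeSceneImage(sceneImage(render), paths$image, config@bitDepth)
    writeTruthCSV(render, paths$truth)
    writeSceneConfig(config, paths$config)
    .logmsg(verbose, "simulated ", what, ": ", nrow(sceneTruth(render)),
        " truth records -> ", outDir)
    invisible(paths)
}

#' Run the uniformity pipeline on one or more images
#'
#' Detects wells in each input image, pools the samples, fits the normalized
#' uniformity surface, and writes the surface grid, iso-map fractions and
#' line profiles as CSV (plus optional rendered figures).
#'
#' @param inputs character paths of input images, or a list of image
#'   matrices.
#' @param outDir output directory.
#' @param method "bspline" or "rbf".
#' @param isoThresholds iso-map thresholds (fractions of maximum).
#' @param params a [detectionParams()] list.
#' @param figures also render PNG figures of the surface, iso-map and line
#'   profiles.
#' @param verbose log progress (counts of detected wells, warnings) to
#'   stderr.
#' @param ... passed to [fitSurface()].
#' @return invisible list with the profile and written paths.
#' @export
runUniformity <- function(inputs, outDir, method = "bspline",
        isoThresholds = c(0.60, 0.80, 0.90, 0.95),
        params = detectionParams(), figures = FALSE, verbose = TRUE, ...) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wells <- .detectAll(inputs, params, verbose)
    pooled <- poolSamples(wells)
    .logmsg(verbose, "pooled ", nrow(samples(pooled)), " samples from ",
        length(wells), " image(s)")
    profile <- fitSurface(pooled, method = method, ...)
    iso <- isoMap(profile, isoThresholds)
    lp <- rbind(lineProfiles(profile, "horizontal"),
                lineProfiles(profile, "vertical"))
    paths <- list(surface = file.path(outDir, "surface.csv"),
        iso = file.path(outDir, "iso_fractions.csv"),
        profiles = file.path(outDir, "line_profiles.csv"))
    writeProfileCSV(profile, paths$surface)
    writeTableCSV(data.frame(threshold = iso$thresholds,
        fraction_of_valid_region = iso$fractions), paths$iso)
    writeTableCSV(lp, paths$profiles)
    if (figures)
        paths$figures <- writeUniformityFigures(profile, iso, lp, outDir)
    .logmsg(verbose, "uniformity artifacts written to ", outDir)
    invisible(list(profile = profile, paths = paths))
}

.detectAll <- function(inputs, params, verbose) {
    if (!is.list(inputs)) inputs <- as.list(inputs)
    lapply(seq_along(inputs), function(i) {
        img <- inputs[[i]]
        id <- if (is.character(img)) basename(img) else paste0("image", i)
        if (is.character(img)) img <- loadImage(img)
        w <- detectWells(img, params, imageId = id)
        .logmsg(verbose, id, ": ", nrow(w), " wells detected")
        if (!nrow(w)) stop("no wells detected in ", id)
        w
    })
}

#' Run the distortion pipeline on one or more images
#'
#' Per image: detect wells, build the central reference grid, match, and
#' compute the local actual-vs-expected distortion percentages; reports
#' are concatenated. An image
#' that fails (e.g. too few central wells) is logged and skipped; the others
#' are still processed.
#'
#' @param inputs character paths of input images, or a list of matrices.
#' @param outDir output directory.
#' @param params a [detectionParams()] list.
#' @param centralFrac,tolerance see [buildReferenceGrid()] and
#'   [matchWells()].
#' @param verbose log progress to stderr.
#' @return invisible list with the reports and written paths.
#' @export
runDistortion <- function(inputs, outDir, params = detectionParams(),
        centralFrac = 0.2, tolerance = 0.5, verbose = TRUE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.list(inputs)) inputs <- as.list(inputs)
    reports <- list()
    for (i in seq_along(inputs)) {
        img <- inputs[[i]]
        id <- if (is.character(img)) basename(img) else paste0("image", i)
        res <- try({
            if (is.character(img)) img <- loadImage(img)
            w <- detectWells(img, params, imageId = id)
            grid <- buildReferenceGrid(w, centralFrac = centralFrac)
            matches <- matchWells(w, grid, tolerance = tolerance)
            nu <- sum(!matches$matched)
            if (nu) .logmsg(verbose, id, ": ", nu, " unmatched wells")
            computeDistortion(matches, attr(w, "imageDim"), imageId = id)
        }, silent = TRUE)
        if (inherits(res, "try-error")) {
            message("image '", id, "' failed: ",
                attr(res, "condition")$message)
        } else {
            reports[[id]] <- res
            .logmsg(verbose, id, ": max |distortion| = ",
                sprintf("%.3f%%", maxAbsDistortion(res)), " (",
                distortionSign(res), ")")
        }
    }
    if (!length(reports)) stop("no image produced a distortion report")
    path <- file.path(outDir, "distortion.csv")
    writeDistortionCSV(reports, path)
    invisible(list(reports = reports, paths = list(distortion = path,
        summary = paste0(path, ".summary.yaml"))))
}

#' Flat-field correct images with a fitted profile
#'
#' Builds the inverse-profile correction map (gain floor applied) and writes
#' corrected images next to \code{outDir}, plus the gain grid as CSV.
#'
#' @param inputs character paths of input images, or a list of matrices.
#' @param profile a [UniformityProfile-class].
#' @param outDir output directory.
#' @param floor gain floor (see [buildCorrection()]).
#' @param verbose log clamping/outside counts to stderr.
#' @return invisible list with the correction map and corrected images.
#' @export
runFlatfield <- function(inputs, profile, outDir, floor = 0.05,
        verbose = TRUE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.list(inputs)) inputs <- as.list(inputs)
    map <- NULL
    corrected <- list()
    for (i in seq_along(inputs)) {
        img <- inputs[[i]]
        id <- if (is.character(img)) basename(img) else paste0("image", i)
        if (is.character(img)) img <- loadImage(img)
        if (is.null(map)) {
            map <- buildCorrection(profile, floor = floor,
                imageDim = dim(img))
            .logmsg(verbose, "correction map: ", map@clamped,
                " clamped px, ", map@outside, " outside valid region")
        }
        out <- applyCorrection(img, map)
        corrected[[id]] <- out
        writeSceneImage(out, file.path(outDir,
            paste0("corrected_", sub("\\.[^.]+$", "", id), ".tif")))
    }
    writeCorrectionCSV(map, file.path(outDir, "correction_gain.csv"))
    invisible(list(map = map, corrected = corrected))
}

#' Render Fig.-style uniformity figures (optional products)
#'
#' @param profile a [UniformityProfile-class].
#' @param iso an [isoMap()] result.
#' @param lp a [lineProfiles()] table.
#' @param outDir output directory for PNG files.
#' @return character vector of written paths, invisibly.
#' @export
writeUniformityFigures <- function(profile, iso, lp, outDir) {
    paths <- character(0)
    f1 <- file.path(outDir, "uniformity_map.png")
    grDevices::png(f1, width = 700, height = 600)
    graphics::image(profile@gridX, profile@gridY, t(profile@values),
        col = grDevices::hcl.colors(64, "viridis"), xlab = "x (px)",
        ylab = "y (px)", main = "Normalized fluorescence uniformity",
        ylim = rev(range(profile@gridY)))
    grDevices::dev.off()
    f2 <- file.path(outDir, "iso_map.png")
    grDevices::png(f2, width = 700, height = 600)
    lev <- matrix(0, nrow(profile@values), ncol(profile@values))
    for (m in iso$masks) lev <- lev + m
    graphics::image(profile@gridX, profile@gridY, t(lev),
        col = grDevices::hcl.colors(length(iso$masks) + 1, "plasma"),
        xlab = "x (px)", ylab = "y (px)",
        main = paste("Iso-map:", paste(names(iso$fractions),
            collapse = ", ")), ylim = rev(range(profile@gridY)))
    grDevices::dev.off()
    f3 <- file.path(outDir, "line_profiles.png")
    grDevices::png(f3, width = 900, height = 450)
    graphics::par(mfrow = c(1, 2))
    for (ax in unique(lp$axis)) {
        sub <- lp[lp$axis == ax, ]
        graphics::plot(NA, xlim = range(sub$coord_px),
            ylim = c(0, 1.05), xlab = paste(ax, "coordinate (px)"),
            ylab = "normalized intensity", main = paste(ax, "profiles"))
        for (p in unique(sub$position))
            graphics::lines(sub$coord_px[sub$position == p],
                sub$value[sub$position == p],
                col = which(unique(sub$position) == p))
    }
    grDevices::dev.off()
    invisible(c(f1, f2, f3))
}
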