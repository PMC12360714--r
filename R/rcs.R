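# Concentration-linearity analysis of a nine-well dilution-series target:
# ROI extraction, control-well baselining, normalization, and the power-law
# fit y = 10^C * x^m in log10-log10 space.

#' Default dilution series for synthetic concentration targets (nM)
#' @export
rcsDefaultConcentrations <- function() c(0, 1, 3, 10, 30, 60, 100, 300, 1000)

#' Extract dilution-series well intensities from an image
#'
#' Measures each well with a circular ROI of half the well diameter (ROI
#' radius = diameter / 4), subtracts the control (0 nM) well mean
#' (baselining), and normalizes to the maximum baselined value among wells
#' eligible for the fit. A non-control well whose baselined value is not
#' positive is flagged excluded (its log is undefined; this situation arises
#' when correction artifacts push the control above a low-concentration
#' well).
#'
#' @param image numeric matrix of counts.
#' @param centers 9 x 2 matrix (or data.frame x, y) of well centers in
#'   pixels.
#' @param diameterPx well diameter in pixels (scalar or per-well).
#' @param concentrations nine concentrations in nM, exactly one 0.
#' @return data.frame: well, conc_nM, roi_mean, roi_sd, n_px, baselined,
#'   normalized, excluded, reason.
#' @examples
#' cfg <- SceneConfig(imageSize = c(256, 256), mmPerPx = 0.25)
#' r <- renderRCS(rcsDefaultConcentrations(), cfg)
#' tr <- sceneTruth(r)
#' extractRCSWells(sceneImage(r), cbind(tr$x_true_px, tr$y_true_px),
#'     10 / 0.25, tr$conc_nM)
#' @export
extractRCSWells <- function(image, centers, diameterPx, concentrations) {
    centers <- as.matrix(centers)
    if (nrow(centers) != 9 || length(concentrations) != 9)
        stop("exactly 9 wells are required")
    if (sum(concentrations == 0) != 1)
        stop("exactly one control (0 nM) well is required")
    radius <- rep_len(diameterPx, 9) / 4    # half-diameter ROI
    roi <- lapply(seq_len(9), function(i)
        measureDiskROI(image, centers[i, ], radius[i]))
    df <- data.frame(well = seq_len(9), conc_nM = concentrations,
        roi_mean = vapply(roi, `[[`, numeric(1), "mean"),
        roi_sd = vapply(roi, `[[`, numeric(1), "sd"),
        n_px = vapply(roi, `[[`, numeric(1), "n"))
    control <- df$roi_mean[df$conc_nM == 0]
    df$baselined <- df$roi_mean - control
    df$excluded <- df$conc_nM > 0 & df$baselined <= 0
    df$reason <- ifelse(df$excluded,
        "non-positive intensity after baselining", "")
    usable <- df$conc_nM > 0 & !df$excluded
    if (any(usable)) {
        top <- max(df$baselined[usable])
        df$normalized <- df$baselined / top
    } else df$normalized <- NA_real_
    df
}

#' Fit the power-law concentration-response model
#'
#' Ordinary least squares on log10(normalized baselined intensity) versus
#' log10(concentration) over the usable wells (concentration > 0, baselined
#' value > 0): the model y = 10^C * x^m. The slope m is the linearity
#' measure, ideally 1; excluded wells are carried in the result.
#'
#' @param wells output of [extractRCSWells()].
#' @return an [RCSFit-class].
#' @examples
#' wells <- data.frame(well = 1:9,
#'     conc_nM = rcsDefaultConcentrations(),
#'     roi_mean = 100 + 5 * rcsDefaultConcentrations())
#' wells$baselined <- wells$roi_mean - wells$roi_mean[wells$conc_nM == 0]
#' wells$excluded <- FALSE; wells$reason <- ""
#' wells$normalized <- wells$baselined / max(wells$baselined)
#' linearitySlope(fitLinearity(wells))   # exactly 1
#' @export
fitLinearity <- function(wells) {
    usable <- wells$conc_nM > 0 & !wells$excluded & wells$baselined > 0
    excluded <- wells[wells$excluded, , drop = FALSE]
    if (sum(usable) < 3)
        stop("fewer than 3 usable wells for the linearity fit; excluded: ",
            if (nrow(excluded)) paste(excluded$well, collapse = ", ")
            else "none")
    lx <- log10(wells$conc_nM[usable])
    ly <- log10(wells$normalized[usable])
    fit <- stats::lm(ly ~ lx)
    # r^2 computed directly: summary.lm warns on exact (noise-free) fits
    ssTot <- sum((ly - mean(ly))^2)
    r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else 1
    out <- new("RCSFit")   # slotwise: a slot named C would match new(Class=)
    out@C <- unname(stats::coef(fit)[1])
    out@m <- unname(stats::coef(fit)[2])
    out@r2 <- r2
    out@nIncluded <- as.integer(sum(usable))
    out@wells <- wells
    out@excluded <- excluded
    out
}

#' Linearity before and after flat-field correction, across placements
#'
#' For each placement of the dilution-series target in the field of view,
#' renders the scene, fits the linearity model on the raw image, then
#' flat-field-corrects the image with the supplied profile and refits —
#' mirroring the pre/post structure of a correction-validation experiment.
#' Errors in one placement are reported and do not stop the others.
#'
#' @param sceneFun function(offsetMM, rotationDeg) returning a
#'   [PhantomRender-class] of an RCS scene (see [renderRCS()]).
#' @param placements data.frame with columns label, offset_x_mm,
#'   offset_y_mm, rotation_deg.
#' @param profile a [UniformityProfile-class] used for correction, or NULL
#'   to skip the post column.
#' @param floor gain floor passed to [buildCorrection()].
#' @param wellDiameterMM well diameter of the rendered target, mm.
#' @return data.frame: label, m_pre, r2_pre, n_excluded_pre, m_post,
#'   r2_post, n_excluded_post.
#' @export
linearityExperiment <- function(sceneFun, placements, profile = NULL,
        floor = 0.05, wellDiameterMM = 10) {
    map <- NULL
    one <- function(pl) {
        out <- data.frame(label = pl$label, m_pre = NA_real_,
            r2_pre = NA_real_, n_excluded_pre = NA_integer_,
            m_post = NA_real_, r2_post = NA_real_,
            n_excluded_post = NA_integer_)
        res <- try({
            render <- sceneFun(c(pl$offset_x_mm, pl$offset_y_mm),
                pl$rotation_deg)
            tr <- sceneTruth(render)
            cfg <- sceneConfig(render)
            centers <- cbind(tr$x_true_px, tr$y_true_px)
            diameterPx <- wellDiameterMM / cfg@mmPerPx
            pre <- fitLinearity(extractRCSWells(sceneImage(render), centers,
                diameterPx, tr$conc_nM))
            out$m_pre <- pre@m; out$r2_pre <- pre@r2
            out$n_excluded_pre <- nrow(pre@excluded)
            if (!is.null(profile)) {
                if (is.null(map))
                    map <<- buildCorrection(profile, floor = floor,
                        imageDim = dim(sceneImage(render)))
                corr <- applyCorrection(sceneImage(render), map)
                post <- fitLinearity(extractRCSWells(corr, centers,
                    diameterPx, tr$conc_nM))
                out$m_post <- post@m; out$r2_post <- post@r2
                out$n_excluded_post <- nrow(post@excluded)
            }
        }, silent = TRUE)
        if (inherits(res, "try-error"))
            message("placement '", pl$label, "' failed: ",
                attr(res, "condition")$message)
        out
    }
    do.call(rbind, lapply(seq_len(nrow(placements)), function(i)
        one(placements[i, ])))
}

#' Write linearity-fit results as CSV
#'
#' @param fits an [RCSFit-class], a list of them with names as position
#'   labels, or a [linearityExperiment()] table.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeRCSFitCSV <- function(fits, path) {
    if (is.data.frame(fits)) return(writeTableCSV(fits, path))
    if (is(fits, "RCSFit")) fits <- list(fit = fits)
    df <- do.call(rbind, lapply(names(fits), function(nm) {
        f <- fits[[nm]]
        data.frame(label = nm, C = f@C, m = f@m, r2 = f@r2,
            n_included = f@nIncluded,
            excluded_wells = paste(f@excluded$well, collapse = ";"))
    }))
    writeTableCSV(df, path)
}
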