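# Local geometric distortion against a reference grid built from central
# wells, in the style of ISO 17850 dot-target measurements.

#' Build an ideal reference lattice from central wells
#'
#' Estimates the lattice pitch and orientation from the wells nearest the
#' image center — the central region is assumed distortion-free, which is the
#' standard premise of dot-target distortion measurement — and extends an
#' ideal grid over the full index range of the detections. The central window
#' (default: a disc spanning 20% of the image diagonal) must contain at least
#' 9 wells; the basis and anchor are then refined by an affine least-squares
#' fit to the (at most) 25 wells nearest the center, keeping the estimate
#' local so that real distortion farther out cannot bias the pitch.
#'
#' @param wells detected wells (from [detectWells()]).
#' @param imageDim c(height, width); defaults to the detections' attribute.
#' @param centralFrac diameter of the central window as a fraction of the
#'   image diagonal.
#' @param maxBasisWells number of center-most wells used for the affine fit.
#' @return a [ReferenceGrid-class].
#' @examples
#' cfg <- SceneConfig(grid = GridSpec(extentMM = 20), imageSize = c(160, 160),
#'     mmPerPx = 0.2)
#' g <- buildReferenceGrid(detectWells(sceneImage(renderRUD(cfg))))
#' g@basis
#' @export
buildReferenceGrid <- function(wells, imageDim = NULL, centralFrac = 0.2,
        maxBasisWells = 25L) {
    imageDim <- imageDim %||% attr(wells, "imageDim")
    if (is.null(imageDim)) stop("imageDim required")
    ctr <- imageCenter(imageDim)
    p <- cbind(wells$x_px, wells$y_px)
    dctr <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
    rWin <- centralFrac * imageDiagonal(imageDim) / 2
    central <- which(dctr <= rWin)
    if (length(central) < 9)
        stop("insufficient central wells: ", length(central),
            " found within the central window, at least 9 required")
    core <- central[order(dctr[central])]
    core <- core[seq_len(min(maxBasisWells, length(core)))]
    cp <- p[core, , drop = FALSE]
    # nearest-neighbour displacement vectors among the core wells
    dmat <- as.matrix(stats::dist(cp))
    diag(dmat) <- Inf
    pitch0 <- stats::median(apply(dmat, 1, min))
    pairs <- which(dmat > 0.6 * pitch0 & dmat < 1.4 * pitch0, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    v <- cp[pairs[, 2], , drop = FALSE] - cp[pairs[, 1], , drop = FALSE]
    # cluster into the two lattice directions (angles mod pi)
    ang <- atan2(v[, 2], v[, 1]) %% pi
    ref <- ang[1]
    d1 <- abs(((ang - ref + pi / 2) %% pi) - pi / 2) < pi / 4
    avgDir <- function(vv) {
        rep <- vv[1, ]
        flip <- (vv %*% rep) < 0
        vv[flip, ] <- -vv[flip, , drop = FALSE]
        colMeans(vv)
    }
    if (!any(d1) || all(d1))
        stop("could not identify two lattice directions from central wells")
    b1 <- avgDir(v[d1, , drop = FALSE])
    b2 <- avgDir(v[!d1, , drop = FALSE])
    # order/orient: column 1 ~ +x, column 2 ~ +y
    if (abs(b1[1]) < abs(b2[1])) { tmp <- b1; b1 <- b2; b2 <- tmp }
    if (b1[1] < 0) b1 <- -b1
    if (b2[2] < 0) b2 <- -b2
    B <- cbind(b1, b2)
    anchor <- p[which.min(dctr), ]
    # refine anchor and basis by an affine LS fit on the core wells
    idxCore <- t(round(solve(B, t(cp) - anchor)))
    X <- cbind(1, idxCore)
    cf <- solve(crossprod(X), crossprod(X, cp))
    anchor <- cf[1, ]
    B <- t(cf[2:3, ])
    idxAll <- t(round(solve(B, t(p) - anchor)))
    iRange <- range(idxAll[, 1]); jRange <- range(idxAll[, 2])
    grid <- expand.grid(i = iRange[1]:iRange[2], j = jRange[1]:jRange[2])
    pred <- t(anchor + B %*% t(as.matrix(grid)))
    predicted <- data.frame(i = grid$i, j = grid$j, x_px = pred[, 1],
        y_px = pred[, 2])
    new("ReferenceGrid", anchor = as.numeric(anchor), basis = B,
        indexRange = rbind(i = iRange, j = jRange), predicted = predicted,
        pitchPx = mean(c(sqrt(sum(B[, 1]^2)), sqrt(sum(B[, 2]^2)))))
}

#' Match detected wells to reference-grid points
#'
#' Each well is assigned to the nearest ideal lattice point within
#' \code{tolerance} (a fraction of the lattice pitch, default half a pitch).
#' If two wells claim the same lattice point the nearer one is kept and the
#' other is reported unmatched.
#'
#' @param wells detected wells.
#' @param grid a [ReferenceGrid-class].
#' @param tolerance match radius as a fraction of the pitch.
#' @return data.frame: x_px, y_px, i, j, x_ref, y_ref, offset_px, matched,
#'   reason.
#' @export
matchWells <- function(wells, grid, tolerance = 0.5) {
    stopifnot(is(grid, "ReferenceGrid"))
    p <- cbind(wells$x_px, wells$y_px)
    idx <- t(round(solve(grid@basis, t(p) - grid@anchor)))
    ref <- t(grid@anchor + grid@basis %*% t(idx))
    off <- sqrt(rowSums((p - ref)^2))
    tolPx <- tolerance * grid@pitchPx
    matched <- off <= tolPx
    reason <- ifelse(matched, "", "beyond tolerance")
    key <- paste(idx[, 1], idx[, 2])
    for (k in unique(key[matched])) {
        rows <- which(key == k & matched)
        if (length(rows) > 1) {
            lose <- rows[-which.min(off[rows])]
            matched[lose] <- FALSE
            reason[lose] <- "ambiguous: nearer well kept"
        }
    }
    data.frame(x_px = p[, 1], y_px = p[, 2], i = idx[, 1], j = idx[, 2],
        x_ref = ref[, 1], y_ref = ref[, 2], offset_px = off,
        matched = matched, reason = reason)
}

#' Compute local geometric distortion from matched wells
#'
#' For every matched well, the actual distance (image center to the well
#' centroid) is compared with the expected distance (image center to the
#' matched reference-grid point):
#' distortion(%) = 100 * (actual - expected) / expected.
#' Central wells are excluded: the ratio is undefined at the grid origin
#' and, at expected distances comparable to the centroid uncertainty, it
#' amplifies sub-pixel noise into arbitrarily large percentages. The cutoff
#' is \code{minExpectedFrac} of the lattice pitch (estimated from the
#' reference points), default half a pitch, so at most the single
#' centermost well is dropped. Negative overall distortion indicates
#' barrel, positive pincushion; the sign summary is taken from the mean
#' distortion of the outermost quartile of wells (by expected distance),
#' called "minimal" within 0.05%.
#'
#' @param matches output of [matchWells()].
#' @param imageDim c(height, width) defining the image center.
#' @param imageId identifier stored with the records.
#' @param minExpectedFrac wells with expected distance below this fraction
#'   of the lattice pitch are treated as central and excluded.
#' @return a [DistortionReport-class].
#' @export
computeDistortion <- function(matches, imageDim, imageId = "",
        minExpectedFrac = 0.5) {
    ctr <- imageCenter(imageDim)
    m <- matches[matches$matched, , drop = FALSE]
    if (!nrow(m)) stop("no matched wells")
    actual <- sqrt((m$x_px - ctr[1])^2 + (m$y_px - ctr[2])^2)
    expected <- sqrt((m$x_ref - ctr[1])^2 + (m$y_ref - ctr[2])^2)
    keep <- expected > minExpectedFrac * .refPitch(m)
    if (!any(keep))
        stop("degenerate: all matched wells are at the grid origin")
    rec <- data.frame(x_px = m$x_px[keep], y_px = m$y_px[keep],
        x_ref = m$x_ref[keep], y_ref = m$y_ref[keep],
        actual_dist_px = actual[keep], expected_dist_px = expected[keep],
        distortion_pct = 100 * (actual[keep] - expected[keep]) /
            expected[keep],
        image_id = imageId)
    outer <- rec$expected_dist_px >= 0.75 * max(rec$expected_dist_px)
    mOuter <- mean(rec$distortion_pct[outer])
    sign <- if (mOuter < -0.05) "barrel" else if (mOuter > 0.05)
        "pincushion" else "minimal"
    new("DistortionReport", records = rec, center = ctr,
        maxAbs = max(abs(rec$distortion_pct)), signSummary = sign)
}

# Lattice pitch estimated from matched reference points: median nearest-
# neighbour distance of a deterministic subsample.
.refPitch <- function(m) {
    ref <- unique(cbind(m$x_ref, m$y_ref))
    if (nrow(ref) < 2) return(0)
    probe <- ref[unique(round(seq(1, nrow(ref), length.out = 64))), ,
        drop = FALSE]
    d2 <- outer(probe[, 1], ref[, 1], "-")^2 +
          outer(probe[, 2], ref[, 2], "-")^2
    d2[d2 < 1e-12] <- Inf
    stats::median(sqrt(apply(d2, 1, min)))
}

#' Keystone asymmetry differentials of a distortion report
#'
#' Mean-distortion differences between the left/right and top/bottom
#' half-planes. Radially symmetric distortion gives differentials near 0;
#' keystone from a tilted object plane makes one half-plane positive and the
#' opposite negative, so its differential moves away from 0 and flips sign
#' with the tilt.
#'
#' @param report a [DistortionReport-class].
#' @return named numeric c(left_right, top_bottom); NA (with a warning) for
#'   a differential whose half-plane holds no wells.
#' @export
keystoneAsymmetry <- function(report) {
    stopifnot(is(report, "DistortionReport"))
    r <- report@records
    ctr <- report@center
    half <- function(a, b) {
        if (!length(a) || !length(b)) {
            warning("empty half-plane: differential undefined")
            return(NA_real_)
        }
        mean(a) - mean(b)
    }
    c(left_right = half(r$distortion_pct[r$x_px < ctr[1]],
            r$distortion_pct[r$x_px > ctr[1]]),
      top_bottom = half(r$distortion_pct[r$y_px < ctr[2]],
            r$distortion_pct[r$y_px > ctr[2]]))
}

#' Write distortion records as CSV with a summary sidecar
#'
#' @param report a [DistortionReport-class] (or a list of them, concatenated).
#' @param path output CSV path; summary sidecar at \code{<path>.summary.yaml}.
#' @return the path, invisibly.
#' @export
writeDistortionCSV <- function(report, path) {
    reports <- if (is(report, "DistortionReport")) list(report) else report
    rec <- do.call(rbind, lapply(reports, records))
    writeTableCSV(rec[c("x_px", "y_px", "actual_dist_px",
        "expected_dist_px", "distortion_pct", "image_id")], path)
    asym <- lapply(reports, function(r) as.list(keystoneAsymmetry(r)))
    yaml::write_yaml(list(
        max_abs_distortion_pct = max(vapply(reports, maxAbsDistortion,
            numeric(1))),
        sign_summary = vapply(reports, distortionSign, character(1)),
        asymmetry = asym), paste0(path, ".summary.yaml"))
    invisible(path)
}
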