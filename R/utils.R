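# Internal helpers shared across modules.
#
# Pixel-coordinate convention (everywhere in the package): 0-based, pixel
# centers at integer coordinates, origin at the top-left pixel center,
# x rightward (matrix column), y downward (matrix row). A matrix image is
# addressed as image[y + 1, x + 1].

imageCenter <- function(dim) {
    c((dim[2] - 1) / 2, (dim[1] - 1) / 2)   # (x, y)
}

imageDiagonal <- function(dim) {
    sqrt(sum((dim - 1)^2))
}

# Point-in-polygon test for the convex-hull valid region. `hull` is a
# two-column (x, y) matrix of vertices in order; points on the boundary count
# as inside (within a small tolerance), so samples on the hull are valid.
pointsInHull <- function(hull, x, y, tol = 1e-9) {
    n <- nrow(hull)
    inside <- rep(TRUE, length(x))
    # consistent orientation: signed area
    x2 <- c(hull[-1, 1], hull[1, 1]); y2 <- c(hull[-1, 2], hull[1, 2])
    area <- sum(hull[, 1] * y2 - x2 * hull[, 2]) / 2
    s <- if (area >= 0) 1 else -1
    scale <- max(abs(hull)) + 1
    for (k in seq_len(n)) {
        k2 <- if (k == n) 1L else k + 1L
        ex <- hull[k2, 1] - hull[k, 1]; ey <- hull[k2, 2] - hull[k, 2]
        cross <- s * (ex * (y - hull[k, 2]) - ey * (x - hull[k, 1]))
        inside <- inside & (cross >= -tol * scale)
    }
    inside
}

# 2D rotation of an n x 2 matrix of (x, y) rows, degrees, about the origin.
rotateXY <- function(xy, deg) {
    th <- deg * pi / 180
    cbind(xy[, 1] * cos(th) - xy[, 2] * sin(th),
          xy[, 1] * sin(th) + xy[, 2] * cos(th))
}

# Numbers in CSV outputs are written with 6 significant digits.
writeTableCSV <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
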