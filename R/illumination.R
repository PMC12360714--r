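# Illumination / collection-efficiency field evaluation.

# Raw (un-normalized) field value at pixel coordinates (x, y).
.illumRaw <- function(field, x, y, dim) {
    H <- dim[1]; W <- dim[2]
    p <- field@params
    switch(field@kind,
        uniform = rep(1, length(x)),
        radial_gaussian = {
            ctr <- p$center %||% c(0.5, 0.5)
            sigmaFrac <- p$sigmaFrac %||% 0.35
            floorv <- p$floor %||% 0
            cx <- ctr[1] * (W - 1); cy <- ctr[2] * (H - 1)
            sigma <- sigmaFrac * min(W, H)
            floorv + (1 - floorv) *
                exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
        },
        separable_polynomial = {
            u <- 2 * x / (W - 1) - 1
            v <- 2 * y / (H - 1) - 1
            px <- .polyEval(p$coefX %||% 1, u)
            py <- .polyEval(p$coefY %||% 1, v)
            px * py
        },
        tabulated = .bilinear(p$values, x, y, dim),
        stop("unknown illumination kind: ", field@kind))
}

.polyEval <- function(coef, u) {
    out <- rep(0, length(u))
    for (i in seq_along(coef)) out <- out + coef[i] * u^(i - 1)
    out
}

# Bilinear interpolation of a matrix (rows = y) stretched over the frame.
.bilinear <- function(values, x, y, dim) {
    nr <- nrow(values); nc <- ncol(values)
    u <- x / (dim[2] - 1) * (nc - 1)
    v <- y / (dim[1] - 1) * (nr - 1)
    u <- pmin(pmax(u, 0), nc - 1); v <- pmin(pmax(v, 0), nr - 1)
    i0 <- pmin(floor(v), nr - 2); j0 <- pmin(floor(u), nc - 2)
    fu <- u - j0; fv <- v - i0
    v00 <- values[cbind(i0 + 1, j0 + 1)]
    v01 <- values[cbind(i0 + 1, j0 + 2)]
    v10 <- values[cbind(i0 + 2, j0 + 1)]
    v11 <- values[cbind(i0 + 2, j0 + 2)]
    (1 - fv) * ((1 - fu) * v00 + fu * v01) + fv * ((1 - fu) * v10 + fu * v11)
}

# Normalization constant: field maximum over (a decimation of) the pixel
# grid, so that the returned relative efficiency peaks at 1.
.illumNormConst <- function(field, dim) {
    if (field@kind == "uniform") return(1)
    nx <- min(dim[2], 256L); ny <- min(dim[1], 256L)
    xs <- seq(0, dim[2] - 1, length.out = nx)
    ys <- seq(0, dim[1] - 1, length.out = ny)
    g <- expand.grid(x = xs, y = ys)
    mx <- max(.illumRaw(field, g$x, g$y, dim))
    if (!is.finite(mx) || mx <= 0)
        stop("illumination field is not strictly positive over the frame")
    mx
}

#' Evaluate an illumination field at pixel positions
#'
#' Returns the relative illumination/collection efficiency in (0, 1] at the
#' given pixel coordinates, normalized so the field's maximum over the frame
#' is 1. The field is a property of the instrument and is defined in the
#' camera pixel frame.
#'
#' @param field an [IlluminationField-class].
#' @param x,y pixel coordinates (0-based).
#' @param dim image dimensions c(height, width) in pixels.
#' @return numeric vector of efficiencies, same length as \code{x}.
#' @examples
#' f <- IlluminationField("radial_gaussian", sigmaFrac = 0.4)
#' evalIllumination(f, c(63.5, 0), c(63.5, 0), dim = c(128, 128))
#' @export
evalIllumination <- function(field, x, y, dim) {
    stopifnot(is(field, "IlluminationField"), length(x) == length(y))
    raw <- .illumRaw(field, x, y, dim) / .illumNormConst(field, dim)
    if (any(raw <= 0))
        stop("illumination field evaluates non-positive at requested points")
    raw
}
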