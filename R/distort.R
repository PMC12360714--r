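# Forward geometric distortion: keystone (projective, object-plane tilt)
# followed by a two-term Brown radial model.

#' Apply a distortion field to ideal pixel positions
#'
#' Maps undistorted pixel positions through the scene's distortion model.
#' Keystone (the projective map of an object plane tilted by \code{tiltDeg}
#' about a horizontal axis through the principal point) is applied first,
#' then the radial term \eqn{r' = r (1 + k_1 r_n^2 + k_2 r_n^4)} with
#' \eqn{r_n = r / (\mathrm{diagonal}/2)}. With all coefficients zero the map
#' is the identity.
#'
#' @param field a [DistortionField-class].
#' @param xy n x 2 matrix (or length-2 vector) of (x, y) pixel positions.
#' @param dim image dimensions c(height, width); supplies the default
#'   principal point (image center) and focal length (image diagonal).
#' @return n x 2 matrix of distorted positions.
#' @examples
#' d <- DistortionField(k1 = -0.05)
#' distortPoints(d, cbind(c(10, 100), c(10, 100)), dim = c(128, 128))
#' @export
distortPoints <- function(field, xy, dim) {
    stopifnot(is(field, "DistortionField"))
    if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
    ctr <- field@center
    if (anyNA(ctr)) ctr <- imageCenter(dim)
    f <- field@focalPx
    if (is.na(f)) f <- imageDiagonal(dim)
    dx <- xy[, 1] - ctr[1]
    dy <- xy[, 2] - ctr[2]
    # keystone: object plane tilted about the horizontal axis through the
    # principal point; pinhole projection with focal length f
    th <- field@tiltDeg * pi / 180
    if (th != 0) {
        denom <- 1 - dy * sin(th) / f
        if (any(denom <= 0))
            stop("keystone map not invertible over the requested points")
        dx <- dx / denom
        dy <- dy * cos(th) / denom
    }
    # radial (Brown, two terms), radius normalized by half the diagonal
    if (field@k1 != 0 || field@k2 != 0) {
        rn2 <- (dx^2 + dy^2) / (imageDiagonal(dim) / 2)^2
        s <- 1 + field@k1 * rn2 + field@k2 * rn2^2
        dx <- dx * s
        dy <- dy * s
    }
    cbind(ctr[1] + dx, ctr[2] + dy)
}
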