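#' @import methods
NULL

# ---------------------------------------------------------------------------
# Scene description classes
# ---------------------------------------------------------------------------

#' Dot-grid geometry of a uniformity/distortion target
#'
#' Describes the square lattice of fluorescent wells of a reference
#' uniformity-and-distortion (RUD) style target: equal circular wells of
#' diameter \code{wellDiameterMM} at center-to-center pitch \code{pitchMM}
#' over a square imaging area of side \code{extentMM}. The number of wells per
#' axis is derived as \code{floor(extentMM / pitchMM) + 1}, so the defaults
#' (1 mm wells, 2 mm pitch, 100 mm extent) give a 51 x 51 = 2601 well grid.
#'
#' @slot wellDiameterMM well diameter in mm.
#' @slot pitchMM center-to-center well spacing in mm.
#' @slot extentMM side length of the square imaging area in mm.
#'
#' @seealso [GridSpec()] for the constructor, [wellsPerAxis()].
#' @exportClass GridSpec
setClass("GridSpec",
    representation(wellDiameterMM = "numeric", pitchMM = "numeric",
        extentMM = "numeric"),
    prototype(wellDiameterMM = 1, pitchMM = 2, extentMM = 100))

setValidity("GridSpec", function(object) {
    if (length(object@wellDiameterMM) != 1 || length(object@pitchMM) != 1 ||
        length(object@extentMM) != 1)
        return("wellDiameterMM, pitchMM and extentMM must be scalars")
    if (!(object@wellDiameterMM > 0))
        return("wellDiameterMM must be > 0")
    if (!(object@pitchMM > object@wellDiameterMM))
        return("pitchMM must exceed wellDiameterMM (wells must not touch)")
    if (object@extentMM < 0)
        return("extentMM must be >= 0")
    TRUE
})

#' @param wellDiameterMM,pitchMM,extentMM see slots.
#' @rdname GridSpec-class
#' @export
GridSpec <- function(wellDiameterMM = 1, pitchMM = 2, extentMM = 100) {
    new("GridSpec", wellDiameterMM = wellDiameterMM, pitchMM = pitchMM,
        extentMM = extentMM)
}

.illumKinds <- c("uniform", "radial_gaussian", "separable_polynomial",
    "tabulated")

#' Spatial illumination / collection-efficiency field
#'
#' Models the combined excitation-illumination and collection-efficiency
#' nonuniformity of an imaging system as a smooth, strictly positive relative
#' efficiency defined over the camera frame and internally normalized to a
#' maximum of 1. Available kinds:
#' \describe{
#'   \item{uniform}{constant 1 (no parameters).}
#'   \item{radial_gaussian}{\code{params$center} (fractions of the frame,
#'     default c(0.5, 0.5)), \code{params$sigmaFrac} (Gaussian sigma as a
#'     fraction of min(W, H), default 0.35), optional \code{params$floor}
#'     (additive pedestal before normalization, default 0).}
#'   \item{separable_polynomial}{\code{params$coefX}, \code{params$coefY}:
#'     polynomial coefficients (intercept first) evaluated on each axis
#'     rescaled to [-1, 1]; the field is the product of the two polynomials
#'     and must be strictly positive over the frame.}
#'   \item{tabulated}{\code{params$values}: a matrix (rows = y) bilinearly
#'     interpolated across the frame; values must be > 0.}
#' }
#' The field lives in the camera pixel frame (it belongs to the instrument,
#' not to the phantom), so moving the target does not move the field.
#'
#' @slot kind one of the kinds above.
#' @slot params named list of kind-specific parameters.
#'
#' @seealso [evalIllumination()]
#' @exportClass IlluminationField
setClass("IlluminationField",
    representation(kind = "character", params = "list"),
    prototype(kind = "uniform", params = list()))

setValidity("IlluminationField", function(object) {
    if (length(object@kind) != 1 || !object@kind %in% .illumKinds)
        return(paste("kind must be one of:", paste(.illumKinds, collapse = ", ")))
    if (object@kind == "tabulated") {
        v <- object@params$values
        if (!is.matrix(v) || any(!is.finite(v)) || any(v <= 0))
            return("tabulated illumination needs params$values: a finite, strictly positive matrix")
    }
    TRUE
})

#' @param kind,params see slots; parameters may also be given in \code{...}.
#' @param ... elements appended to \code{params}.
#' @rdname IlluminationField-class
#' @export
IlluminationField <- function(kind = "uniform", params = list(), ...) {
    new("IlluminationField", kind = kind, params = c(params, list(...)))
}

#' Geometric distortion map (radial + keystone)
#'
#' Forward distortion applied to ideal (undistorted) pixel positions. The
#' radial component is the Brown model truncated at two terms,
#' \deqn{r' = r (1 + k_1 r_n^2 + k_2 r_n^4),}
#' with \eqn{r_n} the radius normalized by half the image diagonal, so
#' \eqn{k_1 < 0} gives barrel and \eqn{k_1 > 0} pincushion distortion.
#' Keystone is modeled as the projective map induced by tilting the object
#' plane by \code{tiltDeg} about a horizontal axis through the principal
#' point, with effective focal length \code{focalPx} (default: the image
#' diagonal in pixels). Keystone is applied first (object-plane geometry),
#' then the radial lens term. \code{k1 = k2 = tiltDeg = 0} is the identity.
#'
#' @slot k1,k2 dimensionless radial coefficients.
#' @slot tiltDeg object-plane tilt in degrees.
#' @slot center principal point (x, y) in pixels; NA = image center.
#' @slot focalPx effective focal length in pixels; NA = image diagonal.
#'
#' @seealso [distortPoints()]
#' @exportClass DistortionField
setClass("DistortionField",
    representation(k1 = "numeric", k2 = "numeric", tiltDeg = "numeric",
        center = "numeric", focalPx = "numeric"),
    prototype(k1 = 0, k2 = 0, tiltDeg = 0, center = c(NA_real_, NA_real_),
        focalPx = NA_real_))

setValidity("DistortionField", function(object) {
    if (length(object@center) != 2)
        return("center must be length-2 (x, y) or c(NA, NA)")
    if (abs(object@tiltDeg) >= 45)
        return("tiltDeg must be in (-45, 45) for an invertible map")
    TRUE
})

#' @param k1,k2,tiltDeg,center,focalPx see slots.
#' @rdname DistortionField-class
#' @export
DistortionField <- function(k1 = 0, k2 = 0, tiltDeg = 0,
        center = c(NA_real_, NA_real_), focalPx = NA_real_) {
    new("DistortionField", k1 = k1, k2 = k2, tiltDeg = tiltDeg,
        center = as.numeric(center), focalPx = focalPx)
}

.noiseKinds <- c("none", "gaussian", "poisson_like")

#' Full ground-truth description of a synthetic phantom scene
#'
#' Bundles everything the renderer needs: target geometry, illumination field,
#' distortion map, image raster geometry, signal levels, PSF blur, noise model
#' and placement of the target within the field of view. A fixed config and
#' seed render to a bit-identical image.
#'
#' @slot grid a [GridSpec-class] (used by the dot-grid renderer).
#' @slot illumination an [IlluminationField-class].
#' @slot distortion a [DistortionField-class].
#' @slot imageSize integer (height, width) in pixels.
#' @slot mmPerPx object-plane sampling in mm per pixel.
#' @slot wellPeak nominal well signal amplitude in counts (at illumination 1).
#' @slot background additive, spatially constant background offset in counts.
#' @slot psfSigma Gaussian PSF sigma in pixels (0 = no blur).
#' @slot noise one of "none", "gaussian", "poisson_like". Gaussian noise has
#'   sd \code{noiseStrength} counts; poisson_like is Gaussian with
#'   sd \code{noiseStrength * sqrt(signal)} (shot-like scaling without
#'   coupling to the integer bit depth).
#' @slot noiseStrength noise scale (counts, or counts^(1/2) for poisson_like).
#' @slot seed integer RNG seed; fixes the rendered noise.
#' @slot offsetMM (x, y) displacement of the target center from the image
#'   center, in mm.
#' @slot rotationDeg in-plane rotation of the target, degrees.
#' @slot bitDepth output bit depth (8 or 16); rendered counts are clamped to
#'   the representable range.
#' @slot supersample linear subpixel sampling factor for anti-aliased disk
#'   edges (default 4).
#'
#' @seealso [SceneConfig()], [renderRUD()], [renderRCS()], [renderCylinders()]
#' @exportClass SceneConfig
setClass("SceneConfig",
    representation(grid = "GridSpec", illumination = "IlluminationField",
        distortion = "DistortionField", imageSize = "integer",
        mmPerPx = "numeric", wellPeak = "numeric", background = "numeric",
        psfSigma = "numeric", noise = "character", noiseStrength = "numeric",
        seed = "integer", offsetMM = "numeric", rotationDeg = "numeric",
        bitDepth = "integer", supersample = "integer"))

setValidity("SceneConfig", function(object) {
    if (length(object@imageSize) != 2 || any(object@imageSize < 8))
        return("imageSize must be (height, width), each >= 8 pixels")
    if (!(object@mmPerPx > 0)) return("mmPerPx must be > 0")
    if (object@wellPeak <= 0) return("wellPeak must be > 0")
    if (object@background < 0) return("background must be >= 0")
    if (object@psfSigma < 0) return("psfSigma must be >= 0")
    if (!object@noise %in% .noiseKinds)
        return(paste("noise must be one of:", paste(.noiseKinds, collapse = ", ")))
    if (object@noiseStrength < 0) return("noiseStrength must be >= 0")
    if (length(object@offsetMM) != 2) return("offsetMM must be length 2 (x, y)")
    if (!object@bitDepth %in% c(8L, 16L)) return("bitDepth must be 8 or 16")
    if (object@supersample < 1) return("supersample must be >= 1")
    TRUE
})

#' @param grid,illumination,distortion,imageSize,mmPerPx,wellPeak,background
#'   see slots.
#' @param psfSigma,noise,noiseStrength,seed,offsetMM,rotationDeg,bitDepth
#'   see slots.
#' @param supersample see slots.
#' @rdname SceneConfig-class
#' @export
SceneConfig <- function(grid = GridSpec(), illumination = IlluminationField(),
        distortion = DistortionField(), imageSize = c(512L, 512L),
        mmPerPx = 0.2, wellPeak = 30000, background = 0, psfSigma = 1,
        noise = "none", noiseStrength = 0, seed = 1L,
        offsetMM = c(0, 0), rotationDeg = 0, bitDepth = 16L,
        supersample = 4L) {
    new("SceneConfig", grid = grid, illumination = illumination,
        distortion = distortion, imageSize = as.integer(imageSize),
        mmPerPx = mmPerPx, wellPeak = wellPeak, background = background,
        psfSigma = psfSigma, noise = noise, noiseStrength = noiseStrength,
        seed = as.integer(seed), offsetMM = as.numeric(offsetMM),
        rotationDeg = rotationDeg, bitDepth = as.integer(bitDepth),
        supersample = as.integer(supersample))
}

#' A rendered synthetic phantom scene with its ground truth
#'
#' @slot image numeric matrix of counts, \code{image[y + 1, x + 1]} with
#'   0-based pixel coordinates, origin top-left, x rightward, y downward.
#' @slot truth data.frame with one row per rendered well/feature; for grid
#'   scenes the columns are well_row, well_col, x_true_px, y_true_px (post
#'   distortion), x_undist_px, y_undist_px, illum, intensity_true.
#' @slot config the [SceneConfig-class] that produced the render.
#'
#' @exportClass PhantomRender
setClass("PhantomRender",
    representation(image = "matrix", truth = "data.frame",
        config = "SceneConfig"))

# ---------------------------------------------------------------------------
# Analysis classes
# ---------------------------------------------------------------------------

#' Pooled uniformity samples from one or more images
#'
#' Well centroids and mean intensities pooled ("stitched") across images of a
#' dot-grid target acquired in the same camera frame; the phantom moves, the
#' camera does not, so samples live in shared pixel coordinates.
#'
#' @slot samples data.frame with columns x_px, y_px, intensity, n_obs.
#' @slot imageDim integer (height, width) of the camera frame.
#'
#' @seealso [poolSamples()]
#' @exportClass UniformitySamples
setClass("UniformitySamples",
    representation(samples = "data.frame", imageDim = "integer"))

setValidity("UniformitySamples", function(object) {
    s <- object@samples
    need <- c("x_px", "y_px", "intensity")
    if (!all(need %in% names(s)))
        return("samples must have columns x_px, y_px, intensity")
    if (nrow(s)) {
        if (any(s$intensity <= 0)) return("intensities must be > 0")
        H <- object@imageDim[1]; W <- object@imageDim[2]
        if (any(s$x_px < 0 | s$x_px > W - 1 | s$y_px < 0 | s$y_px > H - 1))
            return("sample coordinates fall outside the stated image dimensions")
    }
    TRUE
})

#' Fitted, max-normalized fluorescence uniformity surface
#'
#' A smooth surface fitted to pooled well samples by either a tensor-product
#' cubic b-spline (smoothing chosen by generalized cross-validation) or exact
#' thin-plate RBF interpolation with a small ridge, then normalized so that
#' its maximum over the valid region equals 1. The valid region is the convex
#' hull of the samples; evaluation outside it is refused unless extrapolation
#' is requested explicitly.
#'
#' @slot method "bspline" or "rbf".
#' @slot fit internal fit object (opaque; use [evalProfile()]).
#' @slot normConst fitted maximum, in counts, used for normalization.
#' @slot gridX,gridY pixel coordinates of the evaluation lattice.
#' @slot values matrix of normalized fitted values, rows indexed by gridY,
#'   columns by gridX; clipped to [0, 1]; NA outside the valid region.
#' @slot mask logical matrix: TRUE inside the valid region.
#' @slot hull two-column matrix of convex-hull vertices (x, y).
#' @slot imageDim integer (height, width) of the camera frame.
#' @slot clipped number of valid-region lattice points whose raw fitted value
#'   was negative and got clipped to 0.
#'
#' @seealso [fitSurface()], [evalProfile()], [isoMap()], [lineProfiles()]
#' @exportClass UniformityProfile
setClass("UniformityProfile",
    representation(method = "character", fit = "list", normConst = "numeric",
        gridX = "numeric", gridY = "numeric", values = "matrix",
        mask = "matrix", hull = "matrix", imageDim = "integer",
        clipped = "integer"))

#' Ideal reference lattice estimated from central wells
#'
#' @slot anchor pixel position (x, y) of the central lattice point.
#' @slot basis 2 x 2 matrix whose columns are the two lattice basis vectors
#'   in pixels.
#' @slot indexRange 2 x 2 matrix: rows = (i, j), columns = (min, max).
#' @slot predicted data.frame i, j, x_px, y_px of ideal lattice positions.
#' @slot pitchPx mean basis-vector length (pixel pitch of the lattice).
#'
#' @seealso [buildReferenceGrid()]
#' @exportClass ReferenceGrid
setClass("ReferenceGrid",
    representation(anchor = "numeric", basis = "matrix",
        indexRange = "matrix", predicted = "data.frame", pitchPx = "numeric"))

setValidity("ReferenceGrid", function(object) {
    b <- object@basis
    if (!all(dim(b) == c(2, 2))) return("basis must be 2 x 2")
    l1 <- sqrt(sum(b[, 1]^2)); l2 <- sqrt(sum(b[, 2]^2))
    if (l1 == 0 || l2 == 0) return("basis vectors must be nonzero")
    if (abs(b[1, 1] * b[2, 2] - b[2, 1] * b[1, 2]) / (l1 * l2) < 0.2)
        return("basis vectors are (near) parallel")
    if (max(l1, l2) / min(l1, l2) > 1.25)
        return("basis vector lengths differ by more than 25% (not a square lattice)")
    TRUE
})

#' Local geometric distortion report
#'
#' One record per matched well with the actual center-to-well distance, the
#' expected center-to-grid-point distance, and the local distortion
#' \deqn{\mathrm{distortion}(\%) = 100 \cdot
#'   \frac{\mathrm{actual} - \mathrm{expected}}{\mathrm{expected}}.}
#'
#' @slot records data.frame: x_px, y_px, x_ref, y_ref, actual_dist_px,
#'   expected_dist_px, distortion_pct, image_id.
#' @slot center image center (x, y) used for the distances.
#' @slot maxAbs maximum |distortion_pct|.
#' @slot signSummary "barrel", "pincushion" or "minimal", from the sign of the
#'   mean distortion of the outermost quartile of wells.
#'
#' @seealso [computeDistortion()], [keystoneAsymmetry()]
#' @exportClass DistortionReport
setClass("DistortionReport",
    representation(records = "data.frame", center = "numeric",
        maxAbs = "numeric", signSummary = "character"))

#' Per-pixel flat-field correction map
#'
#' The reciprocal of a normalized uniformity profile, evaluated on the full
#' camera frame. Profile values below \code{floor} are clamped (bounding the
#' gain at 1/floor); pixels outside the profile's valid region carry gain NA
#' and are passed through unchanged by [applyCorrection()].
#'
#' @slot gain numeric matrix (height x width) of multiplicative gains.
#' @slot floor minimum profile value used in the reciprocal.
#' @slot clamped number of pixels whose gain was clamped at 1/floor.
#' @slot outside number of pixels outside the valid region.
#' @slot provenance free-text identifier of the source profile.
#'
#' @seealso [buildCorrection()], [applyCorrection()]
#' @exportClass CorrectionMap
setClass("CorrectionMap",
    representation(gain = "matrix", floor = "numeric", clamped = "integer",
        outside = "integer", provenance = "character"))

#' Power-law concentration-linearity fit
#'
#' Parameters of the model \eqn{y = 10^C x^m} fitted by ordinary least
#' squares in log10-log10 space to baselined, normalized well intensities of
#' a dilution-series target; \eqn{m} is the linearity measure and ideally 1.
#'
#' @slot C intercept of the log-log fit.
#' @slot m slope (linearity measure).
#' @slot r2 coefficient of determination of the log-log fit.
#' @slot nIncluded number of wells used in the fit.
#' @slot wells data.frame of all wells with baselined/normalized values and
#'   exclusion flags (see [extractRCSWells()]).
#' @slot excluded data.frame subset of wells excluded from the fit, with
#'   reasons.
#'
#' @seealso [fitLinearity()]
#' @exportClass RCSFit
setClass("RCSFit",
    representation(C = "numeric", m = "numeric", r2 = "numeric",
        nIncluded = "integer", wells = "data.frame", excluded = "data.frame"))
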