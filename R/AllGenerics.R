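# Accessors and show methods. Slot access from user code goes through these.

#' @rdname GridSpec-class
#' @param object,x a phantomQA object.
#' @export
setGeneric("wellsPerAxis", function(object) standardGeneric("wellsPerAxis"))

#' @describeIn GridSpec-class number of wells along one axis,
#'   \code{floor(extentMM / pitchMM) + 1}.
#' @export
setMethod("wellsPerAxis", "GridSpec", function(object)
    as.integer(floor(object@extentMM / object@pitchMM) + 1))

#' @describeIn GridSpec-class total number of wells in the square grid.
#' @export
setGeneric("totalWells", function(object) standardGeneric("totalWells"))

#' @rdname GridSpec-class
#' @export
setMethod("totalWells", "GridSpec", function(object)
    as.integer(wellsPerAxis(object)^2))

#' @describeIn PhantomRender-class the rendered image matrix (counts).
#' @export
setGeneric("sceneImage", function(object) standardGeneric("sceneImage"))

#' @rdname PhantomRender-class
#' @export
setMethod("sceneImage", "PhantomRender", function(object) object@image)

#' @describeIn PhantomRender-class the ground-truth table.
#' @export
setGeneric("sceneTruth", function(object) standardGeneric("sceneTruth"))

#' @rdname PhantomRender-class
#' @export
setMethod("sceneTruth", "PhantomRender", function(object) object@truth)

#' @describeIn PhantomRender-class the generating [SceneConfig-class].
#' @export
setGeneric("sceneConfig", function(object) standardGeneric("sceneConfig"))

#' @rdname PhantomRender-class
#' @export
setMethod("sceneConfig", "PhantomRender", function(object) object@config)

#' @describeIn UniformitySamples-class the pooled sample table.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname UniformitySamples-class
#' @export
setMethod("samples", "UniformitySamples", function(object) object@samples)

#' @describeIn UniformityProfile-class normalization constant (fitted
#'   maximum, counts).
#' @export
setGeneric("normConstant", function(object) standardGeneric("normConstant"))

#' @rdname UniformityProfile-class
#' @export
setMethod("normConstant", "UniformityProfile", function(object)
    object@normConst)

#' @describeIn UniformityProfile-class matrix of normalized fitted values on
#'   the evaluation lattice (NA outside the valid region).
#' @export
setGeneric("profileValues", function(object) standardGeneric("profileValues"))

#' @rdname UniformityProfile-class
#' @export
setMethod("profileValues", "UniformityProfile", function(object)
    object@values)

#' @describeIn UniformityProfile-class logical valid-region mask on the
#'   evaluation lattice.
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname UniformityProfile-class
#' @export
setMethod("validMask", "UniformityProfile", function(object) object@mask)

#' @describeIn UniformityProfile-class fit method ("bspline" or "rbf").
#' @export
setGeneric("fitMethod", function(object) standardGeneric("fitMethod"))

#' @rdname UniformityProfile-class
#' @export
setMethod("fitMethod", "UniformityProfile", function(object) object@method)

#' @describeIn DistortionReport-class per-well distortion records.
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname DistortionReport-class
#' @export
setMethod("records", "DistortionReport", function(object) object@records)

#' @describeIn DistortionReport-class maximum absolute local distortion (%).
#' @export
setGeneric("maxAbsDistortion", function(object)
    standardGeneric("maxAbsDistortion"))

#' @rdname DistortionReport-class
#' @export
setMethod("maxAbsDistortion", "DistortionReport", function(object)
    object@maxAbs)

#' @describeIn DistortionReport-class "barrel", "pincushion" or "minimal".
#' @export
setGeneric("distortionSign", function(object)
    standardGeneric("distortionSign"))

#' @rdname DistortionReport-class
#' @export
setMethod("distortionSign", "DistortionReport", function(object)
    object@signSummary)

#' @describeIn RCSFit-class the linearity slope m of the log-log fit.
#' @export
setGeneric("linearitySlope", function(object)
    standardGeneric("linearitySlope"))

#' @rdname RCSFit-class
#' @export
setMethod("linearitySlope", "RCSFit", function(object) object@m)

#' @describeIn RCSFit-class wells excluded from the fit, with reasons.
#' @export
setGeneric("excludedWells", function(object) standardGeneric("excludedWells"))

#' @rdname RCSFit-class
#' @export
setMethod("excludedWells", "RCSFit", function(object) object@excluded)

# --- show methods ----------------------------------------------------------

setMethod("show", "GridSpec", function(object) {
    cat(sprintf("GridSpec: %g mm wells, %g mm pitch, %g mm extent (%d x %d = %d wells)\n",
        object@wellDiameterMM, object@pitchMM, object@extentMM,
        wellsPerAxis(object), wellsPerAxis(object), totalWells(object)))
})

setMethod("show", "IlluminationField", function(object) {
    cat(sprintf("IlluminationField: kind = %s\n", object@kind))
})

setMethod("show", "DistortionField", function(object) {
    cat(sprintf("DistortionField: k1 = %g, k2 = %g, tilt = %g deg%s\n",
        object@k1, object@k2, object@tiltDeg,
        if (object@k1 == 0 && object@k2 == 0 && object@tiltDeg == 0)
            " (identity)" else ""))
})

setMethod("show", "SceneConfig", function(object) {
    cat(sprintf("SceneConfig: %d x %d px, %g mm/px, peak %g, bg %g, psf %g px, noise %s, seed %d\n",
        object@imageSize[1], object@imageSize[2], object@mmPerPx,
        object@wellPeak, object@background, object@psfSigma, object@noise,
        object@seed))
    show(object@grid); show(object@illumination); show(object@distortion)
})

setMethod("show", "PhantomRender", function(object) {
    cat(sprintf("PhantomRender: %d x %d px image, %d truth records\n",
        nrow(object@image), ncol(object@image), nrow(object@truth)))
})

setMethod("show", "UniformitySamples", function(object) {
    cat(sprintf("UniformitySamples: %d samples in a %d x %d px frame\n",
        nrow(object@samples), object@imageDim[1], object@imageDim[2]))
})

setMethod("show", "UniformityProfile", function(object) {
    v <- object@values[object@mask]
    cat(sprintf(
        "UniformityProfile (%s): %d x %d lattice, norm const %.4g, range [%.3f, %.3f] on valid region\n",
        object@method, length(object@gridY), length(object@gridX),
        object@normConst, min(v), max(v)))
})

setMethod("show", "ReferenceGrid", function(object) {
    cat(sprintf(
        "ReferenceGrid: anchor (%.2f, %.2f), pitch %.3f px, %d predicted points\n",
        object@anchor[1], object@anchor[2], object@pitchPx,
        nrow(object@predicted)))
})

setMethod("show", "DistortionReport", function(object) {
    cat(sprintf(
        "DistortionReport: %d wells, max |distortion| = %.3f%%, pattern: %s\n",
        nrow(object@records), object@maxAbs, object@signSummary))
})

setMethod("show", "CorrectionMap", function(object) {
    cat(sprintf(
        "CorrectionMap: %d x %d px, floor %.3g, %d clamped, %d outside valid region\n",
        nrow(object@gain), ncol(object@gain), object@floor, object@clamped,
        object@outside))
})

setMethod("show", "RCSFit", function(object) {
    cat(sprintf("RCSFit: m = %.4f, C = %.4f, r^2 = %.5f, n = %d (%d excluded)\n",
        object@m, object@C, object@r2, object@nIncluded,
        nrow(object@excluded)))
})
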