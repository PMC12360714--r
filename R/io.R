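# Image and configuration I/O.

#' Load a single-channel grayscale image
#'
#' Reads an 8- or 16-bit TIFF or PNG into a numeric matrix of raw counts
#' (no rescaling). Multi-channel images are accepted only when all channels
#' are identical, in which case the first channel is used.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param bitDepth bit depth hint used when the file does not record one
#'   (PNG is read back on its native scale via this value); default 16 for
#'   TIFF, taken from the file for PNG when available.
#' @return numeric matrix of counts with attribute \code{bitDepth}.
#' @seealso [writeSceneImage()]
#' @export
loadImage <- function(path, bitDepth = NULL) {
    if (!file.exists(path)) stop("cannot read image: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
        img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
        depth <- attr(img, "bits.per.sample") %||% bitDepth %||% 16L
        img <- unclass(img)
        attributes(img) <- attributes(img)["dim"]
    } else if (ext == "png") {
        img <- png::readPNG(path, info = TRUE)
        info <- attr(img, "info")
        depth <- bitDepth %||% info$bit.depth %||% 8L
        img <- unclass(img)
        attributes(img) <- attributes(img)["dim"]
        img <- img * (2^depth - 1)   # readPNG rescales to [0, 1]
    } else stop("unsupported image format: .", ext)
    if (length(dim(img)) == 3) {
        ch <- dim(img)[3]
        for (k in seq_len(ch)[-1])
            if (any(img[, , k] != img[, , 1]))
                stop("multi-channel image with differing channels; ",
                     "reduce to one channel before loading")
        img <- img[, , 1]
    }
    if (!is.matrix(img)) stop("image did not reduce to a single channel")
    storage.mode(img) <- "double"
    attr(img, "bitDepth") <- as.integer(depth)
    img
}

#' Write an image matrix as 16-bit TIFF (default) or PNG
#'
#' Counts are rounded and saturated at the bit-depth maximum (with a warning
#' if saturation occurs).
#'
#' @param image numeric matrix of counts.
#' @param path output path; format chosen by extension.
#' @param bitDepth 8 or 16.
#' @return the path, invisibly.
#' @export
writeSceneImage <- function(image, path, bitDepth = 16L) {
    maxCount <- 2^bitDepth - 1
    if (any(image > maxCount + 0.5))
        warning(sum(image > maxCount + 0.5),
            " pixels saturate the ", bitDepth, "-bit output range")
    q <- round(pmin(pmax(image, 0), maxCount)) / maxCount
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff"))
        tiff::writeTIFF(q, path, bits.per.sample = bitDepth,
            compression = "none")
    else if (ext == "png")
        png::writePNG(q, path)
    else stop("unsupported image format: .", ext)
    invisible(path)
}

#' Write a ground-truth table as CSV
#'
#' @param render a [PhantomRender-class] (or a truth data.frame).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTruthCSV <- function(render, path) {
    truth <- if (is(render, "PhantomRender")) sceneTruth(render) else render
    writeTableCSV(truth, path)
}

# --- SceneConfig <-> plain-text (YAML) round trip --------------------------

.sceneConfigToList <- function(config) {
    list(
        grid = list(wellDiameterMM = config@grid@wellDiameterMM,
            pitchMM = config@grid@pitchMM, extentMM = config@grid@extentMM),
        illumination = list(kind = config@illumination@kind,
            params = lapply(config@illumination@params, function(p)
                if (is.matrix(p)) list(matrix = TRUE, nrow = nrow(p),
                    data = as.numeric(p)) else p)),
        distortion = list(k1 = config@distortion@k1, k2 = config@distortion@k2,
            tiltDeg = config@distortion@tiltDeg,
            center = as.numeric(config@distortion@center),
            focalPx = config@distortion@focalPx),
        imageSize = as.integer(config@imageSize), mmPerPx = config@mmPerPx,
        wellPeak = config@wellPeak, background = config@background,
        psfSigma = config@psfSigma, noise = config@noise,
        noiseStrength = config@noiseStrength, seed = config@seed,
        offsetMM = as.numeric(config@offsetMM),
        rotationDeg = config@rotationDeg,
        bitDepth = config@bitDepth, supersample = config@supersample)
}

.sceneConfigFromList <- function(x) {
    params <- lapply(x$illumination$params, function(p)
        if (is.list(p) && isTRUE(p$matrix))
            matrix(as.numeric(p$data), nrow = p$nrow)
        else if (is.list(p)) as.numeric(unlist(p)) else p)
    SceneConfig(
        grid = GridSpec(x$grid$wellDiameterMM, x$grid$pitchMM,
            x$grid$extentMM),
        illumination = IlluminationField(x$illumination$kind, params),
        distortion = DistortionField(x$distortion$k1, x$distortion$k2,
            x$distortion$tiltDeg, as.numeric(unlist(x$distortion$center)),
            x$distortion$focalPx),
        imageSize = as.integer(unlist(x$imageSize)), mmPerPx = x$mmPerPx,
        wellPeak = x$wellPeak, background = x$background,
        psfSigma = x$psfSigma, noise = x$noise,
        noiseStrength = x$noiseStrength, seed = x$seed,
        offsetMM = as.numeric(unlist(x$offsetMM)),
        rotationDeg = x$rotationDeg, bitDepth = x$bitDepth,
        supersample = x$supersample)
}

#' Write / read a SceneConfig as a plain-text (YAML) file
#'
#' The round trip is lossless: \code{readSceneConfig(writeSceneConfig(cfg))}
#' reproduces \code{cfg}.
#'
#' @param config a [SceneConfig-class].
#' @param path a .yaml/.yml file path.
#' @return \code{writeSceneConfig}: the path, invisibly;
#'   \code{readSceneConfig}: a [SceneConfig-class].
#' @export
writeSceneConfig <- function(config, path) {
    validObject(config)
    yaml::write_yaml(.sceneConfigToList(config), path,
        precision = 15L)
    invisible(path)
}

#' @rdname writeSceneConfig
#' @export
readSceneConfig <- function(path) {
    .sceneConfigFromList(yaml::read_yaml(path))
}
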