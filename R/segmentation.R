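#' Resample a slice onto the 560 x 560 network canvas
#'
#' The aspect ratio is preserved: the longer side is scaled to 560 pixels
#' (nearest-neighbour), the shorter side is centered with zero-padding.
#' The returned placement record allows \code{\link{postprocessCanvas}} to
#' map canvas-resolution label maps back to the original shape exactly.
#'
#' @param image non-empty numeric matrix.
#' @param size canvas side length (560 by default).
#' @return list with \code{canvas} (size x size matrix) and
#'   \code{placement} (original and scaled dims plus offsets).
#' @export
preprocessCanvas <- function(image, size = 560L) {
    stopifnot(is.matrix(image), nrow(image) >= 1L, ncol(image) >= 1L)
    scale <- size / max(dim(image))
    outR <- if (nrow(image) >= ncol(image)) size else
        max(1L, round(nrow(image) * scale))
    outC <- if (ncol(image) >= nrow(image)) size else
        max(1L, round(ncol(image) * scale))
    scaled <- nnResize(image, outR, outC)
    offR <- (size - outR) %/% 2L
    offC <- (size - outC) %/% 2L
    canvas <- matrix(0, size, size)
    canvas[offR + seq_len(outR), offC + seq_len(outC)] <- scaled
    list(canvas = canvas,
         placement = list(origRows = nrow(image), origCols = ncol(image),
                          outRows = outR, outCols = outC,
                          offRow = offR, offCol = offC, size = size))
}

#' Map canvas-resolution labels back to the original slice shape
#'
#' Inverse of \code{\link{preprocessCanvas}}: the zero-padding bands are
#' stripped, then the label map is rescaled back to the original shape by
#' nearest neighbour. For integer-ratio scales the round trip is the
#' identity.
#'
#' @param canvasLabels size x size label matrix.
#' @param placement placement record from the matching preprocess call.
#' @return label matrix at the original shape.
#' @export
postprocessCanvas <- function(canvasLabels, placement) {
    p <- placement
    if (!all(dim(canvasLabels) == c(p$size, p$size)))
        stop("canvas shape does not match the placement record")
    core <- canvasLabels[p$offRow + seq_len(p$outRows),
                         p$offCol + seq_len(p$outCols), drop = FALSE]
    out <- nnResize(core, p$origRows, p$origCols)
    storage.mode(out) <- "integer"
    out
}

# ---- segmenter contract ------------------------------------------------

#' Segmenter contract and implementations
#'
#' A segmenter turns a grayscale slice into a per-pixel label map of the
#' same shape, with every output value a valid class id. Three
#' implementations are provided:
#' \describe{
#'   \item{OracleSegmenter}{returns held ground-truth label maps,
#'     optionally corrupted: exactly \code{floor(rate * n_pixels)} pixels
#'     per slice are flipped to a uniformly random different class,
#'     deterministically under the stored seed. Used to test downstream
#'     stages at a controlled error rate.}
#'   \item{NearestMeanSegmenter}{assigns each pixel the class whose mean
#'     intensity is nearest (ties to the lowest class id); exact on
#'     noise-free renderings.}
#'   \item{TrainableSegmenter}{a per-pixel multinomial softmax classifier
#'     over intensity radial-basis features plus normalized spatial
#'     coordinates, trained with categorical cross-entropy
#'     (\code{\link{trainSegmenter}}). A deliberately small, desk-scale
#'     stand-in for a full convolutional segmentation network; any
#'     stronger model can be dropped in behind the same generic.}
#' }
#'
#' @export
setClass("Segmenter", representation("VIRTUAL"))

#' @slot truth list of ground-truth label matrices, one per slice.
#' @slot corruptionRate fraction of pixels to flip per slice, in [0, 1).
#' @slot seed integer seed driving the corruption.
#' @rdname Segmenter-class
#' @export
setClass("OracleSegmenter", contains = "Segmenter", representation(
    truth = "list", corruptionRate = "numeric", seed = "integer"),
    validity = function(object) {
        if (object@corruptionRate < 0 || object@corruptionRate >= 1)
            return("corruptionRate must be in [0, 1)")
        TRUE
    })

#' @param truth an \code{AnatomySeries} with labels, or a list of label
#'   matrices.
#' @param corruptionRate,seed see slots.
#' @rdname Segmenter-class
#' @export
OracleSegmenter <- function(truth, corruptionRate = 0, seed = 1L) {
    if (is(truth, "AnatomySeries"))
        truth <- lapply(seriesSlices(truth), sliceLabels)
    if (any(vapply(truth, is.null, TRUE)))
        stop("oracle truth must have a label map for every slice")
    new("OracleSegmenter", truth = truth,
        corruptionRate = corruptionRate, seed = as.integer(seed))
}

#' @slot intensityMap named numeric class mean intensities.
#' @rdname Segmenter-class
#' @export
setClass("NearestMeanSegmenter", contains = "Segmenter",
         representation(intensityMap = "numeric"))

#' @param intensityMap named numeric covering all 9 class names.
#' @rdname Segmenter-class
#' @export
NearestMeanSegmenter <- function(intensityMap = defaultIntensityMap()) {
    if (!all(labelClasses()$name %in% names(intensityMap)))
        stop("intensityMap must cover all 9 classes")
    new("NearestMeanSegmenter", intensityMap = intensityMap)
}

#' @slot weights 9 x nFeatures numeric matrix of softmax weights.
#' @slot featureSpec list: rbf centers, rbf width, intensity scale.
#' @slot classes the class-name vector the weights rows correspond to.
#' @rdname Segmenter-class
#' @export
setClass("TrainableSegmenter", contains = "Segmenter", representation(
    weights = "matrix", featureSpec = "list", classes = "character"))

#' @param rbfCenters,rbfWidth intensity radial-basis grid (intensity
#'   units); defaults cover the default intensity map's range.
#' @param rbfGain multiplicative gain on the RBF feature block; keeps the
#'   optimal weights small so Adam reaches them quickly at small learning
#'   rates.
#' @rdname Segmenter-class
#' @export
TrainableSegmenter <- function(rbfCenters = seq(0, 360, by = 40),
                               rbfWidth = 25, rbfGain = 40) {
    fs <- list(centers = rbfCenters, width = rbfWidth, iscale = 350,
               gain = rbfGain)
    nf <- .nFeatures(fs)
    new("TrainableSegmenter",
        weights = matrix(0, nLabelClasses(), nf),
        featureSpec = fs, classes = labelClasses()$name)
}

.nFeatures <- function(fs) 2L + length(fs$centers) + 2L

# Per-pixel design matrix: bias, scaled intensity, intensity RBFs,
# normalized row/col coordinates (centered).
.pixelFeatures <- function(img, fs) {
    n <- length(img)
    I <- as.vector(img)
    rows <- nrow(img); cols <- ncol(img)
    yn <- (row(img) - 0.5) / rows - 0.5
    xn <- (col(img) - 0.5) / cols - 0.5
    # the RBF block carries a gain so the optimal softmax weights are small
    # in magnitude and reachable in few Adam steps at the default 0.001
    # learning rate (Adam steps are bounded by the learning rate)
    rbf <- matrix(vapply(fs$centers,
                         function(c0) exp(-(I - c0)^2 / (2 * fs$width^2)),
                         numeric(n)), nrow = n) * (fs$gain %||% 1)
    cbind(1, I / fs$iscale, rbf, as.vector(yn), as.vector(xn))
}

.softmax <- function(Z) {
    Z <- Z - apply(Z, 1L, max)
    E <- exp(Z)
    E / rowSums(E)
}

#' Predict a per-pixel label map for one slice
#'
#' @param segmenter a \code{\linkS4class{Segmenter}}.
#' @param image numeric matrix (may be NULL for the oracle).
#' @param sliceIndex 1-based index of the slice within its series; the
#'   oracle uses it to select the matching truth map and to derive its
#'   per-slice corruption stream.
#' @param ... unused.
#' @return integer label matrix of the same shape as the input.
#' @export
setGeneric("predictLabels",
           function(segmenter, image, sliceIndex = 1L, ...)
               standardGeneric("predictLabels"))

#' @rdname predictLabels
#' @export
setMethod("predictLabels", "OracleSegmenter",
function(segmenter, image, sliceIndex = 1L, ...) {
    if (sliceIndex > length(segmenter@truth))
        stop("oracle has no truth for slice ", sliceIndex)
    lab <- segmenter@truth[[sliceIndex]]
    nflip <- floor(segmenter@corruptionRate * length(lab))
    if (nflip > 0) {
        lab <- withSeed(segmenter@seed + sliceIndex, {
            idx <- sample.int(length(lab), nflip)
            shift <- sample.int(nLabelClasses() - 1L, nflip, replace = TRUE)
            lab[idx] <- (lab[idx] + shift) %% nLabelClasses()
            lab
        })
    }
    storage.mode(lab) <- "integer"
    lab
})

#' @rdname predictLabels
#' @export
setMethod("predictLabels", "NearestMeanSegmenter",
function(segmenter, image, sliceIndex = 1L, ...) {
    means <- segmenter@intensityMap[labelClasses()$name]
    D <- abs(outer(as.vector(image), unname(means), "-"))
    lab <- matrix(max.col(-D, ties.method = "first") - 1L,
                  nrow(image), ncol(image))
    storage.mode(lab) <- "integer"
    lab
})

#' @rdname predictLabels
#' @export
setMethod("predictLabels", "TrainableSegmenter",
function(segmenter, image, sliceIndex = 1L, ...) {
    Phi <- .pixelFeatures(image, segmenter@featureSpec)
    scores <- Phi %*% t(segmenter@weights)
    lab <- matrix(max.col(scores, ties.method = "first") - 1L,
                  nrow(image), ncol(image))
    storage.mode(lab) <- "integer"
    lab
})

#' Segment every slice of a series
#'
#' Runs the segmenter over each slice and attaches the predicted label
#' maps (at original resolution); images and geometry are untouched.
#'
#' @param series an \code{AnatomySeries}.
#' @param segmenter a \code{\linkS4class{Segmenter}}.
#' @return the series with predicted labels.
#' @export
segmentSeries <- function(series, segmenter) {
    sl <- seriesSlices(series)
    out <- lapply(seq_along(sl), function(i) {
        s <- sl[[i]]
        lab <- predictLabels(segmenter, sliceImage(s), sliceIndex = i)
        if (!is.null(sliceImage(s)) &&
            !all(dim(lab) == dim(sliceImage(s))))
            stop("segmenter returned a label map of the wrong shape")
        AnatomySlice(image = sliceImage(s), labels = lab,
                     geometry = sliceGeometry(s))
    })
    AnatomySeries(out, manufacturer = manufacturer(series),
                  bsa = seriesBSA(series), heightCm = series@heightCm,
                  weightKg = series@weightKg)
}
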