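#' Training configuration
#'
#' Mirrors the published training recipe: categorical cross-entropy over
#' batches of 20 images at learning rate 0.001, with random rescaling,
#' rotation, shearing and translation augmentation, training until the
#' validation loss plateaus. "Plateau" means no new validation-loss
#' minimum for \code{patience} consecutive epochs.
#'
#' @param batchSize images per optimizer step (>= 1).
#' @param learningRate Adam step size.
#' @param patience epochs of non-improving validation loss before stopping
#'   (>= 1).
#' @param maxEpochs hard epoch cap.
#' @param pixelsPerImage pixels sampled per image per step (the per-pixel
#'   classifier trains on a pixel subsample rather than full frames).
#' @param augment list of augmentation ranges: \code{rescale} (length-2
#'   multiplicative range), \code{rotateDeg}, \code{shearDeg},
#'   \code{translateFrac} (symmetric half-ranges). Set to NULL to disable.
#' @param seed integer; all training randomness (shuffling, augmentation,
#'   pixel sampling, weight init) derives from it.
#' @return a \code{TrainConfig} list.
#' @export
trainConfig <- function(batchSize = 20L, learningRate = 0.001,
                        patience = 5L, maxEpochs = 100L,
                        pixelsPerImage = 1500L,
                        augment = list(rescale = c(0.9, 1.1),
                                       rotateDeg = 10, shearDeg = 5,
                                       translateFrac = 0.05),
                        seed = 1L) {
    stopifnot(batchSize >= 1L, patience >= 1L, maxEpochs >= 1L,
              learningRate > 0, pixelsPerImage >= 1L)
    structure(list(batchSize = as.integer(batchSize),
                   learningRate = learningRate,
                   patience = as.integer(patience),
                   maxEpochs = as.integer(maxEpochs),
                   pixelsPerImage = as.integer(pixelsPerImage),
                   augment = augment, seed = as.integer(seed)),
              class = "TrainConfig")
}

# Random affine augmentation (nearest-neighbour warp about the image
# center, background fill 0) applied jointly to image and labels so the
# pair stays consistent. Draws its parameters from the current RNG stream.
.augmentPair <- function(img, lab, aug) {
    s <- runif(1, aug$rescale[1], aug$rescale[2])
    th <- runif(1, -aug$rotateDeg, aug$rotateDeg) * pi / 180
    sh <- tan(runif(1, -aug$shearDeg, aug$shearDeg) * pi / 180)
    tr <- runif(2, -aug$translateFrac, aug$translateFrac) * dim(img)
    M <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) %*%
        matrix(c(1, 0, sh, 1), 2) * s
    Minv <- solve(M)
    cr <- (nrow(img) + 1) / 2; cc <- (ncol(img) + 1) / 2
    dst <- cbind(as.vector(row(img)) - cr - tr[1],
                 as.vector(col(img)) - cc - tr[2])
    src <- dst %*% t(Minv)
    ri <- round(src[, 1] + cr); ci <- round(src[, 2] + cc)
    ok <- ri >= 1 & ri <= nrow(img) & ci >= 1 & ci <= ncol(img)
    idx <- ri + (ci - 1L) * nrow(img)
    wi <- matrix(0, nrow(img), ncol(img))
    wl <- matrix(0L, nrow(img), ncol(img))
    wi[ok] <- img[idx[ok]]
    wl[ok] <- lab[idx[ok]]
    list(image = wi, labels = wl)
}

.asSlicePairs <- function(x) {
    if (is(x, "AnatomySeries")) x <- seriesSlices(x)
    lapply(x, function(s) {
        img <- sliceImage(s); lab <- sliceLabels(s)
        if (is.null(img) || is.null(lab))
            stop("training data need both image and labels on every slice")
        if (!.validLabelValues(lab))
            stop("label map contains invalid class ids")
        list(image = img, labels = lab)
    })
}

# Plateau rule: training stops after epoch e when no new validation-loss
# minimum (strict improvement) occurred in the last `patience` epochs.
# Returns TRUE when the sequence of per-epoch losses says "stop now".
.plateauReached <- function(valLosses, patience) {
    n <- length(valLosses)
    if (n <= patience) return(FALSE)
    bestEpoch <- which.min(valLosses)   # first occurrence = strict minima
    (n - bestEpoch) >= patience
}

# mean categorical cross-entropy of weights W on feature matrix Phi /
# integer labels y (0-based)
.cceLoss <- function(W, Phi, y) {
    P <- .softmax(Phi %*% t(W))
    -mean(log(pmax(P[cbind(seq_along(y), y + 1L)], 1e-12)))
}

#' Train the lightweight per-pixel segmenter
#'
#' Mini-batch Adam on the categorical cross-entropy of the softmax
#' pixel classifier. Each epoch shuffles the training slices into batches
#' of \code{batchSize} images; each image is augmented and subsampled to
#' \code{pixelsPerImage} pixels. After every epoch the validation loss is
#' evaluated on a fixed pixel subsample of the validation set; training
#' stops when it has not reached a new minimum for \code{patience}
#' consecutive epochs (or at \code{maxEpochs}), and the weights with the
#' lowest validation loss are returned. Fully reproducible under
#' \code{config$seed}.
#'
#' @param model a \code{\linkS4class{TrainableSegmenter}}.
#' @param trainSet,valSet \code{AnatomySeries} (or lists of slices) with
#'   images and labels.
#' @param config a \code{\link{trainConfig}}.
#' @return list with \code{model} (trained) and \code{history}
#'   (data.frame: epoch, train_loss, val_loss).
#' @export
trainSegmenter <- function(model, trainSet, valSet, config = trainConfig()) {
    stopifnot(is(model, "TrainableSegmenter"),
              inherits(config, "TrainConfig"))
    tr <- .asSlicePairs(trainSet)
    va <- .asSlicePairs(valSet)
    if (!length(tr) || !length(va))
        stop("training and validation sets must be non-empty")
    fs <- model@featureSpec

    withSeed(config$seed, {
        W <- matrix(rnorm(length(model@weights), 0, 0.01),
                    nrow(model@weights), ncol(model@weights))
        # fixed validation pixel subsample
        vPhi <- NULL; vy <- NULL
        nPer <- ceiling(20000 / length(va))
        for (p in va) {
            k <- min(nPer, length(p$image))
            idx <- sample.int(length(p$image), k)
            Phi <- .pixelFeatures(p$image, fs)
            vPhi <- rbind(vPhi, Phi[idx, , drop = FALSE])
            vy <- c(vy, as.vector(p$labels)[idx])
        }

        m <- W * 0; v <- W * 0; t <- 0
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        best <- Inf; bestW <- W
        hist <- data.frame(epoch = integer(), train_loss = numeric(),
                           val_loss = numeric())

        for (epoch in seq_len(config$maxEpochs)) {
            ord <- sample.int(length(tr))
            batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
            eLoss <- 0
            for (b in batches) {
                Phi <- NULL; y <- NULL
                for (i in b) {
                    p <- tr[[i]]
                    if (!is.null(config$augment))
                        p <- .augmentPair(p$image, p$labels, config$augment)
                    k <- min(config$pixelsPerImage, length(p$image))
                    idx <- sample.int(length(p$image), k)
                    F1 <- .pixelFeatures(p$image, fs)
                    Phi <- rbind(Phi, F1[idx, , drop = FALSE])
                    y <- c(y, as.vector(p$labels)[idx])
                }
                P <- .softmax(Phi %*% t(W))
                n <- length(y)
                eLoss <- eLoss +
                    -mean(log(pmax(P[cbind(seq_len(n), y + 1L)], 1e-12)))
                Y <- matrix(0, n, nLabelClasses())
                Y[cbind(seq_len(n), y + 1L)] <- 1
                G <- t(P - Y) %*% Phi / n
                t <- t + 1
                m <- b1 * m + (1 - b1) * G
                v <- b2 * v + (1 - b2) * G^2
                mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
                W <- W - config$learningRate * mh / (sqrt(vh) + eps)
            }
            vLoss <- .cceLoss(W, vPhi, vy)
            hist <- rbind(hist, data.frame(
                epoch = epoch, train_loss = eLoss / length(batches),
                val_loss = vLoss))
            if (vLoss < best) {
                best <- vLoss; bestW <- W
            }
            if (.plateauReached(hist$val_loss, config$patience)) break
        }
        out <- model
        out@weights <- bestW
        list(model = out, history = hist)
    })
}

#' Save / load a trainable segmenter
#'
#' Single-file JSON container embedding the weights, the feature
#' specification and the class list, so a saved model is self-describing.
#'
#' @param model a \code{TrainableSegmenter}.
#' @param path JSON file path.
#' @return \code{loadSegmenter}: a \code{TrainableSegmenter}.
#' @export
saveSegmenter <- function(model, path) {
    stopifnot(is(model, "TrainableSegmenter"))
    jsonlite::write_json(list(
        format = "axistack-segmenter-1",
        classes = model@classes,
        feature_spec = model@featureSpec,
        weights = model@weights), path, digits = NA, auto_unbox = TRUE,
        matrix = "rowmajor")
    invisible(path)
}

#' @rdname saveSegmenter
#' @export
loadSegmenter <- function(path) {
    d <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(d$format, "axistack-segmenter-1"))
        stop("unsupported segmenter container: ", d$format)
    fs <- list(centers = d$feature_spec$centers,
               width = d$feature_spec$width,
               iscale = d$feature_spec$iscale,
               gain = d$feature_spec$gain %||% 1)
    new("TrainableSegmenter", weights = as.matrix(d$weights),
        featureSpec = fs, classes = d$classes)
}
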