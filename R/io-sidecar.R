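# Sidecar dialect: one directory per series holding a series.json manifest,
# a 16-bit grayscale TIFF per slice image and an 8-bit PNG per label map.
# Designed so the whole pipeline is exercisable without DICOM fixtures;
# round-trips bit-exactly (images are integer-valued, 16-bit).

.sidecarSchema <- "axistack-sidecar-1"

.geometryToList <- function(g) list(
    pixel_spacing_row = g@pixelSpacingRow,
    pixel_spacing_col = g@pixelSpacingCol,
    slice_thickness = g@sliceThickness,
    slice_position = g@slicePosition,
    rows = g@rows, cols = g@cols)

.geometryFromList <- function(gl, idx) {
    need <- c("pixel_spacing_row", "pixel_spacing_col", "slice_thickness",
              "slice_position", "rows", "cols")
    miss <- setdiff(need, names(gl))
    gl <- gl[!vapply(gl, is.null, TRUE)]
    miss <- union(miss, setdiff(need, names(gl)))
    if (length(miss))
        stop("slice index ", idx, ": missing geometry field(s): ",
             paste(miss, collapse = ", "))
    SliceGeometry(gl$pixel_spacing_row, gl$pixel_spacing_col,
                  gl$slice_thickness, gl$slice_position, gl$rows, gl$cols)
}

.writeSidecar <- function(series, path) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(path)) stop("cannot create directory: ", path)
    sl <- seriesSlices(series)
    manifest <- list(schema = .sidecarSchema,
                     manufacturer = manufacturer(series))
    if (!is.na(seriesBSA(series))) manifest$bsa <- seriesBSA(series)
    if (!is.na(series@heightCm)) manifest$height_cm <- series@heightCm
    if (!is.na(series@weightKg)) manifest$weight_kg <- series@weightKg
    entries <- vector("list", length(sl))
    for (i in seq_along(sl)) {
        s <- sl[[i]]
        stem <- sprintf("slice_%03d", i - 1L)
        e <- list(geometry = .geometryToList(sliceGeometry(s)))
        img <- sliceImage(s)
        if (!is.null(img)) {
            if (any(img < 0) || any(img > 65535) ||
                any(img != round(img)))
                stop("sidecar images must be integer-valued in [0, 65535]")
            e$image <- paste0(stem, ".tif")
            tiff::writeTIFF(img / 65535, file.path(path, e$image),
                            bits.per.sample = 16L)
        }
        lab <- sliceLabels(s)
        if (!is.null(lab)) {
            e$labels <- paste0(stem, "_labels.png")
            png::writePNG(lab / 255, file.path(path, e$labels))
        }
        entries[[i]] <- e
    }
    manifest$slices <- entries
    jsonlite::write_json(manifest, file.path(path, "series.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(NULL)
}

.readSidecar <- function(path) {
    mf <- file.path(path, "series.json")
    if (!file.exists(mf)) stop("no series.json under ", path)
    manifest <- jsonlite::read_json(mf)
    if (!identical(manifest$schema, .sidecarSchema))
        stop("unsupported sidecar schema: ", manifest$schema)
    if (!length(manifest$slices)) stop("series has no slices")
    slices <- lapply(seq_along(manifest$slices), function(i) {
        e <- manifest$slices[[i]]
        geom <- .geometryFromList(e$geometry, i - 1L)
        img <- NULL
        if (!is.null(e$image)) {
            img <- tiff::readTIFF(file.path(path, e$image))
            img <- matrix(round(img * 65535), nrow(img), ncol(img))
        }
        lab <- NULL
        if (!is.null(e$labels)) {
            lab <- png::readPNG(file.path(path, e$labels))
            lab <- matrix(as.integer(round(lab * 255)), nrow(lab), ncol(lab))
        }
        AnatomySlice(image = img, labels = lab, geometry = geom)
    })
    AnatomySeries(slices,
                  manufacturer = manifest$manufacturer %||% "uncalibrated",
                  bsa = manifest$bsa %||% NA_real_,
                  heightCm = manifest$height_cm %||% NA_real_,
                  weightKg = manifest$weight_kg %||% NA_real_)
}

#' Read / write a slice series
#'
#' \code{readSeries} loads a transaxial anatomy series from disk and
#' returns its slices sorted by ascending slice position; missing optional
#' metadata stays absent (NA), never defaulted. \code{writeSeries} writes
#' a series such that reading it back reproduces images, labels and
#' geometry bit-exactly.
#'
#' Two dialects are supported: \code{"sidecar"} (a series.json manifest
#' plus one 16-bit TIFF image and one 8-bit PNG label map per slice;
#' read/write) and \code{"dicom"} (single-frame explicit-VR little-endian
#' files, uncompressed; geometry from PixelSpacing, SliceThickness,
#' ImagePositionPatient and Manufacturer; label maps are not part of the
#' DICOM dialect).
#'
#' Unknown manufacturer strings map to \code{"uncalibrated"}, for which
#' calibration is the identity.
#'
#' @param path directory holding the series.
#' @param dialect "sidecar" or "dicom".
#' @param series an \code{\linkS4class{AnatomySeries}}.
#' @return \code{readSeries}: an \code{AnatomySeries};
#'   \code{writeSeries}: invisibly NULL.
#' @export
readSeries <- function(path, dialect = c("sidecar", "dicom")) {
    dialect <- match.arg(dialect)
    if (!dir.exists(path)) stop("no such directory: ", path)
    switch(dialect, sidecar = .readSidecar(path), dicom = .readDicomDir(path))
}

#' @rdname readSeries
#' @export
writeSeries <- function(series, path, dialect = c("sidecar", "dicom")) {
    dialect <- match.arg(dialect)
    stopifnot(is(series, "AnatomySeries"))
    if (nSlices(series) == 0L) stop("cannot write an empty series")
    switch(dialect,
           sidecar = .writeSidecar(series, path),
           dicom = .writeDicomDir(series, path))
}
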