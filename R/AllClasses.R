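#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Per-slice acquisition geometry
#'
#' World-coordinate convention: pixel indices are 0-based and the world
#' position of a pixel center is \code{(index + 0.5) * spacing} in-plane;
#' the through-plane coordinate of a slice is \code{slicePosition} (mm,
#' increasing cranially). Center-of-voxel sampling keeps the trilinear
#' interpolation used in reconstruction symmetric.
#'
#' @slot pixelSpacingRow,pixelSpacingCol mm per pixel (strictly positive).
#' @slot sliceThickness slab thickness in mm (strictly positive).
#' @slot slicePosition through-plane slice-center coordinate in mm.
#' @slot rows,cols pixel counts.
#' @export
setClass("SliceGeometry", representation(
    pixelSpacingRow = "numeric",
    pixelSpacingCol = "numeric",
    sliceThickness  = "numeric",
    slicePosition   = "numeric",
    rows            = "integer",
    cols            = "integer"
), validity = function(object) {
    msg <- character()
    for (s in c("pixelSpacingRow", "pixelSpacingCol", "sliceThickness"))
        if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) ||
            slot(object, s) <= 0)
            msg <- c(msg, paste0(s, " must be a single positive number"))
    if (length(object@slicePosition) != 1L || !is.finite(object@slicePosition))
        msg <- c(msg, "slicePosition must be a single finite number")
    if (object@rows < 1L || object@cols < 1L)
        msg <- c(msg, "rows and cols must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @param pixelSpacingRow,pixelSpacingCol,sliceThickness,slicePosition,rows,cols
#'   see slots.
#' @rdname SliceGeometry-class
#' @export
SliceGeometry <- function(pixelSpacingRow, pixelSpacingCol, sliceThickness,
                          slicePosition, rows, cols) {
    new("SliceGeometry",
        pixelSpacingRow = as.numeric(pixelSpacingRow),
        pixelSpacingCol = as.numeric(pixelSpacingCol),
        sliceThickness = as.numeric(sliceThickness),
        slicePosition = as.numeric(slicePosition),
        rows = as.integer(rows), cols = as.integer(cols))
}

#' One transaxial anatomy slice
#'
#' Holds a grayscale intensity image and/or a label map together with its
#' acquisition geometry. Image matrices are oriented rows = anterior to
#' posterior, columns = right to left; intensities are non-negative
#' integers (16-bit DICOM convention). Label maps take values in the
#' nine-class vocabulary of \code{\link{labelClasses}}.
#'
#' @slot image numeric matrix or NULL.
#' @slot labels integer-valued matrix of label ids or NULL; when both image
#'   and labels are present their shapes agree.
#' @slot geometry a \code{\linkS4class{SliceGeometry}}.
#' @export
setClass("AnatomySlice", representation(
    image    = "matrixOrNULL",
    labels   = "matrixOrNULL",
    geometry = "SliceGeometry"
), validity = function(object) {
    msg <- character()
    g <- object@geometry
    for (nm in c("image", "labels")) {
        m <- slot(object, nm)
        if (!is.null(m) && (nrow(m) != g@rows || ncol(m) != g@cols))
            msg <- c(msg, paste0(nm, " shape does not match geometry rows/cols"))
    }
    if (is.null(object@image) && is.null(object@labels))
        msg <- c(msg, "slice needs an image or a label map")
    if (!is.null(object@labels) && !.validLabelValues(object@labels))
        msg <- c(msg, "labels contain values outside the 0-8 class vocabulary")
    if (length(msg)) msg else TRUE
})

#' @param image,labels,geometry see slots.
#' @rdname AnatomySlice-class
#' @export
AnatomySlice <- function(image = NULL, labels = NULL, geometry) {
    if (!is.null(labels)) storage.mode(labels) <- "integer"
    new("AnatomySlice", image = image, labels = labels, geometry = geometry)
}

#' An ordered transaxial slice series (one study)
#'
#' Slices are kept sorted by ascending \code{slicePosition}; ascending
#' position defines the z axis of all reconstructed volumes.
#'
#' @slot slices list of \code{\linkS4class{AnatomySlice}}.
#' @slot manufacturer one of "A", "B", "uncalibrated". Unknown scanner
#'   strings map to "uncalibrated", for which calibration is the identity.
#' @slot bsa body surface area in m2 (NA when unknown).
#' @slot heightCm,weightKg optional patient biometrics (NA when unknown).
#' @export
setClass("AnatomySeries", representation(
    slices       = "list",
    manufacturer = "character",
    bsa          = "numeric",
    heightCm     = "numeric",
    weightKg     = "numeric"
), prototype(manufacturer = "uncalibrated", bsa = NA_real_,
             heightCm = NA_real_, weightKg = NA_real_),
validity = function(object) {
    msg <- character()
    if (!all(vapply(object@slices, is, TRUE, "AnatomySlice")))
        msg <- c(msg, "all slices must be AnatomySlice objects")
    if (!(object@manufacturer %in% c("A", "B", "uncalibrated")))
        msg <- c(msg, "manufacturer must be 'A', 'B' or 'uncalibrated'")
    pos <- vapply(object@slices, function(s) s@geometry@slicePosition, 0)
    if (length(pos) > 1L) {
        if (any(duplicated(pos)))
            msg <- c(msg, "duplicate slice positions")
        else if (is.unsorted(pos))
            msg <- c(msg, "slices must be sorted by ascending slicePosition")
    }
    if (length(msg)) msg else TRUE
})

#' @param slices,manufacturer,bsa,heightCm,weightKg see slots. Slices given
#'   in any order are sorted by ascending slice position.
#' @rdname AnatomySeries-class
#' @export
AnatomySeries <- function(slices, manufacturer = "uncalibrated",
                          bsa = NA_real_, heightCm = NA_real_,
                          weightKg = NA_real_) {
    pos <- vapply(slices, function(s) s@geometry@slicePosition, 0)
    if (any(duplicated(pos)))
        stop("duplicate slice position(s): ",
             paste(unique(pos[duplicated(pos)]), collapse = ", "))
    new("AnatomySeries", slices = slices[order(pos)],
        manufacturer = manufacturer, bsa = as.numeric(bsa),
        heightCm = as.numeric(heightCm), weightKg = as.numeric(weightKg))
}

#' Fractional per-class occupancy volume
#'
#' The reconstructed 3D thorax model: for each of the nine classes a grid
#' of fractional occupancy in [0, 1]; per-voxel occupancies sum to 1.
#' Array layout is [y, x, z, class] with class index = label id + 1.
#'
#' @slot occupancy 4D numeric array.
#' @slot voxelSize (dy, dx, dz) in mm.
#' @slot origin world-mm coordinate of the corner of voxel [1,1,1]
#'   (voxel centers sit half a voxel inside).
#' @export
setClass("LabelVolume", representation(
    occupancy = "array",
    voxelSize = "numeric",
    origin    = "numeric"
), validity = function(object) {
    msg <- character()
    d <- dim(object@occupancy)
    if (length(d) != 4L || d[4] != nLabelClasses())
        msg <- c(msg, "occupancy must be [y, x, z, 9]")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
        msg <- c(msg, "voxelSize must be 3 positive numbers (dy, dx, dz)")
    if (length(object@origin) != 3L)
        msg <- c(msg, "origin must have length 3")
    if (!length(msg)) {
        rng <- range(object@occupancy)
        if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
            msg <- c(msg, "occupancies must lie in [0, 1]")
        tot <- rowSums(matrix(object@occupancy, prod(d[1:3]), d[4]))
        if (max(abs(tot - 1)) > 1e-6)
            msg <- c(msg, "per-voxel occupancies must sum to 1")
    }
    if (length(msg)) msg else TRUE
})

#' @param occupancy,voxelSize,origin see slots.
#' @rdname LabelVolume-class
#' @export
LabelVolume <- function(occupancy, voxelSize, origin = c(0, 0, 0)) {
    new("LabelVolume", occupancy = occupancy,
        voxelSize = as.numeric(voxelSize), origin = as.numeric(origin))
}

.measureNamesRaw <- c("lvedv_ml", "rvedv_ml", "lv_wall_volume_ml",
                      "lv_mass_g", "asc_aorta_diameter_mm",
                      "pleural_fluid_ml")
.measureNamesIndexed <- c("lvedvi", "rvedvi", "lvmi", "asc_aorta_i",
                          "mass_volume_ratio")

#' Raw and BSA-indexed study measurements
#'
#' Raw measures carry ml / g / mm units; indexed measures are raw divided
#' by body surface area (ml/m2, g/m2, mm/m2); the mass:volume ratio is
#' LVMi / LVEDVi (dimensionless). For uncalibrated measures
#' indexed * bsa reproduces raw to 1e-9; once a per-manufacturer linear
#' calibration has been applied the indexed values are decoupled from the
#' raw ones and \code{calibrated} is TRUE.
#'
#' @slot raw named numeric: lvedv_ml, rvedv_ml, lv_wall_volume_ml,
#'   lv_mass_g, asc_aorta_diameter_mm, pleural_fluid_ml.
#' @slot indexed named numeric: lvedvi, rvedvi, lvmi, asc_aorta_i,
#'   mass_volume_ratio. asc_aorta_i and the diameter may be NA when the
#'   ascending aorta is not measurable.
#' @slot bsa body surface area in m2.
#' @slot calibrated logical flag.
#' @export
setClass("StudyMeasures", representation(
    raw        = "numeric",
    indexed    = "numeric",
    bsa        = "numeric",
    calibrated = "logical"
), prototype(calibrated = FALSE), validity = function(object) {
    msg <- character()
    if (!setequal(names(object@raw), .measureNamesRaw))
        msg <- c(msg, "raw must be named: ",
                 paste(.measureNamesRaw, collapse = ", "))
    if (!setequal(names(object@indexed), .measureNamesIndexed))
        msg <- c(msg, "indexed must be named: ",
                 paste(.measureNamesIndexed, collapse = ", "))
    if (length(object@bsa) != 1L || is.na(object@bsa) || object@bsa <= 0)
        msg <- c(msg, "bsa must be a single positive number")
    if (!length(msg) && !object@calibrated) {
        chk <- c(lvedvi = "lvedv_ml", rvedvi = "rvedv_ml",
                 lvmi = "lv_mass_g", asc_aorta_i = "asc_aorta_diameter_mm")
        for (i in names(chk)) {
            iv <- object@indexed[[i]]; rv <- object@raw[[chk[[i]]]]
            if (is.na(iv) != is.na(rv))
                msg <- c(msg, paste0(i, " and ", chk[[i]],
                                     " disagree on missingness"))
            else if (!is.na(iv) && abs(iv * object@bsa - rv) > 1e-9)
                msg <- c(msg, paste0(i, " * bsa != ", chk[[i]]))
        }
        mvr <- object@indexed[["mass_volume_ratio"]]
        lvedvi <- object@indexed[["lvedvi"]]
        if (!is.na(mvr) && lvedvi > 0 &&
            abs(mvr - object@indexed[["lvmi"]] / lvedvi) > 1e-9)
            msg <- c(msg, "mass_volume_ratio != lvmi / lvedvi")
    }
    if (length(msg)) msg else TRUE
})

#' @param raw,indexed,bsa,calibrated see slots.
#' @rdname StudyMeasures-class
#' @export
StudyMeasures <- function(raw, indexed, bsa, calibrated = FALSE) {
    new("StudyMeasures", raw = raw[.measureNamesRaw],
        indexed = indexed[.measureNamesIndexed],
        bsa = as.numeric(bsa), calibrated = calibrated)
}

#' Per-manufacturer linear calibration model
#'
#' One ordinary-least-squares (slope, intercept) pair per (manufacturer,
#' measure), mapping the raw pipeline value onto the clinically reported
#' ("final") value; absorbs the systematic acquisition bias between
#' scanner manufacturers.
#'
#' @slot table data.frame with columns manufacturer, measure, slope,
#'   intercept, n, r_squared.
#' @export
setClass("CalibrationModel", representation(table = "data.frame"),
validity = function(object) {
    need <- c("manufacturer", "measure", "slope", "intercept", "n",
              "r_squared")
    msg <- character()
    if (!all(need %in% names(object@table)))
        msg <- c(msg, paste("table needs columns:",
                            paste(need, collapse = ", ")))
    else {
        if (any(object@table$n < 3))
            msg <- c(msg, "each calibration entry must be fitted on >= 3 points")
        if (any(duplicated(object@table[c("manufacturer", "measure")])))
            msg <- c(msg, "duplicate (manufacturer, measure) entries")
    }
    if (length(msg)) msg else TRUE
})

#' @param table see slot.
#' @rdname CalibrationModel-class
#' @export
CalibrationModel <- function(table = data.frame(
        manufacturer = character(), measure = character(),
        slope = numeric(), intercept = numeric(), n = integer(),
        r_squared = numeric(), stringsAsFactors = FALSE)) {
    new("CalibrationModel", table = table)
}

# ---- show methods -----------------------------------------------------

setMethod("show", "SliceGeometry", function(object) {
    cat(sprintf(
        "SliceGeometry: %d x %d px, spacing %.3g x %.3g mm, thickness %.3g mm, z = %.3g mm\n",
        object@rows, object@cols, object@pixelSpacingRow,
        object@pixelSpacingCol, object@sliceThickness,
        object@slicePosition))
})

setMethod("show", "AnatomySlice", function(object) {
    cat(sprintf("AnatomySlice [%d x %d] image: %s, labels: %s, z = %.3g mm\n",
                object@geometry@rows, object@geometry@cols,
                if (is.null(object@image)) "absent" else "present",
                if (is.null(object@labels)) "absent" else "present",
                object@geometry@slicePosition))
})

setMethod("show", "AnatomySeries", function(object) {
    pos <- vapply(object@slices, function(s) s@geometry@slicePosition, 0)
    cat(sprintf("AnatomySeries: %d slice(s), manufacturer %s, BSA %s m2\n",
                length(object@slices), object@manufacturer,
                format(object@bsa)))
    if (length(pos))
        cat(sprintf("  z range: %.3g .. %.3g mm\n", min(pos), max(pos)))
})

setMethod("show", "LabelVolume", function(object) {
    d <- dim(object@occupancy)
    cat(sprintf("LabelVolume: %d x %d x %d voxels of %.3g x %.3g x %.3g mm\n",
                d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
                object@voxelSize[3]))
    v <- vapply(0:8, function(k) structureVolume(object, k), 0)
    present <- which(v > 1e-9) - 1L
    cat("  non-empty classes:",
        paste(sprintf("%s (%.1f ml)", labelName(present), v[present + 1L]),
              collapse = ", "), "\n")
})

setMethod("show", "StudyMeasures", function(object) {
    cat(sprintf("StudyMeasures (%s), BSA %.3f m2\n",
                if (object@calibrated) "calibrated" else "raw",
                object@bsa))
    cat(sprintf("  LVEDVi %.1f  RVEDVi %.1f ml/m2 | LVMi %.1f g/m2 | MVR %.2f | AAo_i %s mm/m2 | effusion %.1f ml\n",
                object@indexed[["lvedvi"]], object@indexed[["rvedvi"]],
                object@indexed[["lvmi"]],
                object@indexed[["mass_volume_ratio"]],
                format(round(object@indexed[["asc_aorta_i"]], 2)),
                object@raw[["pleural_fluid_ml"]]))
})

setMethod("show", "CalibrationModel", function(object) {
    cat("CalibrationModel with", nrow(object@table), "entries\n")
    if (nrow(object@table)) print(object@table, row.names = FALSE)
})

# ---- accessors --------------------------------------------------------

#' Accessors for series and slice containers
#'
#' @param x an \code{AnatomySeries}, \code{AnatomySlice} or
#'   \code{LabelVolume}.
#' @param i slice index.
#' @return \code{seriesSlices}: list of slices; \code{getSlice}: one slice;
#'   \code{sliceImage}/\code{sliceLabels}: matrices or NULL;
#'   \code{sliceGeometry}: a \code{SliceGeometry}; \code{slicePositions}:
#'   numeric vector; \code{manufacturer}/\code{seriesBSA}: scalars;
#'   \code{voxelSize}/\code{volumeOrigin}: numeric length-3;
#'   \code{occupancyArray}: the 4D array.
#' @export
seriesSlices <- function(x) x@slices

#' @rdname seriesSlices
#' @export
getSlice <- function(x, i) x@slices[[i]]

#' @rdname seriesSlices
#' @export
nSlices <- function(x) length(x@slices)

#' @rdname seriesSlices
#' @export
sliceImage <- function(x) x@image

#' @rdname seriesSlices
#' @export
sliceLabels <- function(x) x@labels

#' @rdname seriesSlices
#' @export
sliceGeometry <- function(x) x@geometry

#' @rdname seriesSlices
#' @export
slicePositions <- function(x)
    vapply(x@slices, function(s) s@geometry@slicePosition, 0)

#' @rdname seriesSlices
#' @export
manufacturer <- function(x) x@manufacturer

#' @rdname seriesSlices
#' @export
seriesBSA <- function(x) x@bsa

#' @rdname seriesSlices
#' @export
voxelSize <- function(x) x@voxelSize

#' @rdname seriesSlices
#' @export
volumeOrigin <- function(x) x@origin

#' @rdname seriesSlices
#' @export
occupancyArray <- function(x) x@occupancy

#' @rdname seriesSlices
#' @export
rawMeasures <- function(x) x@raw

#' @rdname seriesSlices
#' @export
indexedMeasures <- function(x) x@indexed

#' @rdname seriesSlices
#' @export
isCalibrated <- function(x) x@calibrated

#' @rdname seriesSlices
#' @export
calibrationTable <- function(x) x@table
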