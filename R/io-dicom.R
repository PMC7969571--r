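# Minimal single-frame DICOM reader/writer: explicit VR little endian,
# uncompressed MONOCHROME2 16-bit pixels. Covers exactly the tags the
# pipeline needs (PixelSpacing, SliceThickness, ImagePositionPatient,
# Manufacturer, Rows/Columns, PatientSize/Weight, PixelData); multi-frame,
# oblique and compressed transfer syntaxes are out of scope.

.dcmExplicitLE <- "1.2.840.10008.1.2.1"
.longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcmElement <- function(group, element, vr, value) {
    hdr <- writeBin(as.integer(c(group, element)), raw(), size = 2,
                    endian = "little")
    if (vr %in% c("CS", "DS", "LO", "UI", "SH", "PN")) {
        v <- charToRaw(as.character(value))
        if (length(v) %% 2L) v <- c(v, if (vr == "UI") as.raw(0) else
                                        charToRaw(" "))
        c(hdr, charToRaw(vr),
          writeBin(length(v), raw(), size = 2, endian = "little"), v)
    } else if (vr == "US") {
        v <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
        c(hdr, charToRaw(vr),
          writeBin(length(v), raw(), size = 2, endian = "little"), v)
    } else if (vr == "UL") {
        v <- writeBin(as.integer(value), raw(), size = 4, endian = "little")
        c(hdr, charToRaw(vr),
          writeBin(length(v), raw(), size = 2, endian = "little"), v)
    } else if (vr == "OW") {
        c(hdr, charToRaw(vr), as.raw(c(0, 0)),
          writeBin(length(value), raw(), size = 4, endian = "little"),
          value)
    } else stop("unhandled VR: ", vr)
}

.writeDicomSlice <- function(slice, series, file) {
    img <- sliceImage(slice)
    if (is.null(img)) stop("DICOM dialect requires an image on every slice")
    if (any(img < 0) || any(img > 65535) || any(img != round(img)))
        stop("DICOM images must be integer-valued in [0, 65535]")
    g <- sliceGeometry(slice)
    ds <- function(x) paste(format(x, digits = 15, scientific = FALSE,
                                   trim = TRUE), collapse = "\\")
    # pixel data: row-major uint16, two's-complement trick for writeBin
    v <- as.integer(t(img))
    v[v > 32767L] <- v[v > 32767L] - 65536L
    px <- writeBin(v, raw(), size = 2, endian = "little")

    body <- c(
        .dcmElement(0x0008, 0x0060, "CS", "MR"),
        .dcmElement(0x0008, 0x0070, "LO", manufacturer(series)),
        if (!is.na(series@heightCm))
            .dcmElement(0x0010, 0x1020, "DS", ds(series@heightCm / 100)),
        if (!is.na(series@weightKg))
            .dcmElement(0x0010, 0x1030, "DS", ds(series@weightKg)),
        .dcmElement(0x0018, 0x0050, "DS", ds(g@sliceThickness)),
        .dcmElement(0x0020, 0x0032, "DS", ds(c(0, 0, g@slicePosition))),
        .dcmElement(0x0028, 0x0002, "US", 1L),
        .dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
        .dcmElement(0x0028, 0x0010, "US", g@rows),
        .dcmElement(0x0028, 0x0011, "US", g@cols),
        .dcmElement(0x0028, 0x0030, "DS",
                    ds(c(g@pixelSpacingRow, g@pixelSpacingCol))),
        .dcmElement(0x0028, 0x0100, "US", 16L),
        .dcmElement(0x0028, 0x0101, "US", 16L),
        .dcmElement(0x0028, 0x0102, "US", 15L),
        .dcmElement(0x0028, 0x0103, "US", 0L),
        .dcmElement(0x7FE0, 0x0010, "OW", px))

    tsui <- .dcmElement(0x0002, 0x0010, "UI", .dcmExplicitLE)
    meta <- c(.dcmElement(0x0002, 0x0000, "UL", length(tsui)), tsui)
    con <- file(file, "wb")
    on.exit(close(con))
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, body), con)
}

.readDicomFile <- function(file) {
    buf <- readBin(file, raw(), file.size(file))
    if (length(buf) < 160 ||
        rawToChar(buf[129:132]) != "DICM")
        stop("not a DICOM file (missing DICM marker): ", file)
    pos <- 133L
    u16 <- function(at) sum(as.integer(buf[at + 0:1]) * c(1, 256))
    u32 <- function(at) sum(as.integer(buf[at + 0:3]) * 256^(0:3))
    fields <- list()
    while (pos + 7L <= length(buf)) {
        group <- u16(pos); element <- u16(pos + 2L)
        vr <- rawToChar(buf[pos + 4:5])
        if (!grepl("^[A-Z]{2}$", vr))
            stop("implicit-VR or corrupt DICOM not supported: ", file)
        if (vr %in% .longVRs) {
            len <- u32(pos + 8L); vstart <- pos + 12L
        } else {
            len <- u16(pos + 6L); vstart <- pos + 8L
        }
        val <- buf[vstart + seq_len(len) - 1L]
        key <- sprintf("%04X,%04X", group, element)
        fields[[key]] <- list(vr = vr, raw = val)
        pos <- vstart + len
        if (group == 0x7FE0 && element == 0x0010) break
    }
    getStr <- function(key) {
        f <- fields[[key]]
        if (is.null(f)) return(NULL)
        trimws(rawToChar(f$raw))
    }
    getDS <- function(key) {
        s <- getStr(key)
        if (is.null(s)) return(NULL)
        as.numeric(strsplit(s, "\\\\")[[1]])
    }
    getUS <- function(key) {
        f <- fields[[key]]
        if (is.null(f)) return(NULL)
        readBin(f$raw, "integer", size = 2, signed = FALSE,
                endian = "little")
    }
    list(manufacturer = getStr("0008,0070"),
         heightM = getDS("0010,1020"), weightKg = getDS("0010,1030"),
         thickness = getDS("0018,0050"), ipp = getDS("0020,0032"),
         rows = getUS("0028,0010"), cols = getUS("0028,0011"),
         spacing = getDS("0028,0030"),
         pixels = fields[["7FE0,0010"]]$raw)
}

.mapManufacturer <- function(s) {
    if (is.null(s) || !nzchar(s)) return("uncalibrated")
    if (s %in% c("A", "B")) s else "uncalibrated"
}

.readDicomDir <- function(path) {
    files <- sort(list.files(path, pattern = "\\.dcm$", full.names = TRUE))
    if (!length(files)) stop("no .dcm files under ", path)
    height <- NA_real_; weight <- NA_real_; manu <- "uncalibrated"
    slices <- lapply(seq_along(files), function(i) {
        d <- .readDicomFile(files[i])
        idx <- i - 1L
        if (is.null(d$spacing) || length(d$spacing) != 2L)
            stop("slice index ", idx, ": missing PixelSpacing (",
                 basename(files[i]), ")")
        if (is.null(d$thickness))
            stop("slice index ", idx, ": missing slice_thickness (",
                 basename(files[i]), ")")
        if (is.null(d$ipp) || length(d$ipp) < 3L)
            stop("slice index ", idx, ": missing ImagePositionPatient (",
                 basename(files[i]), ")")
        if (is.null(d$rows) || is.null(d$cols) || is.null(d$pixels))
            stop("slice index ", idx, ": missing pixel data or dimensions")
        v <- readBin(d$pixels, "integer", n = d$rows * d$cols, size = 2,
                     signed = FALSE, endian = "little")
        img <- t(matrix(v, d$cols, d$rows))    # stored row-major
        if (!is.null(d$manufacturer)) manu <<- .mapManufacturer(d$manufacturer)
        if (!is.null(d$heightM)) height <<- d$heightM * 100
        if (!is.null(d$weightKg)) weight <<- d$weightKg
        AnatomySlice(image = img,
                     geometry = SliceGeometry(d$spacing[1], d$spacing[2],
                                              d$thickness, d$ipp[3],
                                              d$rows, d$cols))
    })
    AnatomySeries(slices, manufacturer = manu, heightCm = height,
                  weightKg = weight)
}

.writeDicomDir <- function(series, path) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(path)) stop("cannot create directory: ", path)
    sl <- seriesSlices(series)
    for (i in seq_along(sl))
        .writeDicomSlice(sl[[i]], series,
                         file.path(path, sprintf("slice_%03d.dcm", i - 1L)))
    invisible(NULL)
}
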