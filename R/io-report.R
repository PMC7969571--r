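.reportSchema <- "axistack-report-1"

#' Write / read a machine-readable study report
#'
#' The report JSON carries a stable schema version, the raw and (when
#' applicable) calibrated BSA-indexed values, one boolean per diagnostic
#' flag plus \code{abnormal_any}, and provenance: the thresholds used and
#' a calibration model identifier. Numbers round-trip to full double
#' precision.
#'
#' @param measures a \code{\linkS4class{StudyMeasures}}.
#' @param flags named logical vector as returned by \code{\link{diagnose}}.
#' @param path output JSON file.
#' @param thresholds the \code{\linkS4class{DiagnosticThresholds}} the
#'   flags were computed with (recorded as provenance).
#' @param calibrationId free-text identifier of the calibration model
#'   applied ("none" for raw measures).
#' @return \code{writeReport}: invisibly the report list;
#'   \code{readReport}: the parsed report list.
#' @export
writeReport <- function(measures, flags, path, thresholds = NULL,
                        calibrationId = "none") {
    stopifnot(is(measures, "StudyMeasures"), is.logical(flags))
    doc <- list(
        schema_version = .reportSchema,
        bsa_m2 = measures@bsa,
        calibrated = isCalibrated(measures),
        raw = as.list(rawMeasures(measures)),
        indexed = as.list(indexedMeasures(measures)),
        flags = c(as.list(flags),
                  list(abnormal_any = any(flags, na.rm = TRUE))),
        provenance = list(
            thresholds = if (is.null(thresholds)) NULL else
                thresholdsAsList(thresholds),
            calibration_model = calibrationId))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
    invisible(doc)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
    doc <- jsonlite::read_json(path)
    if (!identical(doc$schema_version, .reportSchema))
        stop("unsupported report schema: ", doc$schema_version)
    doc
}
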