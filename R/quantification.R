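#' Body surface area from height and weight
#'
#' Mosteller by default: sqrt(height_cm x weight_kg / 3600); Du Bois
#' (0.007184 h^0.725 w^0.425) available as an alternative convention.
#'
#' @param heightCm,weightKg positive numerics.
#' @param formula "mosteller" or "dubois".
#' @return BSA in m2.
#' @examples
#' bsa(180, 80)  # 2.0
#' @export
bsa <- function(heightCm, weightKg, formula = c("mosteller", "dubois")) {
    formula <- match.arg(formula)
    if (any(heightCm <= 0) || any(weightKg <= 0))
        stop("height and weight must be positive")
    switch(formula,
           mosteller = sqrt(heightCm * weightKg / 3600),
           dubois = 0.007184 * heightCm^0.725 * weightKg^0.425)
}

#' Ascending aortic diameter from the 3D model
#'
#' The single aorta class does not separate ascending from descending
#' aorta, so the ascending component is identified geometrically: on each
#' axial plane where the (argmax-rendered) aorta mask splits into at least
#' two connected components, the most anterior component (smallest
#' centroid row) is taken as ascending aorta and its equivalent-circle
#' diameter is 2 sqrt(area / pi). The study value is the maximum over
#' qualifying planes. Planes where the aorta forms fewer than two
#' components do not qualify; if no plane qualifies the diameter is not
#' measurable and NA is returned (distinct from 0).
#'
#' @param volume a \code{\linkS4class{LabelVolume}}.
#' @return diameter in mm, or NA_real_ when not measurable.
#' @export
ascendingAortaDiameter <- function(volume) {
    lab <- argmaxVolume(volume)
    vs <- voxelSize(volume)
    aid <- labelId("aorta")
    best <- NA_real_
    for (j in seq_len(dim(lab)[3])) {
        mask <- lab[, , j] == aid
        if (!any(mask)) next
        cc <- EBImage::bwlabel(EBImage::Image(mask * 1))
        cc <- EBImage::imageData(cc)
        ncomp <- max(cc)
        if (ncomp < 2) next
        # most anterior component = smallest mean row index
        meanRow <- vapply(seq_len(ncomp),
                          function(k) mean(row(cc)[cc == k]), 0)
        k <- which.min(meanRow)
        area <- sum(cc == k) * vs[1] * vs[2]
        d <- 2 * sqrt(area / pi)
        if (is.na(best) || d > best) best <- d
    }
    best
}

#' Derive raw and BSA-indexed study measures from the 3D model
#'
#' LVEDV and RVEDV are the LV/RV cavity volumes; LV mass is the LV wall
#' volume times the 1.05 g/ml myocardial density convention; pleural fluid
#' is the pleural-effusion class volume; the ascending aortic diameter
#' comes from \code{\link{ascendingAortaDiameter}}. Indexed values divide
#' by BSA; the mass:volume ratio is LVMi / LVEDVi.
#'
#' @param volume a \code{LabelVolume}.
#' @param bsa body surface area in m2, > 0.
#' @return a \code{\linkS4class{StudyMeasures}} (uncalibrated).
#' @export
deriveMeasures <- function(volume, bsa) {
    if (length(bsa) != 1L || is.na(bsa) || bsa <= 0)
        stop("bsa must be a single positive number")
    lvedv <- structureVolume(volume, "lv_cavity")
    rvedv <- structureVolume(volume, "rv_cavity")
    wall <- structureVolume(volume, "lv_wall")
    mass <- wall * 1.05
    eff <- structureVolume(volume, "pleural_effusion")
    aad <- ascendingAortaDiameter(volume)
    raw <- c(lvedv_ml = lvedv, rvedv_ml = rvedv,
             lv_wall_volume_ml = wall, lv_mass_g = mass,
             asc_aorta_diameter_mm = aad, pleural_fluid_ml = eff)
    lvedvi <- lvedv / bsa
    indexed <- c(lvedvi = lvedvi, rvedvi = rvedv / bsa,
                 lvmi = mass / bsa, asc_aorta_i = aad / bsa,
                 mass_volume_ratio = if (lvedvi > 0)
                     (mass / bsa) / lvedvi else NA_real_)
    StudyMeasures(raw, indexed, bsa)
}

# the indexed measures the per-manufacturer regression is fitted for
.calibratedMeasures <- c("lvedvi", "rvedvi", "lvmi", "mass_volume_ratio",
                         "asc_aorta_i")

#' Fit one per-manufacturer calibration entry
#'
#' Ordinary least squares of the clinically reported ("final") value on
#' the raw pipeline value, fitted separately per scanner manufacturer and
#' measure; stored with n and R-squared.
#'
#' @param raw,final numeric vectors of paired values (>= 3 pairs).
#' @param manufacturer "A" or "B".
#' @param measure one of lvedvi, rvedvi, lvmi, mass_volume_ratio,
#'   asc_aorta_i.
#' @param model an existing \code{\linkS4class{CalibrationModel}} to add
#'   the entry to.
#' @return the updated \code{CalibrationModel}.
#' @export
fitCalibration <- function(raw, final, manufacturer, measure,
                           model = CalibrationModel()) {
    stopifnot(length(raw) == length(final), length(raw) >= 3L,
              measure %in% .calibratedMeasures,
              manufacturer %in% c("A", "B"))
    if (var(raw) == 0)
        stop("zero variance in raw values; cannot fit a calibration line")
    fit <- stats::lm(final ~ raw)
    co <- stats::coef(fit)
    sst <- sum((final - mean(final))^2)
    r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
    tab <- calibrationTable(model)
    tab <- tab[!(tab$manufacturer == manufacturer &
                 tab$measure == measure), , drop = FALSE]
    tab <- rbind(tab, data.frame(
        manufacturer = manufacturer, measure = measure,
        slope = unname(co[2]), intercept = unname(co[1]),
        n = length(raw), r_squared = r2, stringsAsFactors = FALSE))
    CalibrationModel(tab)
}

#' Apply a per-manufacturer calibration to study measures
#'
#' Maps each of the five indexed measures through its fitted (slope,
#' intercept). The "uncalibrated" manufacturer is the identity. Missing
#' entries for a requested measure raise an error naming the measures.
#'
#' @param measures an uncalibrated \code{StudyMeasures}.
#' @param model a \code{CalibrationModel}.
#' @param manufacturer "A", "B" or "uncalibrated".
#' @param recomputeMvr recompute the mass:volume ratio from the calibrated
#'   LVMi and LVEDVi instead of calibrating it directly (the default
#'   calibrates it directly, as one of the fitted models).
#' @return a calibrated \code{StudyMeasures}.
#' @export
applyCalibration <- function(measures, model, manufacturer,
                             recomputeMvr = FALSE) {
    stopifnot(is(measures, "StudyMeasures"), is(model, "CalibrationModel"))
    idx <- indexedMeasures(measures)
    if (manufacturer == "uncalibrated")
        return(StudyMeasures(rawMeasures(measures), idx, measures@bsa,
                             calibrated = TRUE))
    tab <- calibrationTable(model)
    tab <- tab[tab$manufacturer == manufacturer, , drop = FALSE]
    want <- if (recomputeMvr)
        setdiff(.calibratedMeasures, "mass_volume_ratio")
    else .calibratedMeasures
    miss <- setdiff(want, tab$measure)
    if (length(miss))
        stop("no calibration entry for manufacturer ", manufacturer,
             ", measure(s): ", paste(miss, collapse = ", "))
    out <- idx
    for (msr in want) {
        e <- tab[tab$measure == msr, ]
        out[[msr]] <- e$slope * idx[[msr]] + e$intercept
    }
    if (recomputeMvr)
        out[["mass_volume_ratio"]] <-
            if (out[["lvedvi"]] > 0) out[["lvmi"]] / out[["lvedvi"]]
            else NA_real_
    StudyMeasures(rawMeasures(measures), out, measures@bsa,
                  calibrated = TRUE)
}

#' Persist / restore a calibration model as JSON
#'
#' The JSON is keyed by (manufacturer, measure) and carries slope,
#' intercept, n and R-squared per entry.
#'
#' @param model a \code{CalibrationModel}.
#' @param path JSON file.
#' @return \code{loadCalibration}: a \code{CalibrationModel}.
#' @export
saveCalibration <- function(model, path) {
    stopifnot(is(model, "CalibrationModel"))
    jsonlite::write_json(list(format = "axistack-calibration-1",
                              entries = calibrationTable(model)),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname saveCalibration
#' @export
loadCalibration <- function(path) {
    d <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(d$format, "axistack-calibration-1"))
        stop("unsupported calibration container: ", d$format)
    CalibrationModel(as.data.frame(d$entries))
}

#' Diagnostic cut-offs
#'
#' Published BSA-indexed abnormality cut-offs: LVEDVi > 94 ml/m2 (LV
#' dilatation), RVEDVi > 98 ml/m2 (RV dilatation), LVMi > 83.5 g/m2 (LV
#' hypertrophy), mass:volume ratio > 0.84. All comparisons are strict.
#' No published indexed cut-off exists for the ascending aortic diameter
#' or for pleural fluid volume, so \code{aortaIMax} (mm/m2) and
#' \code{effusionMlMin} (ml) must be supplied by the caller; the package's
#' phantom tests use 17 mm/m2 and 50 ml.
#'
#' @slot lvedviMax,rvedviMax,lvmiMax,mvrMax,aortaIMax,effusionMlMin
#'   strictly positive thresholds.
#' @export
setClass("DiagnosticThresholds", representation(
    lvedviMax = "numeric", rvedviMax = "numeric", lvmiMax = "numeric",
    mvrMax = "numeric", aortaIMax = "numeric", effusionMlMin = "numeric"),
    validity = function(object) {
        v <- c(object@lvedviMax, object@rvedviMax, object@lvmiMax,
               object@mvrMax, object@aortaIMax, object@effusionMlMin)
        if (any(is.na(v)) || any(v <= 0))
            return("all thresholds must be strictly positive numbers")
        TRUE
    })

#' @param aortaIMax,effusionMlMin required configurable cut-offs.
#' @param lvedviMax,rvedviMax,lvmiMax,mvrMax published defaults.
#' @rdname DiagnosticThresholds-class
#' @export
diagnosticThresholds <- function(aortaIMax, effusionMlMin,
                                 lvedviMax = 94, rvedviMax = 98,
                                 lvmiMax = 83.5, mvrMax = 0.84) {
    new("DiagnosticThresholds", lvedviMax = lvedviMax,
        rvedviMax = rvedviMax, lvmiMax = lvmiMax, mvrMax = mvrMax,
        aortaIMax = aortaIMax, effusionMlMin = effusionMlMin)
}

#' @param x a \code{DiagnosticThresholds}.
#' @rdname DiagnosticThresholds-class
#' @export
thresholdsAsList <- function(x) list(
    lvedvi_max = x@lvedviMax, rvedvi_max = x@rvedviMax,
    lvmi_max = x@lvmiMax, mvr_max = x@mvrMax,
    aorta_i_max = x@aortaIMax, effusion_ml_min = x@effusionMlMin)

setMethod("show", "DiagnosticThresholds", function(object) {
    cat("DiagnosticThresholds:",
        sprintf("LVEDVi > %g, RVEDVi > %g, LVMi > %g, MVR > %g, AAo_i > %g, effusion > %g ml\n",
                object@lvedviMax, object@rvedviMax, object@lvmiMax,
                object@mvrMax, object@aortaIMax, object@effusionMlMin))
})

#' Classify a study against the diagnostic cut-offs
#'
#' Each flag is true iff its (calibrated) measure strictly exceeds its
#' threshold. A non-measurable ascending aorta (NA) yields
#' \code{aorta_dilated = FALSE}.
#'
#' @param measures a calibrated (or raw) \code{StudyMeasures}.
#' @param thresholds a \code{\linkS4class{DiagnosticThresholds}}.
#' @return named logical vector: lv_dilated, rv_dilated, lv_hypertrophy,
#'   raised_mvr, aorta_dilated, pleural_effusion.
#' @export
diagnose <- function(measures, thresholds) {
    stopifnot(is(measures, "StudyMeasures"),
              is(thresholds, "DiagnosticThresholds"))
    idx <- indexedMeasures(measures)
    raw <- rawMeasures(measures)
    aao <- idx[["asc_aorta_i"]]
    c(lv_dilated = unname(idx[["lvedvi"]] > thresholds@lvedviMax),
      rv_dilated = unname(idx[["rvedvi"]] > thresholds@rvedviMax),
      lv_hypertrophy = unname(idx[["lvmi"]] > thresholds@lvmiMax),
      raised_mvr = unname(idx[["mass_volume_ratio"]] > thresholds@mvrMax),
      aorta_dilated = if (is.na(aao)) FALSE else
          unname(aao > thresholds@aortaIMax),
      pleural_effusion = unname(raw[["pleural_fluid_ml"]] >
                                thresholds@effusionMlMin))
}
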