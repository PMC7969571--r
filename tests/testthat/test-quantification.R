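test_that("Mosteller BSA matches closed-form values", {
    expect_equal(bsa(170, 70), sqrt(11900 / 3600), tolerance = 1e-12)
    expect_equal(round(bsa(170, 70), 4), 1.8181)
    expect_equal(bsa(180, 80), 2.0)
    expect_equal(bsa(100, 36), 1.0)
    expect_error(bsa(-170, 70), "positive")
    # Du Bois alternative available
    expect_equal(bsa(180, 80, "dubois"),
                 0.007184 * 180^0.725 * 80^0.425, tolerance = 1e-12)
})

test_that("derived measures index correctly and use the 1.05 g/ml convention", {
    ph <- coarsePhantom("normal")
    ser <- slicePhantom(ph, 4, 0, 2)
    vol <- assembleVolume(ser)
    ms <- deriveMeasures(vol, 2.0)
    raw <- rawMeasures(ms); idx <- indexedMeasures(ms)
    expect_equal(raw[["lv_mass_g"]], raw[["lv_wall_volume_ml"]] * 1.05)
    expect_equal(idx[["lvedvi"]] * 2.0, raw[["lvedv_ml"]],
                 tolerance = 1e-9)
    expect_equal(idx[["lvmi"]] * 2.0, raw[["lv_mass_g"]], tolerance = 1e-9)
    expect_equal(idx[["mass_volume_ratio"]],
                 idx[["lvmi"]] / idx[["lvedvi"]], tolerance = 1e-9)
    expect_error(deriveMeasures(vol, 0), "positive")
})

test_that("indexing consistency holds on randomized measures", {
    set.seed(4)
    for (k in 1:50) {
        b <- runif(1, 1.4, 2.4)
        lvedv <- runif(1, 60, 260); rvedv <- runif(1, 60, 260)
        wall <- runif(1, 50, 220); aad <- runif(1, 18, 50)
        raw <- c(lvedv_ml = lvedv, rvedv_ml = rvedv,
                 lv_wall_volume_ml = wall, lv_mass_g = wall * 1.05,
                 asc_aorta_diameter_mm = aad,
                 pleural_fluid_ml = runif(1, 0, 300))
        idx <- c(lvedvi = lvedv / b, rvedvi = rvedv / b,
                 lvmi = wall * 1.05 / b, asc_aorta_i = aad / b,
                 mass_volume_ratio = (wall * 1.05) / lvedv)
        ms <- StudyMeasures(raw, idx, b)       # validity enforces identity
        expect_s4_class(ms, "StudyMeasures")
        expect_equal(indexedMeasures(ms)[["rvedvi"]] * b, rvedv,
                     tolerance = 1e-9)
    }
    # and a violated identity is rejected
    raw <- c(lvedv_ml = 100, rvedv_ml = 100, lv_wall_volume_ml = 100,
             lv_mass_g = 105, asc_aorta_diameter_mm = 30,
             pleural_fluid_ml = 0)
    idx <- c(lvedvi = 60, rvedvi = 50, lvmi = 52.5, asc_aorta_i = 15,
             mass_volume_ratio = 0.875)
    expect_error(StudyMeasures(raw, idx, 2.0), "bsa")
})

test_that("ascending aorta is the most anterior component's diameter", {
    # two tubes: anterior radius 15, posterior radius 10 -> 30 mm
    sp <- phantomSpec(list(tube(c(90, 50), 15, c(10, 110), "aorta"),
                           tube(c(90, 130), 10, c(10, 110), "aorta")))
    ph <- buildPhantom(sp, voxelMm = 1)
    vol <- assembleVolume(slicePhantom(ph, 2, 0, 1), dzMm = 2)
    d <- ascendingAortaDiameter(vol)
    expect_equal(d, 30, tolerance = 1 / 15)    # within a voxel width
    # a single-component aorta is not measurable (NA, distinct from 0)
    sp1 <- phantomSpec(list(tube(c(90, 50), 15, c(10, 110), "aorta")))
    ph1 <- buildPhantom(sp1, voxelMm = 2)
    vol1 <- assembleVolume(slicePhantom(ph1, 4, 0, 2))
    expect_true(is.na(ascendingAortaDiameter(vol1)))
    # no aorta at all
    sp0 <- phantomSpec(list(ellipsoid(c(90, 90, 60), c(20, 20, 20),
                                      "lv_cavity")))
    vol0 <- assembleVolume(slicePhantom(buildPhantom(sp0, voxelMm = 2),
                                        4, 0, 2))
    expect_true(is.na(ascendingAortaDiameter(vol0)))
})

test_that("equivalent-circle diameter follows 2 sqrt(area/pi)", {
    # plane with anterior component of area pi * 12.5^2 -> 25 mm
    occ <- array(0, c(60, 60, 3, 9)); occ[, , , 1] <- 1
    mask <- (row(matrix(0, 60, 60)) - 15)^2 +
        (col(matrix(0, 60, 60)) - 30)^2 <= 12.5^2
    area <- sum(mask)                           # voxel-counted area, 1 mm px
    mask2 <- (row(matrix(0, 60, 60)) - 50)^2 +
        (col(matrix(0, 60, 60)) - 30)^2 <= 5^2
    for (j in 1:3) {
        occ[, , j, 2][mask | mask2] <- 1
        occ[, , j, 1][mask | mask2] <- 0
    }
    vol <- LabelVolume(occ, c(1, 1, 2))
    expect_equal(ascendingAortaDiameter(vol), 2 * sqrt(area / pi),
                 tolerance = 1e-9)
})

test_that("calibration fits exact lines and applies per manufacturer", {
    x <- c(40, 80, 120, 160, 200)
    m <- fitCalibration(x, 1.2 * x - 4, "A", "lvedvi")
    tab <- calibrationTable(m)
    expect_equal(tab$slope, 1.2, tolerance = 1e-9)
    expect_equal(tab$intercept, -4, tolerance = 1e-9)
    expect_equal(tab$r_squared, 1, tolerance = 1e-12)
    # identity when raw == final
    m2 <- fitCalibration(x, x, "B", "rvedvi")
    t2 <- calibrationTable(m2)
    expect_equal(t2$slope, 1, tolerance = 1e-12)
    expect_equal(t2$intercept, 0, tolerance = 1e-9)
    expect_error(fitCalibration(rep(5, 4), 1:4, "A", "lvmi"),
                 "zero variance")
    expect_error(fitCalibration(x[1:2], x[1:2], "A", "lvmi"))

    # OLS agrees with the closed-form normal equations on noisy data
    set.seed(8)
    raw <- runif(50, 50, 150)
    fin <- 1.1 * raw - 5 + rnorm(50, 0, 2)
    mm <- calibrationTable(fitCalibration(raw, fin, "A", "lvedvi"))
    slopeNE <- sum((raw - mean(raw)) * (fin - mean(fin))) /
        sum((raw - mean(raw))^2)
    expect_equal(mm$slope, slopeNE, tolerance = 1e-12)
    expect_equal(mm$intercept, mean(fin) - slopeNE * mean(raw),
                 tolerance = 1e-12)
    expect_true(mm$slope > 1.05 && mm$slope < 1.15)
})

test_that("applyCalibration maps the five indexed measures", {
    raw <- c(lvedv_ml = 200, rvedv_ml = 150, lv_wall_volume_ml = 100,
             lv_mass_g = 105, asc_aorta_diameter_mm = 30,
             pleural_fluid_ml = 10)
    idx <- c(lvedvi = 100, rvedvi = 75, lvmi = 52.5, asc_aorta_i = 15,
             mass_volume_ratio = 0.525)
    ms <- StudyMeasures(raw, idx, 2.0)
    # identity model leaves measures unchanged
    id <- CalibrationModel()
    for (msr in c("lvedvi", "rvedvi", "lvmi", "mass_volume_ratio",
                  "asc_aorta_i"))
        id <- fitCalibration(c(40, 90, 140), c(40, 90, 140), "A", msr, id)
    out <- applyCalibration(ms, id, "A")
    expect_true(isCalibrated(out))
    expect_equal(indexedMeasures(out), indexedMeasures(ms),
                 tolerance = 1e-9)
    # slope 1.1, intercept -5 on lvedvi 100 -> 105
    m <- fitCalibration(c(40, 90, 140), 1.1 * c(40, 90, 140) - 5,
                        "A", "lvedvi", id)
    out2 <- applyCalibration(ms, m, "A")
    expect_equal(indexedMeasures(out2)[["lvedvi"]], 105, tolerance = 1e-9)
    # uncalibrated manufacturer: identity without any entries
    out3 <- applyCalibration(ms, CalibrationModel(), "uncalibrated")
    expect_equal(indexedMeasures(out3), indexedMeasures(ms))
    # missing entries are named
    expect_error(applyCalibration(ms, CalibrationModel(), "A"),
                 "lvedvi")
})

test_that("calibration round-trips values generated on a line", {
    true <- seq(50, 150, length.out = 20)
    biased <- applyManufacturerBias(true, 1.15, -8)
    m <- fitCalibration(biased, true, "B", "lvmi")
    e <- calibrationTable(m)
    expect_equal(e$slope * biased + e$intercept, true, tolerance = 1e-9)
})

test_that("diagnosis uses strict thresholds from the published cut-offs", {
    thr <- diagnosticThresholds(aortaIMax = 17, effusionMlMin = 50)
    mk <- function(lvedvi = 80, rvedvi = 80, lvmi = 60, mvr = NULL,
                   aao = 14, eff = 0, b = 2) {
        mvr <- mvr %||% (lvmi / lvedvi)
        raw <- c(lvedv_ml = lvedvi * b, rvedv_ml = rvedvi * b,
                 lv_wall_volume_ml = lvmi * b / 1.05, lv_mass_g = lvmi * b,
                 asc_aorta_diameter_mm = aao * b, pleural_fluid_ml = eff)
        idx <- c(lvedvi = lvedvi, rvedvi = rvedvi, lvmi = lvmi,
                 asc_aorta_i = aao, mass_volume_ratio = mvr)
        StudyMeasures(raw, idx, b, calibrated = TRUE)
    }
    expect_true(diagnose(mk(lvedvi = 95), thr)[["lv_dilated"]])
    expect_false(diagnose(mk(lvedvi = 94), thr)[["lv_dilated"]])   # strict
    expect_true(diagnose(mk(rvedvi = 98.1), thr)[["rv_dilated"]])
    expect_false(diagnose(mk(rvedvi = 98), thr)[["rv_dilated"]])
    expect_true(diagnose(mk(lvmi = 83.6, mvr = 0.8), thr)[["lv_hypertrophy"]])
    expect_true(diagnose(mk(mvr = 0.85), thr)[["raised_mvr"]])
    expect_false(diagnose(mk(mvr = 0.84), thr)[["raised_mvr"]])
    expect_true(diagnose(mk(aao = 17.5), thr)[["aorta_dilated"]])
    expect_true(diagnose(mk(eff = 51), thr)[["pleural_effusion"]])
    expect_false(any(diagnose(mk(), thr)))
})

test_that("diagnosis is monotone in each measure", {
    thr <- diagnosticThresholds(aortaIMax = 17, effusionMlMin = 50)
    set.seed(12)
    mk <- function(v, b = 2) {
        raw <- c(lvedv_ml = v[1] * b, rvedv_ml = v[2] * b,
                 lv_wall_volume_ml = v[3] * b / 1.05, lv_mass_g = v[3] * b,
                 asc_aorta_diameter_mm = v[5] * b, pleural_fluid_ml = v[6])
        idx <- c(lvedvi = v[1], rvedvi = v[2], lvmi = v[3],
                 asc_aorta_i = v[5], mass_volume_ratio = v[4])
        StudyMeasures(raw, idx, b, calibrated = TRUE)
    }
    for (k in 1:25) {
        v <- c(runif(1, 60, 130), runif(1, 60, 130), runif(1, 50, 110),
               runif(1, 0.5, 1.1), runif(1, 10, 25), runif(1, 0, 120))
        f0 <- diagnose(mk(v), thr)
        for (i in seq_along(v)) {
            v2 <- v; v2[i] <- v2[i] * 1.3
            if (i == 1) v2[4] <- v2[4] / 1.3    # keep mvr consistent story
            f1 <- diagnose(mk(v2), thr)
            nm <- c("lv_dilated", "rv_dilated", "lv_hypertrophy",
                    "raised_mvr", "aorta_dilated", "pleural_effusion")[i]
            expect_true(f1[[nm]] >= f0[[nm]])
        }
    }
})
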