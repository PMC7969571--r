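test_that("primitive truth volumes match their closed forms", {
    # lv_cavity ellipsoid semi-axes (30, 30, 40) mm: 4/3 pi 3 3 4 cm^3
    sp <- phantomSpec(list(ellipsoid(c(90, 90, 60), c(30, 30, 40),
                                     "lv_cavity")))
    ph <- buildPhantom(sp, voxelMm = 2)
    expect_equal(ph$truth$volume_ml[["lv_cavity"]], 4 / 3 * pi * 3 * 3 * 4,
                 tolerance = 1e-12)
    expect_equal(round(ph$truth$volume_ml[["lv_cavity"]], 3), 150.796)

    # aorta tube radius 15, height 100: pi 1.5^2 10 cm^3 = 70.686 ml
    sp2 <- phantomSpec(list(tube(c(90, 90), 15, c(10, 110), "aorta")))
    ph2 <- buildPhantom(sp2, voxelMm = 2)
    expect_equal(round(ph2$truth$volume_ml[["aorta"]], 3), 70.686)

    # shell = outer - inner
    sp3 <- phantomSpec(list(ellipsoidShell(c(90, 90, 60), c(40, 40, 40),
                                           c(30, 30, 30), "lv_wall")))
    ph3 <- buildPhantom(sp3, voxelMm = 2)
    expect_equal(ph3$truth$volume_ml[["lv_wall"]],
                 4 / 3 * pi * (4^3 - 3^3), tolerance = 1e-12)

    # crescent prism hits its target volume analytically
    sp4 <- phantomSpec(list(crescentPrism(150, c(90, 100), 75, c(5, 45),
                                          "pleural_effusion")))
    ph4 <- buildPhantom(sp4, voxelMm = 2)
    expect_equal(ph4$truth$volume_ml[["pleural_effusion"]], 150)

    # empty spec: all zero, all background
    ph5 <- buildPhantom(phantomSpec(list()), voxelMm = 4)
    expect_true(all(ph5$truth$volume_ml == 0))
    expect_true(all(ph5$labels == 0L))
})

test_that("primitives outside the grid are rejected", {
    expect_error(phantomSpec(list(ellipsoid(c(90, 90, 60), c(95, 30, 30),
                                            "lv_cavity"))),
                 "outside the phantom grid")
})

test_that("voxel-counted volume converges to the closed form with resolution", {
    sp <- phantomSpec(list(ellipsoid(c(90, 90, 60), c(30, 30, 40),
                                     "lv_cavity")))
    err <- vapply(c(2, 1), function(v) {
        ph <- buildPhantom(sp, voxelMm = v)
        counted <- sum(ph$labels == labelId("lv_cavity")) * v^3 / 1000
        abs(counted - ph$truth$volume_ml[["lv_cavity"]])
    }, 0)
    expect_lt(err[2], err[1])
    expect_lt(err[2] / 150.796, 0.01)
})

test_that("painter's algorithm marks overlapped classes voxel-exact", {
    sp <- phantomSpec(list(
        ellipsoid(c(90, 90, 60), c(30, 30, 30), "lv_cavity"),
        ellipsoid(c(110, 90, 60), c(30, 30, 30), "rv_cavity")))
    ph <- buildPhantom(sp, voxelMm = 2)
    expect_setequal(ph$truth$voxel_exact, c("lv_cavity", "rv_cavity"))
    v <- 2^3 / 1000
    expect_equal(ph$truth$volume_ml[["lv_cavity"]],
                 sum(ph$labels == labelId("lv_cavity")) * v)
    expect_equal(ph$truth$volume_ml[["rv_cavity"]],
                 sum(ph$labels == labelId("rv_cavity")) * v)
    # later primitive wins where they overlap and keeps analytic truth
    expect_equal(ph$truth$volume_ml[["rv_cavity"]],
                 4 / 3 * pi * 27, tolerance = 0.05 * 4 / 3 * pi * 27)
})

test_that("slice counts follow the slab arithmetic", {
    sp <- phantomSpec(list(tube(c(90, 90), 15, c(0, 100), "aorta")),
                      gridMm = c(180, 180, 100))
    ph <- buildPhantom(sp, voxelMm = 2)
    expect_equal(nSlices(slicePhantom(ph, 10, 0, 2)), 10L)   # 100/10
    expect_equal(nSlices(slicePhantom(ph, 10, 10, 2)), 5L)
    # thickness beyond the extent: single slice, not an error
    expect_equal(nSlices(slicePhantom(ph, 150, 0, 2)), 1L)
})

test_that("summed slice areas recover an ellipsoid volume within 2%", {
    sp <- phantomSpec(list(ellipsoid(c(90, 90, 60), c(30, 30, 40),
                                     "lv_cavity")))
    ph <- buildPhantom(sp, voxelMm = 1)
    ser <- slicePhantom(ph, 2, 0, 1)
    area <- vapply(seriesSlices(ser), function(s)
        sum(sliceLabels(s) == labelId("lv_cavity")) * 1 * 1, 0)
    vol <- sum(area * 2) / 1000
    expect_equal(vol, 150.796, tolerance = 0.02)
})

test_that("rendering is deterministic under seed and exact at zero noise", {
    ser <- slicePhantom(coarsePhantom("normal"), 8, 2, 2)
    r0 <- renderSlices(ser, noiseSd = 0, seed = 3)
    im <- defaultIntensityMap()
    s <- getSlice(r0, 4)
    expect_equal(sliceImage(s),
                 matrix(unname(im[labelClasses()$name][
                     as.vector(sliceLabels(s)) + 1L]),
                     nrow(sliceLabels(s)), ncol(sliceLabels(s))))
    a <- renderSlices(ser, noiseSd = 5, seed = 11)
    b <- renderSlices(ser, noiseSd = 5, seed = 11)
    expect_series_equal(a, b)
    c2 <- renderSlices(ser, noiseSd = 5, seed = 12)
    expect_false(identical(sliceImage(getSlice(a, 1)),
                           sliceImage(getSlice(c2, 1))))
})

test_that("rendering does not disturb the global RNG stream", {
    ser <- slicePhantom(coarsePhantom("normal"), 8, 2, 2)
    set.seed(99); before <- .Random.seed
    invisible(renderSlices(ser, noiseSd = 5, seed = 4))
    expect_identical(.Random.seed, before)
})

test_that("nearest-mean classification recovers >= 99.9% of labels at sd 5", {
    ser <- renderedSeries("normal", noiseSd = 5, seed = 2)
    seg <- NearestMeanSegmenter()
    agree <- 0; total <- 0
    for (i in seq_len(nSlices(ser))) {
        s <- getSlice(ser, i)
        pred <- predictLabels(seg, sliceImage(s))
        agree <- agree + sum(pred == sliceLabels(s))
        total <- total + length(pred)
    }
    expect_gte(agree / total, 0.999)
})

test_that("manufacturer bias is affine and recoverable by OLS", {
    expect_equal(applyManufacturerBias(100, 1, 0), 100)
    expect_equal(applyManufacturerBias(100, 1.1, -5), 105)
    expect_error(applyManufacturerBias(100, -1, 0))
    # noiseless recovery: fit on 50 biased values -> slope/intercept exact
    true <- seq(40, 140, length.out = 50)
    biased <- applyManufacturerBias(true, 1.1, -5)
    m <- fitCalibration(true, biased, "A", "lvedvi")
    tab <- calibrationTable(m)
    expect_equal(tab$slope, 1.1, tolerance = 1e-9)
    expect_equal(tab$intercept, -5, tolerance = 1e-9)
})

test_that("each diagnostic preset sits >= 15% beyond its cut-off in truth", {
    thr <- diagnosticThresholds(aortaIMax = 17, effusionMlMin = 50)
    get <- function(nm) buildPhantom(phantomPreset(nm), voxelMm = 2)$truth
    t1 <- get("dilated_lv")
    expect_gte(t1$volume_ml[["lv_cavity"]] / t1$bsa_m2, 94 * 1.15)
    t2 <- get("hypertrophied_lv")
    expect_gte(t2$volume_ml[["lv_wall"]] * 1.05 / t2$bsa_m2, 83.5 * 1.15)
    t3 <- get("raised_mvr")
    mvr <- (t3$volume_ml[["lv_wall"]] * 1.05) / t3$volume_ml[["lv_cavity"]]
    expect_gte(mvr, 0.84 * 1.15)
    t4 <- get("dilated_aorta")
    expect_gte(t4$asc_aorta_diameter_mm / t4$bsa_m2, 17 * 1.15)
    t5 <- get("pleural_effusion")
    expect_gte(t5$volume_ml[["pleural_effusion"]], 50 * 1.15)
})
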