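# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, force(expr), envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

# coarse phantom (2 mm voxels): fast, adequate for contract tests
coarsePhantom <- function(name = "normal") {
    cached(paste0("coarse_", name),
           buildPhantom(phantomPreset(name), voxelMm = 2))
}

# labeled + rendered series from the coarse phantom
renderedSeries <- function(name = "normal", thickness = 4, gap = 0,
                           px = 2, noiseSd = 5, seed = 1) {
    key <- paste("ser", name, thickness, gap, px, noiseSd, seed, sep = "_")
    cached(key, {
        ser <- slicePhantom(coarsePhantom(name), thickness, gap, px)
        renderSlices(ser, noiseSd = noiseSd, seed = seed)
    })
}

# a small hand-built series for IO tests
tinySeries <- function(nSlices = 3, rows = 6, cols = 7, seed = 1,
                       withImages = TRUE, withLabels = TRUE,
                       manufacturer = "A", bsa = NA_real_) {
    set.seed(seed)
    slices <- lapply(seq_len(nSlices), function(k) {
        g <- SliceGeometry(1.5, 2, 8, slicePosition = (k - 1) * 10,
                           rows = rows, cols = cols)
        AnatomySlice(
            image = if (withImages)
                matrix(sample(0:65535, rows * cols, TRUE), rows, cols),
            labels = if (withLabels)
                matrix(sample(0:8, rows * cols, TRUE), rows, cols),
            geometry = g)
    })
    AnatomySeries(slices, manufacturer = manufacturer, bsa = bsa)
}

expect_series_equal <- function(a, b) {
    expect_equal(nSlices(a), nSlices(b))
    for (i in seq_len(nSlices(a))) {
        sa <- getSlice(a, i); sb <- getSlice(b, i)
        expect_equal(sliceImage(sa), sliceImage(sb))
        expect_equal(sliceLabels(sa), sliceLabels(sb))
        ga <- sliceGeometry(sa); gb <- sliceGeometry(sb)
        for (s in c("pixelSpacingRow", "pixelSpacingCol", "sliceThickness",
                    "slicePosition", "rows", "cols"))
            expect_equal(slot(ga, s), slot(gb, s))
    }
    expect_identical(manufacturer(a), manufacturer(b))
    expect_equal(seriesBSA(a), seriesBSA(b))
}
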