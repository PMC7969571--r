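test_that("Dice follows 2TP/(2TP+FP+FN) with the vacuous convention", {
    a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
    expect_equal(dice(a, a), 1.0)
    expect_equal(dice(a, !a), 0.0)
    # TP=1, FN=1, FP=0 -> 2/3
    p <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
    t <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
    expect_equal(dice(p, t), 2 / 3)
    # both empty: 1.0, flagged vacuous
    z <- matrix(FALSE, 2, 2)
    expect_equal(as.numeric(dice(z, z)), 1.0)
    expect_true(attr(dice(z, z), "vacuous"))
    expect_error(dice(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shape")
})

test_that("Dice is symmetric and permutation invariant", {
    set.seed(5)
    for (k in 1:20) {
        a <- matrix(runif(64) < 0.4, 8)
        b <- matrix(runif(64) < 0.4, 8)
        expect_equal(dice(a, b), dice(b, a))
        perm <- sample(64)
        expect_equal(dice(matrix(a[perm], 8), matrix(b[perm], 8)),
                     dice(a, b))
    }
})

test_that("per-class Dice equals independent pixel counting", {
    ser <- renderedSeries("pleural_effusion")
    pred <- segmentSeries(ser, OracleSegmenter(ser, corruptionRate = 0.1,
                                               seed = 9))
    pl <- sliceLabels(getSlice(pred, 10)); tl <- sliceLabels(getSlice(ser, 10))
    d <- perClassDice(pl, tl)
    for (nm in names(d)) {
        c0 <- labelId(nm)
        tp <- sum(pl == c0 & tl == c0)
        fp <- sum(pl == c0 & tl != c0)
        fn <- sum(pl != c0 & tl == c0)
        expect_equal(unname(d[[nm]]), 2 * tp / (2 * tp + fp + fn))
    }
    # identical maps: all 1; a fully swapped class: both zero
    expect_true(all(perClassDice(tl, tl) == 1))
    sw <- tl; sw[tl == 4L] <- 8L; sw[tl == 8L] <- 4L
    dsw <- perClassDice(sw, tl)
    expect_equal(unname(dsw[["lv_cavity"]]), 0)
    expect_equal(unname(dsw[["rv_cavity"]]), 0)
})

test_that("binary diagnostics reproduce the printed worked examples", {
    b <- binaryDiagnostics(1, 0, 0, 1)
    expect_equal(c(b$accuracy, b$sensitivity, b$specificity, b$kappa),
                 c(1, 1, 1, 1))
    # LV dilatation matrix: kappa 0.75, and the aorta matrix: kappa 0.79
    b1 <- binaryDiagnostics(43, 11, 8, 138)
    expect_equal(round(b1$kappa, 2), 0.75)
    b2 <- binaryDiagnostics(7, 3, 0, 44)
    expect_equal(round(b2$kappa, 2), 0.79)
    expect_equal(b2$sensitivity, 1.0)
    # undefined statistics are absent, not NaN
    b3 <- binaryDiagnostics(0, 2, 0, 3)
    expect_null(b3$sensitivity)
    expect_false(is.null(b3$specificity))
})

test_that("kappa is 1 iff FP=FN=0, and 0 under row/column independence", {
    expect_equal(binaryDiagnostics(5, 0, 0, 7)$kappa, 1)
    expect_lt(binaryDiagnostics(5, 1, 0, 7)$kappa, 1)
    # independence: predictions random wrt truth -> kappa 0
    # rows (40, 60): preds 50/50 independent -> tp=20 fp=30 fn=20 tn=30
    expect_equal(binaryDiagnostics(20, 30, 20, 30)$kappa, 0)
})

test_that("confusion reconstruction inverts printed statistics exactly", {
    # only the perfect 1/1 matrix matches (2, 100, 100, 100)
    s <- reconstructConfusion(2, 100, 100, 100)
    expect_equal(nrow(s), 1L)
    expect_equal(unlist(s[1, 1:4]), c(tp = 1, fn = 0, fp = 0, tn = 1))
    # the two derived unique solutions
    s2 <- reconstructConfusion(200, 84.3, 92.6, 90.5)
    expect_equal(nrow(s2), 1L)
    expect_equal(unlist(s2[1, 1:4]), c(tp = 43, fn = 8, fp = 11, tn = 138))
    s3 <- reconstructConfusion(54, 100, 93.6, 94.4)
    expect_equal(nrow(s3), 1L)
    expect_equal(unlist(s3[1, 1:4]), c(tp = 7, fn = 0, fp = 3, tn = 44))
    # impossible statistics: empty result
    expect_equal(nrow(reconstructConfusion(3, 100, 100, 50)), 0L)
})

test_that("reconstruction recovers randomized matrices from their rounding", {
    set.seed(20)
    for (k in 1:30) {
        n <- sample(20:300, 1)
        tp <- sample(0:n, 1); fn <- sample(0:(n - tp), 1)
        fp <- sample(0:(n - tp - fn), 1); tn <- n - tp - fn - fp
        if (tp + fn == 0 || tn + fp == 0) next
        b <- binaryDiagnostics(tp, fp, fn, tn)
        sols <- reconstructConfusion(
            n, round(100 * b$sensitivity, 1),
            round(100 * b$specificity, 1), round(100 * b$accuracy, 1))
        hit <- any(sols$tp == tp & sols$fn == fn & sols$fp == fp &
                   sols$tn == tn)
        expect_true(hit)
    }
})

test_that("Wilson intervals reproduce the printed confidence bounds", {
    ci <- wilsonInterval(9, 10, 0.95)
    expect_equal(round(unname(ci) * 100, 1), c(59.6, 98.2))
    ci2 <- wilsonInterval(10, 10, 0.95)
    expect_equal(unname(ci2[2]), 1.0)
    expect_gte(ci2[[1]], 0.722)
    expect_lte(ci2[[1]], 0.723)
})

test_that("Wilson bounds are proper intervals containing the estimate", {
    set.seed(3)
    for (k in 1:50) {
        n <- sample(1:200, 1); x <- sample(0:n, 1)
        ci <- wilsonInterval(x, n)
        expect_gte(ci[[1]], 0); expect_lte(ci[[2]], 1)
        expect_lte(ci[[1]], x / n + 1e-12)
        expect_gte(ci[[2]], x / n - 1e-12)
    }
})

test_that("Pearson r and r^2 match hand-computed values", {
    x <- 1:10
    expect_equal(pearson(x, 2 * x + 1)$r, 1.0)
    p <- pearson(x, -x)
    expect_equal(p$r, -1.0); expect_equal(p$r_squared, 1.0)
    expect_equal(round(pearson(c(1, 2, 3), c(1, 2, 4))$r_squared, 4),
                 0.9643)
    expect_error(pearson(c(1, 1, 1), 1:3), "zero variance")
})

test_that("ROC AUC, Youden cut-off and degenerate cases behave", {
    r <- rocCurve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
    expect_equal(r$auc, 0.75)
    # perfectly separated
    expect_equal(rocCurve(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1.0)
    # identical scores: chance
    expect_equal(rocCurve(rep(1, 10), rep(0:1, 5))$auc, 0.5)
    expect_error(rocCurve(1:4, c(1, 1, 1, 1)), "both classes")
    # tpr/fpr monotone along the threshold sweep
    expect_true(all(diff(r$tpr) <= 0))
    expect_true(all(diff(r$fpr) <= 0))
})

test_that("AUC equals exhaustive pairwise concordance on small instances", {
    set.seed(14)
    for (k in 1:40) {
        n <- sample(4:8, 1)
        labels <- c(0, 1, sample(0:1, n - 2, TRUE))
        scores <- round(runif(n), 2)            # ties likely
        pos <- scores[labels == 1]; neg <- scores[labels == 0]
        conc <- mean(outer(pos, neg, function(p, q)
            (p > q) + 0.5 * (p == q)))
        expect_equal(rocCurve(scores, labels)$auc, conc, tolerance = 1e-12)
    }
})

test_that("Youden's J picks the lower threshold on ties and reports kappa", {
    scores <- c(1, 2, 3, 4)
    labels <- c(0, 0, 1, 1)
    r <- rocCurve(scores, labels)
    expect_equal(r$youden_threshold, 2)
    expect_equal(r$accuracy, 1)
    expect_equal(r$kappa, 1)
})
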