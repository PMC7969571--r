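#' Dice overlap coefficient
#'
#' Dice = 2 TP / (2 TP + FP + FN) between a predicted and a reference
#' binary mask. Two empty masks agree on absence and score 1 (flagged as
#' vacuous via the "vacuous" attribute).
#'
#' @param pred,truth logical (or 0/1) arrays of identical shape.
#' @return Dice fraction in [0, 1].
#' @export
dice <- function(pred, truth) {
    if (!all(dim(pred) == dim(truth)) ||
        length(pred) != length(truth))
        stop("mask shapes differ")
    p <- as.logical(pred); t <- as.logical(truth)
    tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
    if (tp + fp + fn == 0L)
        return(structure(1, vacuous = TRUE))
    2 * tp / (2 * tp + fp + fn)
}

#' Per-class Dice over two label maps
#'
#' Dice of the binary mask of each class present in either map; classes
#' absent from both are omitted (their Dice would be vacuous).
#'
#' @param pred,truth integer label maps of identical shape.
#' @param classes class ids to report (default: those present in either
#'   map).
#' @return named numeric (by class name) with attribute \code{mean}.
#' @export
perClassDice <- function(pred, truth, classes = NULL) {
    if (!all(dim(pred) == dim(truth))) stop("label map shapes differ")
    if (is.null(classes))
        classes <- sort(unique(c(as.vector(pred), as.vector(truth))))
    d <- vapply(classes, function(c0) as.numeric(dice(pred == c0,
                                                      truth == c0)), 0)
    names(d) <- labelName(classes)
    attr(d, "mean") <- mean(d)
    d
}

#' Mean foreground Dice of a segmenter over a labeled series
#'
#' Per-class Dice pooled over all slices (pixel counts aggregated before
#' the ratio), averaged over the non-background classes present in the
#' ground truth.
#'
#' @param predSeries,truthSeries \code{AnatomySeries} with labels.
#' @return mean foreground Dice.
#' @export
meanForegroundDice <- function(predSeries, truthSeries) {
    ps <- lapply(seriesSlices(predSeries), sliceLabels)
    ts <- lapply(seriesSlices(truthSeries), sliceLabels)
    stopifnot(length(ps) == length(ts))
    classes <- setdiff(sort(unique(unlist(lapply(ts, as.vector)))), 0L)
    d <- vapply(classes, function(c0) {
        tp <- fp <- fn <- 0
        for (i in seq_along(ps)) {
            p <- ps[[i]] == c0; t <- ts[[i]] == c0
            tp <- tp + sum(p & t); fp <- fp + sum(p & !t)
            fn <- fn + sum(!p & t)
        }
        2 * tp / (2 * tp + fp + fn)
    }, 0)
    mean(d)
}

#' Binary diagnostic statistics from a confusion matrix
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/n and
#' Cohen's kappa (p_o - p_e)/(1 - p_e) with p_o the accuracy and
#' p_e = [(TP+FN)(TP+FP) + (TN+FP)(TN+FN)] / n^2. Statistics whose
#' denominator is empty are omitted from the result (absent, not NaN).
#'
#' @param tp,fp,fn,tn non-negative integer counts, n = tp+fp+fn+tn >= 1.
#' @return named list: n plus whichever of accuracy, sensitivity,
#'   specificity, kappa are defined.
#' @export
binaryDiagnostics <- function(tp, fp, fn, tn) {
    stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
    n <- tp + fp + fn + tn
    if (n < 1) stop("empty confusion matrix")
    out <- list(n = n, accuracy = (tp + tn) / n)
    if (tp + fn >= 1) out$sensitivity <- tp / (tp + fn)
    if (tn + fp >= 1) out$specificity <- tn / (tn + fp)
    pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
    if (pe < 1) out$kappa <- (out$accuracy - pe) / (1 - pe)
    else if (out$accuracy == 1) out$kappa <- 1
    out
}

# half-up rounding match at the precision the figure was printed with
.matchesPrinted <- function(x, printed) {
    digits <- if (printed == round(printed)) 0L else 1L
    roundHalfUp(x, digits) == printed
}

#' Reconstruct integer confusion matrices from printed statistics
#'
#' Exhaustively enumerates all (TP, FN, FP, TN) with TP+FN+FP+TN = n whose
#' sensitivity, specificity and accuracy each round (half-up, at the
#' precision of the printed figure: one decimal for "84.3", integer for
#' "80") to the given percentages. This inverts the rounded statistics a
#' study reports into the exact integer matrices compatible with them,
#' from which exact kappa values can be computed.
#'
#' @param n total cases.
#' @param sensitivityPct,specificityPct,accuracyPct percentages as
#'   printed.
#' @return data.frame with columns tp, fn, fp, tn, kappa (one row per
#'   solution; zero rows when no matrix is compatible).
#' @export
reconstructConfusion <- function(n, sensitivityPct, specificityPct,
                                 accuracyPct) {
    stopifnot(n >= 1)
    sols <- list()
    for (P in seq_len(n - 1L)) {          # need both classes present
        N <- n - P
        tps <- which(vapply(0:P, function(tp)
            .matchesPrinted(100 * tp / P, sensitivityPct), TRUE)) - 1L
        if (!length(tps)) next
        tns <- which(vapply(0:N, function(tn)
            .matchesPrinted(100 * tn / N, specificityPct), TRUE)) - 1L
        if (!length(tns)) next
        for (tp in tps) for (tn in tns) {
            if (.matchesPrinted(100 * (tp + tn) / n, accuracyPct)) {
                k <- binaryDiagnostics(tp, N - tn, P - tp, tn)$kappa
                sols[[length(sols) + 1L]] <-
                    data.frame(tp = tp, fn = P - tp, fp = N - tn,
                               tn = tn, kappa = k)
            }
        }
    }
    if (!length(sols))
        return(data.frame(tp = integer(), fn = integer(), fp = integer(),
                          tn = integer(), kappa = numeric()))
    do.call(rbind, sols)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,trials counts, 0 <= successes <= trials, trials >= 1.
#' @param confidence confidence level (default 0.95).
#' @return c(lower, upper) fractions.
#' @examples
#' wilsonInterval(9, 10)   # c(0.596..., 0.982...)
#' @export
wilsonInterval <- function(successes, trials, confidence = 0.95) {
    stopifnot(trials >= 1, successes >= 0, successes <= trials)
    z <- stats::qnorm(1 - (1 - confidence) / 2)
    p <- successes / trials
    denom <- 1 + z^2 / trials
    center <- (p + z^2 / (2 * trials)) / denom
    half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
    c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Pearson correlation and its square
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list(r, r_squared).
#' @export
pearson <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 3)
    if (var(x) == 0 || var(y) == 0)
        stop("zero variance input")
    r <- stats::cor(x, y)
    list(r = r, r_squared = r^2)
}

#' Empirical ROC curve, AUC and Youden-optimal cut-off
#'
#' The curve sweeps all distinct score thresholds (classification rule:
#' positive iff score > threshold); AUC is the trapezoidal area, which on
#' the empirical curve equals the Mann-Whitney pairwise concordance. The
#' optimal cut-off maximizes Youden's J = sensitivity + specificity - 1,
#' ties resolved to the lower threshold; accuracy and Cohen's kappa are
#' reported at that cut-off.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels 0/1 (or logical) true classes; both classes must be
#'   present.
#' @return list: thresholds, tpr, fpr, auc, youden_threshold, plus
#'   accuracy and kappa at the Youden cut-off.
#' @export
rocCurve <- function(scores, labels) {
    labels <- as.integer(as.logical(labels))
    stopifnot(length(scores) == length(labels))
    if (length(unique(labels)) < 2L)
        stop("both classes must be present")
    P <- sum(labels == 1L); N <- sum(labels == 0L)
    # thresholds: below all scores, then each distinct score
    thr <- c(-Inf, sort(unique(scores)))
    tpr <- vapply(thr, function(t) sum(scores > t & labels == 1L) / P, 0)
    fpr <- vapply(thr, function(t) sum(scores > t & labels == 0L) / N, 0)
    ord <- order(fpr, tpr)                 # ascending fpr for integration
    auc <- sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tail(tpr[ord], -1)) / 2)
    J <- tpr + (1 - fpr) - 1
    best <- which(J == max(J))
    bi <- best[which.min(thr[best])]
    t0 <- thr[bi]
    pred <- scores > t0
    tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
    fn <- P - tp; tn <- N - fp
    bd <- binaryDiagnostics(tp, fp, fn, tn)
    list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
         youden_threshold = t0, accuracy = bd$accuracy, kappa = bd$kappa)
}
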