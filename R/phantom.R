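#' Geometric primitives for synthetic thorax phantoms
#'
#' A phantom is a list of solid primitives painted into a voxel grid in
#' order (painter's algorithm: later primitives overwrite earlier ones).
#' Each primitive has a closed-form volume, so downstream volumetry can be
#' checked against analytic truth. Coordinates are world mm, x = column
#' (right to left), y = row (anterior to posterior), z = through-plane
#' (caudal to cranial).
#'
#' \code{ellipsoid}: axis-aligned ellipsoid, volume 4/3 pi a b c.
#' \code{ellipsoidShell}: outer minus concentric inner ellipsoid (the LV
#' wall); volume is the difference of the two closed forms.
#' \code{tube}: vertical circular cylinder, volume pi r^2 h.
#' \code{crescentPrism}: posterior crescent of a given target volume --
#' the lune between two equal circles whose centers are offset along +y,
#' extruded over a z range; the offset is solved numerically so the
#' analytic volume equals \code{volumeMl} exactly.
#'
#' @param center,centerXY world-mm center, (x, y, z) or (x, y).
#' @param semi,outerSemi,innerSemi semi-axes (a, b, c) in mm, all > 0.
#' @param radius tube / crescent circle radius in mm.
#' @param zRange length-2 numeric, mm.
#' @param volumeMl target crescent volume in ml.
#' @param class a label class name (see \code{\link{labelClasses}}).
#' @return a primitive description list.
#' @export
ellipsoid <- function(center, semi, class) {
    stopifnot(length(center) == 3L, length(semi) == 3L, all(semi > 0))
    list(type = "ellipsoid", center = as.numeric(center),
         semi = as.numeric(semi), class = class)
}

#' @rdname ellipsoid
#' @export
ellipsoidShell <- function(center, outerSemi, innerSemi, class) {
    stopifnot(all(outerSemi > innerSemi), all(innerSemi > 0))
    list(type = "shell", center = as.numeric(center),
         outer = as.numeric(outerSemi), inner = as.numeric(innerSemi),
         class = class)
}

#' @rdname ellipsoid
#' @export
tube <- function(centerXY, radius, zRange, class) {
    stopifnot(length(centerXY) == 2L, radius > 0, length(zRange) == 2L,
              zRange[2] > zRange[1])
    list(type = "tube", center = as.numeric(centerXY),
         radius = as.numeric(radius), zRange = as.numeric(zRange),
         class = class)
}

#' @rdname ellipsoid
#' @export
crescentPrism <- function(volumeMl, centerXY, radius, zRange, class) {
    stopifnot(volumeMl > 0, radius > 0, length(zRange) == 2L,
              zRange[2] > zRange[1])
    h <- zRange[2] - zRange[1]
    targetArea <- volumeMl * 1000 / h            # mm^2
    if (targetArea >= pi * radius^2)
        stop("crescent volume exceeds the full cylinder capacity")
    luneArea <- function(d) {                     # equal circles offset d
        ov <- 2 * radius^2 * acos(d / (2 * radius)) -
            (d / 2) * sqrt(4 * radius^2 - d^2)
        pi * radius^2 - ov
    }
    d <- uniroot(function(d) luneArea(d) - targetArea,
                 lower = 1e-9, upper = 2 * radius - 1e-9,
                 tol = 1e-12)$root
    list(type = "crescent", center = as.numeric(centerXY),
         radius = as.numeric(radius), offset = d,
         zRange = as.numeric(zRange), volumeMl = as.numeric(volumeMl),
         class = class)
}

.primitiveVolumeMl <- function(p) {
    switch(p$type,
        ellipsoid = 4 / 3 * pi * prod(p$semi) / 1000,
        shell = 4 / 3 * pi * (prod(p$outer) - prod(p$inner)) / 1000,
        tube = pi * p$radius^2 * diff(p$zRange) / 1000,
        crescent = p$volumeMl,
        stop("unknown primitive type"))
}

.primitiveBBox <- function(p) {
    switch(p$type,
        ellipsoid = rbind(p$center - p$semi, p$center + p$semi),
        shell = rbind(p$center - p$outer, p$center + p$outer),
        tube = rbind(c(p$center - p$radius, p$zRange[1]),
                     c(p$center + p$radius, p$zRange[2])),
        crescent = rbind(c(p$center - p$radius, p$zRange[1]),
                         c(p$center[1] + p$radius,
                           p$center[2] + p$radius, p$zRange[2])))
}

#' Specify a synthetic thorax phantom
#'
#' @param primitives list of primitives (see \code{\link{ellipsoid}}),
#'   painted in order.
#' @param gridMm (x, y, z) extent of the voxel grid in mm.
#' @param bodyOutline list with \code{center} (x, y) and \code{semi}
#'   (a, b): the torso cross-section ellipse (documentation of the scene;
#'   structures are expected to lie within it).
#' @param manufacturer scanner label "A", "B" or "uncalibrated".
#' @param biasProfile named list of \code{c(slope, intercept)} pairs per
#'   indexed measure, emulating the systematic acquisition bias between
#'   manufacturers; identity when omitted.
#' @param intensityMap named numeric, class name -> mean intensity.
#' @param noiseSd Gaussian intensity noise SD.
#' @param bsa body surface area (m2) attributed to the synthetic patient.
#' @param seed integer seed for rendering noise.
#' @param expectedFlags character vector naming the diagnostic flags this
#'   phantom is built to raise (empty for a normal study).
#' @return a \code{PhantomSpec} list.
#' @export
phantomSpec <- function(primitives, gridMm = c(180, 180, 120),
                        bodyOutline = list(center = c(90, 90),
                                           semi = c(88, 85)),
                        manufacturer = "uncalibrated",
                        biasProfile = NULL,
                        intensityMap = defaultIntensityMap(),
                        noiseSd = 5, bsa = 1.9, seed = 1L,
                        expectedFlags = character()) {
    stopifnot(all(gridMm > 0), length(gridMm) == 3L)
    for (p in primitives) {
        bb <- .primitiveBBox(p)
        if (any(bb[1, ] < -1e-9) || any(bb[2, ] > gridMm + 1e-9))
            stop("primitive of class '", p$class,
                 "' extends outside the phantom grid")
    }
    structure(list(primitives = primitives, gridMm = as.numeric(gridMm),
                   bodyOutline = bodyOutline, manufacturer = manufacturer,
                   biasProfile = biasProfile, intensityMap = intensityMap,
                   noiseSd = noiseSd, bsa = bsa, seed = as.integer(seed),
                   expectedFlags = expectedFlags),
              class = "PhantomSpec")
}

#' Default pseudo-MR class intensity map
#'
#' Class mean intensities chosen a minimum of 40 units apart so that, at
#' the default noise SD of 5, per-pixel nearest-mean classification is
#' essentially error free (4 SDs to the decision boundary). Blood pools
#' are bright (bright-blood convention), myocardium and fluid darker.
#'
#' @return named numeric vector over the 9 class names.
#' @export
defaultIntensityMap <- function() {
    c(background = 10, pleural_effusion = 50, lv_wall = 90,
      right_atrium = 130, pulmonary_artery = 170, left_atrium = 210,
      lv_cavity = 250, rv_cavity = 290, aorta = 330)
}

# voxel-center coordinate vectors for a grid of extent `ext` at voxel `v`
.gridCenters <- function(ext, v) {
    n <- max(1L, round(ext / v))
    (seq_len(n) - 0.5) * v
}

#' Voxelize a phantom and compute its ground truth
#'
#' Paints the spec's primitives into an isotropic voxel grid in order
#' (later primitives overwrite earlier ones). Truth volumes are the
#' closed-form primitive volumes; any class that loses voxels to a later
#' overlapping primitive (or overwrites another) has its truth volume
#' recomputed voxel-exactly at build resolution, so recovery tests remain
#' fair under overlap.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param voxelMm isotropic build resolution in mm.
#' @return list with \code{labels} (3D integer array [y, x, z]),
#'   \code{voxelMm}, \code{spec}, and \code{truth}: per-class volumes (ml,
#'   named by class), \code{asc_aorta_diameter_mm} (diameter of the most
#'   anterior aorta tube when the spec has at least two, else NA),
#'   \code{bsa_m2}, and \code{voxel_exact} (classes whose truth is
#'   voxel-counted because of overlap).
#' @export
buildPhantom <- function(spec, voxelMm = 1) {
    stopifnot(inherits(spec, "PhantomSpec"), voxelMm > 0)
    xs <- .gridCenters(spec$gridMm[1], voxelMm)
    ys <- .gridCenters(spec$gridMm[2], voxelMm)
    zs <- .gridCenters(spec$gridMm[3], voxelMm)
    ny <- length(ys); nx <- length(xs); nz <- length(zs)
    labels <- array(0L, c(ny, nx, nz))

    volume <- setNames(numeric(nLabelClasses()), labelClasses()$name)
    dirty <- character()

    idxWindow <- function(coords, lo, hi)
        which(coords >= lo - voxelMm & coords <= hi + voxelMm)

    for (p in spec$primitives) {
        cls <- labelId(p$class)
        bb <- .primitiveBBox(p)
        ix <- idxWindow(xs, bb[1, 1], bb[2, 1])
        iy <- idxWindow(ys, bb[1, 2], bb[2, 2])
        iz <- idxWindow(zs, bb[1, 3], bb[2, 3])
        if (!length(ix) || !length(iy) || !length(iz)) next
        X <- xs[ix]; Y <- ys[iy]; Z <- zs[iz]
        mask <- switch(p$type,
            ellipsoid = {
                fy <- ((Y - p$center[2]) / p$semi[2])^2
                fx <- ((X - p$center[1]) / p$semi[1])^2
                fz <- ((Z - p$center[3]) / p$semi[3])^2
                outer(outer(fy, fx, "+"), fz, "+") <= 1
            },
            shell = {
                qo <- outer(outer(((Y - p$center[2]) / p$outer[2])^2,
                                  ((X - p$center[1]) / p$outer[1])^2, "+"),
                            ((Z - p$center[3]) / p$outer[3])^2, "+")
                qi <- outer(outer(((Y - p$center[2]) / p$inner[2])^2,
                                  ((X - p$center[1]) / p$inner[1])^2, "+"),
                            ((Z - p$center[3]) / p$inner[3])^2, "+")
                qo <= 1 & qi > 1
            },
            tube = {
                circ <- outer((Y - p$center[2])^2, (X - p$center[1])^2,
                              "+") <= p$radius^2
                inz <- Z >= p$zRange[1] & Z <= p$zRange[2]
                outer(circ, inz, "&")
            },
            crescent = {
                inA <- outer((Y - p$center[2])^2, (X - p$center[1])^2,
                             "+") <= p$radius^2
                inB <- outer((Y - (p$center[2] - p$offset))^2,
                             (X - p$center[1])^2, "+") <= p$radius^2
                inz <- Z >= p$zRange[1] & Z <= p$zRange[2]
                outer(inA & !inB, inz, "&")
            })
        sub <- labels[iy, ix, iz, drop = FALSE]
        hit <- sub[mask]
        overwritten <- unique(hit[hit != 0L & hit != cls])
        if (length(overwritten)) {
            dirty <- union(dirty, labelName(overwritten))
            dirty <- union(dirty, p$class)
        }
        sub[mask] <- cls
        labels[iy, ix, iz] <- sub
        volume[p$class] <- volume[p$class] + .primitiveVolumeMl(p)
    }
    # voxel-exact truth for classes affected by overlap
    vvol <- voxelMm^3 / 1000
    for (nm in dirty)
        volume[nm] <- sum(labels == labelId(nm)) * vvol
    volume["background"] <- 0

    # ascending aorta: the most anterior (smallest center y) aorta tube,
    # when the spec separates ascending and descending tubes
    at <- Filter(function(p) p$type == "tube" && p$class == "aorta",
                 spec$primitives)
    aad <- if (length(at) >= 2L) {
        ya <- vapply(at, function(p) p$center[2], 0)
        2 * at[[which.min(ya)]]$radius
    } else NA_real_

    list(labels = labels, voxelMm = voxelMm, spec = spec,
         truth = list(volume_ml = volume,
                      asc_aorta_diameter_mm = aad,
                      bsa_m2 = spec$bsa,
                      voxel_exact = dirty))
}

#' Slice a phantom volume into a transaxial anatomy stack
#'
#' Each slice's label map is the weighted majority class within its
#' through-plane slab per pixel column (emulating the partial-volume
#' averaging of thick slices); ties break to the lowest class id. The
#' number of slices is \code{floor((zExtent - thickness) / (thickness +
#' gap)) + 1}; slice k covers z in [k (t+g), k (t+g) + t] and its recorded
#' position is the slab center. A thickness exceeding the volume extent
#' yields a single-slice series.
#'
#' @param phantom result of \code{\link{buildPhantom}}.
#' @param thicknessMm slab thickness, > 0.
#' @param gapMm inter-slab gap, >= 0.
#' @param pixelSpacingMm in-plane pixel spacing of the emitted slices.
#' @return an \code{\linkS4class{AnatomySeries}} with label maps only.
#' @export
slicePhantom <- function(phantom, thicknessMm, gapMm = 0,
                         pixelSpacingMm = phantom$voxelMm) {
    stopifnot(thicknessMm > 0, gapMm >= 0, pixelSpacingMm > 0)
    labels <- phantom$labels
    v <- phantom$voxelMm
    extZ <- dim(labels)[3] * v
    nsl <- max(1L, floor((extZ - thicknessMm) / (thicknessMm + gapMm)) + 1L)

    # in-plane resample indices (nearest voxel center)
    ny <- max(1L, round(dim(labels)[1] * v / pixelSpacingMm))
    nx <- max(1L, round(dim(labels)[2] * v / pixelSpacingMm))
    ri <- pmin(dim(labels)[1],
               pmax(1L, ceiling(((seq_len(ny) - 0.5) * pixelSpacingMm) / v)))
    ci <- pmin(dim(labels)[2],
               pmax(1L, ceiling(((seq_len(nx) - 0.5) * pixelSpacingMm) / v)))

    slices <- vector("list", nsl)
    for (k in seq_len(nsl)) {
        a <- (k - 1) * (thicknessMm + gapMm)
        b <- a + thicknessMm
        # voxel layers overlapping [a, b] and their overlap weights
        l0 <- max(1L, floor(a / v) + 1L)
        l1 <- min(dim(labels)[3], ceiling(b / v))
        ls <- l0:l1
        w <- pmin(b, ls * v) - pmax(a, (ls - 1) * v)
        votes <- matrix(0, ny * nx, nLabelClasses())
        for (j in seq_along(ls)) {
            lab <- labels[ri, ci, ls[j]]
            votes[cbind(seq_len(ny * nx), as.vector(lab) + 1L)] <-
                votes[cbind(seq_len(ny * nx), as.vector(lab) + 1L)] + w[j]
        }
        lab <- matrix(max.col(votes, ties.method = "first") - 1L, ny, nx)
        geom <- SliceGeometry(pixelSpacingMm, pixelSpacingMm, thicknessMm,
                              slicePosition = (a + b) / 2,
                              rows = ny, cols = nx)
        slices[[k]] <- AnatomySlice(labels = lab, geometry = geom)
    }
    AnatomySeries(slices, manufacturer = phantom$spec$manufacturer,
                  bsa = phantom$spec$bsa)
}

#' Render pseudo-MR intensities for a labeled series
#'
#' Each pixel's intensity is its class mean plus i.i.d. Gaussian noise,
#' rounded to the nearest integer and clipped to the 16-bit range
#' (acquisition images are integer-valued). Reproducible under
#' \code{seed}; with \code{noiseSd = 0} the image is a deterministic
#' recoloring of the label map.
#'
#' @param series an \code{AnatomySeries} whose slices carry label maps.
#' @param intensityMap named numeric covering all 9 class names.
#' @param noiseSd Gaussian noise SD (intensity units), >= 0.
#' @param seed integer.
#' @return the series with images added.
#' @export
renderSlices <- function(series, intensityMap = defaultIntensityMap(),
                         noiseSd = 5, seed = 1L) {
    if (!all(labelClasses()$name %in% names(intensityMap)))
        stop("intensityMap must cover all 9 classes")
    stopifnot(noiseSd >= 0)
    means <- intensityMap[labelClasses()$name]
    slices <- withSeed(seed, lapply(seriesSlices(series), function(s) {
        lab <- sliceLabels(s)
        if (is.null(lab)) stop("renderSlices needs label maps on all slices")
        img <- matrix(means[as.vector(lab) + 1L], nrow(lab), ncol(lab))
        if (noiseSd > 0)
            img <- img + matrix(rnorm(length(lab), 0, noiseSd),
                                nrow(lab), ncol(lab))
        img <- pmin(pmax(round(img), 0), 65535)
        AnatomySlice(image = img, labels = lab, geometry = sliceGeometry(s))
    }))
    AnatomySeries(slices, manufacturer = manufacturer(series),
                  bsa = seriesBSA(series), heightCm = series@heightCm,
                  weightKg = series@weightKg)
}

#' Apply a manufacturer acquisition bias to a true value
#'
#' Emulates the systematic, approximately affine bias between scanner
#' manufacturers that the per-manufacturer linear calibration is designed
#' to absorb: biased = slope * value + intercept.
#'
#' @param value numeric true value(s).
#' @param slope affine slope, > 0.
#' @param intercept affine intercept.
#' @return biased value(s).
#' @export
applyManufacturerBias <- function(value, slope, intercept = 0) {
    stopifnot(slope > 0)
    slope * value + intercept
}

#' Built-in diagnostic phantom presets
#'
#' One fixture per diagnostic flag, each sized at least 15 percent beyond
#' its published cut-off (at BSA 1.9 m2), plus a normal study:
#' \describe{
#'   \item{normal}{no flag raised; LVEDVi ~ 85, LVMi ~ 65, MVR ~ 0.76.}
#'   \item{dilated_lv}{LVEDVi ~ 108.6 ml/m2 (cut-off 94).}
#'   \item{hypertrophied_lv}{LVMi ~ 96.6 g/m2 (cut-off 83.5). Note that
#'     LVMi > 83.5 with LVEDVi <= 94 forces MVR >= 83.5/94 = 0.888 > 0.84,
#'     so this fixture necessarily raises the raised-MVR flag as well;
#'     both are its expected flags.}
#'   \item{raised_mvr}{MVR ~ 0.97 (cut-off 0.84) with normal LVEDVi/LVMi.}
#'   \item{dilated_aorta}{ascending aortic diameter 40 mm, indexed
#'     ~ 21.1 mm/m2 (suggested cut-off 17).}
#'   \item{pleural_effusion}{150 ml posterior crescent (suggested
#'     cut-off 50 ml).}
#' }
#'
#' @param name preset name.
#' @param manufacturer,biasProfile,noiseSd,seed forwarded to
#'   \code{\link{phantomSpec}}.
#' @return a \code{PhantomSpec}.
#' @export
phantomPreset <- function(name = c("normal", "dilated_lv",
                                   "hypertrophied_lv", "raised_mvr",
                                   "dilated_aorta", "pleural_effusion"),
                          manufacturer = "uncalibrated",
                          biasProfile = NULL, noiseSd = 5, seed = 1L) {
    name <- match.arg(name)
    lvC <- c(119, 100, 55)          # LV center
    base <- list(
        rv = ellipsoid(c(52, 88, 55), c(25, 22, 32), "rv_cavity"),
        la = ellipsoid(c(115, 148, 92), c(20, 16, 18), "left_atrium"),
        ra = ellipsoid(c(45, 138, 92), c(18, 15, 18), "right_atrium"),
        aoDesc = tube(c(75, 135), 9, c(0, 120), "aorta"),
        pa = tube(c(58, 58), 10, c(70, 110), "pulmonary_artery"))
    lv <- function(cav, out)
        list(wall = ellipsoidShell(lvC, out, cav, "lv_wall"),
             cavity = ellipsoid(lvC, cav, "lv_cavity"))
    aoAsc <- tube(c(95, 48), 12, c(10, 110), "aorta")

    prims <- switch(name,
        normal = c(lv(c(33, 33, 35.4), c(40, 40, 41.6)), base,
                   list(aoAsc = aoAsc)),
        dilated_lv = c(lv(c(34, 34, 42.6), c(41, 41, 45.8)), base,
                       list(aoAsc = aoAsc)),
        hypertrophied_lv = c(lv(c(31, 31, 38.1), c(41, 41, 46.6)), base,
                             list(aoAsc = aoAsc)),
        raised_mvr = c(lv(c(30, 30, 35.3), c(38, 38, 42.3)), base,
                       list(aoAsc = aoAsc)),
        dilated_aorta = c(lv(c(33, 33, 35.4), c(40, 40, 41.6)), base,
                          list(aoAsc = tube(c(90, 45), 20, c(10, 110),
                                            "aorta"))),
        pleural_effusion = c(lv(c(33, 33, 35.4), c(40, 40, 41.6)), base,
                             list(aoAsc = aoAsc,
                                  eff = crescentPrism(150, c(90, 100), 75,
                                                      c(5, 45),
                                                      "pleural_effusion"))))
    flags <- switch(name,
        normal = character(),
        dilated_lv = "lv_dilated",
        hypertrophied_lv = c("lv_hypertrophy", "raised_mvr"),
        raised_mvr = "raised_mvr",
        dilated_aorta = "aorta_dilated",
        pleural_effusion = "pleural_effusion")
    phantomSpec(unname(prims), manufacturer = manufacturer,
                biasProfile = biasProfile, noiseSd = noiseSd,
                seed = seed, expectedFlags = flags)
}
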