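#' Assemble labeled slices into a 3D occupancy volume
#'
#' Each slice's label map is one-hot encoded per class, resampled in-plane
#' (bilinear, on voxel-center coordinates) to a common target grid, placed
#' at its through-plane position, and interpolated linearly along z onto a
#' regular lattice -- trilinear interpolation of the per-class indicator
#' fields. Interpolating indicators rather than argmax-relabeling
#' preserves partial-volume information for volumetry; use
#' \code{\link{argmaxVolume}} for a hard-label rendering.
#'
#' The target in-plane resolution defaults to the finest pixel spacing in
#' the series and dz to \code{min(2, finest in-plane spacing)} mm. Slices
#' represent slabs, so the volume extends half a slice thickness beyond
#' the first and last slice centers by constant extension (otherwise the
#' apical/basal slabs would lose half their volume). Gaps between slabs
#' are spanned linearly with no gap-aware correction.
#'
#' @param series an \code{AnatomySeries} with >= 2 labeled slices at
#'   strictly increasing positions. Slices of differing in-plane extent
#'   are resampled onto the union bounding box.
#' @param inPlaneMm,dzMm optional overrides of the target resolution.
#' @return a \code{\linkS4class{LabelVolume}}.
#' @export
assembleVolume <- function(series, inPlaneMm = NULL, dzMm = NULL) {
    sl <- seriesSlices(series)
    if (length(sl) < 2L)
        stop("assembleVolume needs >= 2 slices; for a single slice, ",
             "treat it as one slab of its stated thickness")
    labs <- lapply(sl, sliceLabels)
    if (any(vapply(labs, is.null, TRUE)))
        stop("all slices must carry label maps")
    geoms <- lapply(sl, sliceGeometry)
    pos <- vapply(geoms, function(g) g@slicePosition, 0)

    finest <- min(vapply(geoms, function(g)
        min(g@pixelSpacingRow, g@pixelSpacingCol), 0))
    dxy <- inPlaneMm %||% finest
    dz <- dzMm %||% min(2, finest)

    extY <- max(vapply(geoms, function(g) g@rows * g@pixelSpacingRow, 0))
    extX <- max(vapply(geoms, function(g) g@cols * g@pixelSpacingCol, 0))
    ny <- max(1L, round(extY / dxy))
    nx <- max(1L, round(extX / dxy))
    yq <- (seq_len(ny) - 0.5) * dxy
    xq <- (seq_len(nx) - 0.5) * dxy

    nc <- nLabelClasses()
    # per-slice one-hot stacks resampled onto the target in-plane grid
    K <- length(sl)
    stack <- array(0, c(ny, nx, K, nc))
    for (k in seq_len(K)) {
        lab <- labs[[k]]; g <- geoms[[k]]
        for (c0 in sort(unique(as.vector(lab)))) {
            ind <- matrix(as.numeric(lab == c0), nrow(lab), ncol(lab))
            stack[, , k, c0 + 1L] <- bilinearResample(
                ind, g@pixelSpacingRow, g@pixelSpacingCol, yq, xq)
        }
    }

    t1 <- geoms[[1]]@sliceThickness; tK <- geoms[[K]]@sliceThickness
    z0 <- pos[1] - t1 / 2
    z1 <- pos[K] + tK / 2
    nz <- max(1L, round((z1 - z0) / dz))
    zq <- z0 + (seq_len(nz) - 0.5) * dz

    occ <- array(0, c(ny, nx, nz, nc))
    for (j in seq_len(nz)) {
        z <- zq[j]
        if (z <= pos[1]) {
            occ[, , j, ] <- stack[, , 1, ]
        } else if (z >= pos[K]) {
            occ[, , j, ] <- stack[, , K, ]
        } else {
            k <- findInterval(z, pos)
            w <- (pos[k + 1] - z) / (pos[k + 1] - pos[k])
            occ[, , j, ] <- w * stack[, , k, ] +
                (1 - w) * stack[, , k + 1, ]
        }
    }
    # bilinear edge clamping can leave per-voxel sums marginally off 1;
    # renormalize to restore the partition of unity exactly
    tot <- rowSums(matrix(occ, ny * nx * nz, nc))
    occ <- occ / as.vector(tot)
    LabelVolume(occ, voxelSize = c(dxy, dxy, dz), origin = c(0, 0, z0))
}

#' Volume of one anatomical structure
#'
#' Sum of the class's fractional occupancy times the voxel volume,
#' reported in ml. A class absent from the volume yields 0.
#'
#' @param volume a \code{\linkS4class{LabelVolume}}.
#' @param cls class id (0-8) or class name.
#' @return volume in ml.
#' @export
structureVolume <- function(volume, cls) {
    if (is.character(cls)) cls <- labelId(cls)
    stopifnot(cls %in% 0:8)
    vox <- prod(voxelSize(volume))        # mm^3
    sum(occupancyArray(volume)[, , , cls + 1L]) * vox / 1000
}

#' Hard-label rendering of an occupancy volume
#'
#' Per-voxel argmax over the 9 class occupancies (ties to the lowest class
#' id). Intended for visualization/export; volumetry should use the
#' fractional occupancies.
#'
#' @param volume a \code{LabelVolume}.
#' @return 3D integer array of class ids.
#' @export
argmaxVolume <- function(volume) {
    occ <- occupancyArray(volume)
    d <- dim(occ)
    m <- matrix(occ, d[1] * d[2] * d[3], d[4])
    array(max.col(m, ties.method = "first") - 1L, d[1:3])
}

#' Export the assembled model as NIfTI
#'
#' Writes the argmax rendering with the volume's voxel dimensions.
#' Requires the RNifti package.
#'
#' @param volume a \code{LabelVolume}.
#' @param path output .nii or .nii.gz path.
#' @return invisibly the path.
#' @export
exportNifti <- function(volume, path) {
    if (!requireNamespace("RNifti", quietly = TRUE))
        stop("exportNifti requires the RNifti package")
    arr <- argmaxVolume(volume)
    img <- RNifti::asNifti(arr, pixdim = voxelSize(volume))
    RNifti::writeNifti(img, path)
    invisible(path)
}
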