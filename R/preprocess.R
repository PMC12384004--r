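# Intensity normalization, absolute discretization and mask algebra.

#' Fit a histogram-based normalization map from a reference scan
#'
#' Computes the empirical intensities of the reference scan at a set of
#' anchor percentiles. Applying the resulting map to another scan
#' (\code{\link{applyNormalization}}) linearly aligns that scan's
#' percentile values with the reference's, reducing scanner- and
#' patient-specific intensity variability before feature extraction.
#'
#' @param reference an \linkS4class{ImageVolume} serving as the
#'   intensity standard.
#' @param mask optional \linkS4class{MaskVolume}; when given, percentiles
#'   are computed over in-mask voxels only.
#' @param anchors strictly increasing percentiles in [0, 100]. The
#'   default spans the distribution while staying robust to tails.
#' @return A \linkS4class{NormalizationMap}.
#' @export
fitReferenceHistogram <- function(reference, mask = NULL,
                                  anchors = c(1, 5, 25, 50, 75, 95, 99)) {
    stopifnot(is(reference, "ImageVolume"))
    if (length(anchors) < 2L)
        stop("at least 2 anchor percentiles are required")
    if (any(anchors < 0) || any(anchors > 100) || any(diff(anchors) <= 0))
        stop("anchors must be strictly increasing within [0, 100]")
    v <- reference@voxels
    if (!is.null(mask)) {
        stopifnot(is(mask, "MaskVolume"))
        if (!identical(dim(mask@voxels), dim(v)))
            stop("mask shape does not match the reference")
        v <- v[mask@voxels == 1]
        if (length(v) == 0L) stop("mask selects no voxels")
    }
    vals <- unname(quantile(v, probs = anchors / 100, type = 7, names = FALSE))
    new("NormalizationMap", anchors = as.numeric(anchors),
        referenceValues = as.numeric(vals))
}

# Piecewise-linear map through (knotsX, knotsY) with terminal-segment
# slope extrapolation beyond the outermost knots. Duplicate x knots
# (degenerate image percentiles) are collapsed by averaging y.
piecewiseLinear <- function(x, knotsX, knotsY) {
    ux <- unique(knotsX)
    if (length(ux) < length(knotsX)) {
        knotsY <- vapply(ux, function(k) mean(knotsY[knotsX == k]), 0)
        knotsX <- ux
    }
    n <- length(knotsX)
    out <- approx(knotsX, knotsY, xout = x, rule = 2, ties = "ordered")$y
    loSlope <- (knotsY[2] - knotsY[1]) / (knotsX[2] - knotsX[1])
    hiSlope <- (knotsY[n] - knotsY[n - 1]) / (knotsX[n] - knotsX[n - 1])
    below <- x < knotsX[1]
    above <- x > knotsX[n]
    out[below] <- knotsY[1] + loSlope * (x[below] - knotsX[1])
    out[above] <- knotsY[n] + hiSlope * (x[above] - knotsX[n])
    out
}

#' Apply a normalization map to an image
#'
#' Monotone piecewise-linear intensity transform: the image's own
#' percentile values at the map's anchors are mapped exactly onto the
#' reference values; intensities beyond the outermost anchors are
#' extrapolated with the terminal segment slope. The voxel intensity
#' order is preserved.
#'
#' A degenerate image (all voxels equal) cannot define a percentile
#' spread; it is flagged with a warning and returned as a constant image
#' at the reference median-anchor value.
#'
#' @param image an \linkS4class{ImageVolume}.
#' @param map a \linkS4class{NormalizationMap}.
#' @return The normalized \linkS4class{ImageVolume}.
#' @export
applyNormalization <- function(image, map) {
    stopifnot(is(image, "ImageVolume"), is(map, "NormalizationMap"))
    validObject(map)
    v <- image@voxels
    qin <- unname(quantile(v, probs = map@anchors / 100, type = 7,
                           names = FALSE))
    if (diff(range(v)) == 0 && length(unique(map@referenceValues)) >= 2L) {
        warning("degenerate image: all voxels equal; returning a constant")
        mid <- piecewiseLinear(50, map@anchors, map@referenceValues)
        out <- array(mid, dim(v))
        return(ImageVolume(out, image@spacing, image@origin))
    }
    out <- piecewiseLinear(as.numeric(v), qin, map@referenceValues)
    ImageVolume(array(out, dim(v)), image@spacing, image@origin)
}

#' Absolute (fixed bin width) discretization
#'
#' Assigns in-mask voxels the gray level
#' \code{floor(x / W) - floor(min / W) + 1} where \code{min} is the
#' in-mask minimum, so binning is anchored to absolute HU bin edges and
#' invariant under intensity shifts that are exact multiples of the bin
#' width. Out-of-mask voxels get level 0.
#'
#' @param image an \linkS4class{ImageVolume} (or
#'   \linkS4class{FilteredImage}).
#' @param mask a \linkS4class{MaskVolume} with at least one voxel.
#' @param binWidthHu positive bin width (25 HU is the conventional
#'   absolute bin width for CT radiomics).
#' @return A \linkS4class{DiscretizedVolume}.
#' @export
discretize <- function(image, mask, binWidthHu = 25) {
    stopifnot(is(image, "ImageVolume"), is(mask, "MaskVolume"))
    if (binWidthHu <= 0) stop("bin width must be positive")
    if (!identical(dim(image@voxels), dim(mask@voxels)))
        stop("image and mask shapes differ")
    res <- cpp_discretize(as.numeric(image@voxels),
                          as.logical(mask@voxels == 1), binWidthHu)
    lev <- res$levels
    dim(lev) <- dim(image@voxels)
    new("DiscretizedVolume", levels = lev, binWidthHu = binWidthHu,
        nLevels = as.integer(res$nLevels))
}

#' Geometric mask expansion
#'
#' Dilates a binary mask by a physical margin: the output contains
#' exactly the voxels whose centre lies within Euclidean distance
#' \code{marginMm} of some input foreground voxel centre, with
#' anisotropic spacing respected. Always a superset of the input; at
#' sub-voxel margins (e.g. 0.5 mm at 1 mm in-plane spacing) it is a
#' no-op.
#'
#' @param mask a \linkS4class{MaskVolume}.
#' @param marginMm non-negative margin in millimetres.
#' @return The expanded \linkS4class{MaskVolume}.
#' @export
expandMask <- function(mask, marginMm = 0.5) {
    stopifnot(is(mask, "MaskVolume"))
    if (marginMm < 0) stop("margin must be non-negative")
    sp <- mask@spacing
    d <- dim(mask@voxels)
    reach <- floor(marginMm / sp)
    offs <- expand.grid(i = -reach[1]:reach[1], j = -reach[2]:reach[2],
                        k = -reach[3]:reach[3])
    dist <- sqrt((offs$i * sp[1])^2 + (offs$j * sp[2])^2 +
                 (offs$k * sp[3])^2)
    offs <- offs[dist <= marginMm + 1e-12, , drop = FALSE]
    src <- mask@voxels == 1
    out <- array(FALSE, d)
    for (r in seq_len(nrow(offs))) {
        oi <- offs$i[r]; oj <- offs$j[r]; ok <- offs$k[r]
        # destination ranges receiving mass from the shifted source
        di <- max(1, 1 + oi):min(d[1], d[1] + oi)
        dj <- max(1, 1 + oj):min(d[2], d[2] + oj)
        dk <- max(1, 1 + ok):min(d[3], d[3] + ok)
        out[di, dj, dk] <- out[di, dj, dk] | src[di - oi, dj - oj, dk - ok]
    }
    MaskVolume(out, mask@spacing, mask@origin)
}

#' Union of several masks
#'
#' @param masks list of aligned \linkS4class{MaskVolume}s.
#' @return A \linkS4class{MaskVolume} marking voxels in any input.
#' @export
unionMasks <- function(masks) {
    stopifnot(length(masks) >= 1L)
    v <- masks[[1]]@voxels
    for (m in masks[-1]) {
        if (!identical(dim(m@voxels), dim(v))) stop("mask shapes differ")
        v <- pmax(v, m@voxels)
    }
    MaskVolume(v, masks[[1]]@spacing, masks[[1]]@origin)
}

#' Mask subtraction (lungs minus expanded tumor)
#'
#' Set difference of two aligned masks, used to strip the (expanded)
#' gross tumor volume from the lungs so that only healthy parenchyma is
#' featurized. An empty result is an error: there would be nothing left
#' to featurize.
#'
#' @param lungs,gtvExpanded aligned \linkS4class{MaskVolume}s.
#' @return A \linkS4class{MaskVolume} of \code{lungs} minus
#'   \code{gtvExpanded}.
#' @export
subtractMask <- function(lungs, gtvExpanded) {
    stopifnot(is(lungs, "MaskVolume"), is(gtvExpanded, "MaskVolume"))
    if (!identical(dim(lungs@voxels), dim(gtvExpanded@voxels)))
        stop("mask shapes differ")
    out <- lungs@voxels * (1 - gtvExpanded@voxels)
    if (!any(out == 1))
        stop("empty region: no parenchyma left after GTV subtraction")
    MaskVolume(out, lungs@spacing, lungs@origin)
}
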