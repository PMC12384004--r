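# Filter bank: undecimated 3D wavelet subbands, Laplacian of Gaussian,
# gradient magnitude and monotone intensity transforms.

# Orthonormal 1D decomposition low-pass taps per family. Taps are scaled
# by 1/sqrt(2) so that |H(w)|^2 + |G(w)|^2 = 1 per axis: the undecimated
# transform then conserves energy exactly and reconstruction needs no
# renormalization.
waveletTaps <- function(family = c("coif1", "haar")) {
    family <- match.arg(family)
    lo <- switch(family,
        coif1 = c(-0.015655728135465,  -0.072732619512854,
                   0.384864846864203,   0.852572020212255,
                   0.337897662457809,  -0.072732619512854),
        haar  = c(0.707106781186547, 0.707106781186547))
    lo <- lo / sqrt(2)
    L <- length(lo)
    hi <- rev(lo) * (-1)^(seq_len(L) - 1)   # quadrature mirror filter
    list(lo = lo, hi = hi, length = L, center = (L - 1) %/% 2)
}

convolveAxis <- function(v, taps, axis, center,
                         boundary = c("periodic", "replicate"),
                         correlate = FALSE) {
    boundary <- match.arg(boundary)
    d <- dim(v)
    out <- cpp_conv_axis(as.numeric(v), as.integer(d), as.numeric(taps),
                         as.integer(axis - 1), as.integer(center),
                         if (boundary == "periodic") 0L else 1L,
                         isTRUE(correlate))
    dim(out) <- d
    out
}

#' Undecimated single-level 3D wavelet decomposition
#'
#' Separable stationary (undecimated) wavelet transform with periodic
#' boundary handling: a low- (L) or high-pass (H) analysis filter is
#' applied along each axis, giving 8 shape-preserving subbands labelled
#' \code{wavelet-LLL} through \code{wavelet-HHH} (letter order = axis
#' order). Filters are scaled so that the transform conserves energy
#' exactly and \code{\link{waveletReconstruct}} inverts it to machine
#' precision.
#'
#' @param image an \linkS4class{ImageVolume}; every dimension must be at
#'   least the filter length.
#' @param family wavelet family; \code{"coif1"} (default, the
#'   conventional choice for CT radiomics extraction) or \code{"haar"}.
#' @return Named list of 8 \linkS4class{FilteredImage}s in the order
#'   LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH.
#' @export
waveletSubbands <- function(image, family = "coif1") {
    stopifnot(is(image, "ImageVolume"))
    w <- waveletTaps(family)
    d <- dim(image@voxels)
    if (any(d < w$length))
        stop("volume smaller than the wavelet filter (", w$length, " taps)")
    ord <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
    out <- vector("list", 8L)
    names(out) <- ord
    for (nm in ord) {
        letters3 <- strsplit(nm, "")[[1]]
        v <- image@voxels
        for (ax in 1:3) {
            taps <- if (letters3[ax] == "L") w$lo else w$hi
            v <- convolveAxis(v, taps, ax, w$center, "periodic")
        }
        out[[nm]] <- new("FilteredImage", voxels = v,
                         spacing = image@spacing, origin = image@origin,
                         label = paste0("wavelet-", nm))
    }
    out[ord]
}

#' Invert an undecimated wavelet decomposition
#'
#' @param subbands the list returned by \code{\link{waveletSubbands}}.
#' @param family the family used for decomposition.
#' @return The reconstructed \linkS4class{ImageVolume}.
#' @export
waveletReconstruct <- function(subbands, family = "coif1") {
    w <- waveletTaps(family)
    acc <- NULL
    for (nm in names(subbands)) {
        letters3 <- strsplit(sub("^wavelet-", "", subbands[[nm]]@label),
                             "")[[1]]
        v <- subbands[[nm]]@voxels
        for (ax in 1:3) {
            taps <- if (letters3[ax] == "L") w$lo else w$hi
            v <- convolveAxis(v, taps, ax, w$center, "periodic",
                              correlate = TRUE)
        }
        acc <- if (is.null(acc)) v else acc + v
    }
    first <- subbands[[1]]
    ImageVolume(acc, first@spacing, first@origin)
}

# Sampled Gaussian and second-derivative-of-Gaussian taps for one axis.
# sigma in voxels; derivative taps are forced to zero sum so constants
# map exactly to zero.
gaussianKernels <- function(sigmaVox) {
    r <- max(1L, as.integer(ceiling(4 * sigmaVox)))
    x <- -r:r
    g <- exp(-x^2 / (2 * sigmaVox^2))
    g <- g / sum(g)
    d2 <- (x^2 - sigmaVox^2) / sigmaVox^4 * g
    d2 <- d2 - mean(d2)
    list(g = g, d2 = d2, center = r)
}

#' Laplacian of Gaussian filter
#'
#' Band-pass response highlighting blob-like structure at physical scale
#' \code{sigmaMm}: the sum over axes of the second Gaussian derivative,
#' with per-axis sigma \code{sigmaMm / spacing} in voxels and
#' derivatives in mm^-2. Replicate boundary handling. The label encodes
#' the scale, e.g. \code{"log-sigma-2-0-mm-3D"} for 2 mm.
#'
#' @param image an \linkS4class{ImageVolume}.
#' @param sigmaMm positive Gaussian scale in millimetres.
#' @return A \linkS4class{FilteredImage}.
#' @export
logFilter <- function(image, sigmaMm) {
    stopifnot(is(image, "ImageVolume"))
    if (sigmaMm <= 0) stop("sigma must be positive")
    sp <- image@spacing
    sigVox <- sigmaMm / sp
    if (all(sigVox < 0.5))
        warning("sigma is sub-voxel in every axis; response is noise-dominated")
    v <- image@voxels
    acc <- array(0, dim(v))
    for (ax in 1:3) {
        kern <- lapply(1:3, function(a) {
            kk <- gaussianKernels(sigVox[a])
            if (a == ax) list(taps = kk$d2 / sp[a]^2, center = kk$center)
            else list(taps = kk$g, center = kk$center)
        })
        t1 <- v
        for (a in 1:3)
            t1 <- convolveAxis(t1, kern[[a]]$taps, a, kern[[a]]$center,
                               "replicate")
        acc <- acc + t1
    }
    lab <- paste0("log-sigma-", gsub("\\.", "-", sprintf("%.1f", sigmaMm)),
                  "-mm-3D")
    new("FilteredImage", voxels = acc, spacing = image@spacing,
        origin = image@origin, label = lab)
}

#' Gradient magnitude
#'
#' Euclidean norm of the central-difference intensity gradient with
#' physical spacing in the denominator (HU/mm); one-sided differences at
#' the volume faces.
#'
#' @param image an \linkS4class{ImageVolume} with every dimension at
#'   least 2.
#' @return A \linkS4class{FilteredImage} labelled \code{"gradient"}.
#' @export
gradientMagnitude <- function(image) {
    stopifnot(is(image, "ImageVolume"))
    v <- image@voxels
    d <- dim(v)
    if (any(d < 2)) stop("each dimension must be at least 2")
    sp <- image@spacing
    sq <- array(0, d)
    for (ax in 1:3) {
        n <- d[ax]
        idxHi <- pmin(seq_len(n) + 1L, n)
        idxLo <- pmax(seq_len(n) - 1L, 0L + 1L)
        denom <- (idxHi - idxLo) * sp[ax]
        hi <- switch(ax, v[idxHi, , , drop = FALSE],
                         v[, idxHi, , drop = FALSE],
                         v[, , idxHi, drop = FALSE])
        lo <- switch(ax, v[idxLo, , , drop = FALSE],
                         v[, idxLo, , drop = FALSE],
                         v[, , idxLo, drop = FALSE])
        g <- hi - lo
        g <- sweep(g, ax, denom, "/")
        sq <- sq + g^2
    }
    new("FilteredImage", voxels = sqrt(sq), spacing = image@spacing,
        origin = image@origin, label = "gradient")
}

#' Monotone intensity transforms
#'
#' Per-voxel square, square root, logarithm and exponential transforms
#' with the standard radiomics domain handling: with
#' \code{M = max(|x|)},
#' \itemize{
#'   \item square: \code{(x / sqrt(M))^2 * sign(1)} i.e. \code{x^2 / M}
#'     (range-preserving);
#'   \item squareroot: \code{sign(x) * sqrt(M * |x|)};
#'   \item logarithm: \code{sign(x) * c * log(|x| + 1)} with
#'     \code{c = M / log(M + 1)};
#'   \item exponential: \code{exp(c * x)} with \code{c = log(M) / M}.
#' }
#' All outputs are finite for any finite input, negative HU pass through
#' safely, and square followed by squareroot recovers \code{|x|}
#' exactly.
#'
#' @param image an \linkS4class{ImageVolume}.
#' @return Named list of 4 \linkS4class{FilteredImage}s
#'   (\code{square}, \code{squareroot}, \code{logarithm},
#'   \code{exponential}).
#' @export
intensityTransforms <- function(image) {
    stopifnot(is(image, "ImageVolume"))
    v <- image@voxels
    M <- max(abs(v))
    mk <- function(x, lab) new("FilteredImage", voxels = x,
                               spacing = image@spacing,
                               origin = image@origin, label = lab)
    if (M == 0) {
        z <- array(0, dim(v))
        return(list(square = mk(z, "square"),
                    squareroot = mk(z, "squareroot"),
                    logarithm = mk(z, "logarithm"),
                    exponential = mk(array(1, dim(v)), "exponential")))
    }
    sq <- v^2 / M
    sr <- sign(v) * sqrt(M * abs(v))
    lg <- sign(v) * (M / log(M + 1)) * log(abs(v) + 1)
    ex <- exp((log(M) / M) * v)
    list(square = mk(sq, "square"), squareroot = mk(sr, "squareroot"),
         logarithm = mk(lg, "logarithm"), exponential = mk(ex, "exponential"))
}

#' Default filter registry
#'
#' Controls which derived images \code{\link{filterBank}} produces.
#'
#' @param original,wavelet,log,gradient,square,squareroot,logarithm,
#'   exponential logical switches per filter.
#' @param logSigmasMm LoG scales in mm; 2 mm is the scale conventionally
#'   reported for lung parenchyma, 4 mm adds a coarser band.
#' @param waveletFamily wavelet family string.
#' @return A named list understood by \code{\link{filterBank}} and
#'   \code{\link{extractionConfig}}.
#' @export
filterRegistry <- function(original = TRUE, wavelet = TRUE, log = TRUE,
                           gradient = TRUE, square = TRUE,
                           squareroot = TRUE, logarithm = TRUE,
                           exponential = TRUE, logSigmasMm = c(2, 4),
                           waveletFamily = "coif1") {
    list(original = original, wavelet = wavelet, log = log,
         gradient = gradient, square = square, squareroot = squareroot,
         logarithm = logarithm, exponential = exponential,
         logSigmasMm = logSigmasMm, waveletFamily = waveletFamily)
}

#' Apply the enabled filters to an image
#'
#' @param image an \linkS4class{ImageVolume}.
#' @param registry a \code{\link{filterRegistry}}.
#' @return Named list of \linkS4class{FilteredImage}s, including the
#'   unfiltered image under \code{"original"} when enabled.
#' @export
filterBank <- function(image, registry = filterRegistry()) {
    out <- list()
    if (isTRUE(registry$original))
        out$original <- new("FilteredImage", voxels = image@voxels,
                            spacing = image@spacing, origin = image@origin,
                            label = "original")
    if (isTRUE(registry$wavelet))
        out <- c(out, waveletSubbands(image, registry$waveletFamily))
    if (isTRUE(registry$log))
        for (s in registry$logSigmasMm) {
            f <- logFilter(image, s)
            out[[f@label]] <- f
        }
    if (isTRUE(registry$gradient))
        out$gradient <- gradientMagnitude(image)
    tr <- NULL
    for (nm in c("square", "squareroot", "logarithm", "exponential"))
        if (isTRUE(registry[[nm]])) {
            if (is.null(tr)) tr <- intensityTransforms(image)
            out[[nm]] <- tr[[nm]]
        }
    names(out) <- vapply(out, function(f) f@label, "")
    out
}
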