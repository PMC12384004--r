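# First-order statistics and gray-level matrix texture features
# (GLCM, GLDM, GLSZM) on masked, discretized, optionally filtered
# volumes.

#' Gray level co-occurrence matrix
#'
#' @slot matrix Ng x Ng normalized symmetric co-occurrence
#'   probabilities.
#' @slot distance Chebyshev offset distance.
#' @slot directions integer matrix of pooled 3D offsets.
#' @export
setClass("GLCM",
    representation(matrix = "matrix", distance = "integer",
                   directions = "matrix"))

setValidity("GLCM", function(object) {
    m <- object@matrix
    if (nrow(m) != ncol(m)) return("matrix must be square")
    if (any(m < 0)) return("entries must be non-negative")
    if (abs(sum(m) - 1) > 1e-8) return("entries must sum to 1")
    if (max(abs(m - t(m))) > 1e-12) return("matrix must be symmetric")
    TRUE
})

#' Gray level dependence matrix
#'
#' @slot matrix Ng x Nd dependence counts.
#' @slot alpha dependence tolerance on gray-level difference.
#' @slot Nz total dependence count (= in-mask voxel count).
#' @export
setClass("GLDM",
    representation(matrix = "matrix", alpha = "integer", Nz = "numeric"))

setValidity("GLDM", function(object) {
    if (any(object@matrix < 0)) return("counts must be non-negative")
    if (abs(sum(object@matrix) - object@Nz) > 1e-9)
        return("counts must sum to Nz")
    TRUE
})

#' Gray level size zone matrix
#'
#' @slot matrix Ng x Ns zone counts (column j = zones of size j).
#' @slot Nz total zone count.
#' @export
setClass("GLSZM",
    representation(matrix = "matrix", Nz = "numeric"))

setValidity("GLSZM", function(object) {
    if (any(object@matrix < 0)) return("counts must be non-negative")
    if (abs(sum(object@matrix) - object@Nz) > 1e-9)
        return("counts must sum to Nz")
    TRUE
})

# The 13 unique 3D direction offsets (one representative per +/- pair)
# at a given Chebyshev distance.
glcmOffsets <- function(distance = 1L) {
    g <- expand.grid(i = -1:1, j = -1:1, k = -1:1)
    g <- g[!(g$i == 0 & g$j == 0 & g$k == 0), ]
    # keep one representative per antipodal pair: first nonzero positive
    keep <- apply(g, 1, function(o) {
        nz <- o[o != 0]
        nz[1] > 0
    })
    as.matrix(g[keep, , drop = FALSE]) * distance
}

#' Build a gray level co-occurrence matrix
#'
#' Counts co-occurrences of gray-level pairs over the 13 unique 3D
#' direction offsets at the given Chebyshev distance, restricted to
#' in-mask voxel pairs, symmetrized, pooled across directions and
#' normalized to probabilities. With \code{pool = "average"} each
#' direction is normalized separately and the matrices averaged.
#'
#' @param levels a \linkS4class{DiscretizedVolume} (0 marks
#'   out-of-mask voxels).
#' @param distance positive integer offset distance.
#' @param pool \code{"sum"} (default) or \code{"average"}.
#' @return A \linkS4class{GLCM}.
#' @export
glcmBuild <- function(levels, distance = 1L, pool = c("sum", "average")) {
    stopifnot(is(levels, "DiscretizedVolume"))
    pool <- match.arg(pool)
    lev <- levels@levels
    if (sum(lev > 0) < 2L) stop("need at least 2 in-mask voxels")
    ng <- levels@nLevels
    offs <- glcmOffsets(as.integer(distance))
    if (pool == "sum") {
        counts <- cpp_glcm_counts(as.integer(lev), as.integer(dim(lev)),
                                  as.integer(ng), offs)
        m <- counts / sum(counts)
    } else {
        m <- matrix(0, ng, ng)
        used <- 0L
        for (r in seq_len(nrow(offs))) {
            cr <- cpp_glcm_counts(as.integer(lev), as.integer(dim(lev)),
                                  as.integer(ng),
                                  offs[r, , drop = FALSE])
            s <- sum(cr)
            if (s > 0) {
                m <- m + cr / s
                used <- used + 1L
            }
        }
        m <- m / used
    }
    new("GLCM", matrix = m, distance = as.integer(distance),
        directions = offs)
}

#' GLCM Correlation
#'
#' Linear dependence of paired gray levels:
#' \code{(sum_ij i*j*p(i,j) - mu_x*mu_y) / (sigma_x*sigma_y)}. Returns 1
#' for a degenerate region with a single gray level (the conventional
#' limit).
#'
#' @param m a \linkS4class{GLCM}.
#' @return Scalar in [-1, 1].
#' @export
glcmCorrelation <- function(m) {
    p <- m@matrix
    i <- seq_len(nrow(p))
    px <- rowSums(p)
    mux <- sum(i * px)
    sx2 <- sum((i - mux)^2 * px)
    if (sx2 <= 0) return(1)
    e <- sum(outer(i, i) * p)
    (e - mux * mux) / sx2          # symmetric matrix: mu_x = mu_y
}

#' GLCM Informational Measure of Correlation 1
#'
#' \code{(HXY - HXY1) / max(HX, HY)} with Shannon entropies in bits and
#' the convention \code{0 * log 0 = 0}; returns 0 when
#' \code{max(HX, HY) = 0} (single gray level).
#'
#' @param m a \linkS4class{GLCM}.
#' @return Scalar (non-positive).
#' @export
glcmImc1 <- function(m) {
    p <- m@matrix
    px <- rowSums(p)
    py <- colSums(p)
    xlogx <- function(x) ifelse(x > 0, x * log2(x), 0)
    hx <- -sum(xlogx(px))
    hy <- -sum(xlogx(py))
    if (max(hx, hy) <= 0) return(0)
    hxy <- -sum(xlogx(p))
    pq <- outer(px, py)
    hxy1 <- -sum(ifelse(p > 0 & pq > 0, p * log2(pq), 0))
    (hxy - hxy1) / max(hx, hy)
}

#' Build a gray level dependence matrix
#'
#' For each in-mask voxel of level i, its dependence is
#' \code{j = 1 + } the number of neighbours within Chebyshev distance
#' \code{distance} (26-neighbourhood at distance 1, out-of-mask
#' neighbours excluded) whose level differs from i by at most
#' \code{alpha}.
#'
#' @param levels a \linkS4class{DiscretizedVolume}.
#' @param alpha non-negative gray-level difference tolerance.
#' @param distance neighbourhood Chebyshev radius.
#' @return A \linkS4class{GLDM}.
#' @export
gldmBuild <- function(levels, alpha = 0L, distance = 1L) {
    stopifnot(is(levels, "DiscretizedVolume"))
    lev <- levels@levels
    if (!any(lev > 0)) stop("mask selects no voxels")
    counts <- cpp_gldm_counts(as.integer(lev), as.integer(dim(lev)),
                              as.integer(levels@nLevels),
                              as.integer(alpha), as.integer(distance))
    # trim trailing all-zero dependence columns (keep at least one)
    nd <- max(which(colSums(counts) > 0))
    counts <- counts[, seq_len(nd), drop = FALSE]
    new("GLDM", matrix = counts, alpha = as.integer(alpha),
        Nz = sum(counts))
}

#' GLDM Low Gray Level Emphasis
#'
#' \code{sum_ij P(i,j) / i^2 / Nz}: large when low gray levels dominate
#' the dependence structure.
#'
#' @param m a \linkS4class{GLDM}.
#' @return Scalar in (0, 1].
#' @export
gldmLowGrayLevelEmphasis <- function(m) {
    i <- seq_len(nrow(m@matrix))
    sum(rowSums(m@matrix) / i^2) / m@Nz
}

#' Build a gray level size zone matrix
#'
#' Zones are 26-connected components of equal gray level within the
#' mask; entry (i, j) counts zones of level i and size j voxels.
#'
#' @param levels a \linkS4class{DiscretizedVolume}.
#' @return A \linkS4class{GLSZM}.
#' @export
glszmBuild <- function(levels) {
    stopifnot(is(levels, "DiscretizedVolume"))
    lev <- levels@levels
    if (!any(lev > 0)) stop("mask selects no voxels")
    lab <- cpp_label_zones(as.integer(lev), as.integer(dim(lev)))
    inz <- lab > 0
    zsize <- tabulate(lab[inz])
    zlev <- lev[inz][match(seq_along(zsize), lab[inz])]
    ng <- levels@nLevels
    ns <- max(zsize)
    m <- matrix(tabulate(zlev + ng * (zsize - 1), ng * ns), ng, ns)
    new("GLSZM", matrix = m, Nz = length(zsize))
}

#' GLSZM Size Zone Non-Uniformity Normalized
#'
#' \code{sum_j (sum_i P(i,j))^2 / Nz^2}: 1 when all zones share one
#' size, small when zone sizes are heterogeneous.
#'
#' @param m a \linkS4class{GLSZM}.
#' @return Scalar in (0, 1].
#' @export
glszmSizeZoneNonUniformityNormalized <- function(m) {
    sj <- colSums(m@matrix)
    sum(sj^2) / m@Nz^2
}

#' First-order statistics of masked intensities
#'
#' Order statistics and moments of the (possibly filtered, never
#' discretized) in-mask intensities. Variance is the population
#' variance; skewness is the standardized third moment (0 for a
#' constant region); energy is the sum of squared intensities.
#'
#' @param values numeric vector of in-mask voxel intensities.
#' @return Named vector: Maximum, Median, Mean, Minimum, Range,
#'   Variance, Skewness, Energy.
#' @export
firstOrderFeatures <- function(values) {
    if (length(values) == 0L) stop("empty region")
    m <- mean(values)
    m2 <- mean((values - m)^2)
    m3 <- mean((values - m)^3)
    c(Maximum = max(values), Median = median(values), Mean = m,
      Minimum = min(values), Range = max(values) - min(values),
      Variance = m2, Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
      Energy = sum(values^2))
}

#' Feature-extraction configuration
#'
#' @param filters a \code{\link{filterRegistry}}.
#' @param binWidthHu absolute discretization bin width (HU) applied,
#'   with the same width, to the intensity range of every filtered
#'   image.
#' @param gtvMarginMm geometric GTV expansion before subtraction (mm).
#' @param normalizationMap optional \linkS4class{NormalizationMap}
#'   applied before filtering; \code{NULL} skips normalization (for
#'   HU-calibrated inputs).
#' @param glcmDistance,gldmAlpha,gldmDistance texture-matrix settings.
#' @param glcmPool direction pooling, \code{"sum"} or \code{"average"}.
#' @param featureClasses subset of
#'   \code{c("firstorder", "glcm", "gldm", "glszm")}.
#' @return A configuration list for \code{\link{extractFeatures}}.
#' @export
extractionConfig <- function(filters = filterRegistry(), binWidthHu = 25,
                             gtvMarginMm = 0.5, normalizationMap = NULL,
                             glcmDistance = 1L, gldmAlpha = 0L,
                             gldmDistance = 1L, glcmPool = "sum",
                             featureClasses = c("firstorder", "glcm",
                                                "gldm", "glszm")) {
    list(filters = filters, binWidthHu = binWidthHu,
         gtvMarginMm = gtvMarginMm, normalizationMap = normalizationMap,
         glcmDistance = glcmDistance, gldmAlpha = gldmAlpha,
         gldmDistance = gldmDistance, glcmPool = glcmPool,
         featureClasses = featureClasses)
}

# The lungs-minus-expanded-GTV region of a patient.
parenchymaMask <- function(patient, marginMm = 0.5) {
    gtvs <- patient@gtvMasks
    if (length(gtvs) == 0L) return(patient@lungMask)
    expanded <- lapply(gtvs, expandMask, marginMm = marginMm)
    subtractMask(patient@lungMask, unionMasks(expanded))
}

# Features of one filtered image over a region.
filteredImageFeatures <- function(fimg, mask, config) {
    vals <- fimg@voxels[mask@voxels == 1]
    out <- numeric(0)
    if ("firstorder" %in% config$featureClasses) {
        fo <- firstOrderFeatures(vals)
        names(fo) <- paste0(fimg@label, "_firstorder_", names(fo))
        out <- c(out, fo)
    }
    needTexture <- any(c("glcm", "gldm", "glszm") %in% config$featureClasses)
    if (needTexture) {
        disc <- discretize(fimg, mask, config$binWidthHu)
        if ("glcm" %in% config$featureClasses) {
            g <- glcmBuild(disc, config$glcmDistance, config$glcmPool)
            out <- c(out, setNames(
                c(glcmCorrelation(g), glcmImc1(g)),
                paste0(fimg@label, "_glcm_", c("Correlation", "Imc1"))))
        }
        if ("gldm" %in% config$featureClasses) {
            dm <- gldmBuild(disc, config$gldmAlpha, config$gldmDistance)
            out <- c(out, setNames(
                gldmLowGrayLevelEmphasis(dm),
                paste0(fimg@label, "_gldm_LowGrayLevelEmphasis")))
        }
        if ("glszm" %in% config$featureClasses) {
            sz <- glszmBuild(disc)
            out <- c(out, setNames(
                glszmSizeZoneNonUniformityNormalized(sz),
                paste0(fimg@label, "_glszm_SizeZoneNonUniformityNormalized")))
        }
    }
    out
}

#' Extract the radiomic feature row of one patient and phase
#'
#' Runs the full per-patient chain: build the healthy-parenchyma region
#' (lungs minus expanded GTVs), optionally normalize intensities, apply
#' the filter bank, then compute first-order features on the filtered
#' intensities and texture features on the absolutely discretized
#' filtered intensities. Feature names follow the canonical
#' \code{filter_class_feature} scheme (e.g.
#' \code{"wavelet-HHH_glcm_Correlation"}).
#'
#' @param patient a \linkS4class{SyntheticPatient} (or any object with
#'   \code{phase0}/\code{phase50}, \code{lungMask} and \code{gtvMasks}
#'   slots).
#' @param phase \code{"phase0"} or \code{"phase50"}.
#' @param region currently \code{"lungs-gtv"}, the healthy parenchyma.
#' @param config an \code{\link{extractionConfig}}.
#' @return Named numeric vector, one value per enabled
#'   (filter x feature) pair.
#' @export
extractFeatures <- function(patient, phase = c("phase0", "phase50"),
                            region = "lungs-gtv",
                            config = extractionConfig()) {
    phase <- match.arg(phase)
    region <- match.arg(region, "lungs-gtv")
    img <- slot(patient, phase)
    mask <- parenchymaMask(patient, config$gtvMarginMm)
    if (!is.null(config$normalizationMap))
        img <- applyNormalization(img, config$normalizationMap)
    bank <- filterBank(img, config$filters)
    unlist(unname(lapply(bank, filteredImageFeatures, mask = mask,
                         config = config)))
}

#' Extract the feature table of a whole cohort
#'
#' @param cohort a \linkS4class{RadiomicsCohort}.
#' @param phase \code{"phase0"} or \code{"phase50"}.
#' @param config an \code{\link{extractionConfig}}.
#' @return A \linkS4class{FeatureTable} (patients x features).
#' @export
extractCohortFeatures <- function(cohort, phase, config = extractionConfig()) {
    rows <- lapply(cohort@patients, extractFeatures, phase = phase,
                   config = config)
    m <- do.call(rbind, rows)
    rownames(m) <- vapply(cohort@patients, function(p) p@patientId, "")
    FeatureTable(m)
}

#' Phase-difference features
#'
#' Elementwise Phase 0 minus Phase 50 feature values, the respiratory-
#' variation (delta-phase) design. The orientation (0 minus 50) is fixed
#' by convention; downstream models are sign-invariant up to coefficient
#' sign.
#'
#' @param t0,t50 \linkS4class{FeatureTable}s with identical patients and
#'   features.
#' @return A \linkS4class{FeatureTable} of differences.
#' @export
deltaFeatures <- function(t0, t50) {
    stopifnot(is(t0, "FeatureTable"), is(t50, "FeatureTable"))
    if (!identical(dimnames(t0), dimnames(t50)))
        stop("feature tables must share patients and feature names")
    FeatureTable(featureMatrix(t0) - featureMatrix(t50))
}
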