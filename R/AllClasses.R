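#' @useDynLib dlcoRadiomics, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot show setValidity
#' @importFrom stats quantile cor median rnorm runif rbinom rpois plogis
#'   qlogis qnorm pnorm wilcox.test fisher.test chisq.test glm predict
#'   binomial coef sd approx setNames as.formula
#' @importFrom utils read.csv write.csv modifyList
#' @import SummarizedExperiment
NULL

# ---------------------------------------------------------------------------
# Image containers
# ---------------------------------------------------------------------------

#' 3D scalar image volume in Hounsfield units
#'
#' The elementary container consumed by every filter and feature
#' computation: a 3D voxel grid in HU together with its physical voxel
#' spacing and origin (world coordinates of voxel \code{[1,1,1]};
#' physical position = origin + (index - 1) * spacing).
#'
#' @slot voxels 3D numeric array of intensities (HU).
#' @slot spacing numeric(3), positive voxel spacing in millimetres.
#' @slot origin numeric(3), world origin in millimetres.
#' @export
setClass("ImageVolume",
    representation(voxels = "array", spacing = "numeric", origin = "numeric"))

setValidity("ImageVolume", function(object) {
    d <- dim(object@voxels)
    if (length(d) != 3L)
        return("voxels must be a 3D array")
    if (!is.numeric(object@voxels))
        return("voxels must be numeric")
    if (anyNA(object@voxels) || any(!is.finite(object@voxels)))
        return("voxels must be finite")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        return("spacing must be 3 positive reals")
    if (length(object@origin) != 3L || anyNA(object@origin))
        return("origin must be 3 reals")
    TRUE
})

#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array (HU).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) world origin in mm.
#' @return An \linkS4class{ImageVolume}.
#' @examples
#' img <- ImageVolume(array(rnorm(8), c(2, 2, 2)))
#' @export
ImageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Binary mask aligned to an image volume
#'
#' A \{0,1\} voxel grid sharing shape, spacing and origin with the image
#' it annotates (lungs, gross tumor volume, or derived regions such as
#' lungs-minus-GTV).
#'
#' @export
setClass("MaskVolume", contains = "ImageVolume")

setValidity("MaskVolume", function(object) {
    v <- object@voxels
    if (!all(v == 0 | v == 1))
        return("mask voxels must be 0 or 1")
    TRUE
})

#' Construct a MaskVolume
#'
#' @param voxels 3D array of \{0,1\} (logical or numeric).
#' @param spacing,origin as for \code{\link{ImageVolume}}.
#' @return A \linkS4class{MaskVolume}.
#' @export
MaskVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    v <- array(as.numeric(voxels), dim(voxels))
    new("MaskVolume", voxels = v, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Piecewise-linear histogram normalization map
#'
#' Anchor percentiles together with the reference intensities they map
#' onto; applying the map aligns an image's intensity distribution with
#' the reference scan's at those percentiles.
#'
#' @slot anchors strictly increasing percentiles in [0, 100].
#' @slot referenceValues non-decreasing reference intensities, one per
#'   anchor.
#' @export
setClass("NormalizationMap",
    representation(anchors = "numeric", referenceValues = "numeric"))

setValidity("NormalizationMap", function(object) {
    a <- object@anchors
    if (length(a) < 2L) return("at least 2 anchors required")
    if (any(a < 0) || any(a > 100)) return("anchors must lie in [0, 100]")
    if (any(diff(a) <= 0)) return("anchors must be strictly increasing")
    r <- object@referenceValues
    if (length(r) != length(a)) return("one reference value per anchor")
    if (any(diff(r) < 0)) return("reference values must be non-decreasing")
    TRUE
})

#' Absolutely discretized volume
#'
#' Gray levels obtained by fixed-bin-width (absolute) discretization of
#' in-mask intensities; 0 marks voxels outside the mask.
#'
#' @slot levels 3D integer array; in-mask values in [1, nLevels].
#' @slot binWidthHu positive bin width in HU.
#' @slot nLevels number of occupied-or-below gray levels.
#' @export
setClass("DiscretizedVolume",
    representation(levels = "array", binWidthHu = "numeric",
                   nLevels = "integer"))

setValidity("DiscretizedVolume", function(object) {
    l <- object@levels
    if (length(dim(l)) != 3L) return("levels must be a 3D array")
    if (any(l < 0)) return("levels must be non-negative")
    if (object@binWidthHu <= 0) return("bin width must be positive")
    if (max(l) > object@nLevels) return("levels exceed nLevels")
    TRUE
})

#' A filtered derived image
#'
#' An \linkS4class{ImageVolume} plus the canonical label of the filter
#' that produced it (e.g. \code{"wavelet-HHH"},
#' \code{"log-sigma-2-0-mm-3D"}, \code{"gradient"}, \code{"original"}).
#'
#' @slot label character filter label used as the feature-name prefix.
#' @export
setClass("FilteredImage", contains = "ImageVolume",
    representation(label = "character"))

setValidity("FilteredImage", function(object) {
    if (length(object@label) != 1L || !nzchar(object@label))
        return("label must be a non-empty string")
    TRUE
})

# ---------------------------------------------------------------------------
# Feature table
# ---------------------------------------------------------------------------

#' Patients-by-features table
#'
#' A \linkS4class{SummarizedExperiment} holding one assay
#' (\code{"features"}) with features as rows (canonical
#' \code{filter_class_feature} names) and patients as columns.
#' Construct from a patients x features matrix with
#' \code{FeatureTable()}; recover that orientation with
#' \code{\link{featureMatrix}}.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
    if (!identical(assayNames(object), "features"))
        return("FeatureTable must hold a single assay named 'features'")
    if (anyDuplicated(rownames(object)))
        return("duplicate feature names")
    if (anyDuplicated(colnames(object)))
        return("duplicate patient ids")
    a <- assay(object, "features")
    if (!is.numeric(a)) return("feature values must be numeric")
    if (any(is.infinite(a))) return("feature values must be finite or NA")
    TRUE
})

#' Construct a FeatureTable from a patients x features matrix
#'
#' @param x numeric matrix, rows = patients (rownames = patient ids),
#'   columns = canonical feature names.
#' @return A \linkS4class{FeatureTable}.
#' @export
FeatureTable <- function(x) {
    x <- as.matrix(x)
    if (is.null(rownames(x))) rownames(x) <- paste0("P", seq_len(nrow(x)))
    se <- SummarizedExperiment(assays = list(features = t(x)))
    new("FeatureTable", se)
}

#' Extract the patients x features matrix
#'
#' @param x A \linkS4class{FeatureTable}.
#' @return Numeric matrix, rows = patients, columns = features.
#' @export
featureMatrix <- function(x) {
    stopifnot(is(x, "FeatureTable"))
    t(assay(x, "features"))
}

# ---------------------------------------------------------------------------
# Synthetic cohort
# ---------------------------------------------------------------------------

#' One synthetic patient
#'
#' Paired-phase volumes, lung and lesion masks, and a one-row clinical
#' record. Masks are defined on the Phase 0 geometry and shared by both
#' phases.
#'
#' @export
setClass("SyntheticPatient",
    representation(patientId = "character", phase0 = "ImageVolume",
                   phase50 = "ImageVolume", lungMask = "MaskVolume",
                   gtvMasks = "list", clinical = "data.frame"))

setValidity("SyntheticPatient", function(object) {
    if (!identical(dim(object@phase0@voxels), dim(object@phase50@voxels)))
        return("phase volumes must share shape")
    if (!identical(object@phase0@spacing, object@phase50@spacing))
        return("phase volumes must share spacing")
    lung <- object@lungMask@voxels
    for (g in object@gtvMasks) {
        if (!is(g, "MaskVolume")) return("gtvMasks must hold MaskVolume")
        if (any(g@voxels == 1 & lung == 0))
            return("GTV must lie inside the lung mask")
    }
    if (nrow(object@clinical) != 1L) return("clinical must have one row")
    if (object@clinical$dlco_baseline_pct <= 0)
        return("DLCO must be positive")
    TRUE
})

#' A synthetic cohort
#'
#' @slot patients list of \linkS4class{SyntheticPatient}.
#' @slot clinical per-patient clinical table (one row per patient).
#' @slot latents per-patient latent generator parameters (correlation
#'   length, parenchymal mean and spread) kept for diagnostics.
#' @slot config the \linkS4class{CohortConfig} used.
#' @export
setClass("RadiomicsCohort",
    representation(patients = "list", clinical = "data.frame",
                   latents = "data.frame", config = "ANY"))

#' Selection outcome of the iterative correlation clustering
#'
#' @slot selected ordered selected feature names.
#' @slot iterations number of clustering passes performed.
#' @slot audit per-iteration record of clusters, association p-values
#'   and winners.
#' @export
setClass("SelectionResult",
    representation(selected = "character", iterations = "integer",
                   audit = "list"))

#' LASSO radiomic score model
#'
#' Selected feature names and their L1-penalized logistic coefficients;
#' the radiomic score of a patient is the intercept-free sum of
#' coefficient times feature value.
#'
#' @slot featureNames character, features entering the score.
#' @slot coefficients numeric, one per feature.
#' @slot lambda the penalty at which coefficients were taken.
#' @export
setClass("ScoreModel",
    representation(featureNames = "character", coefficients = "numeric",
                   lambda = "numeric"))

setValidity("ScoreModel", function(object) {
    if (length(object@featureNames) != length(object@coefficients))
        return("one coefficient per feature")
    if (any(!is.finite(object@coefficients)))
        return("coefficients must be finite")
    if (length(object@lambda) != 1L || object@lambda <= 0)
        return("lambda must be a positive scalar")
    TRUE
})

#' Repeated cross-validation result
#'
#' @slot aucs per-repetition pooled AUCs.
#' @slot median,iqr summary across repetitions (iqr = c(Q1, Q3)).
#' @slot k,reps,seed the cross-validation design.
#' @export
setClass("CVResult",
    representation(aucs = "numeric", median = "numeric", iqr = "numeric",
                   k = "integer", reps = "integer", seed = "integer"))

setValidity("CVResult", function(object) {
    if (any(object@aucs < 0 | object@aucs > 1))
        return("AUCs must lie in [0, 1]")
    if (length(object@iqr) != 2L) return("iqr must be c(Q1, Q3)")
    if (object@median < object@iqr[1] - 1e-12 ||
        object@median > object@iqr[2] + 1e-12)
        return("median must lie within the IQR")
    TRUE
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "ImageVolume", function(object) {
    d <- dim(object@voxels)
    cat(class(object), sprintf("%dx%dx%d", d[1], d[2], d[3]),
        "spacing", paste(format(object@spacing), collapse = "x"), "mm\n")
    v <- object@voxels
    cat("  intensity range:", format(min(v)), "..", format(max(v)), "\n")
})

setMethod("show", "NormalizationMap", function(object) {
    cat("NormalizationMap with", length(object@anchors), "anchors\n")
    print(data.frame(percentile = object@anchors,
                     reference = object@referenceValues))
})

setMethod("show", "RadiomicsCohort", function(object) {
    n <- length(object@patients)
    cat("RadiomicsCohort with", n, "patients\n")
    if (n > 0) {
        cl <- object@clinical
        cat("  abnormal baseline DLCO:",
            sum(cl$dlco_baseline_pct < 75 | cl$dlco_baseline_pct > 140),
            "/", n, "\n")
        cat("  with post-treatment DLCO:",
            sum(!is.na(cl$dlco_post_pct)), "/", n, "\n")
    }
})

setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult:", length(object@selected), "features after",
        object@iterations, "iteration(s)\n")
    for (f in object@selected) cat("  -", f, "\n")
})

setMethod("show", "ScoreModel", function(object) {
    cat("ScoreModel (lambda =", format(object@lambda), ")\n")
    print(data.frame(feature = object@featureNames,
                     coefficient = object@coefficients))
})

setMethod("show", "CVResult", function(object) {
    cat(sprintf("CVResult: %d x %d-fold CV, median AUC %.3f (IQR %.3f-%.3f)\n",
                object@reps, object@k, object@median,
                object@iqr[1], object@iqr[2]))
})

# ---------------------------------------------------------------------------
# Accessors
# ---------------------------------------------------------------------------

#' Accessors for image containers
#'
#' @param x an \linkS4class{ImageVolume} (or subclass).
#' @return \code{voxels}: the 3D array; \code{imageSpacing}: numeric(3)
#'   spacing in mm; \code{imageOrigin}: numeric(3) origin in mm.
#' @export
voxels <- function(x) x@voxels

#' @rdname voxels
#' @export
imageSpacing <- function(x) x@spacing

#' @rdname voxels
#' @export
imageOrigin <- function(x) x@origin

#' Accessors for cohorts and selection results
#'
#' @param x a \linkS4class{RadiomicsCohort} or
#'   \linkS4class{SelectionResult}.
#' @return \code{clinicalTable}: the per-patient clinical data.frame;
#'   \code{cohortPatients}: the list of patients;
#'   \code{selectedFeatures}: the selected feature names.
#' @export
clinicalTable <- function(x) x@clinical

#' @rdname clinicalTable
#' @export
cohortPatients <- function(x) x@patients

#' @rdname clinicalTable
#' @export
selectedFeatures <- function(x) x@selected
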