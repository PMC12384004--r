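# Synthetic 4DCT cohort generator: paired-phase volumes with planted,
# tunable class differences in parenchymal texture, lesions inside an
# ellipsoidal lung, respiratory compression between phases, and clinical
# covariates coupled to the DLCO label.

#' Cohort generator configuration
#'
#' Defaults encode the study conditions: a cohort with 55/98 abnormal
#' baseline DLCO and 24/98 patients with post-treatment spirometry, on
#' 48 x 48 x 32 voxel grids with 1 x 1 x 2.5 mm spacing. The texture
#' and clinical effects are dimensionless separations: at 0 the classes
#' are exchangeable, at 1 the class difference in each planted latent
#' parameter is about twice its within-class spread.
#'
#' @slot nPatients number of patients (0 allowed: empty cohort).
#' @slot gridShape integer(3) voxel grid.
#' @slot spacingMm numeric(3) voxel spacing (mm).
#' @slot fracAbnormal expected fraction with abnormal baseline DLCO.
#' @slot textureEffect separation of parenchymal texture parameters
#'   (correlation length, intensity level and spread) between classes.
#' @slot clinicalEffect shift of the CCI mean (and log-odds of COPD and
#'   smoking) in the abnormal class.
#' @slot nLesionsRange integer interval of lesions per patient.
#' @slot lesionRadiusMmRange lesion radius interval (mm).
#' @slot phaseCompression craniocaudal scale from Phase 0 to Phase 50,
#'   in (0, 1].
#' @slot noiseSdHu independent per-phase acquisition noise (HU).
#' @slot fracWithPost fraction of patients with post-treatment DLCO.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortConfig",
    representation(nPatients = "integer", gridShape = "integer",
                   spacingMm = "numeric", fracAbnormal = "numeric",
                   textureEffect = "numeric", clinicalEffect = "numeric",
                   nLesionsRange = "integer",
                   lesionRadiusMmRange = "numeric",
                   phaseCompression = "numeric", noiseSdHu = "numeric",
                   fracWithPost = "numeric", seed = "integer"))

setValidity("CohortConfig", function(object) {
    if (object@nPatients < 0) return("nPatients must be non-negative")
    if (length(object@gridShape) != 3L || any(object@gridShape < 8))
        return("gridShape must be 3 integers >= 8")
    if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
        return("spacingMm must be 3 positive reals")
    for (f in c("fracAbnormal", "fracWithPost")) {
        v <- slot(object, f)
        if (v < 0 || v > 1) return(paste(f, "must lie in [0, 1]"))
    }
    if (object@textureEffect < 0 || object@clinicalEffect < 0)
        return("effects must be non-negative")
    if (length(object@nLesionsRange) != 2L ||
        object@nLesionsRange[1] < 1 || diff(object@nLesionsRange) < 0)
        return("nLesionsRange must be a non-empty interval >= 1")
    if (length(object@lesionRadiusMmRange) != 2L ||
        object@lesionRadiusMmRange[1] <= 0 ||
        diff(object@lesionRadiusMmRange) < 0)
        return("lesionRadiusMmRange must be a non-empty positive interval")
    if (object@phaseCompression <= 0 || object@phaseCompression > 1)
        return("phaseCompression must lie in (0, 1]")
    if (object@noiseSdHu < 0) return("noiseSdHu must be non-negative")
    # lung semi-axes (mm); the largest lesion must fit inside
    semi <- 0.42 * object@gridShape * object@spacingMm
    if (object@lesionRadiusMmRange[2] >= 0.9 * min(semi))
        return("lesion larger than the lung for this grid")
    TRUE
})

#' Construct a cohort configuration
#'
#' @param nPatients,gridShape,spacingMm,fracAbnormal,textureEffect,
#'   clinicalEffect,nLesionsRange,lesionRadiusMmRange,phaseCompression,
#'   noiseSdHu,fracWithPost,seed see \linkS4class{CohortConfig}.
#' @return A validated \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(nPatients, gridShape = c(48, 48, 32),
                         spacingMm = c(1, 1, 2.5),
                         fracAbnormal = 55 / 98, textureEffect = 1,
                         clinicalEffect = 1, nLesionsRange = c(1, 2),
                         lesionRadiusMmRange = c(4, 8),
                         phaseCompression = 0.85, noiseSdHu = 20,
                         fracWithPost = 24 / 98, seed = 1L) {
    new("CohortConfig", nPatients = as.integer(nPatients),
        gridShape = as.integer(gridShape),
        spacingMm = as.numeric(spacingMm),
        fracAbnormal = fracAbnormal, textureEffect = textureEffect,
        clinicalEffect = clinicalEffect,
        nLesionsRange = as.integer(nLesionsRange),
        lesionRadiusMmRange = as.numeric(lesionRadiusMmRange),
        phaseCompression = phaseCompression, noiseSdHu = noiseSdHu,
        fracWithPost = fracWithPost, seed = as.integer(seed))
}

# Truncated normal draw by inverse-CDF (exact, vector-safe).
rtruncnorm1 <- function(mean, sd, lo, hi) {
    plo <- pnorm(lo, mean, sd)
    phi <- pnorm(hi, mean, sd)
    qnorm(runif(1, plo, phi), mean, sd)
}

# Gaussian random field: white noise smoothed with an anisotropic
# Gaussian kernel (correlation length in mm), rescaled to unit variance.
gaussianField <- function(gridShape, spacingMm, corrLenMm) {
    f <- array(rnorm(prod(gridShape)), gridShape)
    for (ax in 1:3) {
        sig <- corrLenMm / spacingMm[ax]
        if (sig < 0.3) next
        k <- gaussianKernels(sig)
        f <- convolveAxis(f, k$g, ax, k$center, "replicate")
    }
    s <- sd(f)
    if (s > 0) f <- f / s
    f
}

# Axis-aligned craniocaudal compression about the grid centre with
# linear slice interpolation; out-of-range source slices replicate the
# edge.
compressZ <- function(v, compression) {
    if (compression == 1) return(v)
    nz <- dim(v)[3]
    cz <- (nz + 1) / 2
    out <- array(0, dim(v))
    for (z in seq_len(nz)) {
        src <- min(max(cz + (z - cz) / compression, 1), nz)
        z0 <- floor(src)
        w <- src - z0
        z1 <- min(z0 + 1L, nz)
        out[, , z] <- (1 - w) * v[, , z0] + w * v[, , z1]
    }
    out
}

# Ellipsoid membership for a grid, semi-axes in mm. shrinkMm scales the
# ellipsoid down proportionally by shrinkMm / min(semiMm): for a convex
# body E containing the ball B(min semi-axis), t*E dilated by the ball
# of radius (1-t)*min(semi) stays inside E, so any sphere of radius
# shrinkMm centred in the shrunk ellipsoid lies fully inside E.
ellipsoidMask <- function(gridShape, spacingMm, semiMm, shrinkMm = 0) {
    ax <- lapply(1:3, function(a) ((seq_len(gridShape[a]) - 1) -
                                   (gridShape[a] - 1) / 2) * spacingMm[a])
    t <- max(1 - shrinkMm / min(semiMm), 1e-3)
    s <- semiMm * t
    r2 <- outer(outer((ax[[1]] / s[1])^2, (ax[[2]] / s[2])^2, "+"),
                (ax[[3]] / s[3])^2, "+")
    r2 <= 1
}

#' Generate a synthetic cohort
#'
#' Builds \code{nPatients} patients, each with: a baseline-DLCO class
#' drawn Bernoulli(\code{fracAbnormal}); an ellipsoidal lung filled with
#' a correlated Gaussian random field whose correlation length, mean
#' attenuation and spread carry the class signal scaled by
#' \code{textureEffect}; spherical soft-tissue lesions placed fully
#' inside the lung; a Phase 50 volume obtained by craniocaudal
#' compression of the noiseless Phase 0 content plus independent
#' acquisition noise; and clinical covariates whose coupling to the
#' class scales with \code{clinicalEffect}. DLCO percentages are drawn
#' from class-specific truncated normals (normal class centred at 95\%,
#' abnormal at 60\%) and labels re-derived through the 75--140\% rule,
#' so value and label are always consistent.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return A \linkS4class{RadiomicsCohort}.
#' @export
generateCohort <- function(config) {
    validObject(config)
    set.seed(config@seed)
    gs <- config@gridShape
    sp <- config@spacingMm
    semi <- 0.42 * gs * sp
    lung <- ellipsoidMask(gs, sp, semi)
    patients <- vector("list", config@nPatients)
    clinical <- vector("list", config@nPatients)
    latents <- vector("list", config@nPatients)
    eff <- config@textureEffect
    ceff <- config@clinicalEffect
    for (i in seq_len(config@nPatients)) {
        abnormal <- runif(1) < config@fracAbnormal
        # latent parenchyma parameters; class shifts are ~2x the
        # within-class spread at effect 1
        corrLen <- 2.0 * (if (abnormal) 1 + 0.5 * eff else 1) *
            exp(rnorm(1, 0, 0.12))
        meanHu <- -850 + (if (abnormal) 30 * eff else 0) + rnorm(1, 0, 15)
        sdHu <- 60 * (if (abnormal) 1 + 0.3 * eff else 1) *
            exp(rnorm(1, 0, 0.08))
        field <- gaussianField(gs, sp, corrLen)
        body <- 40 + 12 * gaussianField(gs, sp, 1.5)
        vol <- ifelse(lung, meanHu + sdHu * field, body)
        # lesions: spheres fully inside the lung
        nles <- sample(seq(config@nLesionsRange[1],
                           config@nLesionsRange[2]), 1)
        gtvs <- vector("list", nles)
        for (l in seq_len(nles)) {
            r <- runif(1, config@lesionRadiusMmRange[1],
                       config@lesionRadiusMmRange[2])
            inner <- which(ellipsoidMask(gs, sp, semi, shrinkMm = r))
            centre <- arrayInd(inner[sample.int(length(inner), 1)], gs)
            cmm <- (centre - 1 - (gs - 1) / 2) * sp
            ax <- lapply(1:3, function(a) ((seq_len(gs[a]) - 1) -
                                           (gs[a] - 1) / 2) * sp[a])
            d2 <- outer(outer((ax[[1]] - cmm[1])^2, (ax[[2]] - cmm[2])^2,
                              "+"), (ax[[3]] - cmm[3])^2, "+")
            sphere <- d2 <= r^2
            vol[sphere] <- 20 + rnorm(sum(sphere), 0, 5)
            gtvs[[l]] <- MaskVolume(sphere, sp)
        }
        phase0 <- vol + rnorm(length(vol), 0, config@noiseSdHu)
        phase50 <- compressZ(vol, config@phaseCompression) +
            rnorm(length(vol), 0, config@noiseSdHu)
        # clinical covariates
        cci <- rpois(1, 2 + (if (abnormal) ceff else 0))
        copd <- rbinom(1, 1, plogis(qlogis(0.25) +
                                    (if (abnormal) 0.5 * ceff else 0)))
        smoking <- rbinom(1, 1, plogis(qlogis(0.4) +
                                       (if (abnormal) 0.4 * ceff else 0)))
        age <- round(rtruncnorm1(70, 8, 40, 95))
        dlco <- if (abnormal) rtruncnorm1(60, 12, 1, 74.99)
                else rtruncnorm1(95, 10, 75, 140)
        post <- NA_real_
        if (runif(1) < config@fracWithPost)
            post <- rtruncnorm1(dlco - 10, 8, 1, 180)
        pid <- sprintf("P%03d", i)
        row <- data.frame(patient_id = pid, cci = cci, copd = copd,
                          smoking = smoking, age = age,
                          dlco_baseline_pct = dlco, dlco_post_pct = post,
                          stringsAsFactors = FALSE)
        patients[[i]] <- new("SyntheticPatient", patientId = pid,
                             phase0 = ImageVolume(array(phase0, gs), sp),
                             phase50 = ImageVolume(array(phase50, gs), sp),
                             lungMask = MaskVolume(lung, sp),
                             gtvMasks = gtvs, clinical = row)
        clinical[[i]] <- row
        latents[[i]] <- data.frame(patient_id = pid, corr_len_mm = corrLen,
                                   mean_hu = meanHu, sd_hu = sdHu,
                                   abnormal = abnormal,
                                   stringsAsFactors = FALSE)
    }
    emptyClin <- data.frame(patient_id = character(), cci = integer(),
                            copd = integer(), smoking = integer(),
                            age = numeric(),
                            dlco_baseline_pct = numeric(),
                            dlco_post_pct = numeric(),
                            stringsAsFactors = FALSE)
    new("RadiomicsCohort", patients = patients,
        clinical = if (length(clinical)) do.call(rbind, clinical)
                   else emptyClin,
        latents = if (length(latents)) do.call(rbind, latents)
                  else data.frame(),
        config = config)
}
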