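# Shared synthetic-cohort fixtures, built once per test run and
# memoised because cohort generation plus whole-cohort feature
# extraction is the expensive part of the suite.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(key, builder) {
    if (is.null(.fixtureCache[[key]]))
        .fixtureCache[[key]] <- builder()
    .fixtureCache[[key]]
}

# modeling data (features + labels) for a cohort under the study
# conditions, with the pipeline's default normalization
fixtureModelData <- function(n, textureEffect, clinicalEffect,
                             seed, key = NULL) {
    if (is.null(key))
        key <- paste("md", n, textureEffect, clinicalEffect, seed,
                     sep = "_")
    memoFixture(key, function() {
        cohort <- generateCohort(cohortConfig(
            n, textureEffect = textureEffect,
            clinicalEffect = clinicalEffect, seed = seed))
        nm <- fitReferenceHistogram(cohort@patients[[1]]@phase0)
        cohortModelData(cohort,
                        extractionConfig(normalizationMap = nm))
    })
}

# a small cohort (images kept) for IO and per-patient extraction tests
fixtureSmallCohort <- function() {
    memoFixture("small_cohort", function()
        generateCohort(cohortConfig(3, seed = 42)))
}

# features whose class signal the generator plants: spatial correlation
# (GLCM Correlation), gray-level composition (GLDM Low Gray Level
# Emphasis) and the intensity distribution (location/spread first-order
# statistics)
plantedFeaturePattern <- paste0(
    "glcm_Correlation|gldm_LowGrayLevelEmphasis|",
    "firstorder_(Mean|Median|Variance|Energy|Maximum|Minimum|Range)")
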