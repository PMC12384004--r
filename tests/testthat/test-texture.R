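# Texture matrices and first-order features against hand computations
# and brute-force enumeration.

test_that("GLCM of a constant region puts all mass at (1,1)", {
    lev <- array(1L, c(2, 2, 2))
    d <- new("DiscretizedVolume", levels = lev, binWidthHu = 25,
             nLevels = 1L)
    g <- glcmBuild(d)
    expect_equal(g@matrix, matrix(1, 1, 1))
    expect_equal(glcmCorrelation(g), 1)   # degenerate convention
    expect_equal(glcmImc1(g), 0)
})

test_that("GLCM off-diagonal structure for an alternating pattern", {
    lev <- array(rep(c(1L, 2L), 4), c(8, 1, 1))
    d <- new("DiscretizedVolume", levels = lev, binWidthHu = 25,
             nLevels = 2L)
    g <- glcmBuild(d)
    # along the only axis all 7 adjacent pairs alternate: no mass on the
    # diagonal
    expect_equal(g@matrix[1, 1], 0)
    expect_equal(g@matrix[2, 2], 0)
    expect_equal(sum(g@matrix), 1)
    expect_equal(g@matrix[1, 2], g@matrix[2, 1])
})

test_that("hand-computed GLCM correlation and Imc1 conventions hold", {
    # mass split equally between (1,2) and (2,1): perfect negative
    # linear dependence
    p <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
    g <- new("GLCM", matrix = p, distance = 1L,
             directions = matrix(0L, 0, 3))
    expect_equal(glcmCorrelation(g), -1)
    # independent margins give Imc1 = 0
    px <- c(0.3, 0.7)
    gInd <- new("GLCM", matrix = outer(px, px), distance = 1L,
                directions = matrix(0L, 0, 3))
    expect_equal(glcmImc1(gInd), 0, tolerance = 1e-12)
})

test_that("matrix features match brute-force enumeration on random
           grids", {
    set.seed(31)
    for (i in 1:15) {
        d <- randomDiscretizedGrid(ng = sample(2:5, 1))
        lev <- d@levels
        g <- glcmBuild(d)
        p <- oracleGlcmMatrix(lev, d@nLevels)
        expect_equal(g@matrix, p, tolerance = 1e-12)
        expect_equal(glcmCorrelation(g), oracleGlcmCorrelation(p),
                     tolerance = 1e-9)
        expect_equal(glcmImc1(g), oracleGlcmImc1(p), tolerance = 1e-9)

        dm <- gldmBuild(d)
        om <- oracleGldmMatrix(lev, d@nLevels)
        expect_equal(unname(dm@matrix[, seq_len(ncol(om))]), unname(om))
        expect_equal(gldmLowGrayLevelEmphasis(dm), oracleGldmLgle(om),
                     tolerance = 1e-12)

        sz <- glszmBuild(d)
        zones <- oracleGlszmZones(lev)
        expect_equal(sz@Nz, nrow(zones))
        expect_equal(glszmSizeZoneNonUniformityNormalized(sz),
                     oracleSznn(zones), tolerance = 1e-12)
    }
})

test_that("count-conservation invariants hold after every build", {
    set.seed(32)
    for (i in 1:10) {
        d <- randomDiscretizedGrid(dims = c(5, 4, 3), ng = 3)
        nvox <- sum(d@levels > 0)
        expect_equal(sum(glcmBuild(d)@matrix), 1, tolerance = 1e-12)
        dm <- gldmBuild(d)
        expect_equal(dm@Nz, nvox)
        sz <- glszmBuild(d)
        # zones weighted by size recover the in-mask voxel count
        expect_equal(sum(sweep(sz@matrix, 2, seq_len(ncol(sz@matrix)),
                               "*")), nvox)
    }
})

test_that("GLDM low gray level emphasis hand examples", {
    lev1 <- array(1L, c(3, 3, 3))
    d1 <- new("DiscretizedVolume", levels = lev1, binWidthHu = 25,
              nLevels = 1L)
    expect_equal(gldmLowGrayLevelEmphasis(gldmBuild(d1)), 1)
    lev2 <- array(2L, c(3, 3, 3))
    d2 <- new("DiscretizedVolume", levels = lev2, binWidthHu = 25,
              nLevels = 2L)
    expect_equal(gldmLowGrayLevelEmphasis(gldmBuild(d2)), 0.25)
})

test_that("GLSZM zone examples", {
    lev <- array(1L, c(3, 3, 2))
    d <- new("DiscretizedVolume", levels = lev, binWidthHu = 25,
             nLevels = 1L)
    sz <- glszmBuild(d)
    expect_equal(sz@Nz, 1)
    expect_equal(glszmSizeZoneNonUniformityNormalized(sz), 1)

    # two zones of different sizes -> two singleton size bins
    lev2 <- array(0L, c(5, 1, 1))
    lev2[1] <- 1L; lev2[3:5] <- 2L
    d2 <- new("DiscretizedVolume", levels = lev2, binWidthHu = 25,
              nLevels = 2L)
    expect_equal(glszmSizeZoneNonUniformityNormalized(glszmBuild(d2)),
                 0.5)
})

test_that("first-order features match the sort-based oracle", {
    expect_equal(firstOrderFeatures(c(1, 2, 3))[["Maximum"]], 3)
    expect_equal(firstOrderFeatures(c(1, 2, 3))[["Median"]], 2)
    cst <- firstOrderFeatures(rep(4.2, 10))
    expect_equal(cst[["Variance"]], 0)
    expect_equal(cst[["Range"]], 0)
    expect_equal(cst[["Skewness"]], 0)
    set.seed(33)
    for (i in 1:10) {
        v <- rnorm(sample(3:40, 1), sd = 50)
        expect_equal(firstOrderFeatures(v), oracleFirstOrder(v),
                     tolerance = 1e-12)
    }
})

test_that("pooled-direction GLCM features are rotation-consistent for
           isotropic grids", {
    set.seed(34)
    lev <- array(sample.int(3, 64, replace = TRUE), c(4, 4, 4))
    d1 <- new("DiscretizedVolume", levels = lev, binWidthHu = 25,
              nLevels = 3L)
    # 90-degree rotation about the z axis
    rot <- aperm(lev, c(2, 1, 3))[4:1, , ]
    d2 <- new("DiscretizedVolume", levels = rot, binWidthHu = 25,
              nLevels = 3L)
    for (f in list(glcmCorrelation, glcmImc1)) {
        expect_equal(f(glcmBuild(d1)), f(glcmBuild(d2)),
                     tolerance = 1e-9)
    }
})

test_that("feature rows are named by filter, class and feature and are
           local to the mask", {
    coh <- fixtureSmallCohort()
    p <- cohortPatients(coh)[[1]]
    cfg <- extractionConfig(filters = filterRegistry(
        wavelet = FALSE, log = FALSE, gradient = FALSE, square = FALSE,
        squareroot = FALSE, logarithm = FALSE, exponential = FALSE))
    row <- extractFeatures(p, "phase0", config = cfg)
    expect_true(all(startsWith(names(row), "original_")))
    expect_true("original_glcm_Correlation" %in% names(row))

    # perturbing voxels strictly outside lungs-gtv leaves the row
    # unchanged
    p2 <- p
    out <- voxels(p@lungMask) == 0
    v <- voxels(p@phase0)
    v[out] <- v[out] + 500
    p2@phase0 <- ImageVolume(v, imageSpacing(p@phase0))
    expect_identical(extractFeatures(p2, "phase0", config = cfg), row)
})

test_that("an extracted row equals the composition of the verified
           operations", {
    coh <- fixtureSmallCohort()
    p <- cohortPatients(coh)[[2]]
    cfg <- extractionConfig(filters = filterRegistry(
        wavelet = FALSE, log = FALSE, gradient = TRUE, square = FALSE,
        squareroot = FALSE, logarithm = FALSE, exponential = FALSE))
    row <- extractFeatures(p, "phase0", config = cfg)

    region <- subtractMask(p@lungMask,
                           unionMasks(lapply(p@gtvMasks, expandMask,
                                             marginMm = 0.5)))
    img <- p@phase0
    grad <- gradientMagnitude(img)
    vals <- voxels(grad)[voxels(region) == 1]
    expect_equal(row[["gradient_firstorder_Mean"]], mean(vals))
    disc <- discretize(grad, region, 25)
    expect_equal(row[["gradient_glcm_Correlation"]],
                 glcmCorrelation(glcmBuild(disc)))
    expect_equal(row[["gradient_glszm_SizeZoneNonUniformityNormalized"]],
                 glszmSizeZoneNonUniformityNormalized(glszmBuild(disc)))
})

test_that("delta features subtract Phase 50 from Phase 0 elementwise", {
    set.seed(35)
    m0 <- matrix(rnorm(12), 3, dimnames = list(paste0("P", 1:3),
                                               paste0("f", 1:4)))
    m50 <- matrix(rnorm(12), 3, dimnames = dimnames(m0))
    t0 <- FeatureTable(m0); t50 <- FeatureTable(m50)
    expect_equal(featureMatrix(deltaFeatures(t0, t50)), m0 - m50)
    expect_true(all(featureMatrix(deltaFeatures(t0, t0)) == 0))
    z <- FeatureTable(m0 * 0)
    expect_equal(featureMatrix(deltaFeatures(t0, z)), m0)
    bad <- FeatureTable(m50[, c(2, 1, 3, 4)])
    expect_error(deltaFeatures(t0, bad), "share")
})
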