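# Histogram normalization, absolute discretization and mask algebra.

test_that("reference percentiles match brute-force order statistics", {
    ramp <- ImageVolume(array(seq(0, 100, length.out = 125), c(5, 5, 5)))
    nm <- fitReferenceHistogram(ramp, anchors = c(0, 50, 100))
    expect_equal(nm@referenceValues, c(0, 50, 100))

    const <- ImageVolume(array(-600, c(4, 4, 4)))
    nmc <- fitReferenceHistogram(const, anchors = c(10, 90))
    expect_equal(nmc@referenceValues, c(-600, -600))

    set.seed(11)
    img <- randomImage()
    nmr <- fitReferenceHistogram(img, anchors = c(10, 90))
    expect_equal(nmr@referenceValues,
                 oracleQuantile(as.numeric(voxels(img)), c(10, 90)),
                 tolerance = 1e-12)
})

test_that("fitReferenceHistogram validates anchors and masks", {
    img <- randomImage()
    expect_error(fitReferenceHistogram(img, anchors = 50), "2 anchor")
    expect_error(fitReferenceHistogram(img, anchors = c(90, 10)),
                 "increasing")
    empty <- MaskVolume(array(0, dim(voxels(img))), c(1, 1, 2.5))
    expect_error(fitReferenceHistogram(img, mask = empty), "no voxels")
})

test_that("normalizing the reference with its own map is the identity", {
    set.seed(12)
    ref <- randomImage(c(8, 8, 6))
    nm <- fitReferenceHistogram(ref)
    out <- applyNormalization(ref, nm)
    q <- quantile(voxels(out), nm@anchors / 100, type = 7)
    expect_equal(unname(q), nm@referenceValues, tolerance = 1e-9)
    expect_equal(voxels(out), voxels(ref), tolerance = 1e-9)
})

test_that("normalization maps endpoints and forced linear segments", {
    ref <- ImageVolume(array(c(0, 10, 20, 30), c(4, 1, 1)))
    nm <- new("NormalizationMap", anchors = c(0, 100),
              referenceValues = c(0, 30))
    img <- ImageVolume(array(c(0, 1, 2, 3), c(4, 1, 1)))
    out <- applyNormalization(img, nm)
    expect_equal(as.numeric(voxels(out)), c(0, 10, 20, 30))

    set.seed(13)
    img2 <- randomImage()
    nm2 <- fitReferenceHistogram(randomImage(), anchors = c(0, 100))
    out2 <- applyNormalization(img2, nm2)
    expect_equal(min(voxels(out2)), nm2@referenceValues[1])
    expect_equal(max(voxels(out2)), nm2@referenceValues[2])
})

test_that("normalization is monotone and flags degenerate images", {
    set.seed(14)
    ref <- randomImage(c(6, 6, 4))
    nm <- fitReferenceHistogram(ref)
    for (i in 1:10) {
        img <- randomImage(c(6, 6, 4), mean = runif(1, -900, 100),
                           sd = runif(1, 1, 400))
        out <- applyNormalization(img, nm)
        ord <- order(as.numeric(voxels(img)))
        expect_true(all(diff(as.numeric(voxels(out))[ord]) >= -1e-12))
    }
    flat <- ImageVolume(array(5, c(3, 3, 3)))
    expect_warning(res <- applyNormalization(flat, nm), "degenerate")
    expect_equal(dim(voxels(res)), c(3, 3, 3))
    expect_equal(length(unique(as.numeric(voxels(res)))), 1L)
})

test_that("absolute discretization follows the min-referenced formula", {
    msk <- MaskVolume(array(1, c(4, 1, 1)))
    img <- ImageVolume(array(c(0, 24.9, 25, 50), c(4, 1, 1)))
    expect_equal(as.numeric(discretize(img, msk, 25)@levels),
                 c(1, 1, 2, 3))

    const <- ImageVolume(array(-77, c(3, 3, 3)))
    d <- discretize(const, MaskVolume(array(1, c(3, 3, 3))), 25)
    expect_true(all(d@levels == 1))
    expect_equal(d@nLevels, 1L)

    img2 <- ImageVolume(array(c(-1000, -975), c(2, 1, 1)))
    expect_equal(as.numeric(discretize(img2,
                                       MaskVolume(array(1, c(2, 1, 1))),
                                       25)@levels), c(1, 2))
    expect_error(discretize(img2, MaskVolume(array(1, c(2, 1, 1))), 0),
                 "positive")
})

test_that("discretization is invariant under shifts by whole bins", {
    set.seed(15)
    img <- randomImage(c(5, 5, 4))
    msk <- MaskVolume(array(runif(100) < 0.7, c(5, 5, 4)), c(1, 1, 2.5))
    d1 <- discretize(img, msk, 25)
    shifted <- ImageVolume(voxels(img) + 3 * 25, imageSpacing(img))
    d2 <- discretize(shifted, msk, 25)
    expect_identical(d1@levels, d2@levels)
})

test_that("mask expansion respects physical distance and anisotropy", {
    one <- array(0, c(7, 7, 5)); one[4, 4, 3] <- 1
    m <- MaskVolume(one, c(1, 1, 2.5))
    # 0.5 mm reaches no neighbouring centre at this spacing
    expect_identical(voxels(expandMask(m, 0.5)), voxels(m))
    # 1.0 mm adds exactly the 4 in-plane face neighbours
    e <- expandMask(m, 1.0)
    expect_equal(sum(voxels(e)), 5)
    expect_equal(voxels(e)[, , 3][3:5, 3:5],
                 matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3))
    # empty in, empty out; zero margin is the identity
    empty <- MaskVolume(array(0, c(4, 4, 4)))
    expect_equal(sum(voxels(expandMask(empty, 2))), 0)
    expect_identical(voxels(expandMask(m, 0)), voxels(m))
})

test_that("mask expansion is monotone in the margin", {
    set.seed(16)
    m <- MaskVolume(array(runif(6 * 6 * 4) < 0.2, c(6, 6, 4)),
                    c(1, 1, 2.5))
    prev <- voxels(m)
    for (margin in c(0, 1, 2, 3)) {
        cur <- voxels(expandMask(m, margin))
        expect_true(all(cur >= prev))
        prev <- cur
    }
})

test_that("mask subtraction removes lesions and guards emptiness", {
    lungs <- MaskVolume(array(1, c(4, 4, 4)))
    empty <- MaskVolume(array(0, c(4, 4, 4)))
    expect_identical(voxels(subtractMask(lungs, empty)), voxels(lungs))
    expect_error(subtractMask(lungs, lungs), "empty region")

    gtv <- array(0, c(4, 4, 4)); gtv[1:2, 1:2, 1] <- 1
    res <- subtractMask(lungs, MaskVolume(gtv))
    expect_equal(sum(voxels(res)), 64 - 4)
    # union with the removed voxels reconstructs the lungs
    expect_identical(pmax(voxels(res), gtv), voxels(lungs))
})
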