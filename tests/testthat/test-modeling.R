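# DLCO classification, LASSO score, model design and CV evaluation.

test_that("DLCO classification applies the 75-140% rule inclusively", {
    expect_identical(classifyDlco(c(75, 140, 95)),
                     rep("normal", 3))
    expect_identical(classifyDlco(c(74.9, 140.1, 30, 160)),
                     rep("abnormal", 4))
    expect_error(classifyDlco(0), "positive")
})

test_that("LASSO shrinks fully at huge penalties and recovers signs", {
    set.seed(51)
    n <- 80
    x1 <- rnorm(n)
    y <- runif(n) < plogis(3 * x1)
    X <- cbind(strong = as.numeric(scale(x1)), noise = rnorm(n))
    m <- fitLassoLogistic(X, y, seed = 1, lambda = 1e6)
    expect_identical(unname(m@coefficients), c(0, 0))

    m2 <- fitLassoLogistic(X, y, seed = 1)
    expect_gt(m2@coefficients[1], 0)
    # direction agrees with the unpenalized fit
    ref <- glm(y ~ X[, 1], family = binomial())
    expect_gt(sign(m2@coefficients[1]) * sign(coef(ref)[2]), 0)

    m3 <- fitLassoLogistic(X, y, seed = 1)
    expect_identical(m2@coefficients, m3@coefficients)
    expect_identical(m2@lambda, m3@lambda)

    # single-column input works (internal padding)
    m4 <- fitLassoLogistic(X[, 1, drop = FALSE], y, seed = 1)
    expect_length(m4@coefficients, 1L)
})

test_that("the radiomic score is the intercept-free weighted sum", {
    model <- new("ScoreModel",
                 featureNames = c("wavelet-HHH_glcm_Correlation",
                                  "wavelet-LLL_gldm_LowGrayLevelEmphasis"),
                 coefficients = c(-39.20, 57.85), lambda = 0.1)
    row <- c("wavelet-HHH_glcm_Correlation" = 1,
             "wavelet-LLL_gldm_LowGrayLevelEmphasis" = 0)
    expect_equal(radiomicScore(row, model), -39.20)
    expect_equal(radiomicScore(row * 0, model), 0)
    # exact linearity in each feature value
    row2 <- row
    row2[2] <- 2
    expect_equal(radiomicScore(row2, model) - radiomicScore(row, model),
                 57.85 * 2)
    expect_error(radiomicScore(c(x = 1), model), "missing")
})

test_that("the model matrix enumerates exactly the thirteen designs", {
    specs <- buildModelMatrix()
    expect_equal(nrow(specs), 13L)
    expect_false(any(duplicated(specs)))
    clin <- specs[specs$kind == "clinical", ]
    expect_equal(nrow(clin), 1L)
    expect_identical(clin$endpoint, "baseline")
    expect_identical(clin$phaseDesign, "none")
    for (ep in c("baseline", "post"))
        for (kd in c("radiomic", "clinical-radiomic"))
            expect_setequal(specs$phaseDesign[specs$kind == kd &
                                              specs$endpoint == ep],
                            c("Phase0", "Phase50", "Delta"))
})

test_that("rank AUC matches pair counting and the tie convention", {
    expect_equal(rocAuc(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE)), 1)
    expect_equal(rocAuc(rep(3, 6), rep(c(TRUE, FALSE), 3)), 0.5)
    expect_error(rocAuc(1:3, rep(TRUE, 3)), "both classes")
    set.seed(52)
    for (i in 1:10) {
        n <- sample(6:20, 1)
        s <- sample(1:8, n, replace = TRUE)   # deliberate ties
        lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (length(unique(lab)) < 2) next
        expect_equal(rocAuc(s, lab), oracleAuc(s, lab))
        expect_equal(rocAuc(s, lab),
                     as.numeric(pROC::auc(pROC::roc(
                         lab, s, direction = "<", quiet = TRUE))))
        # invariance under strictly monotone transforms
        expect_equal(rocAuc(exp(s / 2), lab), rocAuc(s, lab))
        expect_equal(rocAuc(rank(s, ties.method = "average"), lab),
                     rocAuc(s, lab))
    }
})

test_that("paired signed-rank test handles exact, degenerate and
           approximate cases", {
    expect_equal(pairedWilcoxonSignedRank(1:10, 1:10), 1)
    base <- c(10, 20, 30, 40, 50)
    expect_equal(pairedWilcoxonSignedRank(base + c(1, 2, 3, 4, 5), base),
                 0.0625)
    set.seed(53)
    p <- replicate(50, {
        d <- rnorm(24)
        pairedWilcoxonSignedRank(d, rep(0, 24))
    })
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(mean(p < 0.05), 0)   # some rejections
    expect_lt(mean(p < 0.05), 0.2) # but near the nominal level
})

test_that("clinical association table picks the right test per
           variable", {
    set.seed(54)
    n <- 40
    lab <- rep(c(TRUE, FALSE), each = n / 2)
    clin <- data.frame(cci = rpois(n, 2) + lab * 2,
                       copd = as.integer(c(rep(1, 10), rep(0, 10),
                                           rep(0, 18), rep(1, 2))),
                       age = rnorm(n, 70, 8),
                       same = rep(3, n))
    tab <- clinicalAssociationTable(clin, lab,
                                    c("cci", "copd", "age", "same"))
    expect_identical(tab$test[tab$variable == "cci"],
                     "wilcoxon-rank-sum")
    expect_identical(tab$test[tab$variable == "age"],
                     "wilcoxon-rank-sum")
    expect_equal(tab$p[tab$variable == "same"], 1)
    expect_lt(tab$p[tab$variable == "cci"], 0.05)
})

test_that("the 10/0 vs 0/10 table reproduces the hypergeometric
           Fisher p-value", {
    lab <- rep(c(TRUE, FALSE), each = 10)
    clin <- data.frame(exposed = as.integer(lab))
    tab <- clinicalAssociationTable(clin, lab, "exposed")
    expect_identical(tab$test, "fisher-exact")
    # 2 / choose(20, 10) by direct enumeration of the margins
    expect_equal(tab$p, 2 / choose(20, 10), tolerance = 1e-10)
})

test_that("repeated k-fold evaluation is deterministic and shares folds
           across kinds", {
    data <- fixtureModelData(40, 1, 1, seed = 77, key = "md_small")
    spec <- list(kind = "radiomic", phaseDesign = "Phase0",
                 endpoint = "baseline")
    r1 <- repeatedKFoldAuc(spec, data, reps = 3, seed = 9)
    r2 <- repeatedKFoldAuc(spec, data, reps = 3, seed = 9)
    expect_identical(r1@aucs, r2@aucs)
    expect_true(all(r1@aucs >= 0 & r1@aucs <= 1))
    expect_true(r1@median >= r1@iqr[1] && r1@median <= r1@iqr[2])
})

test_that("a permuted-label canary shows no information leakage", {
    data <- fixtureModelData(40, 1, 1, seed = 77, key = "md_small")
    spec <- list(kind = "radiomic", phaseDesign = "Phase0",
                 endpoint = "baseline")
    # the planted signal is strong ...
    rs <- repeatedKFoldAuc(spec, data, reps = 3, seed = 9)
    expect_gt(rs@median, 0.8)
    # ... yet with permuted labels the cross-validated AUC collapses to
    # chance: selection and fitting leak nothing from held-out folds
    rp <- repeatedKFoldAuc(spec, data, reps = 15, seed = 9,
                           permuteLabels = TRUE)
    expect_lt(abs(rp@median - 0.5), 0.15)
})
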