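# DLCO classification, LASSO radiomic score, the thirteen-model design
# and repeated stratified k-fold cross-validated AUC evaluation.

#' Classify a DLCO percent-predicted value
#'
#' DLCO is normal when it lies in 75--140\% of predicted (both
#' boundaries inclusive) and abnormal otherwise.
#'
#' @param dlcoPct positive percent-predicted DLCO value(s).
#' @return Character vector of \code{"normal"} / \code{"abnormal"}.
#' @export
classifyDlco <- function(dlcoPct) {
    if (any(dlcoPct <= 0)) stop("DLCO percent predicted must be positive")
    ifelse(dlcoPct >= 75 & dlcoPct <= 140, "normal", "abnormal")
}

# Deterministic integer sub-seed below 2^31 derived from (seed, salt).
subSeed <- function(seed, ...) {
    salts <- c(...)
    s <- as.numeric(seed) %% 2147483629
    for (x in salts) s <- (s * 48271 + as.numeric(x)) %% 2147483629
    as.integer(s) + 1L
}

# Stratified fold assignment: within each class, a seeded shuffle dealt
# round-robin into k folds.
stratifiedFolds <- function(labels, k, seed) {
    labels <- as.logical(labels)
    fold <- integer(length(labels))
    rng <- local({
        set.seed(seed)
        lapply(c(TRUE, FALSE), function(cl) {
            idx <- which(labels == cl)
            sample(idx)
        })
    })
    for (idx in rng)
        fold[idx] <- rep_len(seq_len(k), length(idx))
    fold
}

#' Fit an L1-penalized logistic score model
#'
#' LASSO logistic regression on standardized features with the penalty
#' chosen at the internal cross-validated deviance minimum. The
#' returned coefficients define the radiomic score (no intercept);
#' downstream logistic models refit an intercept on the score.
#'
#' @param X standardized numeric feature matrix (columns mean 0, sd 1).
#' @param y binary labels with at least 2 observations per class.
#' @param seed integer controlling the internal fold split.
#' @param nfolds internal folds for the penalty search.
#' @param lambda optional fixed penalty; skips the internal search.
#' @return A \linkS4class{ScoreModel}.
#' @export
fitLassoLogistic <- function(X, y, seed = 1L, nfolds = 5L,
                             lambda = NULL) {
    X <- as.matrix(X)
    y <- as.numeric(as.logical(y))
    if (min(table(y)) < 2L) stop("need at least 2 observations per class")
    nms <- colnames(X)
    if (is.null(nms)) nms <- paste0("f", seq_len(ncol(X)))
    padded <- ncol(X) < 2L
    if (padded) X <- cbind(X, .pad = 0)       # glmnet needs >= 2 columns
    if (!is.null(lambda)) {
        fit <- suppressWarnings(
            glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                           standardize = FALSE, lambda = lambda))
        beta <- as.numeric(coef(fit, s = lambda, exact = FALSE))[-1]
        lam <- as.numeric(lambda)
    } else {
        foldid <- stratifiedFolds(y == 1, min(nfolds, min(table(y))),
                                  subSeed(seed, 104729))
        fit <- suppressWarnings(
            glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                              standardize = FALSE, foldid = foldid,
                              nlambda = 50,
                              type.measure = "deviance"))
        beta <- as.numeric(coef(fit, s = "lambda.min"))[-1]
        lam <- as.numeric(fit$lambda.min)
    }
    if (padded) beta <- beta[1]
    new("ScoreModel", featureNames = nms, coefficients = beta,
        lambda = lam)
}

#' Radiomic score of a feature row
#'
#' The intercept-free linear score: the sum over selected features of
#' coefficient times feature value.
#'
#' @param featureRow named numeric vector containing every model
#'   feature.
#' @param model a \linkS4class{ScoreModel}.
#' @return Scalar score.
#' @export
radiomicScore <- function(featureRow, model) {
    missing <- setdiff(model@featureNames, names(featureRow))
    if (length(missing) > 0)
        stop("missing features: ", paste(missing, collapse = ", "))
    sum(model@coefficients *
        as.numeric(featureRow[model@featureNames]))
}

#' Enumerate the thirteen model specifications
#'
#' \{radiomic, clinical-radiomic\} x \{Phase0, Phase50, Delta\} x
#' \{baseline, post\} (12 models) plus the single clinical model at
#' baseline.
#'
#' @return data.frame with columns \code{kind}, \code{phaseDesign},
#'   \code{endpoint}; 13 rows.
#' @export
buildModelMatrix <- function() {
    g <- expand.grid(kind = c("radiomic", "clinical-radiomic"),
                     phaseDesign = c("Phase0", "Phase50", "Delta"),
                     endpoint = c("baseline", "post"),
                     stringsAsFactors = FALSE)
    g <- g[order(g$endpoint, g$kind, g$phaseDesign), ]
    out <- rbind(data.frame(kind = "clinical", phaseDesign = "none",
                            endpoint = "baseline",
                            stringsAsFactors = FALSE), g)
    rownames(out) <- NULL
    out
}

#' Rank-based AUC
#'
#' Probability that a randomly chosen positive outscores a randomly
#' chosen negative, with tied scores counted half (the Mann-Whitney
#' convention).
#'
#' @param scores numeric scores.
#' @param labels binary labels; \code{TRUE} = positive.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
    labels <- as.logical(labels)
    n1 <- sum(labels)
    n0 <- sum(!labels)
    if (n1 == 0L || n0 == 0L) stop("both classes must be present")
    r <- rank(scores)
    (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank p-value for paired measurements (e.g. baseline
#' vs post-treatment DLCO): exact for at most 25 non-zero differences
#' without ties, otherwise the normal approximation. All differences
#' zero returns p = 1 by convention.
#'
#' @param baseline,post paired numeric vectors.
#' @return p-value in (0, 1].
#' @export
pairedWilcoxonSignedRank <- function(baseline, post) {
    stopifnot(length(baseline) == length(post))
    d <- baseline - post
    d <- d[d != 0]
    if (length(d) == 0L) return(1)
    ties <- anyDuplicated(abs(d)) > 0
    useExact <- length(d) <= 25 && !ties
    res <- suppressWarnings(
        wilcox.test(d, alternative = "two.sided", exact = useExact,
                    correct = !useExact))
    min(1, res$p.value)
}

#' Univariate clinical association table
#'
#' Tests each clinical covariate against the binary abnormal-DLCO
#' label: continuous variables with the Wilcoxon rank-sum test,
#' categorical variables with Pearson's chi-squared test, switching to
#' Fisher's exact test when any expected cell count is 5 or less.
#'
#' @param clinical data.frame of covariates (one row per patient).
#' @param labels binary abnormal-DLCO labels.
#' @param variables covariate columns to test; defaults to every column
#'   except identifiers and DLCO columns.
#' @return data.frame with columns \code{variable}, \code{test},
#'   \code{p}.
#' @export
clinicalAssociationTable <- function(clinical, labels,
                                     variables = NULL) {
    labels <- as.logical(labels)
    if (length(unique(labels)) < 2L)
        stop("labels must contain both classes")
    if (is.null(variables))
        variables <- setdiff(names(clinical),
                             c("patient_id", "dlco_baseline_pct",
                               "dlco_post_pct"))
    rows <- lapply(variables, function(v) {
        x <- clinical[[v]]
        categorical <- is.factor(x) || is.character(x) || is.logical(x) ||
            length(unique(x)) <= 2
        if (!categorical) {
            p <- associationPValue(x, labels)
            test <- "wilcoxon-rank-sum"
        } else {
            tab <- table(factor(x), factor(labels, c(FALSE, TRUE)))
            if (length(unique(x)) < 2L) {
                p <- 1
                test <- "degenerate"
            } else {
                expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
                if (any(expected <= 5)) {
                    p <- fisher.test(tab)$p.value
                    test <- "fisher-exact"
                } else {
                    p <- chisq.test(tab, correct = FALSE)$p.value
                    test <- "pearson-chisq"
                }
            }
        }
        data.frame(variable = v, test = test, p = p,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Repeated stratified k-fold cross-validation
# ---------------------------------------------------------------------------

#' Assemble per-design modeling data from a cohort
#'
#' Extracts Phase 0, Phase 50 and delta feature tables plus the clinical
#' table and derived abnormal-DLCO labels, the single container consumed
#' by the evaluation functions.
#'
#' @param cohort a \linkS4class{RadiomicsCohort}.
#' @param config an \code{\link{extractionConfig}}.
#' @return List with elements \code{features} (named list of
#'   patients x features matrices for Phase0, Phase50, Delta),
#'   \code{clinical}, \code{baselineLabel}, \code{postLabel} (NA where
#'   no post-treatment DLCO exists).
#' @export
cohortModelData <- function(cohort, config = extractionConfig()) {
    t0 <- extractCohortFeatures(cohort, "phase0", config)
    t50 <- extractCohortFeatures(cohort, "phase50", config)
    cl <- cohort@clinical
    post <- rep(NA, nrow(cl))
    has <- !is.na(cl$dlco_post_pct)
    post[has] <- classifyDlco(cl$dlco_post_pct[has]) == "abnormal"
    list(features = list(Phase0 = featureMatrix(t0),
                         Phase50 = featureMatrix(t50),
                         Delta = featureMatrix(deltaFeatures(t0, t50))),
         clinical = cl,
         baselineLabel = classifyDlco(cl$dlco_baseline_pct) == "abnormal",
         postLabel = post)
}

# Learned radiomic pipeline on training rows only: screening +
# clustering selection, standardization, LASSO score fit; returns train
# and test scores. Falls back to a zero score when nothing survives
# selection or the penalty removes every feature.
foldRadiomicScore <- function(Xtrain, ytrain, Xtest, selectionCfg, seed) {
    sel <- tryCatch(selectFeatures(Xtrain, ytrain, selectionCfg),
                    error = function(e) NULL)
    if (is.null(sel) || length(sel@selected) == 0L)
        return(list(train = rep(0, nrow(Xtrain)),
                    test = rep(0, nrow(Xtest)), model = NULL))
    Xs <- Xtrain[, sel@selected, drop = FALSE]
    mu <- colMeans(Xs)
    sig <- apply(Xs, 2, sd)
    sig[sig == 0] <- 1
    Zs <- scale(Xs, mu, sig)
    model <- fitLassoLogistic(Zs, ytrain, seed = seed)
    Zt <- scale(Xtest[, sel@selected, drop = FALSE], mu, sig)
    list(train = as.numeric(Zs %*% model@coefficients),
         test = as.numeric(Zt %*% model@coefficients),
         model = model)
}

# Fit the per-kind logistic model on training data and predict test
# probabilities. Constant predictors are dropped to keep glm stable.
foldPredict <- function(kind, trainDf, testDf) {
    preds <- setdiff(names(trainDf), "y")
    keep <- preds[vapply(preds, function(p) sd(trainDf[[p]]) > 0, TRUE)]
    if (length(keep) == 0L) return(rep(0.5, nrow(testDf)))
    fml <- stats::as.formula(paste("y ~", paste(keep, collapse = " + ")))
    fit <- suppressWarnings(glm(fml, data = trainDf, family = binomial()))
    as.numeric(suppressWarnings(predict(fit, newdata = testDf,
                                        type = "response")))
}

#' Repeated stratified k-fold cross-validated AUC of one model
#'
#' For each repetition, patients are shuffled into k stratified folds;
#' for each fold the full learned pipeline runs on the training folds
#' only (feature screening, correlation-clustering selection,
#' standardization, LASSO score fit, logistic model fit) and scores the
#' held-out fold. Held-out predictions are pooled into one AUC per
#' repetition; the result reports the per-repetition AUCs with their
#' median and IQR.
#'
#' @param spec one row of \code{\link{buildModelMatrix}} (or an
#'   equivalent list with \code{kind}, \code{phaseDesign},
#'   \code{endpoint}).
#' @param data a \code{\link{cohortModelData}} list.
#' @param k folds (3 by default).
#' @param reps repetitions.
#' @param seed integer; fold splits and penalty searches derive from it,
#'   so identical seeds give identical results and identical fold
#'   splits across model specifications.
#' @param selectionCfg a \code{\link{selectionConfig}}.
#' @param clinicalCovariates clinical columns entering clinical and
#'   clinical-radiomic models.
#' @param permuteLabels permute labels (seeded) before evaluation; a
#'   null-calibration switch used to audit the pipeline for information
#'   leakage.
#' @param scoreCache optional environment memoising the learned fold
#'   scores across model kinds sharing a (design, endpoint); used by
#'   \code{\link{evaluateModels}}.
#' @return A \linkS4class{CVResult}.
#' @export
repeatedKFoldAuc <- function(spec, data, k = 3L, reps = 100L, seed = 1L,
                             selectionCfg = selectionConfig(),
                             clinicalCovariates = "cci",
                             permuteLabels = FALSE, scoreCache = NULL) {
    kind <- spec$kind
    design <- spec$phaseDesign
    endpoint <- spec$endpoint
    labAll <- if (endpoint == "post") data$postLabel else data$baselineLabel
    use <- !is.na(labAll)
    y <- as.logical(labAll[use])
    if (length(y) == 0L || length(unique(y)) < 2L ||
        min(table(y)) < k)
        stop("class too small for ", k, "-fold stratification")
    X <- if (design != "none") data$features[[design]][use, , drop = FALSE]
         else NULL
    clin <- data$clinical[use, , drop = FALSE]
    if (permuteLabels) {
        set.seed(subSeed(seed, 7919))
        y <- sample(y)
    }
    aucs <- numeric(reps)
    for (r in seq_len(reps)) {
        fold <- stratifiedFolds(y, k, subSeed(seed, endpoint == "post", r))
        pooledScore <- numeric(length(y))
        for (f in seq_len(k)) {
            te <- fold == f
            tr <- !te
            cols <- list()
            colsTest <- list()
            if (kind != "clinical") {
                # the learned radiomic score depends only on (design,
                # endpoint, rep, fold), so it is shared across the
                # radiomic and clinical-radiomic kinds
                key <- paste(design, endpoint, r, f, sep = "|")
                canCache <- !is.null(scoreCache) && !permuteLabels
                rs <- if (canCache && !is.null(scoreCache[[key]]))
                    scoreCache[[key]]
                else foldRadiomicScore(X[tr, , drop = FALSE], y[tr],
                                       X[te, , drop = FALSE],
                                       selectionCfg,
                                       subSeed(seed, r, f))
                if (canCache) scoreCache[[key]] <- rs
                cols$score <- rs$train
                colsTest$score <- rs$test
            }
            if (kind != "radiomic")
                for (cv in clinicalCovariates) {
                    cols[[cv]] <- as.numeric(clin[[cv]][tr])
                    colsTest[[cv]] <- as.numeric(clin[[cv]][te])
                }
            trainDf <- data.frame(cols, y = as.numeric(y[tr]))
            testDf <- data.frame(colsTest)
            pooledScore[te] <- foldPredict(kind, trainDf, testDf)
        }
        aucs[r] <- rocAuc(pooledScore, y)
    }
    q <- unname(quantile(aucs, c(0.25, 0.75), type = 7))
    med <- median(aucs)
    new("CVResult", aucs = aucs, median = med,
        iqr = c(min(q[1], med), max(q[2], med)),
        k = as.integer(k), reps = as.integer(reps),
        seed = as.integer(seed))
}

#' Evaluate the full thirteen-model design
#'
#' Runs \code{\link{repeatedKFoldAuc}} for every specification of
#' \code{\link{buildModelMatrix}} on shared fold splits.
#'
#' @inheritParams repeatedKFoldAuc
#' @param specs model specifications; the 13-model design by default.
#' @return List with \code{summary} (data.frame of per-model median and
#'   IQR AUC) and \code{results} (list of \linkS4class{CVResult}).
#' @export
evaluateModels <- function(data, specs = buildModelMatrix(), k = 3L,
                           reps = 100L, seed = 1L,
                           selectionCfg = selectionConfig(),
                           clinicalCovariates = "cci",
                           permuteLabels = FALSE) {
    results <- vector("list", nrow(specs))
    cache <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(specs)))
        results[[i]] <- tryCatch(
            repeatedKFoldAuc(specs[i, ], data, k = k, reps = reps,
                             seed = seed, selectionCfg = selectionCfg,
                             clinicalCovariates = clinicalCovariates,
                             permuteLabels = permuteLabels,
                             scoreCache = cache),
            error = function(e) conditionMessage(e))
    pick <- function(f) vapply(results, function(r)
        if (is(r, "CVResult")) f(r) else NA_real_, 0)
    summary <- cbind(specs, medianAUC = pick(function(r) r@median),
                     q1 = pick(function(r) r@iqr[1]),
                     q3 = pick(function(r) r@iqr[2]),
                     note = vapply(results, function(r)
                         if (is(r, "CVResult")) "" else r, ""))
    names(results) <- paste(specs$kind, specs$phaseDesign, specs$endpoint,
                            sep = "_")
    list(summary = summary, results = results)
}
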