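# Screening and the iterative correlation-clustering selector.

makeLabels <- function(n) rep(c(TRUE, FALSE), length.out = n)

test_that("near-zero-variance screening drops degenerate columns", {
    set.seed(41)
    n <- 100
    tab <- cbind(constant = rep(1, n),
                 noisy = rnorm(n),
                 almost = c(rep(0, 97), 1, 2, 3))
    out <- nearZeroVarianceFilter(tab)
    expect_identical(colnames(out), "noisy")
    expect_error(nearZeroVarianceFilter(tab[, 1, drop = FALSE]),
                 "near-zero-variance")
})

test_that("correlation pruning keeps the better-associated member", {
    set.seed(42)
    n <- 60
    lab <- makeLabels(n)
    base <- rnorm(n) + lab * 2
    tab <- cbind(A = base, B = base, C = rnorm(n))
    out <- pruneHighCorrelation(tab, lab, 0.95)
    expect_setequal(colnames(out), c("A", "C"))   # duplicate reduced

    un <- cbind(x = rnorm(n), y = rnorm(n), z = rnorm(n))
    expect_identical(colnames(pruneHighCorrelation(un, lab, 0.95)),
                     colnames(un))
    # pruneRho = 1 disables pruning even for duplicates
    expect_identical(colnames(pruneHighCorrelation(tab, lab, 1)),
                     colnames(tab))
})

test_that("greedy pruning follows the correlation chain rule", {
    # A ~ B and B ~ C almost perfectly; A most label-associated.
    # visiting pairs by descending correlation must drop B and keep C.
    set.seed(43)
    n <- 200
    lab <- makeLabels(n)
    A <- rnorm(n) + lab * 3
    B <- A + rnorm(n, sd = 0.02)
    C <- B + rnorm(n, sd = 0.06)
    tab <- cbind(A = A, B = B, C = C)
    rho <- abs(cor(tab, method = "spearman"))
    stopifnot(rho["A", "B"] > 0.99, rho["B", "C"] > 0.99)
    out <- pruneHighCorrelation(tab, lab, 0.95)
    expect_true("A" %in% colnames(out))
    expect_false("B" %in% colnames(out))
})

test_that("rank-sum association handles exactness, ties and shifts", {
    expect_equal(associationPValue(c(1, 2, 3, 1, 2, 3),
                                   c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                     FALSE)), 1)
    # fully separated 3 vs 3: 2/20 rank splits are as extreme
    expect_equal(associationPValue(c(1, 2, 3, 10, 11, 12),
                                   c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                     FALSE)), 0.1)
    set.seed(44)
    x <- c(rnorm(50), rnorm(50) + 5)
    lab <- rep(c(FALSE, TRUE), each = 50)
    expect_lt(associationPValue(x, lab), 1e-4)
    expect_error(associationPValue(x, rep(TRUE, 100)), "non-empty")
})

test_that("large-sample association matches the tie-corrected normal
           approximation", {
    set.seed(45)
    for (i in 1:10) {
        n1 <- sample(11:60, 1); n0 <- sample(11:60, 1)
        x <- round(c(rnorm(n1, 0.4), rnorm(n0)), 1)
        lab <- c(rep(TRUE, n1), rep(FALSE, n0))
        ref <- suppressWarnings(
            wilcox.test(x[lab], x[!lab], exact = FALSE,
                        correct = TRUE)$p.value)
        expect_equal(associationPValue(x, lab), min(1, ref),
                     tolerance = 1e-12)
    }
})

test_that("cluster selection is a fixed point on decorrelated tables", {
    set.seed(46)
    n <- 50
    lab <- makeLabels(n)
    tab <- matrix(rnorm(n * 5), n,
                  dimnames = list(NULL, paste0("f", 1:5)))
    res <- iterativeClusterSelect(tab, lab)
    expect_setequal(selectedFeatures(res), colnames(tab))
    expect_equal(res@iterations, 1L)

    single <- tab[, 1, drop = FALSE]
    expect_identical(selectedFeatures(iterativeClusterSelect(single,
                                                             lab)), "f1")
    expect_error(iterativeClusterSelect(tab, rep(TRUE, n)),
                 "both classes")
})

test_that("two tight pairs reduce to their per-cluster winners,
           matching exhaustive search", {
    set.seed(47)
    n <- 80
    lab <- makeLabels(n)
    a <- rnorm(n) + lab * 2
    b <- rnorm(n)
    tab <- cbind(A1 = a + rnorm(n, sd = 0.05),
                 A2 = a + rnorm(n, sd = 0.6),
                 B1 = b + rnorm(n, sd = 0.05),
                 B2 = b + rnorm(n, sd = 0.6))
    cfg <- selectionConfig()
    rho <- abs(cor(tab, method = "spearman"))
    stopifnot(rho["A1", "A2"] > 0.75, rho["B1", "B2"] > 0.75,
              max(rho[c("A1", "A2"), c("B1", "B2")]) < 0.75)
    res <- iterativeClusterSelect(tab, lab, cfg)

    # exhaustive oracle: among all subsets whose pairwise |rho| stays
    # below the threshold, the defined solution is the unique maximal
    # one containing each cluster's smallest-p member
    pv <- apply(tab, 2, function(x)
        suppressWarnings(wilcox.test(x[lab], x[!lab],
                                     exact = FALSE)$p.value))
    winners <- c(names(which.min(pv[c("A1", "A2")])),
                 names(which.min(pv[c("B1", "B2")])))
    nms <- colnames(tab)
    valid <- list()
    for (sz in 1:4) {
        for (sub in combn(nms, sz, simplify = FALSE)) {
            r <- rho[sub, sub, drop = FALSE]
            diag(r) <- 0
            if (max(r) < cfg$clusterRho) valid[[length(valid) + 1]] <- sub
        }
    }
    maximal <- valid[lengths(valid) == max(lengths(valid))]
    withWinners <- Filter(function(s) all(winners %in% s), maximal)
    expect_length(withWinners, 1L)
    expect_setequal(selectedFeatures(res), withWinners[[1]])
})

test_that("selection terminates with pairwise correlations below the
           threshold and is permutation-equivariant", {
    set.seed(48)
    for (i in 1:20) {
        n <- 40
        lab <- makeLabels(n)
        nGroups <- sample(2:4, 1)
        cols <- list()
        for (g in seq_len(nGroups)) {
            base <- rnorm(n) + lab * runif(1, 0, 2)
            for (m in seq_len(sample(1:4, 1)))
                cols[[length(cols) + 1]] <-
                    base + rnorm(n, sd = runif(1, 0.05, 2))
        }
        tab <- do.call(cbind, cols)
        colnames(tab) <- sprintf("f%02d", seq_along(cols))
        res <- iterativeClusterSelect(tab, lab)
        sel <- selectedFeatures(res)
        if (length(sel) > 1) {
            r <- abs(cor(tab[, sel], method = "spearman"))
            diag(r) <- 0
            expect_lt(max(r), 0.75)
        }
        perm <- tab[, sample(ncol(tab)), drop = FALSE]
        expect_setequal(selectedFeatures(iterativeClusterSelect(perm,
                                                                lab)),
                        sel)
        expect_true(res@iterations >= 1)
    }
})

test_that("threshold 1 disables clustering (screening monotonicity)", {
    set.seed(49)
    n <- 40
    lab <- makeLabels(n)
    base <- rnorm(n)
    tab <- cbind(A = base, B = base + rnorm(n, sd = 0.01),
                 C = rnorm(n))
    cfg <- selectionConfig(pruneRho = 1, clusterRho = 0.999999)
    res <- iterativeClusterSelect(tab, lab, cfg)
    expect_gte(length(selectedFeatures(res)), 2L)
    expect_error(selectionConfig(pruneRho = 0.5, clusterRho = 0.75),
                 "clusterRho")
})
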