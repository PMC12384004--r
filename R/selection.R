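# Feature screening and the iterative correlation-clustering selector.

#' Selection configuration
#'
#' @param pruneRho absolute Spearman threshold for the initial pairwise
#'   redundancy pruning (pairs above it are reduced to their more
#'   label-associated member).
#' @param clusterRho absolute Spearman threshold defining cluster edges
#'   in the iterative selector and the stopping rule (selection stops
#'   when all pairwise correlations are below it).
#' @param nzvFreqRatio,nzvUniqueFrac near-zero-variance thresholds: a
#'   column is dropped when the most-common/second-most-common value
#'   frequency ratio exceeds \code{nzvFreqRatio} while the fraction of
#'   distinct values is below \code{nzvUniqueFrac}.
#' @return A configuration list.
#' @export
selectionConfig <- function(pruneRho = 0.95, clusterRho = 0.75,
                            nzvFreqRatio = 19, nzvUniqueFrac = 0.1) {
    if (!(clusterRho < pruneRho && pruneRho <= 1 && clusterRho > 0))
        stop("need 0 < clusterRho < pruneRho <= 1")
    list(pruneRho = pruneRho, clusterRho = clusterRho,
         nzvFreqRatio = nzvFreqRatio, nzvUniqueFrac = nzvUniqueFrac,
         associationTest = "wilcoxon-rank-sum")
}

asFeatureMatrixLike <- function(table) {
    if (is(table, "FeatureTable")) featureMatrix(table) else as.matrix(table)
}

restoreTableType <- function(m, template) {
    if (is(template, "FeatureTable")) FeatureTable(m) else m
}

#' Drop near-zero-variance features
#'
#' Removes constant columns and columns that are almost constant: most-
#' common to second-most-common value frequency ratio above
#' \code{nzvFreqRatio} with distinct-value fraction below
#' \code{nzvUniqueFrac}.
#'
#' @param table a \linkS4class{FeatureTable} or patients x features
#'   matrix.
#' @param config a \code{\link{selectionConfig}}.
#' @return The filtered table (same type as the input).
#' @export
nearZeroVarianceFilter <- function(table, config = selectionConfig()) {
    m <- asFeatureMatrixLike(table)
    if (ncol(m) < 1L) stop("need at least one feature")
    keep <- vapply(seq_len(ncol(m)), function(j) {
        cnt <- sort(rle(sort(m[, j]))$lengths, decreasing = TRUE)
        if (length(cnt) == 1L) return(FALSE)        # constant
        freqRatio <- cnt[1] / cnt[2]
        uniqueFrac <- length(cnt) / nrow(m)
        !(freqRatio > config$nzvFreqRatio &&
          uniqueFrac < config$nzvUniqueFrac)
    }, TRUE)
    if (!any(keep)) stop("all features are near-zero-variance")
    restoreTableType(m[, keep, drop = FALSE], table)
}

# Vectorized two-sided rank-sum p-values (normal approximation with
# tie correction and continuity correction) for every column of X.
rankSumPValuesApprox <- function(X, labels) {
    labels <- as.logical(labels)
    n1 <- sum(labels)
    n0 <- sum(!labels)
    n <- n1 + n0
    vapply(seq_len(ncol(X)), function(j) {
        x <- X[, j]
        r <- rank(x)
        U <- sum(r[labels]) - n1 * (n1 + 1) / 2
        tie <- rle(sort(x))$lengths
        sigma2 <- (n1 * n0 / 12) *
            ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
        if (sigma2 <= 0) return(1)
        z <- U - n1 * n0 / 2
        z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
        min(1, 2 * pnorm(-abs(z)))
    }, 0)
}

#' Wilcoxon rank-sum association with the abnormal-DLCO label
#'
#' Two-sided rank-sum p-value of a feature against a binary label:
#' exact when both groups have at most 10 observations and no ties are
#' present, otherwise the normal approximation with tie correction.
#'
#' @param feature numeric feature column.
#' @param labels binary labels (logical, or coercible to two groups).
#' @return p-value in (0, 1].
#' @export
associationPValue <- function(feature, labels) {
    labels <- as.logical(labels)
    g1 <- feature[labels]
    g0 <- feature[!labels]
    if (length(g1) == 0L || length(g0) == 0L)
        stop("both label groups must be non-empty")
    if (length(unique(feature)) == 1L) return(1)
    ties <- anyDuplicated(feature) > 0
    useExact <- length(g1) <= 10 && length(g0) <= 10 && !ties
    if (!useExact)
        return(rankSumPValuesApprox(matrix(feature, ncol = 1), labels))
    res <- suppressWarnings(
        wilcox.test(g1, g0, alternative = "two.sided", exact = TRUE))
    min(1, res$p.value)
}

# p-values for all columns, using the exact test only where the
# single-column contract would.
columnAssociationPValues <- function(m, labels) {
    labels <- as.logical(labels)
    if (sum(labels) <= 10 && sum(!labels) <= 10)
        return(setNames(vapply(seq_len(ncol(m)), function(j)
            associationPValue(m[, j], labels), 0), colnames(m)))
    setNames(rankSumPValuesApprox(m, labels), colnames(m))
}

# Spearman correlation as Pearson correlation of per-column ranks;
# ranking once lets repeated (sub)matrix correlations reuse it.
columnRanks <- function(m) apply(m, 2, rank)

spearmanMatrix <- function(m, ranks = NULL) {
    if (is.null(ranks)) ranks <- columnRanks(m)
    r <- suppressWarnings(cor(ranks))
    r[!is.finite(r)] <- 0
    r
}

#' Prune highly correlated feature pairs
#'
#' Among every pair with absolute Spearman correlation above
#' \code{pruneRho}, removes the member less associated with the label
#' (larger rank-sum p-value; ties broken toward keeping the
#' lexicographically smaller name). Pairs are visited greedily by
#' descending correlation, so the procedure is deterministic and
#' order-independent.
#'
#' @param table a \linkS4class{FeatureTable} or matrix.
#' @param labels binary labels.
#' @param pruneRho absolute correlation threshold (1 disables pruning).
#' @param .pv precomputed association p-values (internal, avoids
#'   recomputation along the selection chain).
#' @return The pruned table (same type as the input).
#' @export
pruneHighCorrelation <- function(table, labels, pruneRho = 0.95,
                                 .pv = NULL) {
    m <- asFeatureMatrixLike(table)
    if (nrow(m) < 2L) stop("need at least 2 rows")
    if (ncol(m) < 2L || pruneRho >= 1) return(table)
    rho <- abs(spearmanMatrix(m))
    pv <- if (is.null(.pv)) columnAssociationPValues(m, labels)
          else .pv[colnames(m)]
    nms <- colnames(m)
    if (is.null(nms)) nms <- as.character(seq_len(ncol(m)))
    pairs <- which(upper.tri(rho) & rho > pruneRho, arr.ind = TRUE)
    if (nrow(pairs) == 0L) return(table)
    ord <- order(-rho[pairs], nms[pairs[, 1]], nms[pairs[, 2]])
    pairs <- pairs[ord, , drop = FALSE]
    alive <- rep(TRUE, ncol(m))
    for (r in seq_len(nrow(pairs))) {
        a <- pairs[r, 1]; b <- pairs[r, 2]
        if (!alive[a] || !alive[b]) next
        drop <- if (pv[a] < pv[b]) b
                else if (pv[b] < pv[a]) a
                else if (nms[a] <= nms[b]) b else a
        alive[drop] <- FALSE
    }
    restoreTableType(m[, alive, drop = FALSE], table)
}

connectedComponents <- function(adj) {
    n <- nrow(adj)
    comp <- integer(n)
    cur <- 0L
    for (s in seq_len(n)) {
        if (comp[s] != 0L) next
        cur <- cur + 1L
        queue <- s
        comp[s] <- cur
        while (length(queue) > 0) {
            v <- queue[1]
            queue <- queue[-1]
            nb <- which(adj[v, ] & comp == 0L)
            comp[nb] <- cur
            queue <- c(queue, nb)
        }
    }
    comp
}

#' Iterative correlation-clustering feature selection
#'
#' Repeats until no pair of surviving features has absolute Spearman
#' correlation above \code{clusterRho}: features are grouped into
#' clusters (connected components of the correlation graph with edges at
#' |rho| > clusterRho) and each cluster is reduced to its member most
#' associated with the abnormal-DLCO label (smallest rank-sum p-value;
#' ties broken by the lexicographically smallest name). Every iteration
#' with at least one edge strictly reduces the feature count, so the
#' procedure terminates; the audit trail records clusters, p-values and
#' winners per iteration.
#'
#' @param table a \linkS4class{FeatureTable} or patients x features
#'   matrix.
#' @param labels binary labels with both classes present.
#' @param config a \code{\link{selectionConfig}}.
#' @param .pv precomputed association p-values (internal).
#' @return A \linkS4class{SelectionResult}.
#' @export
iterativeClusterSelect <- function(table, labels,
                                   config = selectionConfig(),
                                   .pv = NULL) {
    m <- asFeatureMatrixLike(table)
    if (ncol(m) < 1L) stop("need at least one feature")
    labels <- as.logical(labels)
    if (length(unique(labels)) < 2L)
        stop("labels must contain both classes")
    nms <- colnames(m)
    if (is.null(nms)) {
        nms <- as.character(seq_len(ncol(m)))
        colnames(m) <- nms
    }
    pv <- if (is.null(.pv))
        setNames(unname(columnAssociationPValues(m, labels)), nms)
    else .pv[nms]
    ranks <- columnRanks(m)
    current <- sort(nms)
    audit <- list()
    iterations <- 0L
    repeat {
        iterations <- iterations + 1L
        rho <- abs(spearmanMatrix(
            ranks = ranks[, current, drop = FALSE]))
        diag(rho) <- 0
        adj <- rho > config$clusterRho
        if (length(current) == 1L || !any(adj)) {
            audit[[iterations]] <- list(clusters = as.list(current),
                                        winners = current,
                                        pvalues = pv[current])
            break
        }
        comp <- connectedComponents(adj)
        clusters <- split(current, comp)
        winners <- vapply(clusters, function(members) {
            p <- pv[members]
            best <- members[p == min(p)]
            sort(best)[1]
        }, "")
        audit[[iterations]] <- list(clusters = clusters,
                                    winners = unname(winners),
                                    pvalues = pv[current])
        current <- sort(unname(winners))
    }
    new("SelectionResult", selected = current,
        iterations = iterations, audit = audit)
}

#' Full screening and selection chain
#'
#' Near-zero-variance filter, pairwise redundancy pruning, then the
#' iterative correlation-clustering selector.
#'
#' @inheritParams iterativeClusterSelect
#' @return A \linkS4class{SelectionResult} whose audit trail also
#'   records the feature counts surviving each screening step.
#' @export
selectFeatures <- function(table, labels, config = selectionConfig()) {
    m <- asFeatureMatrixLike(table)
    m1 <- asFeatureMatrixLike(nearZeroVarianceFilter(m, config))
    pv <- columnAssociationPValues(m1, labels)
    m2 <- asFeatureMatrixLike(
        pruneHighCorrelation(m1, labels, config$pruneRho, .pv = pv))
    res <- iterativeClusterSelect(m2, labels, config, .pv = pv)
    res@audit <- c(list(screening = list(
        input = ncol(m), afterNearZeroVariance = ncol(m1),
        afterCorrelationPruning = ncol(m2))), res@audit)
    res
}

#' Serialize a selection result to JSON
#'
#' @param result a \linkS4class{SelectionResult}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSelectionResult <- function(result, path) {
    jsonlite::write_json(
        list(selected = result@selected, iterations = result@iterations,
             audit = result@audit),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
    invisible(path)
}
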